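# Exon inclusion from junction-spanning reads: PSI, tissue aggregation,
# exon classification, isoform selection and the cryptic exonic-bin filters.
#
# Coordinate conventions: 0-based half-open intervals throughout; a splice
# junction is recorded as (donor, acceptor) with donor = last exonic base of
# the upstream exon and acceptor = first exonic base of the downstream exon.

#' Percent-spliced-in from junction read counts
#'
#' Computes the inclusion level of an internal exon from the number of
#' junction-spanning reads supporting its upstream junction (`up`), its
#' downstream junction (`down`) and the junction that skips it (`skip`):
#'
#' \deqn{PSI = 50 (up + down) / (skip + 0.5 (up + down))}
#'
#' The two inclusion junctions each span the exon once while a skipping read
#' spans it once in total, hence the factor 50 and the half-weighting of the
#' inclusion support in the denominator. PSI ranges from 0 (never included)
#' to 100 (always included).
#'
#' @param up,down,skip Non-negative read counts; vectors are recycled to a
#'   common length.
#' @return Numeric vector of PSI values in \[0, 100\]; `NA` where all three
#'   counts are zero (no information).
#' @examples
#' compute_psi(7, 9, 0)    # 100: no skipping reads
#' compute_psi(0, 0, 5)    # 0: no inclusion reads
#' compute_psi(10, 10, 10) # 50
#' @export
compute_psi <- function(up, down, skip) {
  n <- max(length(up), length(down), length(skip))
  up <- rep_len(as.numeric(up), n)
  down <- rep_len(as.numeric(down), n)
  skip <- rep_len(as.numeric(skip), n)
  bad <- !is.na(up + down + skip) & (up < 0 | down < 0 | skip < 0)
  if (any(bad)) stop("junction counts must be non-negative")
  inc <- up + down
  psi <- 50 * inc / (skip + 0.5 * inc)
  psi[inc == 0 & skip == 0] <- NA_real_
  psi
}

#' Count junction reads supporting an internal exon
#'
#' Tallies junction-spanning reads into upstream, downstream and skipping
#' support for one internal exon, requiring both mapped junction ends to lie
#' within a small grace window of the annotated splice sites. Exons without
#' both an upstream and a downstream partner are not internal and are
#' rejected.
#'
#' @param exon A list or one-row data frame with fields `contig`, `start`,
#'   `end` (0-based half-open) and `strand`.
#' @param upstream_end Last exonic base (0-based) of the upstream partner
#'   exon (the donor of the upstream junction on the + strand).
#' @param downstream_start First exonic base (0-based) of the downstream
#'   partner exon.
#' @param junctions Data frame with columns `contig`, `donor`, `acceptor`,
#'   `strand`, `count` (one row per distinct junction; see
#'   [read_junctions()]).
#' @param grace_nt Matching tolerance in nucleotides around each splice site
#'   (default 2).
#' @return Named numeric vector `c(up=, down=, skip=)`.
#' @export
match_junctions <- function(exon, upstream_end, downstream_start, junctions,
                            grace_nt = 2) {
  if (is.null(upstream_end) || is.null(downstream_start) ||
      is.na(upstream_end) || is.na(downstream_start)) {
    stop("internal exons require both upstream and downstream partner exons")
  }
  j <- junctions[junctions$contig == exon$contig &
                   junctions$strand == exon$strand, , drop = FALSE]
  near <- function(x, site) abs(x - site) <= grace_nt
  # exon splice sites in junction coordinates
  acc <- exon$start          # first exonic base
  don <- exon$end - 1        # last exonic base
  up_hit <- near(j$donor, upstream_end) & near(j$acceptor, acc)
  down_hit <- near(j$donor, don) & near(j$acceptor, downstream_start)
  skip_hit <- near(j$donor, upstream_end) & near(j$acceptor, downstream_start) &
    !up_hit & !down_hit
  c(up = sum(j$count[up_hit]),
    down = sum(j$count[down_hit]),
    skip = sum(j$count[skip_hit]))
}

#' Aggregate per-sample PSI within tissues
#'
#' Computes PSI per sample, then averages over the samples of each tissue.
#' A sample with no reads in any of the three junction classes carries no
#' information and is ignored; a tissue in which every sample is all-zero is
#' reported as `NA` ("data not available"), mirroring the rule used for
#' tissue-level absence.
#'
#' @param sample_counts Data frame with columns `sample`, `up`, `down`,
#'   `skip` (one row per sample).
#' @param tissue_map Named character vector mapping sample -> tissue; must
#'   cover every sample.
#' @return Named numeric vector of per-tissue PSI (percent), `NA` where the
#'   tissue has no informative sample.
#' @export
tissue_psi <- function(sample_counts, tissue_map) {
  miss <- setdiff(sample_counts$sample, names(tissue_map))
  if (length(miss)) {
    stop("tissue_map does not cover samples: ", paste(miss, collapse = ", "))
  }
  psi <- compute_psi(sample_counts$up, sample_counts$down, sample_counts$skip)
  tissue <- factor(tissue_map[as.character(sample_counts$sample)])
  out <- tapply(psi, tissue, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else mean(x)
  })
  setNames(as.numeric(out), levels(tissue))
}

#' Filter exons by read support and classify by average inclusion
#'
#' Keeps an exon only if it has enough junction evidence across all samples:
#' either the inclusion support, measured as the average of upstream and
#' downstream junction reads `sum(up + down) / 2`, or the skipping support
#' `sum(skip)` reaches `min_reads`. Exons inside blacklist regions (e.g. the
#' immunoglobulin loci, where repeat-derived exon annotation is unreliable)
#' are dropped regardless of counts. Surviving exons get an average PSI over
#' tissues -- excluding the configured promiscuously transcribed tissues --
#' and a class: constitutive (> upper bound), alternative (within bounds,
#' inclusive) or lowly_included (< lower bound).
#'
#' @param records Data frame with one row per exon: `exon_id`, `contig`,
#'   `start`, `end`, per-exon totals `sum_up`, `sum_down`, `sum_skip`, and
#'   per-tissue PSI columns named `psi.<tissue>`.
#' @param blacklist Optional `GRanges` (or data frame with `contig`, `start`,
#'   `end`) of regions to exclude.
#' @param min_reads Read-support threshold (default 200).
#' @param class_bounds Lower/upper PSI bounds in percent (default `c(15, 85)`).
#' @param excluded_tissues Tissues excluded from the average PSI (default
#'   testis, vagina and EBV-transformed lines).
#' @return The surviving rows of `records` with added columns `avg_psi` and
#'   `class`.
#' @export
filter_and_classify <- function(records, blacklist = NULL, min_reads = 200,
                                class_bounds = c(15, 85),
                                excluded_tissues = c("testis", "vagina", "EBV")) {
  keep <- (records$sum_up + records$sum_down) / 2 >= min_reads |
    records$sum_skip >= min_reads
  if (!is.null(blacklist)) {
    bl <- as_granges(blacklist)
    ex <- GenomicRanges::GRanges(records$contig,
                                 IRanges::IRanges(records$start + 1, records$end))
    keep <- keep & !IRanges::overlapsAny(ex, bl, ignore.strand = TRUE)
  }
  out <- records[keep, , drop = FALSE]
  psi_cols <- grep("^psi\\.", names(out), value = TRUE)
  use <- psi_cols[!sub("^psi\\.", "", psi_cols) %in% excluded_tissues]
  out$avg_psi <- apply(out[, use, drop = FALSE], 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else mean(x)
  })
  out$class <- ifelse(out$avg_psi > class_bounds[2], "constitutive",
                      ifelse(out$avg_psi < class_bounds[1], "lowly_included",
                             "alternative"))
  out
}

#' Summarize tissue inclusion of one exon
#'
#' Reports the maximum PSI, the spread between the most- and least-included
#' tissues, the number of tissues where the exon is detectable (PSI strictly
#' above `detect_pct`), and whether it is detected at all outside the
#' configured testis-like tissues.
#'
#' @param tissue_psis Named numeric vector of per-tissue PSI (may contain
#'   `NA`).
#' @param detect_pct Detectability threshold in percent (strict; default 5).
#' @param testis_like Tissues ignored by the detection flag (default
#'   `"testis"`).
#' @return List with `max_psi`, `max_minus_min_psi`, `n_detectable_tissues`,
#'   `detected_flag`; all `NA` when every tissue is `NA`.
#' @export
summarize_inclusion <- function(tissue_psis, detect_pct = 5,
                                testis_like = "testis") {
  ok <- !is.na(tissue_psis)
  if (!any(ok)) {
    return(list(max_psi = NA_real_, max_minus_min_psi = NA_real_,
                n_detectable_tissues = NA_integer_, detected_flag = NA))
  }
  x <- tissue_psis[ok]
  non_testis <- x[!names(x) %in% testis_like]
  list(max_psi = max(x),
       max_minus_min_psi = max(x) - min(x),
       n_detectable_tissues = sum(x > detect_pct),
       detected_flag = length(non_testis) > 0 && any(non_testis > detect_pct))
}

#' Choose a single inclusion isoform per exon
#'
#' When an exon is seen with several flanking-exon pairs, only one isoform is
#' allowed across tissues: the pair with the most junction reads wins. Ties
#' are broken deterministically by the smaller combined flanking-intron span,
#' then by leftmost upstream coordinate.
#'
#' @param candidates Data frame with one row per candidate pair: `reads`
#'   (total junction reads) and `intron_span` (combined flanking-intron
#'   length, nt), plus an `upstream_end` coordinate for the final tie-break.
#' @return The selected row of `candidates`.
#' @export
select_isoform <- function(candidates) {
  if (!nrow(candidates)) stop("no candidate isoforms")
  ord <- order(-candidates$reads, candidates$intron_span,
               candidates$upstream_end)
  candidates[ord[1], , drop = FALSE]
}

#' Filter exonic bins into cryptic / LINE-derived exon calls
#'
#' From flattened exonic bins with per-condition inclusion estimates: merges
#' neighbouring bins whose inclusion levels are equal in both conditions,
#' then keeps merged bins of at least `min_nt` nucleotides, supported by at
#' least `min_reads` reads, with inclusion strictly above `min_incl` percent
#' in the control or the test condition. Survivors that are not
#' coordinate-identical to a known exon are flagged cryptic; those with one
#' or both splice sites inside a LINE interval are flagged LINE-derived.
#'
#' @param bins Data frame of non-overlapping bins, sorted or not: `contig`,
#'   `start`, `end` (0-based half-open), `reads`, `incl_control`,
#'   `incl_test` (percent).
#' @param known_exons Data frame (`contig`, `start`, `end`) of annotated
#'   exons.
#' @param line_intervals Data frame (`contig`, `start`, `end`) of repeat
#'   annotations.
#' @param min_nt,min_reads,min_incl Filter thresholds (defaults 5 nt, 6
#'   reads, 15 percent; inclusion threshold strict).
#' @return Data frame of surviving merged exons with `cryptic` and
#'   `line_derived` logical columns.
#' @export
filter_exonic_bins <- function(bins, known_exons, line_intervals,
                               min_nt = 5, min_reads = 6, min_incl = 15) {
  if (!nrow(bins)) return(cbind(bins, cryptic = logical(0), line_derived = logical(0)))
  bins <- bins[order(bins$contig, bins$start), , drop = FALSE]
  ov <- with(bins, contig[-1] == contig[-nrow(bins)] &
               start[-1] < end[-nrow(bins)])
  if (any(ov)) stop("exonic bins must be non-overlapping")
  # merge runs of adjacent bins with identical inclusion in both conditions
  new_run <- c(TRUE, !(bins$contig[-1] == bins$contig[-nrow(bins)] &
                         bins$start[-1] == bins$end[-nrow(bins)] &
                         bins$incl_control[-1] == bins$incl_control[-nrow(bins)] &
                         bins$incl_test[-1] == bins$incl_test[-nrow(bins)]))
  run <- cumsum(new_run)
  merged <- data.frame(
    contig = tapply(bins$contig, run, `[`, 1),
    start = as.numeric(tapply(bins$start, run, min)),
    end = as.numeric(tapply(bins$end, run, max)),
    reads = as.numeric(tapply(bins$reads, run, sum)),
    incl_control = as.numeric(tapply(bins$incl_control, run, `[`, 1)),
    incl_test = as.numeric(tapply(bins$incl_test, run, `[`, 1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  keep <- (merged$end - merged$start) >= min_nt &
    merged$reads >= min_reads &
    (merged$incl_control > min_incl | merged$incl_test > min_incl)
  out <- merged[keep, , drop = FALSE]
  key <- function(d) paste(d$contig, d$start, d$end)
  out$cryptic <- !(key(out) %in% key(known_exons))
  out$line_derived <- vapply(seq_len(nrow(out)), function(i) {
    li <- line_intervals[line_intervals$contig == out$contig[i], , drop = FALSE]
    if (!nrow(li)) return(FALSE)
    ss_in <- function(pos) any(pos >= li$start & pos < li$end)
    ss_in(out$start[i]) || ss_in(out$end[i] - 1)
  }, logical(1))
  rownames(out) <- NULL
  out
}

# coerce a data.frame (contig/start/end, 0-based half-open) or GRanges to GRanges
as_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  GenomicRanges::GRanges(x$contig, IRanges::IRanges(x$start + 1, x$end))
}
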