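# Crosslink-track quantification: per-element coverage, relative binding
# scores with age-group enrichment, peak dependence classification,
# locus-normalized metaprofiles (RNA maps) and positional intron profiles.

#' Construct a crosslink track
#'
#' A strand-specific map from genomic position to cDNA (crosslink-event)
#' count for one RBP in one condition, as produced by iCLIP-style
#' protocols.
#'
#' @param positions Data frame with columns `contig`, `pos` (0-based),
#'   `strand`, `count` (positive); duplicate positions are summed.
#' @param rbp,condition Track labels.
#' @param library_size Total mapped cDNAs; defaults to `sum(count)`.
#' @return An object of class `crosslink_track`.
#' @export
crosslink_track <- function(positions, rbp = "RBP", condition = "control",
                            library_size = NULL) {
  stopifnot(all(c("contig", "pos", "strand", "count") %in% names(positions)))
  if (any(positions$count < 0)) stop("crosslink counts must be non-negative")
  key <- paste(positions$contig, positions$pos, positions$strand)
  if (anyDuplicated(key)) {
    agg <- rowsum(positions$count, key)
    first <- !duplicated(key)
    positions <- positions[first, c("contig", "pos", "strand"), drop = FALSE]
    positions$count <- as.numeric(agg[paste(positions$contig, positions$pos,
                                            positions$strand), 1])
  }
  positions <- positions[order(positions$contig, positions$pos), , drop = FALSE]
  rownames(positions) <- NULL
  structure(list(rbp = rbp, condition = condition, positions = positions,
                 library_size = if (is.null(library_size)) sum(positions$count)
                 else library_size),
            class = "crosslink_track")
}

#' @export
print.crosslink_track <- function(x, ...) {
  cat(sprintf("<crosslink_track> %s / %s: %d positions, %g cDNAs (library %g)\n",
              x$rbp, x$condition, nrow(x$positions),
              sum(x$positions$count), x$library_size))
  invisible(x)
}

#' Crosslink coverage of one element
#'
#' Counts crosslink cDNAs falling inside an element on its strand and
#' expresses them as density per 100 nt and as cDNAs per million library
#' cDNAs.
#'
#' @param track A [crosslink_track()].
#' @param element List or one-row data frame with `contig`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @return Named numeric vector `c(cdna = , per_100nt = , per_million = )`.
#' @export
element_coverage <- function(track, element) {
  p <- track$positions
  hit <- p$contig == element$contig & p$strand == element$strand &
    p$pos >= element$start & p$pos < element$end
  n <- sum(p$count[hit])
  len <- element$end - element$start
  c(cdna = n,
    per_100nt = if (len > 0) n / len * 100 else 0,
    per_million = if (track$library_size > 0) n / track$library_size * 1e6 else 0)
}

#' Relative RBP binding scores on top-decile elements
#'
#' Restricts to the 10% of elements with the highest crosslink coverage by
#' any RBP (a proxy for elements on expressed transcripts), then expresses
#' each RBP's coverage on an element relative to the summed coverage of all
#' RBPs there, giving a 0-1 score per element x RBP whose rows sum to 1.
#' Binding preference of an RBP for an age group is the mean score within
#' the group normalized to the mean across groups.
#'
#' @param elements Data frame with `element_id`, `contig`, `start`, `end`,
#'   `strand` and a grouping column (default `age_class`).
#' @param tracks List of [crosslink_track()] objects, one per RBP.
#' @param group_col Grouping column for the enrichment summary.
#' @param top_fraction Fraction of elements retained (default 0.10; ceiling,
#'   ties broken by element id).
#' @return List with `scores` (data frame: element_id, group, one score
#'   column per RBP) and `enrichment` (data frame: rbp, group, mean_score,
#'   enrichment ratio vs the across-group mean). Elements with zero total
#'   coverage inside the decile are dropped with a warning.
#' @export
relative_binding_scores <- function(elements, tracks, group_col = "age_class",
                                    top_fraction = 0.10) {
  if (!length(tracks)) stop("need at least one RBP track")
  if (!nrow(elements)) stop("element set is empty")
  rbps <- vapply(tracks, function(t) t$rbp, character(1))
  cov <- sapply(tracks, function(t) {
    vapply(seq_len(nrow(elements)), function(i) {
      element_coverage(t, elements[i, ])[["per_100nt"]]
    }, numeric(1))
  })
  cov <- matrix(cov, nrow = nrow(elements), dimnames = list(NULL, rbps))
  k <- ceiling(top_fraction * nrow(elements))
  best <- apply(cov, 1, max)
  ord <- order(-best, elements$element_id)
  idx <- ord[seq_len(k)]
  total <- rowSums(cov[idx, , drop = FALSE])
  zero <- total == 0
  if (any(zero)) {
    warning(sum(zero), " top-decile element(s) with zero total coverage excluded")
    idx <- idx[!zero]
    total <- total[!zero]
  }
  if (!length(idx)) stop("no scorable elements in the top decile")
  scores <- cov[idx, , drop = FALSE] / total
  df <- data.frame(element_id = elements$element_id[idx],
                   group = as.character(elements[[group_col]][idx]),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(scores))
  groups <- sort(unique(df$group))
  enr <- do.call(rbind, lapply(rbps, function(r) {
    gm <- vapply(groups, function(g) mean(scores[df$group == g, r]), numeric(1))
    data.frame(rbp = r, group = groups, mean_score = gm,
               enrichment = gm / mean(gm),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(scores = df, enrichment = enr)
}

#' Classify binding peaks by knockdown susceptibility
#'
#' Compares crosslink counts on a fixed set of binding peaks between a
#' control and a co-factor-depleted condition. Counts are normalized to the
#' mean library size, a pseudocount stabilizes the log2 fold change of
#' low-count peaks (a light-weight moderation in place of empirical-Bayes
#' shrinkage), and peaks are classified: `dependent` (LFC <= `dependent_lfc`,
#' i.e. binding collapses on depletion), `independent` (|LFC| <
#' `independent_lfc`), `remaining` otherwise; peaks whose mean normalized
#' count is below `min_count` are `excluded` as too variable to classify.
#'
#' @param peaks Data frame with `peak_id`, `control`, `depleted` raw counts.
#' @param control_lib,depleted_lib Library sizes (total mapped cDNAs);
#'   default to the column sums.
#' @param pseudocount Added to each normalized count (default 4).
#' @param dependent_lfc,independent_lfc Class cutoffs (defaults -1, 0.25).
#' @param min_count Minimum mean normalized count (default 8).
#' @return `peaks` with added `norm_control`, `norm_depleted`, `lfc`,
#'   `class` columns.
#' @export
classify_peak_dependence <- function(peaks, control_lib = NULL,
                                     depleted_lib = NULL, pseudocount = 4,
                                     dependent_lfc = -1, independent_lfc = 0.25,
                                     min_count = 8) {
  if (anyNA(peaks$control) || anyNA(peaks$depleted)) {
    stop("peak counts must be quantified in both conditions")
  }
  if (is.null(control_lib)) control_lib <- sum(peaks$control)
  if (is.null(depleted_lib)) depleted_lib <- sum(peaks$depleted)
  mean_lib <- mean(c(control_lib, depleted_lib))
  peaks$norm_control <- peaks$control / control_lib * mean_lib
  peaks$norm_depleted <- peaks$depleted / depleted_lib * mean_lib
  peaks$lfc <- log2((peaks$norm_depleted + pseudocount) /
                      (peaks$norm_control + pseudocount))
  mean_norm <- (peaks$norm_control + peaks$norm_depleted) / 2
  peaks$class <- ifelse(mean_norm < min_count, "excluded",
                        ifelse(peaks$lfc <= dependent_lfc, "dependent",
                               ifelse(abs(peaks$lfc) < independent_lfc,
                                      "independent", "remaining")))
  peaks
}

#' Locus-normalized binned metaprofile (RNA map)
#'
#' Aligns a window around a set of loci (oriented 5'->3' of the host gene),
#' marks at each relative position whether each locus carries signal --
#' a crosslink event for a count track, or interval overlap for an interval
#' track -- and averages the per-position percent occupancy within bins.
#' Normalization is to the number of input loci, so profiles of locus sets
#' of different sizes are comparable.
#'
#' @param loci Data frame with `contig`, `pos` (0-based anchor position) and
#'   `strand`; must be non-empty.
#' @param track A [crosslink_track()], or a data frame of intervals
#'   (`contig`, `start`, `end`, optionally `strand`) for sequence-content
#'   maps.
#' @param flank_nt Half-window size (default 2000); must be divisible by
#'   `bin_nt`.
#' @param bin_nt Smoothing bin (default 40).
#' @return Data frame `bin_start`, `bin_mid`, `occupancy_pct` with one row
#'   per bin; `bin_start` is the relative coordinate of the bin's 5' edge
#'   (negative = upstream of the locus).
#' @export
rna_map <- function(loci, track, flank_nt = 2000, bin_nt = 40) {
  if (!nrow(loci)) stop("locus set is empty")
  if (flank_nt %% bin_nt != 0) stop("flank_nt must be divisible by bin_nt")
  rel <- seq(-flank_nt, flank_nt - 1)
  occ <- matrix(0, nrow = nrow(loci), ncol = length(rel))
  for (i in seq_len(nrow(loci))) {
    lo <- loci[i, ]
    sgn <- if (identical(lo$strand, "-")) -1 else 1
    abs_pos <- lo$pos + sgn * rel  # genomic position of each relative offset
    if (inherits(track, "crosslink_track")) {
      p <- track$positions
      p <- p[p$contig == lo$contig & p$strand == lo$strand & p$count > 0, ]
      occ[i, ] <- abs_pos %in% p$pos
    } else {
      iv <- track[track$contig == lo$contig, , drop = FALSE]
      if ("strand" %in% names(iv)) iv <- iv[iv$strand == lo$strand, , drop = FALSE]
      if (nrow(iv)) {
        occ[i, ] <- vapply(abs_pos, function(x) {
          any(x >= iv$start & x < iv$end)
        }, logical(1))
      }
    }
  }
  per_pos <- colMeans(occ) * 100
  bin <- rep(seq_len(length(rel) / bin_nt), each = bin_nt)
  data.frame(bin_start = rel[!duplicated(bin)],
             bin_mid = rel[!duplicated(bin)] + bin_nt / 2,
             occupancy_pct = as.numeric(tapply(per_pos, bin, mean)))
}

#' Intron-length-matched control loci
#'
#' Draws control loci whose host-intron length distribution matches that of
#' the case loci, by stratified sampling within intron-length deciles of the
#' pool. Guards RNA-map comparisons against the confounding of binding with
#' intron length.
#'
#' @param case_lengths Intron lengths (nt) of the case loci.
#' @param pool Data frame of candidate control loci with an `intron_length`
#'   column.
#' @param n Number of controls (default `length(case_lengths)`).
#' @return Row indices into `pool`.
#' @export
match_control_loci <- function(case_lengths, pool, n = length(case_lengths)) {
  if (!nrow(pool)) stop("empty control pool")
  br <- unique(quantile(pool$intron_length, probs = seq(0, 1, 0.1)))
  strat_case <- cut(case_lengths, breaks = br, include.lowest = TRUE)
  strat_pool <- cut(pool$intron_length, breaks = br, include.lowest = TRUE)
  want <- round(table(strat_case) / length(case_lengths) * n)
  idx <- unlist(lapply(names(want), function(s) {
    cand <- which(strat_pool == s)
    if (!length(cand) || want[[s]] == 0) return(integer(0))
    cand[sample.int(length(cand), min(want[[s]], length(cand)))]
  }))
  as.integer(idx)
}

#' Classify intronic elements by distance to exons
#'
#' Labels each element `exon_proximal` if within `proximal_nt` of a
#' constitutively used exon, `deep_intronic` if more than `deep_nt` from any
#' exon, and `neither` otherwise. Distances are between closest interval
#' edges (0 if overlapping). Elements of at most `min_size_nt` nucleotides
#' are dropped before classification.
#'
#' @param elements Data frame with `element_id`, `contig`, `start`, `end`.
#' @param exons Data frame with `contig`, `start`, `end`, `class` (as from
#'   [filter_and_classify()]).
#' @param proximal_nt,deep_nt,min_size_nt Thresholds (defaults 500, 2000,
#'   100).
#' @return Data frame `element_id`, `dist_constitutive`, `dist_any`,
#'   `proximity`.
#' @export
classify_proximity <- function(elements, exons, proximal_nt = 500,
                               deep_nt = 2000, min_size_nt = 100) {
  el <- elements[elements$end - elements$start > min_size_nt, , drop = FALSE]
  edge_dist <- function(contig, s, e, set) {
    set <- set[set$contig == contig, , drop = FALSE]
    if (!nrow(set)) return(Inf)
    d <- pmax(set$start - e, s - set$end, 0)
    min(d)
  }
  d_const <- vapply(seq_len(nrow(el)), function(i) {
    edge_dist(el$contig[i], el$start[i], el$end[i],
              exons[exons$class == "constitutive", , drop = FALSE])
  }, numeric(1))
  d_any <- vapply(seq_len(nrow(el)), function(i) {
    edge_dist(el$contig[i], el$start[i], el$end[i], exons)
  }, numeric(1))
  data.frame(element_id = el$element_id,
             dist_constitutive = d_const, dist_any = d_any,
             proximity = ifelse(d_const <= proximal_nt, "exon_proximal",
                                ifelse(d_any > deep_nt, "deep_intronic",
                                       "neither")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Positional binding profile over long introns
#'
#' For introns of at least `min_intron_nt`, tallies the percentage of a
#' track's mapped cDNAs falling into distance bands from either splice
#' site: first 100 nt, 101-500, 501-2000 and 2001-5000 nt. The
#' deep-intronic rank of a track is based on the ratio of the deep band
#' (2001-5000 nt) to the first band.
#'
#' @param tracks List of [crosslink_track()] objects.
#' @param introns Data frame with `contig`, `start`, `end`, `strand`.
#' @param min_intron_nt Minimum intron size (default 7000).
#' @param bands Band edges in nt from the splice site (default
#'   `c(0, 100, 500, 2000, 5000)`).
#' @return Data frame with one row per track: `rbp`, percentage of the
#'   track's intronic reads per band (`band_0_100`, ...), mean read density
#'   per band position (`dens_0_100`, ...), `deep_to_first` density ratio
#'   and `rank` (1 = most deep-intronic); tracks with no reads in the
#'   analyzed introns are reported with zeros and `NA` rank.
#' @export
positional_binding_profile <- function(tracks, introns, min_intron_nt = 7000,
                                       bands = c(0, 100, 500, 2000, 5000)) {
  introns <- introns[introns$end - introns$start >= min_intron_nt, , drop = FALSE]
  if (!nrow(introns)) stop("no introns of sufficient size")
  nb <- length(bands) - 1
  # number of intron positions whose splice-site distance falls in [a, b)
  band_positions <- function(L, a, b) {
    vhi <- min(b - 1, (L - 1) %/% 2)
    if (vhi < a) return(0)
    n <- 2 * (vhi - a + 1)
    if (L %% 2 == 1 && (L - 1) / 2 <= vhi && (L - 1) / 2 >= a) n <- n - 1
    n
  }
  band_pos_total <- vapply(seq_len(nb), function(b) {
    sum(vapply(introns$end - introns$start, band_positions,
               numeric(1), a = bands[b], b = bands[b + 1]))
  }, numeric(1))
  rows <- lapply(tracks, function(t) {
    p <- t$positions
    band_counts <- numeric(nb)
    total <- 0
    for (i in seq_len(nrow(introns))) {
      iv <- introns[i, ]
      inside <- p$contig == iv$contig & p$strand == iv$strand &
        p$pos >= iv$start & p$pos < iv$end
      if (!any(inside)) next
      d5 <- p$pos[inside] - iv$start          # distance from left splice site
      d3 <- iv$end - 1 - p$pos[inside]        # distance from right splice site
      dmin <- pmin(d5, d3)
      cnt <- p$count[inside]
      total <- total + sum(cnt)
      for (b in seq_len(nb)) {
        sel <- dmin >= bands[b] & dmin < bands[b + 1]
        band_counts[b] <- band_counts[b] + sum(cnt[sel])
      }
    }
    pct <- if (total > 0) band_counts / total * 100 else rep(0, nb)
    dens <- ifelse(band_pos_total > 0, band_counts / band_pos_total, 0)
    c(setNames(pct, paste0("band_", bands[-length(bands)], "_", bands[-1])),
      setNames(dens, paste0("dens_", bands[-length(bands)], "_", bands[-1])),
      deep_to_first = if (total > 0 && dens[1] > 0) dens[nb] / dens[1]
      else if (total > 0) Inf else NA_real_,
      total = total)
  })
  out <- data.frame(rbp = vapply(tracks, function(t) t$rbp, character(1)),
                    do.call(rbind, rows), stringsAsFactors = FALSE,
                    row.names = NULL)
  ratable <- !is.na(out$deep_to_first)
  out$rank <- NA_integer_
  out$rank[ratable] <- rank(-out$deep_to_first[ratable], ties.method = "first")
  out
}
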