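# k-mer motif statistics on repeat sequences: occurrence and coverage,
# 100-nt multivalency windows, young-vs-old enrichment with an empirical
# FDR, ESE/ISS cumulative curves and degenerate splice-site search.

# normalize a motif or sequence to a DNA alphabet (RNA motifs use T for U)
as_dna <- function(x) {
  x <- toupper(as.character(x))
  chartr("U", "T", x)
}

# match positions of an IUPAC motif in a sequence; ambiguity codes are
# expanded in the pattern only, so N in the subject never matches
motif_matches <- function(sequence, motif) {
  sequence <- as_dna(sequence)
  motif <- as_dna(motif)
  if (nchar(motif) < 1) stop("motif must have length >= 1")
  if (nchar(sequence) < nchar(motif)) {
    return(IRanges::IRanges())
  }
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(sequence),
                                fixed = c(pattern = FALSE, subject = TRUE))
  methods::as(m, "IRanges")
}

#' Motif occurrences and covered fraction of a sequence
#'
#' Counts all (possibly overlapping) match start positions of a motif in a
#' sequence and the fraction of sequence positions inside at least one
#' match. IUPAC ambiguity codes in the motif are honoured (R = A/G,
#' Y = C/T, N = any); `N` in the sequence never matches. RNA motifs may be
#' given with `U`.
#'
#' @param sequence Character scalar over `{A,C,G,T,N}` (lower case and
#'   RNA `U` accepted).
#' @param motif Motif string, length >= 1.
#' @return Named list `count` (integer) and `covered_fraction` in \[0, 1\];
#'   `(0, 0)` for an empty sequence.
#' @examples
#' motif_occurrences("AAAA", "AA")  # count 3, coverage 1
#' @export
motif_occurrences <- function(sequence, motif) {
  if (!nchar(sequence)) return(list(count = 0L, covered_fraction = 0))
  hits <- motif_matches(sequence, motif)
  cov <- sum(IRanges::width(IRanges::reduce(hits)))
  list(count = length(hits),
       covered_fraction = cov / nchar(sequence))
}

#' Highest motif density in a sliding window
#'
#' Scans all windows of `window_nt` nucleotides and returns the largest
#' percentage of window positions covered by motif matches. Captures local
#' clustering ("multivalency") that a whole-element coverage average dilutes:
#' an element may carry a dense run of silencer motifs in one 100-nt stretch
#' and be otherwise devoid of them.
#'
#' @inheritParams motif_occurrences
#' @param window_nt Window size (default 100); sequences shorter than the
#'   window are scored as a single whole-sequence window.
#' @return Percent of window positions covered, in \[0, 100\].
#' @export
max_window_coverage <- function(sequence, motif, window_nt = 100) {
  len <- nchar(sequence)
  if (!len) return(0)
  hits <- motif_matches(sequence, motif)
  if (!length(hits)) return(0)
  covered <- integer(len)
  red <- IRanges::reduce(hits)
  for (i in seq_along(red)) {
    covered[IRanges::start(red)[i]:IRanges::end(red)[i]] <- 1L
  }
  w <- min(window_nt, len)
  cs <- cumsum(c(0L, covered))
  win_sums <- cs[(w + 1):(len + 1)] - cs[1:(len - w + 1)]
  100 * max(win_sums) / w
}

#' Multivalency call from window coverage
#'
#' Flags motif-dense elements: coverage of at least 10% of the best 100-nt
#' window (two pentamer/hexamer motifs) earns one dot, at least 20% two
#' dots. Thresholds are inclusive so that the canonical two-motif window
#' qualifies.
#'
#' @param max_window_coverage_pct Numeric vector of window coverages
#'   (percent).
#' @param pct_one,pct_two Dot thresholds (defaults 10 and 20).
#' @return Integer vector of dots in `{0, 1, 2}`.
#' @export
call_multivalent <- function(max_window_coverage_pct, pct_one = 10,
                             pct_two = 20) {
  ifelse(max_window_coverage_pct >= pct_two, 2L,
         ifelse(max_window_coverage_pct >= pct_one, 1L, 0L))
}

#' Top-decile motif elements and class enrichment
#'
#' Selects the 10% of elements with the highest window coverage for a motif
#' (ceiling of 0.10 N, ties broken by element id) and compares the age and
#' intron-position composition of the selected set with the expectation from
#' the full element set.
#'
#' @param profiles Data frame with columns `element_id`,
#'   `max_window_coverage_pct`, and one or more grouping columns (e.g.
#'   `age_class`, `proximity`).
#' @param group_cols Grouping columns to evaluate (default all columns other
#'   than id and coverage).
#' @param top_fraction Selected fraction (default 0.10).
#' @return List with `selected` (the flagged rows) and `enrichment`, a data
#'   frame of observed vs expected proportions and their ratio per group
#'   level.
#' @export
top_decile_motif_elements <- function(profiles, group_cols = NULL,
                                      top_fraction = 0.10) {
  if (is.null(group_cols)) {
    group_cols <- setdiff(names(profiles),
                          c("element_id", "max_window_coverage_pct"))
  }
  k <- ceiling(top_fraction * nrow(profiles))
  ord <- order(-profiles$max_window_coverage_pct, profiles$element_id)
  sel <- profiles[ord[seq_len(k)], , drop = FALSE]
  enr <- do.call(rbind, lapply(group_cols, function(col) {
    lev <- sort(unique(as.character(profiles[[col]])))
    obs <- vapply(lev, function(l) mean(sel[[col]] == l), numeric(1))
    exp <- vapply(lev, function(l) mean(profiles[[col]] == l), numeric(1))
    data.frame(group = col, level = lev, observed = obs, expected = exp,
               ratio = ifelse(exp > 0, obs / exp, NA_real_),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(selected = sel, enrichment = enr)
}

#' Rank motifs by young-vs-old coverage shift with empirical FDR
#'
#' For each motif, computes the per-element coverage per 100 nt (covered
#' fraction x 100) separately in evolutionarily young and old element
#' groups, restricted to elements in which the motif occurs, and ranks
#' motifs by the difference of group medians (young - old). The 2.5%
#' extremes of the empirical statistic distribution are flagged as motif
#' gain (upper tail) or loss (lower tail), an empirical FDR < 0.05 call.
#'
#' @param young_seqs,old_seqs Character vectors (or `DNAStringSet`) of
#'   element sequences.
#' @param motif_list Character vector of at least two motifs.
#' @param tail_fraction Flagged fraction per tail (default 0.025).
#' @return Data frame sorted by decreasing statistic: `motif`,
#'   `median_young`, `median_old`, `statistic`, `flag` in
#'   `{"gain", "loss", ""}`. Motifs absent from either group get `NA`
#'   statistics and are never flagged.
#' @export
rank_motif_enrichment <- function(young_seqs, old_seqs, motif_list,
                                  tail_fraction = 0.025) {
  if (length(motif_list) < 2) stop("need at least two motifs to rank")
  if (!length(young_seqs) || !length(old_seqs)) {
    stop("both element groups must be non-empty")
  }
  young_seqs <- as.character(young_seqs)
  old_seqs <- as.character(old_seqs)
  med_cov <- function(seqs, motif) {
    cov <- vapply(seqs, function(s) {
      motif_occurrences(s, motif)$covered_fraction * 100
    }, numeric(1), USE.NAMES = FALSE)
    cov <- cov[cov > 0]  # only elements in which the motif was found
    if (!length(cov)) NA_real_ else median(cov)
  }
  my <- vapply(motif_list, med_cov, numeric(1), seqs = young_seqs)
  mo <- vapply(motif_list, med_cov, numeric(1), seqs = old_seqs)
  stat <- my - mo
  out <- data.frame(motif = motif_list, median_young = my, median_old = mo,
                    statistic = stat, flag = "",
                    stringsAsFactors = FALSE, row.names = NULL)
  idx <- which(!is.na(stat))
  if (length(idx)) {
    k <- ceiling(tail_fraction * length(idx))
    ord <- idx[order(stat[idx], out$motif[idx])]   # ties broken by motif
    out$flag[utils::tail(ord, k)] <- "gain"
    out$flag[utils::head(ord, k)] <- "loss"
  }
  out[order(-out$statistic, out$motif, na.last = TRUE), , drop = FALSE]
}

#' Cumulative curves of splice-regulatory hexamer sets along a ranking
#'
#' Walks a hexamer enrichment ranking (most young-enriched first) and
#' reports, at each rank, the cumulative fraction of the exonic splice
#' enhancer (ESE) and intronic splice silencer (ISS) sets encountered so
#' far. If silencers are preferentially young-enriched their curve rises
#' earlier than the enhancer curve.
#'
#' @param ranked_motifs Character vector of hexamers in enrichment order.
#' @param ese_set,iss_set Character vectors of member hexamers; an empty set
#'   yields a flat zero curve.
#' @return Data frame `rank`, `motif`, `ese_cum`, `iss_cum` with cumulative
#'   fractions in \[0, 1\].
#' @export
ese_iss_cdf <- function(ranked_motifs, ese_set, iss_set) {
  cum_frac <- function(set) {
    if (!length(set)) return(rep(0, length(ranked_motifs)))
    cumsum(ranked_motifs %in% set) / length(set)
  }
  data.frame(rank = seq_along(ranked_motifs), motif = ranked_motifs,
             ese_cum = cum_frac(ese_set), iss_cum = cum_frac(iss_set),
             stringsAsFactors = FALSE)
}

#' Find degenerate splice-site consensus matches
#'
#' Searches a sequence (on its given strand) for the 5' splice-site
#' consensus `GGTRAG` and the 3' splice-site consensus `YYYYYYYYNNAGR`
#' (eight pyrimidines, two arbitrary bases, AG, one purine), with IUPAC
#' matching.
#'
#' @param sequence Character scalar.
#' @return List with integer vectors `five_prime` and `three_prime` of
#'   1-based match start positions.
#' @export
find_splice_site_consensus <- function(sequence) {
  list(five_prime = IRanges::start(motif_matches(sequence, "GGTRAG")),
       three_prime = IRanges::start(motif_matches(sequence, "YYYYYYYYNNAGR")))
}
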