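# Poly(A)-site analysis from 3'-end sequencing: internal-priming filter,
# proximal/distal site pairing per gene and LINE-proximal usage shifts.

#' Internal-priming filter for 3'-end reads
#'
#' Oligo-dT priming on genomic A-rich stretches produces false poly(A)
#' sites. A putative polyadenylation event is removed when the genomic
#' sequence in the 10 nt upstream and downstream (a 20-nt flank) contains a
#' run of six consecutive A nucleotides, or when any 10-nt window within
#' the flank has strictly more than 70% A (i.e. at least 8 of 10).
#'
#' @param flank Character vector of flanking sequences (nominally 20 nt;
#'   shorter flanks at contig ends are scanned as-is).
#' @param run_nt Disallowed homopolymer run length (default 6).
#' @param max_a_frac Maximum tolerated A fraction in any 10-nt window
#'   (default 0.70, strict inequality).
#' @param window_nt A-content window size (default 10).
#' @return Logical vector: `TRUE` = keep (genuine), `FALSE` = remove
#'   (internal-priming artifact).
#' @export
internal_priming_filter <- function(flank, run_nt = 6, max_a_frac = 0.70,
                                    window_nt = 10) {
  flank <- toupper(flank)
  run <- strrep("A", run_nt)
  vapply(flank, function(f) {
    if (grepl(run, f, fixed = TRUE)) return(FALSE)
    len <- nchar(f)
    if (len >= window_nt) {
      is_a <- as.integer(strsplit(f, "", fixed = TRUE)[[1]] == "A")
      cs <- cumsum(c(0L, is_a))
      win <- cs[(window_nt + 1):(len + 1)] - cs[1:(len - window_nt + 1)]
      if (any(win / window_nt > max_a_frac)) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

#' Pair proximal and distal poly(A) sites per gene
#'
#' Takes each gene's two highest-count sites; when both carry at least
#' `min_frac` of the gene's total 3'-end reads they are labelled `pA1`
#' (proximal) and `pA2` (distal) in the gene's transcription order,
#' otherwise every site of the gene stays `unpaired`.
#'
#' @param sites Data frame with columns `gene`, `pos`, `strand`, `count`
#'   (total reads per site).
#' @param min_frac Minimum per-site fraction of the gene total (default
#'   0.05).
#' @return `sites` with an added `role` column in
#'   `{"pA1", "pA2", "unpaired"}`.
#' @export
pair_polya_sites <- function(sites, min_frac = 0.05) {
  sites$role <- "unpaired"
  for (g in unique(sites$gene)) {
    i <- which(sites$gene == g)
    tot <- sum(sites$count[i])
    if (tot <= 0) stop("gene ", g, " has no 3'-end reads")
    if (length(i) < 2) next
    top2 <- i[order(-sites$count[i], sites$pos[i])][1:2]
    if (all(sites$count[top2] / tot >= min_frac)) {
      # proximal = first site in the gene's transcription direction
      minus <- identical(sites$strand[top2[1]], "-")
      genomic <- top2[order(sites$pos[top2])]
      sites$role[genomic] <- if (minus) c("pA2", "pA1") else c("pA1", "pA2")
    }
  }
  sites
}

#' Shift in proximal poly(A)-site usage between conditions
#'
#' For each paired gene, proximal usage is `pA1 / (pA1 + pA2)` in percent
#' per condition; the reported shift is depleted minus control, stratified
#' by whether the proximal site lies within 2 kb of a LINE.
#'
#' @param paired Data frame with one row per paired gene: `gene`,
#'   `control_pa1`, `control_pa2`, `depleted_pa1`, `depleted_pa2` read
#'   counts, and logical `line_within_2kb`.
#' @return List with `per_gene` (adds `use_control`, `use_depleted`,
#'   `delta`; `NA` where a condition has no reads on either site) and
#'   `strata` (mean and median delta per LINE-proximity stratum).
#' @export
proximal_usage_change <- function(paired) {
  use <- function(p1, p2) ifelse(p1 + p2 > 0, 100 * p1 / (p1 + p2), NA_real_)
  paired$use_control <- use(paired$control_pa1, paired$control_pa2)
  paired$use_depleted <- use(paired$depleted_pa1, paired$depleted_pa2)
  paired$delta <- paired$use_depleted - paired$use_control
  strata <- do.call(rbind, lapply(c(TRUE, FALSE), function(fl) {
    d <- paired$delta[paired$line_within_2kb == fl & !is.na(paired$delta)]
    data.frame(line_within_2kb = fl, n = length(d),
               mean_delta = if (length(d)) mean(d) else NA_real_,
               median_delta = if (length(d)) median(d) else NA_real_)
  }))
  list(per_gene = paired, strata = strata)
}

#' Flag poly(A) sites near LINE elements
#'
#' @param sites Data frame with `contig` and `pos` (0-based site position).
#' @param line_elements Data frame with `contig`, `start`, `end`.
#' @param window_nt Proximity window (default 2000); a site inside a LINE
#'   or with its nearest LINE edge at most `window_nt` away is flagged.
#' @return Logical vector `line_within_2kb` parallel to `sites`.
#' @export
annotate_line_proximity <- function(sites, line_elements, window_nt = 2000) {
  vapply(seq_len(nrow(sites)), function(i) {
    li <- line_elements[line_elements$contig == sites$contig[i], , drop = FALSE]
    if (!nrow(li)) return(FALSE)
    pos <- sites$pos[i]
    inside <- pos >= li$start & pos < li$end
    if (any(inside)) return(TRUE)
    d <- pmin(abs(li$start - pos), abs(pos - (li$end - 1)))
    min(d) <= window_nt
  }, logical(1))
}
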