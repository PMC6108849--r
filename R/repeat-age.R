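# Phylogenetic age classification of LINE copies from curated liftover
# ortholog-presence records, plus divergence summaries.

AGE_CLASSES <- c("primate_specific", "euarchontoglires_specific",
                 "one_distant", "two_distant", "degenerate", "unclear")
ORTHOLOG_STATUSES <- c("present", "degenerate", "notLINE", "absent")

#' Default species roles for age classification
#'
#' The six query species used when tracing a human LINE copy through the
#' mammalian phylogeny, grouped by clade role: two primates, two glires
#' (mouse-like rodents) and two laurasiatherians (distant outgroups).
#'
#' @return Named list with character vectors `primates`, `glires`,
#'   `laurasiatherians`.
#' @export
default_species_sets <- function() {
  list(primates = c("gorilla", "rhesus"),
       glires = c("mouse", "rat"),
       laurasiatherians = c("dog", "cow"))
}

#' Curate a raw liftover outcome into an ortholog status
#'
#' A lifted position only counts as a conserved LINE if enough of it is
#' LINE-derived in the target genome: `lifted` with at least 33% repeat
#' overlap is `present`, `lifted` below that is `notLINE` (the locus exists
#' but the repeat does not), `partially_deleted` is `degenerate`, and
#' `deleted` is `absent`.
#'
#' @param lift_outcome Character vector over
#'   `{"lifted", "partially_deleted", "deleted"}`.
#' @param line_overlap_fraction Fraction in \[0, 1\] of the lifted interval
#'   annotated as LINE; only consulted where `lift_outcome == "lifted"`.
#' @param min_overlap Presence threshold (default 0.33, compared with `>=`).
#' @return Character vector of statuses in
#'   `{"present", "degenerate", "notLINE", "absent"}`.
#' @export
curate_liftover_status <- function(lift_outcome, line_overlap_fraction = NA,
                                   min_overlap = 0.33) {
  n <- length(lift_outcome)
  frac <- rep_len(line_overlap_fraction, n)
  ok <- lift_outcome %in% c("lifted", "partially_deleted", "deleted")
  if (!all(ok)) {
    stop("unknown lift outcome: ", paste(unique(lift_outcome[!ok]), collapse = ", "))
  }
  if (any(lift_outcome == "lifted" & is.na(frac))) {
    stop("line_overlap_fraction required for lifted elements")
  }
  out <- rep(NA_character_, n)
  out[lift_outcome == "deleted"] <- "absent"
  out[lift_outcome == "partially_deleted"] <- "degenerate"
  lifted <- lift_outcome == "lifted"
  out[lifted] <- ifelse(frac[lifted] >= min_overlap, "present", "notLINE")
  out
}

#' Classify a LINE copy into a phylogenetic age class
#'
#' Applies a fixed decision table to the per-species ortholog statuses of one
#' or more elements. Rules are tested in order and the first match wins:
#'
#' 1. `primate_specific`: absent in all six species, or seen (present,
#'    degenerate or notLINE) in at least one primate while absent-or-notLINE
#'    in every non-primate species.
#' 2. `euarchontoglires_specific`: absent-or-notLINE in both laurasiatherians
#'    and present-or-degenerate in mouse or rat.
#' 3. `two_distant`: present in both laurasiatherians.
#' 4. `one_distant`: present in exactly one laurasiatherian while the other
#'    is absent-or-notLINE.
#' 5. `degenerate`: degenerate in both laurasiatherians.
#' 6. `unclear` otherwise (e.g. degenerate in one outgroup, absent in the
#'    other); such elements are ignored in phylogenetic comparisons.
#'
#' @param statuses A named character vector (one element) or a data frame /
#'   matrix with one column per species and one row per element; every
#'   configured species must be present.
#' @param species_sets Clade roles, see [default_species_sets()].
#' @return Character vector of age-class labels.
#' @export
classify_age <- function(statuses, species_sets = default_species_sets()) {
  if (is.null(dim(statuses))) statuses <- t(as.matrix(statuses))
  statuses <- as.matrix(statuses)
  all_species <- unlist(species_sets, use.names = FALSE)
  miss <- setdiff(all_species, colnames(statuses))
  if (length(miss)) stop("missing species: ", paste(miss, collapse = ", "))
  bad <- !statuses[, all_species] %in% ORTHOLOG_STATUSES
  if (any(bad)) stop("invalid ortholog status")

  prim <- statuses[, species_sets$primates, drop = FALSE]
  glir <- statuses[, species_sets$glires, drop = FALSE]
  laur <- statuses[, species_sets$laurasiatherians, drop = FALSE]
  nonprim <- cbind(glir, laur)

  row_all <- function(m, set) apply(m, 1, function(x) all(x %in% set))
  row_any <- function(m, set) apply(m, 1, function(x) any(x %in% set))

  r1 <- row_all(statuses[, all_species, drop = FALSE], "absent") |
    (row_any(prim, c("present", "degenerate", "notLINE")) &
       row_all(nonprim, c("absent", "notLINE")))
  r2 <- row_all(laur, c("absent", "notLINE")) &
    row_any(glir, c("present", "degenerate"))
  n_laur_present <- rowSums(laur == "present")
  r3 <- n_laur_present == 2
  r4 <- n_laur_present == 1 &
    row_all(laur, c("present", "absent", "notLINE"))
  r5 <- row_all(laur, "degenerate")

  out <- rep("unclear", nrow(statuses))
  out[r5] <- "degenerate"
  out[r4] <- "one_distant"
  out[r3] <- "two_distant"
  out[r2] <- "euarchontoglires_specific"
  out[r1] <- "primate_specific"
  out
}

#' Classify every element of an ortholog-presence table
#'
#' Long-format convenience wrapper around [classify_age()].
#'
#' @param ortholog_table Data frame with columns `element_id`, `species`,
#'   `status` (long format, one row per element x species).
#' @param species_sets Clade roles, see [default_species_sets()].
#' @return Data frame with columns `element_id`, `age_class`.
#' @export
classify_age_table <- function(ortholog_table,
                               species_sets = default_species_sets()) {
  wide <- tapply(ortholog_table$status,
                 list(ortholog_table$element_id, ortholog_table$species),
                 `[`, 1)
  if (anyNA(wide)) stop("every element needs a status for every species")
  data.frame(element_id = rownames(wide),
             age_class = classify_age(wide, species_sets),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Divergence distribution per age class
#'
#' Summarizes RepeatMasker milliDiv (substitutions per kb relative to the
#' family consensus, a proxy for copy age) within each phylogenetic age
#' class. Evolutionarily young classes are expected to show lower divergence.
#'
#' @param elements Data frame with columns `age_class` and `milli_div`.
#' @param probs Quantiles reported alongside the median (default quartiles).
#' @return Data frame with one row per non-empty class: `age_class`, `n`,
#'   `median`, and one column per requested quantile. Empty input yields an
#'   empty table with a warning.
#' @export
divergence_summary <- function(elements, probs = c(0.25, 0.75)) {
  if (!nrow(elements) || all(is.na(elements$milli_div))) {
    warning("no elements with divergence values")
    return(data.frame(age_class = character(0), n = integer(0),
                      median = numeric(0)))
  }
  grp <- split(elements$milli_div, elements$age_class)
  rows <- lapply(names(grp), function(g) {
    x <- grp[[g]][!is.na(grp[[g]])]
    q <- quantile(x, probs = probs, names = FALSE)
    cbind(data.frame(age_class = g, n = length(x), median = median(x),
                     stringsAsFactors = FALSE),
          setNames(as.data.frame(t(q)), paste0("q", probs * 100)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
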