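# Readers and writers for the external formats the pipeline touches.
# BED (0-based half-open) is the interchange interval format; RepeatMasker
# .out and other 1-based inputs are converted at the boundary.

#' Read a RepeatMasker .out annotation table
#'
#' Parses the standard whitespace-delimited RepeatMasker output (three
#' header lines, 15 columns, optionally a trailing asterisk column),
#' converting 1-based inclusive coordinates to 0-based half-open and the
#' `C` strand code to `-`. milliDiv is the "perc div." column times 10.
#'
#' @param path File path.
#' @param classes Repeat classes to keep, matched against the prefix of the
#'   class/family column (default LINE; use `NULL` to keep everything).
#' @return Data frame: `element_id`, `contig`, `start`, `end`, `strand`,
#'   `family`, `class_family`, `milli_div`, `score`.
#' @export
read_repeatmasker <- function(path, classes = "LINE") {
  lines <- readLines(path)
  if (length(lines) > 3) lines <- lines[-(1:3)] else lines <- character(0)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(element_id = character(0), contig = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), family = character(0),
                      class_family = character(0), milli_div = numeric(0),
                      score = numeric(0)))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  bad <- which(nf < 14)
  if (length(bad)) {
    stop("malformed RepeatMasker row at line ", bad[1] + 3,
         ": expected >=14 columns, found ", nf[bad[1]])
  }
  get <- function(k) vapply(fields, `[`, character(1), k)
  out <- data.frame(
    element_id = paste0("rm", seq_along(fields)),
    contig = get(5),
    start = as.numeric(get(6)) - 1,       # 1-based inclusive -> 0-based
    end = as.numeric(get(7)),
    strand = ifelse(get(9) == "C", "-", get(9)),
    family = get(10),
    class_family = get(11),
    milli_div = as.numeric(get(2)) * 10,  # perc div -> per 1000 nt
    score = as.numeric(get(1)),
    stringsAsFactors = FALSE)
  if (!is.null(classes)) {
    keep <- Reduce(`|`, lapply(classes, function(cl) {
      startsWith(out$class_family, cl)
    }))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a junction-count table
#'
#' TSV with columns `sample`, `contig`, `donor`, `acceptor`, `strand`,
#' `count`; rows with identical keys are summed. Comment lines starting
#' with `#` are skipped.
#'
#' @param path File path.
#' @return Data frame with one row per distinct junction per sample.
#' @export
read_junctions <- function(path) {
  cols <- c("sample", "contig", "donor", "acceptor", "strand", "count")
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!nrow(df)) {
    return(setNames(data.frame(character(0), character(0), numeric(0),
                               numeric(0), character(0), numeric(0)), cols))
  }
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("junction table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$count < 0)) stop("junction counts must be non-negative")
  key <- paste(df$sample, df$contig, df$donor, df$acceptor, df$strand)
  agg <- rowsum(df$count, key)
  first <- df[!duplicated(key), cols, drop = FALSE]
  first$count <- as.numeric(agg[paste(first$sample, first$contig, first$donor,
                                      first$acceptor, first$strand), 1])
  first <- first[order(first$sample, first$contig, first$donor,
                       first$acceptor), , drop = FALSE]
  rownames(first) <- NULL
  first
}

#' Read an ortholog-presence table
#'
#' TSV with columns `element_id`, `species`, `lift_outcome`,
#' `overlap_fraction`; curated statuses are derived with
#' [curate_liftover_status()] unless a `status` column is already present.
#'
#' @param path File path.
#' @return Long data frame with a `status` column.
#' @export
read_ortholog_table <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"status" %in% names(df)) {
    df$status <- curate_liftover_status(df$lift_outcome, df$overlap_fraction)
  }
  df
}

# polynomial rolling hash (mod 2^31 - 1) of a character representation,
# for provenance lines
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_tsv_with_header <- function(df, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_hash=", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a bedGraph track
#'
#' One four-column bedGraph file (0-based half-open single-nucleotide
#' intervals) per crosslink track, with a track definition line naming the
#' RBP, condition and strand.
#'
#' @param track A [crosslink_track()].
#' @param path Output file.
#' @export
write_bedgraph <- function(track, path) {
  p <- track$positions
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s_%s_%s"',
                     track$rbp, track$condition,
                     if (nrow(p)) p$strand[1] else "+"), con)
  if (nrow(p)) {
    write.table(data.frame(p$contig, p$pos, p$pos + 1, p$count), con,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
}

#' Write the synthetic bundle and analysis results to a directory
#'
#' Emits the fixture in its on-disk formats -- FASTA element sequences
#' (via Biostrings), BED6 elements and exons (via rtracklayer), TSV
#' ortholog and truth tables -- plus any result data frames passed in
#' `results`, each as a TSV with a header and a provenance comment line
#' carrying a hash of the generating configuration. Output ordering is
#' deterministic (sorted by contig and start), so identical inputs give
#' byte-identical files.
#'
#' @param bundle A [generate_fixture()] output (or `NULL` to write results
#'   only).
#' @param results Named list of data frames written as `<name>.tsv`.
#' @param out_dir Output directory, created if needed.
#' @param tracks Optional named list of [crosslink_track()]s written as
#'   bedGraph.
#' @return Invisibly, the written file paths.
#' @export
write_outputs <- function(bundle = NULL, results = list(), out_dir,
                          tracks = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop("cannot write to output directory: ", out_dir)
  }
  written <- character(0)
  hash <- if (!is.null(bundle)) config_hash(unclass(bundle$config)) else
    config_hash(results)
  emit_tsv <- function(df, name) {
    if (all(c("contig", "start") %in% names(df))) {
      df <- df[order(df$contig, df$start), , drop = FALSE]
    }
    p <- file.path(out_dir, paste0(name, ".tsv"))
    write_tsv_with_header(df, p, hash)
    written <<- c(written, p)
  }
  if (!is.null(bundle)) {
    seqs <- Biostrings::DNAStringSet(bundle$sequences)
    fa <- file.path(out_dir, "elements.fa")
    Biostrings::writeXStringSet(seqs, fa)
    written <- c(written, fa)
    bed_of <- function(df, name_col) {
      GenomicRanges::GRanges(df$contig,
                             IRanges::IRanges(df$start + 1, df$end),
                             strand = df$strand,
                             name = df[[name_col]], score = 0)
    }
    el_bed <- file.path(out_dir, "elements.bed")
    rtracklayer::export(bed_of(bundle$elements, "element_id"), el_bed,
                        format = "BED")
    ex_bed <- file.path(out_dir, "exons.bed")
    rtracklayer::export(bed_of(bundle$exons, "exon_id"), ex_bed,
                        format = "BED")
    written <- c(written, el_bed, ex_bed)
    emit_tsv(bundle$orthologs, "orthologs")
    emit_tsv(bundle$elements, "elements")
    truth <- data.frame(exon_id = rownames(bundle$psi_table),
                        bundle$psi_table, check.names = FALSE)
    emit_tsv(truth, "planted_psi")
  }
  for (nm in names(results)) emit_tsv(results[[nm]], nm)
  for (nm in names(tracks)) {
    p <- file.path(out_dir, paste0("track_", nm, ".bedgraph"))
    write_bedgraph(tracks[[nm]], p)
    written <- c(written, p)
  }
  invisible(written)
}
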