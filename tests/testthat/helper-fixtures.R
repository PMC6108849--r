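# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no binary fixtures on disk.

small_config <- function(seed = 11, n_genes = 12, n_lines = 60, ...) {
  syn_config(seed = seed, n_genes = n_genes, n_lines = n_lines, n_tissues = 3,
             samples_per_tissue = 3, read_depth = 40, ...)
}

small_bundle <- function(seed = 11, ...) {
  generate_fixture(small_config(seed = seed, ...))
}

# brute-force per-position motif coverage marking (oracle for the
# interval-union implementation)
brute_motif_cover <- function(sequence, motif) {
  L <- nchar(sequence); k <- nchar(motif)
  covered <- logical(L)
  count <- 0L
  if (L >= k) {
    for (i in 1:(L - k + 1)) {
      if (substr(sequence, i, i + k - 1) == motif) {
        count <- count + 1L
        covered[i:(i + k - 1)] <- TRUE
      }
    }
  }
  list(count = count, covered = covered)
}

# brute-force O(L*W) sliding-window coverage maximum (oracle)
brute_max_window <- function(sequence, motif, window = 100) {
  L <- nchar(sequence)
  covered <- brute_motif_cover(sequence, motif)$covered
  w <- min(window, L)
  best <- 0
  for (s in 1:(L - w + 1)) {
    best <- max(best, sum(covered[s:(s + w - 1)]))
  }
  100 * best / w
}

# brute-force internal-priming rule: any 6-A run or any 10-nt window with
# more than 7 A's anywhere in the flank
brute_priming_keep <- function(flank) {
  ch <- strsplit(flank, "")[[1]]
  L <- length(ch)
  runs <- rle(ch)
  if (any(runs$values == "A" & runs$lengths >= 6)) return(FALSE)
  if (L >= 10) {
    for (s in 1:(L - 9)) {
      if (sum(ch[s:(s + 9)] == "A") / 10 > 0.7) return(FALSE)
    }
  }
  TRUE
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
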