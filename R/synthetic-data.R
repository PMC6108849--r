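# Seeded synthetic-data generator. Emulates the statistical structure of the
# study inputs -- intronic LINE copies of known phylogenetic age with
# divergence-scaled sequences, junction-read tables around planted PSI
# values, strand-specific crosslink tracks with age-dependent RBP
# enrichment, and 3'-end reads with labelled internal-priming artifacts --
# so that every downstream stage can be checked against a planted truth.

#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the generator with validation. The defaults
#' describe the study conditions the package is exercised under: an age
#' mixture matching the relative sizes of the phylogenetic L1 classes in the
#' human genome, divergence rates increasing with age, and a repressor RBP
#' enriched four-fold on evolutionarily young elements.
#'
#' @param seed Integer root seed; each generator draws from its own
#'   substream derived from it, so adding one generator does not shift the
#'   others.
#' @param n_genes Number of host genes (one cassette exon each).
#' @param intron_length Log-normal `c(meanlog, sdlog)` of intron lengths in
#'   nt.
#' @param n_lines Number of LINE copies placed into introns.
#' @param age_mixture Named proportions over the five age classes; must sum
#'   to 1.
#' @param divergence_by_age Per-class substitution rate (fraction of sites)
#'   applied to the consensus when generating element sequences.
#' @param n_tissues,samples_per_tissue Tissue panel dimensions.
#' @param read_depth Mean junction reads per exon per sample.
#' @param planted_psi_table Optional exon x tissue matrix of PSI targets in
#'   percent; drawn uniformly on \[0, 100\] when `NULL`.
#' @param rbp_set Named character vector mapping RBP name ->
#'   `"repressor"`/`"enhancer"`.
#' @param repressor_enrichment_on_young Fold enrichment of repressor
#'   crosslink density on young vs old elements (enhancers get the
#'   inverse preference).
#' @param clip_density Baseline crosslink density (cDNAs per nt) on
#'   unenriched elements; 0 yields empty tracks.
#' @param motif_plant List `motif`, `copies`, `spacing` describing the
#'   silencer-motif run planted into young element sequences.
#' @param priming_artifact_rate Fraction of synthetic 3'-end reads placed at
#'   A-rich loci (internal-priming artifacts), in \[0, 1\].
#' @param consensus_length Length of the synthetic LINE consensus (nt).
#' @return A validated list of class `syn_config`.
#' @export
syn_config <- function(seed = 1L,
                       n_genes = 60,
                       intron_length = c(meanlog = log(4000), sdlog = 0.6),
                       n_lines = 500,
                       age_mixture = c(primate_specific = 0.595,
                                       euarchontoglires_specific = 0.050,
                                       one_distant = 0.147,
                                       two_distant = 0.038,
                                       degenerate = 0.170),
                       divergence_by_age = c(primate_specific = 0.05,
                                             euarchontoglires_specific = 0.12,
                                             one_distant = 0.18,
                                             two_distant = 0.25,
                                             degenerate = 0.30),
                       n_tissues = 5,
                       samples_per_tissue = 4,
                       read_depth = 50,
                       planted_psi_table = NULL,
                       rbp_set = c(MATR3 = "repressor", PTBP1 = "repressor",
                                   SRSF1 = "enhancer"),
                       repressor_enrichment_on_young = 4,
                       clip_density = 0.02,
                       motif_plant = list(motif = "CTCTT", copies = 8,
                                          spacing = 10),
                       priming_artifact_rate = 0.3,
                       consensus_length = 6000) {
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              intron_length = intron_length, n_lines = n_lines,
              age_mixture = age_mixture,
              divergence_by_age = divergence_by_age, n_tissues = n_tissues,
              samples_per_tissue = samples_per_tissue,
              read_depth = read_depth,
              planted_psi_table = planted_psi_table, rbp_set = rbp_set,
              repressor_enrichment_on_young = repressor_enrichment_on_young,
              clip_density = clip_density, motif_plant = motif_plant,
              priming_artifact_rate = priming_artifact_rate,
              consensus_length = consensus_length)
  validate_syn_config(cfg)
  structure(cfg, class = "syn_config")
}

validate_syn_config <- function(cfg) {
  if (abs(sum(cfg$age_mixture) - 1) > 1e-9) {
    stop("age_mixture must sum to 1")
  }
  counts <- c(cfg$n_genes, cfg$n_lines, cfg$n_tissues, cfg$samples_per_tissue)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (cfg$read_depth < 0) stop("read_depth must be non-negative")
  if (!is.null(cfg$planted_psi_table) &&
      (any(cfg$planted_psi_table < 0) || any(cfg$planted_psi_table > 100))) {
    stop("planted PSI values must lie in [0, 100]")
  }
  if (cfg$priming_artifact_rate < 0 || cfg$priming_artifact_rate > 1) {
    stop("priming_artifact_rate must lie in [0, 1]")
  }
  miss <- setdiff(names(cfg$age_mixture), names(cfg$divergence_by_age))
  if (length(miss)) stop("divergence_by_age missing classes: ",
                         paste(miss, collapse = ", "))
  invisible(cfg)
}

# independent substream per generator component, derived from the root seed
component_seed <- function(cfg, component) {
  (as.numeric(cfg$seed) * 7919 + component * 104729) %% 2147483647
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# iid substitution of a fraction `rate` of positions to a different base
mutate_sequence <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

# ortholog status template that classify_age() maps back to the true label
age_status_template <- function(age_class) {
  switch(age_class,
    primate_specific = c(gorilla = "present", rhesus = "absent",
                         mouse = "absent", rat = "absent",
                         dog = "absent", cow = "absent"),
    euarchontoglires_specific = c(gorilla = "present", rhesus = "present",
                                  mouse = "present", rat = "absent",
                                  dog = "absent", cow = "absent"),
    one_distant = c(gorilla = "present", rhesus = "present",
                    mouse = "present", rat = "present",
                    dog = "present", cow = "absent"),
    two_distant = c(gorilla = "present", rhesus = "present",
                    mouse = "present", rat = "present",
                    dog = "present", cow = "present"),
    degenerate = c(gorilla = "present", rhesus = "present",
                   mouse = "present", rat = "present",
                   dog = "degenerate", cow = "degenerate"),
    stop("unknown age class: ", age_class)
  )
}

#' Generate the synthetic annotation bundle
#'
#' Builds the full fixture: host-gene models with cassette exons, intronic
#' LINE copies with true age labels, element sequences derived from a single
#' synthetic consensus by iid substitution at the class divergence rate
#' (young elements additionally carry planted silencer-motif runs), a
#' liftover-style ortholog-presence table consistent with each true age, and
#' the planted PSI table.
#'
#' @param config A [syn_config()].
#' @return A list of class `syn_bundle`: `config`, `consensus`, `genes`,
#'   `exons`, `elements`, `sequences` (named character vector), `orthologs`
#'   (long data frame with curated statuses), `psi_table` (exon x tissue,
#'   percent), `tissues`, `samples` (sample -> tissue map).
#' @export
generate_fixture <- function(config) {
  validate_syn_config(config)
  set.seed(component_seed(config, 1))
  consensus <- random_dna(config$consensus_length)

  # gene models: flank exon - intron - cassette exon - intron - flank exon
  flank_w <- 200; cassette_w <- 120; gap <- 10000
  i1 <- pmax(600, round(rlnorm(config$n_genes, config$intron_length[["meanlog"]],
                               config$intron_length[["sdlog"]])))
  i2 <- pmax(600, round(rlnorm(config$n_genes, config$intron_length[["meanlog"]],
                               config$intron_length[["sdlog"]])))
  span <- 2 * flank_w + cassette_w + i1 + i2
  gstart <- cumsum(c(0, head(span + gap, -1)))
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  genes <- data.frame(
    gene = sprintf("gene%03d", seq_len(config$n_genes)), contig = "chrS",
    start = gstart, end = gstart + span, strand = strand,
    intron1_length = i1, intron2_length = i2, stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_len(config$n_genes), function(g) {
    s <- gstart[g]
    e1 <- c(s, s + flank_w)
    ca <- c(e1[2] + i1[g], e1[2] + i1[g] + cassette_w)
    e2 <- c(ca[2] + i2[g], ca[2] + i2[g] + flank_w)
    data.frame(gene = genes$gene[g], contig = "chrS",
               start = c(e1[1], ca[1], e2[1]), end = c(e1[2], ca[2], e2[2]),
               strand = genes$strand[g],
               role = c("flank_left", "cassette", "flank_right"),
               stringsAsFactors = FALSE)
  }))
  exons$exon_id <- sprintf("%s_%s", exons$gene, exons$role)

  # LINE copies dropped into introns, mostly antisense to the host gene
  age <- sample(names(config$age_mixture), config$n_lines, replace = TRUE,
                prob = config$age_mixture)
  host <- sample.int(config$n_genes, config$n_lines, replace = TRUE)
  which_intron <- sample(1:2, config$n_lines, replace = TRUE)
  ilen <- ifelse(which_intron == 1, i1[host], i2[host])
  elen <- pmin(pmax(150, round(rlnorm(config$n_lines, log(600), 0.5))),
               ilen - 40, 3000)
  istart <- ifelse(which_intron == 1,
                   gstart[host] + flank_w,
                   gstart[host] + flank_w + i1[host] + cassette_w)
  offset <- floor(runif(config$n_lines, 20, ilen - elen - 19))
  antisense <- runif(config$n_lines) < 0.7
  estrand <- ifelse(antisense, ifelse(strand[host] == "+", "-", "+"),
                    strand[host])
  elements <- data.frame(
    element_id = sprintf("L1_%04d", seq_len(config$n_lines)), contig = "chrS",
    start = istart + offset, end = istart + offset + elen, strand = estrand,
    family = "L1", gene = genes$gene[host], intron_index = which_intron,
    age_class = age, stringsAsFactors = FALSE)

  # sequences: consensus fragment + iid substitutions at the class rate;
  # young elements get a planted run of silencer motifs
  mp <- config$motif_plant
  seqs <- character(config$n_lines)
  for (i in seq_len(config$n_lines)) {
    off <- sample.int(config$consensus_length - elen[i] + 1, 1)
    s <- substr(consensus, off, off + elen[i] - 1)
    s <- mutate_sequence(s, config$divergence_by_age[[age[i]]])
    if (age[i] == "primate_specific" && !is.null(mp)) {
      step <- nchar(mp$motif) + mp$spacing
      pos <- 10 + (seq_len(mp$copies) - 1) * step
      pos <- pos[pos + nchar(mp$motif) - 1 <= elen[i]]
      for (p in pos) substr(s, p, p + nchar(mp$motif) - 1) <- mp$motif
    }
    seqs[i] <- s
  }
  names(seqs) <- elements$element_id
  # milliDiv mimics the RepeatMasker column: planted substitution rate per kb
  # plus a little annotation noise
  elements$milli_div <- pmax(0, round(
    1000 * config$divergence_by_age[age] + rnorm(config$n_lines, 0, 5)))

  # liftover-style ortholog table consistent with the true ages
  orth <- do.call(rbind, lapply(seq_len(config$n_lines), function(i) {
    st <- age_status_template(age[i])
    lift <- ifelse(st == "present", "lifted",
                   ifelse(st == "degenerate", "partially_deleted", "deleted"))
    frac <- ifelse(lift == "lifted", runif(length(st), 0.34, 1), NA_real_)
    data.frame(element_id = elements$element_id[i], species = names(st),
               lift_outcome = lift, overlap_fraction = frac,
               status = unname(st), stringsAsFactors = FALSE)
  }))
  rownames(orth) <- NULL

  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
  samples <- setNames(rep(tissues, each = config$samples_per_tissue),
                      paste0(rep(tissues, each = config$samples_per_tissue),
                             "_s", seq_len(config$samples_per_tissue)))
  cassette_ids <- exons$exon_id[exons$role == "cassette"]
  psi <- config$planted_psi_table
  if (is.null(psi)) {
    psi <- matrix(round(runif(length(cassette_ids) * config$n_tissues, 0, 100), 1),
                  nrow = length(cassette_ids),
                  dimnames = list(cassette_ids, tissues))
  } else {
    if (!all(cassette_ids %in% rownames(psi))) {
      stop("planted_psi_table must cover all cassette exons")
    }
    psi <- psi[cassette_ids, , drop = FALSE]
    colnames(psi) <- tissues
  }

  structure(list(config = config, consensus = consensus, genes = genes,
                 exons = exons, elements = elements, sequences = seqs,
                 orthologs = orth, psi_table = psi, tissues = tissues,
                 samples = samples),
            class = "syn_bundle")
}

#' @export
print.syn_bundle <- function(x, ...) {
  cat(sprintf(
    "<syn_bundle> %d genes, %d LINE elements, %d tissues x %d samples (seed %d)\n",
    nrow(x$genes), nrow(x$elements), length(x$tissues),
    x$config$samples_per_tissue, x$config$seed))
  invisible(x)
}

#' Generate per-sample junction-read tables
#'
#' Draws junction-spanning read counts for every cassette exon and sample so
#' that the PSI formula applied to the expected counts recovers the planted
#' PSI: with inclusion fraction p, a sample's reads are split multinomially
#' between the upstream junction, the downstream junction and the skipping
#' junction with probabilities proportional to (p, p, 1 - p). Total depth
#' per exon and sample is Poisson around `2 * read_depth` events.
#'
#' @param config A [syn_config()].
#' @param bundle The matching [generate_fixture()] output.
#' @return List with `junctions` (long table: sample, contig, donor,
#'   acceptor, strand, count; zero-count junctions omitted), `counts` (wide
#'   per exon x sample: up, down, skip; all-zero rows flagged `absent`) and
#'   `truth` (the planted PSI matrix).
#' @export
generate_junction_counts <- function(config, bundle) {
  set.seed(component_seed(config, 2))
  psi <- bundle$psi_table
  ex <- bundle$exons
  cassette <- ex[ex$role == "cassette", , drop = FALSE]
  left <- ex[ex$role == "flank_left", , drop = FALSE]
  right <- ex[ex$role == "flank_right", , drop = FALSE]
  samples <- names(bundle$samples)
  rows <- vector("list", nrow(cassette) * length(samples))
  k <- 0
  for (i in seq_len(nrow(cassette))) {
    p <- psi[cassette$exon_id[i], ] / 100
    pr_t <- cbind(p, p, 1 - p) / (1 + p)  # per-tissue junction probabilities
    rownames(pr_t) <- bundle$tissues
    for (s in samples) {
      n <- rpois(1, 2 * config$read_depth)
      cnt <- if (n > 0) {
        as.numeric(rmultinom(1, n, pr_t[bundle$samples[[s]], ]))
      } else c(0, 0, 0)
      k <- k + 1
      rows[[k]] <- data.frame(
        exon_id = cassette$exon_id[i], sample = s,
        tissue = bundle$samples[[s]],
        up = cnt[1], down = cnt[2], skip = cnt[3], stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  counts$absent <- counts$up + counts$down + counts$skip == 0

  idx <- match(counts$exon_id, cassette$exon_id)
  base <- data.frame(
    sample = counts$sample, contig = cassette$contig[idx],
    strand = cassette$strand[idx], stringsAsFactors = FALSE)
  up_j <- cbind(base, donor = left$end[idx] - 1, acceptor = cassette$start[idx],
                count = counts$up)
  down_j <- cbind(base, donor = cassette$end[idx] - 1,
                  acceptor = right$start[idx], count = counts$down)
  skip_j <- cbind(base, donor = left$end[idx] - 1, acceptor = right$start[idx],
                  count = counts$skip)
  junctions <- rbind(up_j, down_j, skip_j)
  junctions <- junctions[junctions$count > 0, , drop = FALSE]
  junctions <- junctions[order(junctions$sample, junctions$donor,
                               junctions$acceptor), , drop = FALSE]
  rownames(junctions) <- NULL
  list(junctions = junctions, counts = counts, truth = psi)
}

#' Generate strand-specific crosslink tracks with age-dependent enrichment
#'
#' For every RBP in the configured set, crosslink cDNAs are scattered
#' uniformly over each element at a Poisson rate per nucleotide:
#' repressor-labelled RBPs get `repressor_enrichment_on_young`-fold the
#' baseline density on evolutionarily young (primate-specific) elements,
#' enhancer-labelled RBPs get the fold on evolutionarily old (one/two
#' distant species) elements instead.
#'
#' @inheritParams generate_junction_counts
#' @return Named list of [crosslink_track()] objects, one per RBP.
#' @export
generate_crosslink_tracks <- function(config, bundle) {
  if (!length(config$rbp_set)) stop("rbp_set must be non-empty")
  set.seed(component_seed(config, 3))
  el <- bundle$elements
  young <- el$age_class == "primate_specific"
  old <- el$age_class %in% c("one_distant", "two_distant")
  fold <- config$repressor_enrichment_on_young
  tracks <- lapply(names(config$rbp_set), function(rbp) {
    role <- config$rbp_set[[rbp]]
    dens <- rep(config$clip_density, nrow(el))
    if (role == "repressor") dens[young] <- dens[young] * fold
    if (role == "enhancer") dens[old] <- dens[old] * fold
    len <- el$end - el$start
    n <- rpois(nrow(el), dens * len)
    pos <- unlist(lapply(seq_len(nrow(el)), function(i) {
      if (n[i] == 0) integer(0)
      else el$start[i] + sample.int(len[i], n[i], replace = TRUE) - 1
    }))
    df <- data.frame(contig = rep(el$contig, n), pos = pos,
                     strand = rep(el$strand, n), count = rep(1, length(pos)),
                     stringsAsFactors = FALSE)
    crosslink_track(df, rbp = rbp, condition = "control")
  })
  names(tracks) <- names(config$rbp_set)
  tracks
}

# a random flank guaranteed to pass / planted to fail the priming filter
passing_flank <- function(width = 20) {
  repeat {
    f <- random_dna(width)
    if (internal_priming_filter(f)) return(f)
  }
}

failing_flank <- function(width = 20) {
  f <- random_dna(width)
  at <- sample.int(width - 5, 1)
  substr(f, at, at + 5) <- "AAAAAA"
  f
}

#' Generate 3'-end reads with labelled internal-priming artifacts
#'
#' Places two poly(A) sites downstream of every gene and draws reads for
#' them; a configured fraction of reads are internal-priming artifacts
#' whose ±10-nt genomic flank is planted to violate the priming filter
#' (a run of six A's), while genuine reads get flanks that pass it. Truth
#' labels are retained so filter sensitivity can be measured exactly.
#'
#' @inheritParams generate_junction_counts
#' @return Data frame with one row per read: `read_id`, `gene`, `contig`,
#'   `pos`, `strand`, `site` (`"pA1"`/`"pA2"` in transcription order),
#'   `flank` (20 nt), `is_artifact`.
#' @export
generate_polya_reads <- function(config, bundle) {
  set.seed(component_seed(config, 4))
  g <- bundle$genes
  n_reads <- rpois(nrow(g), config$read_depth)
  rows <- lapply(seq_len(nrow(g)), function(i) {
    if (n_reads[i] == 0) return(NULL)
    minus <- g$strand[i] == "-"
    # two sites downstream of the gene body, in transcription order
    if (minus) {
      site_pos <- c(pA1 = g$start[i] - 200, pA2 = g$start[i] - 1200)
    } else {
      site_pos <- c(pA1 = g$end[i] + 200, pA2 = g$end[i] + 1200)
    }
    site <- sample(c("pA1", "pA2"), n_reads[i], replace = TRUE,
                   prob = c(0.6, 0.4))
    artifact <- runif(n_reads[i]) < config$priming_artifact_rate
    flank <- vapply(artifact, function(a) {
      if (a) failing_flank() else passing_flank()
    }, character(1))
    data.frame(gene = g$gene[i], contig = g$contig[i],
               pos = unname(site_pos[site]), strand = g$strand[i],
               site = site, flank = flank, is_artifact = artifact,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), contig = character(0),
                      pos = numeric(0), strand = character(0),
                      site = character(0), flank = character(0),
                      is_artifact = logical(0))
  }
  out <- cbind(read_id = sprintf("r%06d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}
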