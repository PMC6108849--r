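toy_track <- function(pos, count = 1, strand = "+", rbp = "RBP",
                      contig = "c1", lib = NULL) {
  n <- length(pos)
  crosslink_track(data.frame(contig = rep_len(contig, n), pos = pos,
                             strand = rep_len(strand, n),
                             count = rep_len(count, n)),
                  rbp = rbp, library_size = lib)
}

test_that("element_coverage computes densities and per-million scaling", {
  el <- list(contig = "c1", start = 100, end = 600, strand = "+")
  tr <- toy_track(c(150, 200, 300, 400, 500))
  expect_equal(element_coverage(tr, el)[["per_100nt"]], 1)  # 5 / 500 * 100
  expect_equal(element_coverage(tr, el)[["per_million"]], 1e6)
  empty <- toy_track(integer(0), count = numeric(0))
  expect_equal(unname(element_coverage(empty, el)), c(0, 0, 0))
  # strand-specific: opposite-strand cDNAs are not counted
  minus <- toy_track(c(150, 200), strand = "-")
  expect_equal(element_coverage(minus, el)[["cdna"]], 0)
})

test_that("relative binding scores sum to one and find planted enrichment", {
  # degenerate case: one RBP holds all the signal on the top element
  els <- data.frame(element_id = sprintf("e%02d", 1:10), contig = "c1",
                    start = (0:9) * 1000, end = (0:9) * 1000 + 500,
                    strand = "+", age_class = rep(c("young", "old"), 5))
  t_a <- toy_track(seq(10, 490, by = 10), rbp = "A")      # all on element 1
  t_b <- toy_track(integer(0), count = numeric(0), rbp = "B")
  res <- relative_binding_scores(els, list(t_a, t_b))
  expect_equal(nrow(res$scores), 1)
  expect_equal(res$scores$A, 1)
  expect_equal(res$scores$B, 0)
  # planted repressor enrichment recovered on synthetic data
  cfg <- syn_config(seed = 61, n_genes = 80, n_lines = 500)
  b <- generate_fixture(cfg)
  tracks <- generate_crosslink_tracks(cfg, b)
  rbs <- relative_binding_scores(b$elements, unname(tracks),
                                 top_fraction = 0.10)
  sums <- rowSums(rbs$scores[, names(tracks), drop = FALSE])
  expect_true(all(abs(sums - 1) < 1e-9))
  enr <- rbs$enrichment
  ratio <- function(rbp) {
    e <- enr[enr$rbp == rbp, ]
    e$mean_score[e$group == "primate_specific"] /
      mean(e$mean_score[e$group %in% c("one_distant", "two_distant")])
  }
  expect_gt(ratio("MATR3"), 1)   # repressor: young over old
  expect_gt(ratio("PTBP1"), 1)
  expect_lt(ratio("SRSF1"), 1)   # enhancer: inverse
})

test_that("peak dependence classification follows the moderated LFC rules", {
  peaks <- data.frame(peak_id = c("p1", "p2", "p3", "p4"),
                      control = c(100, 50, 5, 40),
                      depleted = c(10, 50, 5, 22))
  res <- classify_peak_dependence(peaks, control_lib = 1000,
                                  depleted_lib = 1000)
  # p1: log2(14/104) ~ -2.89 -> dependent
  expect_equal(res$lfc[1], log2(14 / 104))
  expect_equal(res$class, c("dependent", "independent", "excluded",
                            "remaining"))
  # library-size normalization: doubling the depleted library halves its
  # normalized counts
  res2 <- classify_peak_dependence(peaks, control_lib = 1000,
                                   depleted_lib = 2000)
  expect_equal(res2$norm_depleted, peaks$depleted / 2000 * 1500)
  # monotone in the depleted/control ratio
  set.seed(3)
  ctrl <- rep(64, 20)
  dep <- sort(rpois(20, 40))
  lfc <- classify_peak_dependence(
    data.frame(peak_id = 1:20, control = ctrl, depleted = dep),
    control_lib = 1, depleted_lib = 1)$lfc
  expect_true(all(diff(lfc) >= 0))
})

test_that("rna_map is locus-normalized, oriented and bin-averaged", {
  loci <- data.frame(contig = "c1", pos = c(10000, 20000), strand = "+")
  tr <- toy_track(c(10010, 20010))  # one crosslink +10 from each locus
  prof <- rna_map(loci, tr, flank_nt = 200, bin_nt = 20)
  expect_equal(nrow(prof), 20)
  hit_bin <- prof$bin_start == 0
  expect_equal(prof$occupancy_pct[hit_bin], 100 * 1 / 20)  # 1 covered nt / 20
  expect_true(all(prof$occupancy_pct[!hit_bin] == 0))
  # minus-strand locus: downstream is lower genomic coordinate
  lmin <- data.frame(contig = "c1", pos = 5000, strand = "-")
  tmin <- toy_track(4990, strand = "-")
  pmin <- rna_map(lmin, tmin, flank_nt = 100, bin_nt = 10)
  expect_equal(pmin$occupancy_pct[pmin$bin_start == 10], 10)
  # interval track covering everything -> flat 100%
  iv <- data.frame(contig = "c1", start = 0, end = 1e6)
  flat <- rna_map(loci, iv, flank_nt = 100, bin_nt = 10)
  expect_true(all(flat$occupancy_pct == 100))
  expect_error(rna_map(loci[0, ], tr), "empty")
  # union property: profile of pooled loci = locus-count-weighted mean
  l1 <- data.frame(contig = "c1", pos = 10000, strand = "+")
  l2 <- data.frame(contig = "c1", pos = c(20000, 30000), strand = "+")
  p1 <- rna_map(l1, tr, 100, 10)$occupancy_pct
  p2 <- rna_map(l2, tr, 100, 10)$occupancy_pct
  pu <- rna_map(rbind(l1, l2), tr, 100, 10)$occupancy_pct
  expect_equal(pu, (1 * p1 + 2 * p2) / 3)
})

test_that("proximity classes follow the 500/2000 nt rules with size filter", {
  exons <- data.frame(contig = "c1",
                      start = c(10000, 50000), end = c(10100, 50100),
                      class = c("constitutive", "alternative"))
  els <- data.frame(
    element_id = c("near", "deep", "mid", "tiny", "near_alt"),
    contig = "c1",
    start = c(10400, 20000, 11100, 10200, 50400),
    end = c(10700, 22500, 11400, 10290, 50700))
  res <- classify_proximity(els, exons)
  expect_false("tiny" %in% res$element_id)  # 90 nt <= 100 -> dropped
  expect_equal(res$proximity[res$element_id == "near"], "exon_proximal")
  expect_equal(res$proximity[res$element_id == "deep"], "deep_intronic")
  expect_equal(res$proximity[res$element_id == "mid"], "neither")
  # within 500 of an alternative exon only: not exon_proximal, and within
  # 2000 of an exon so not deep either
  expect_equal(res$proximity[res$element_id == "near_alt"], "neither")
})

test_that("positional binding profile ranks deep-intronic tracks", {
  introns <- data.frame(contig = "c1", start = 0, end = 10000, strand = "+")
  near <- toy_track(c(10, 50, 90, 9950, 9990), rbp = "near_ss")
  deep <- toy_track(c(2500, 3000, 3400, 6800, 7200), rbp = "deep")
  res <- positional_binding_profile(list(near, deep), introns)
  expect_equal(res$band_0_100[res$rbp == "near_ss"], 100)
  expect_equal(res$deep_to_first[res$rbp == "near_ss"], 0)
  expect_equal(res$band_2000_5000[res$rbp == "deep"], 100)
  expect_equal(res$rank, c(2, 1))
  # uniform density: per-position band densities are equal
  unif <- toy_track(seq(0, 9999, by = 1), rbp = "unif")
  ru <- positional_binding_profile(list(unif), introns)
  dens <- unlist(ru[1, grep("^dens_", names(ru))])
  expect_true(all(abs(dens - dens[1]) < 1e-9))
  # empty track excluded from ranking
  r0 <- positional_binding_profile(
    list(toy_track(integer(0), count = numeric(0), rbp = "none"), deep),
    introns)
  expect_true(is.na(r0$rank[r0$rbp == "none"]))
  expect_error(positional_binding_profile(list(deep),
                                          introns[integer(0), ]),
               "sufficient size")
})

test_that("metaprofile around repressed loci exceeds matched control", {
  set.seed(71)
  n <- 30
  repressed <- data.frame(contig = "c1", pos = seq(50000, by = 50000,
                                                   length.out = n),
                          strand = "+")
  control <- data.frame(contig = "c1", pos = seq(25000, by = 50000,
                                                 length.out = n),
                        strand = "+")
  # plant crosslinks densely within +/-2 kb of every repressed locus
  planted <- unlist(lapply(repressed$pos, function(p) {
    p + sample(-2000:1999, 220)
  }))
  background <- sample(0:(50000 * (n + 1)), 150)
  tr <- toy_track(c(planted, background))
  prof_r <- rna_map(repressed, tr, flank_nt = 2000, bin_nt = 200)
  prof_c <- rna_map(control, tr, flank_nt = 2000, bin_nt = 200)
  expect_true(all(prof_r$occupancy_pct > prof_c$occupancy_pct))
})

test_that("match_control_loci reproduces the intron-length distribution", {
  set.seed(8)
  case_len <- rlnorm(200, log(5000), 0.8)
  pool <- data.frame(intron_length = rlnorm(5000, log(3000), 1.2))
  idx <- match_control_loci(case_len, pool)
  expect_true(length(idx) > 150)
  # decile-stratified sampling keeps the medians in the same ballpark
  expect_lt(abs(log(median(pool$intron_length[idx]) / median(case_len))), 0.5)
})
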