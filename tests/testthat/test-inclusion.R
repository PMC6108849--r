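test_that("compute_psi matches the formula and its bounds", {
  expect_equal(compute_psi(7, 9, 0), 100)
  expect_equal(compute_psi(0, 0, 5), 0)
  expect_equal(compute_psi(10, 10, 10), 50)  # 50*20/(10+10)
  expect_true(is.na(compute_psi(0, 0, 0)))
  expect_error(compute_psi(-1, 0, 0), "non-negative")
  # stays in [0, 100] and is monotone over random counts
  set.seed(7)
  up <- rpois(200, 5); down <- rpois(200, 5); skip <- rpois(200, 5)
  psi <- compute_psi(up, down, skip)
  ok <- !is.na(psi)
  expect_true(all(psi[ok] >= 0 & psi[ok] <= 100))
  expect_true(all(compute_psi(up + 1, down, skip)[ok] >= psi[ok]))
  expect_true(all(compute_psi(up, down, skip + 1)[ok] <= psi[ok]))
})

test_that("match_junctions respects the grace window and internal-exon rule", {
  exon <- list(contig = "c1", start = 1000, end = 1120, strand = "+")
  up_end <- 799         # last base of upstream exon
  down_start <- 2000
  jt <- data.frame(
    contig = "c1", strand = "+",
    donor = c(799, 799, 1119, 798, 1119, 796, 799),
    acceptor = c(1000, 1001, 2000, 2000, 2002, 1000, 1003),
    count = c(4, 1, 6, 2, 3, 9, 9))
  # rows: up exact(4) + up 1nt off(1); down exact(6); skip 1nt off(2);
  # down 2nt off(3); up donor 3nt off -> dropped(9); up acceptor 3nt off(9)
  res <- match_junctions(exon, up_end, down_start, jt, grace_nt = 2)
  expect_equal(unname(res), c(5, 9, 2))
  expect_error(match_junctions(exon, NA, down_start, jt), "internal exons")
})

test_that("hand-enumerated toy junction table gives (4, 6, 2)", {
  exon <- list(contig = "c1", start = 500, end = 600, strand = "-")
  jt <- data.frame(contig = "c1", strand = "-",
                   donor = c(399, 599, 399), acceptor = c(500, 800, 800),
                   count = c(4, 6, 2))
  expect_equal(unname(match_junctions(exon, 399, 800, jt)), c(4, 6, 2))
})

test_that("tissue_psi averages informative samples and flags absent tissues", {
  counts <- data.frame(
    sample = c("a1", "a2", "b1", "b2", "c1"),
    up = c(4, 6, 0, 8, 0), down = c(4, 6, 0, 8, 0),
    skip = c(4 * 1.5, 1, 0, 2 * 0.25 * 8, 0))
  tm <- c(a1 = "A", a2 = "B", b1 = "B", b2 = "C", c1 = "C")
  # a1: PSI 50*8/(6+4)=40; a2: 50*12/(1+6)~85.7; b1 all-zero (ignored);
  # b2: 50*16/(4+8)~66.7; c1 all-zero
  res <- tissue_psi(counts, tm)
  expect_equal(res[["A"]], 40)
  expect_equal(res[["B"]], compute_psi(6, 6, 1))   # all-zero sample ignored
  expect_equal(res[["C"]], compute_psi(8, 8, 4))
  all_zero <- data.frame(sample = c("x1", "x2"), up = 0, down = 0, skip = 0)
  expect_true(is.na(tissue_psi(all_zero, c(x1 = "X", x2 = "X"))[["X"]]))
  # mixed tissue: one all-zero sample plus one PSI=80 sample -> 80
  mixed <- data.frame(sample = c("m1", "m2"), up = c(0, 8), down = c(0, 8),
                      skip = c(0, 2))  # m2 alone: 50*16/(2+8) = 80
  expect_equal(tissue_psi(mixed, c(m1 = "M", m2 = "M"))[["M"]], 80)
})

test_that("filter_and_classify applies read support, blacklist and bounds", {
  rec <- data.frame(
    exon_id = c("e1", "e2", "e3", "e4", "e5"),
    contig = "c1", start = c(0, 100, 200, 300, 400) * 10,
    end = c(0, 100, 200, 300, 400) * 10 + 50,
    sum_up = c(199 * 2, 10, 500, 500, 500),
    sum_down = c(199 * 2 - 398, 10, 500, 500, 500),
    sum_skip = c(10, 200, 0, 0, 0))
  # e1: (398+0)/2 = 199 < 200 and skip 10 -> dropped
  # e2: inclusion support 10 but skip 200 -> kept
  rec$psi.t1 <- c(50, 90, 90, 50, 10)
  rec$psi.t2 <- c(50, 90, 94, 50, 12)
  rec$psi.testis <- c(50, 1, 1, 1, 99)  # excluded from the average
  out <- filter_and_classify(rec)
  expect_setequal(out$exon_id, c("e2", "e3", "e4", "e5"))
  expect_equal(out$avg_psi[out$exon_id == "e3"], 92)
  expect_equal(out$class[match(c("e2", "e3", "e4", "e5"), out$exon_id)],
               c("constitutive", "constitutive", "alternative",
                 "lowly_included"))
  # boundary values 85 and 15 are alternative (strict > and <)
  bd <- rec[3:4, ]
  bd$psi.t1 <- c(85, 15); bd$psi.t2 <- c(85, 15); bd$psi.testis <- c(0, 0)
  expect_equal(filter_and_classify(bd)$class, c("alternative", "alternative"))
  # blacklist overrides counts
  bl <- data.frame(contig = "c1", start = 1990, end = 2100)
  out_bl <- filter_and_classify(rec, blacklist = bl)
  expect_false("e3" %in% out_bl$exon_id)
  expect_true("e4" %in% out_bl$exon_id)
})

test_that("summarize_inclusion reports spread, detectability and testis rule", {
  psis <- c(brain = 0, liver = 20, heart = 80)
  s <- summarize_inclusion(psis)
  expect_equal(s$max_minus_min_psi, 80)
  expect_equal(s$n_detectable_tissues, 2)
  expect_true(s$detected_flag)
  one <- summarize_inclusion(c(brain = 50))
  expect_equal(one$max_minus_min_psi, 0)
  testis_only <- summarize_inclusion(c(testis = 30, brain = 0, liver = 0))
  expect_false(testis_only$detected_flag)
  expect_equal(testis_only$n_detectable_tissues, 1)
  all_na <- summarize_inclusion(c(a = NA_real_, b = NA_real_))
  expect_true(is.na(all_na$max_psi))
})

test_that("select_isoform prefers reads, then shorter introns, then leftmost", {
  cand <- data.frame(reads = c(30, 20), intron_span = c(5000, 100),
                     upstream_end = c(1, 2))
  expect_equal(select_isoform(cand)$reads, 30)
  tie <- data.frame(reads = c(25, 25), intron_span = c(4000, 2000),
                    upstream_end = c(1, 2))
  expect_equal(select_isoform(tie)$intron_span, 2000)
  expect_equal(select_isoform(tie[2:1, ])$intron_span, 2000)  # order-invariant
  single <- data.frame(reads = 5, intron_span = 100, upstream_end = 0)
  expect_equal(select_isoform(single), single, ignore_attr = TRUE)
  expect_error(select_isoform(cand[0, ]), "no candidate")
})

test_that("filter_exonic_bins merges equal-inclusion neighbours and filters", {
  known <- data.frame(contig = "c1", start = 100, end = 160)
  lines <- data.frame(contig = "c1", start = 150, end = 400)
  bins <- data.frame(
    contig = "c1",
    start = c(100, 130, 200, 300, 500),
    end = c(130, 160, 203, 340, 600),
    reads = c(10, 10, 10, 5, 8),
    incl_control = c(22, 22, 50, 40, 10),
    incl_test = c(22, 22, 50, 40, 12))
  out <- filter_exonic_bins(bins, known, lines)
  # bins 1+2 merge (adjacent, equal inclusion) -> 100-160, known -> not cryptic
  # bin 3 is 3 nt -> dropped; bin 4 has 5 reads -> dropped;
  # bin 5 inclusion <=15 in both -> dropped
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(100, 160))
  expect_false(out$cryptic)
  expect_true(out$line_derived)  # right splice site at 159 inside LINE
  expect_error(
    filter_exonic_bins(data.frame(contig = "c1", start = c(0, 5), end = c(10, 15),
                                  reads = 10, incl_control = 50, incl_test = 50),
                       known, lines),
    "non-overlapping")
})

test_that("exonic-bin survivors equal brute-force enumeration on random sets", {
  set.seed(42)
  known <- data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0))
  lines <- data.frame(contig = "c1", start = 1e6, end = 2e6)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    widths <- sample(c(3, 5, 10), n, replace = TRUE)
    starts <- cumsum(c(0, (widths + sample(c(0, 4), n, replace = TRUE))[-n]))
    bins <- data.frame(contig = "c1", start = starts, end = starts + widths,
                       reads = sample(c(4, 6, 20), n, replace = TRUE),
                       incl_control = sample(c(10, 15, 22), n, replace = TRUE),
                       incl_test = sample(c(10, 30), n, replace = TRUE))
    out <- filter_exonic_bins(bins, known, lines)
    # oracle: explicit merge then filter
    merged <- bins[1, , drop = FALSE]
    if (n > 1) for (i in 2:n) {
      last <- nrow(merged)
      if (bins$start[i] == merged$end[last] &&
          bins$incl_control[i] == merged$incl_control[last] &&
          bins$incl_test[i] == merged$incl_test[last]) {
        merged$end[last] <- bins$end[i]
        merged$reads[last] <- merged$reads[last] + bins$reads[i]
      } else merged <- rbind(merged, bins[i, ])
    }
    keep <- (merged$end - merged$start) >= 5 & merged$reads >= 6 &
      (merged$incl_control > 15 | merged$incl_test > 15)
    expect_equal(out$start, merged$start[keep])
    expect_equal(out$end, merged$end[keep])
    expect_equal(out$reads, merged$reads[keep])
  }
})
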