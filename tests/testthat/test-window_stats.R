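test_that("window construction enumerates sliding starts", {
  w <- make_windows(c(chr1 = 120000), size = 50000, step = 5000)
  expect_equal(nrow(w), 15L)
  expect_equal(w$start, seq(0, 70000, by = 5000))
  expect_true(all(w$end - w$start == 50000))

  expect_equal(nrow(make_windows(c(chr1 = 40000), 50000, 5000)), 0L)

  w2 <- make_windows(c(chr1 = 120000), 50000)
  expect_equal(nrow(w2), floor(120000 / 50000))
  expect_equal(w2$start, c(0, 50000))

  expect_error(make_windows(c(chr1 = 1e5), 0, 10), "positive")
  expect_error(make_windows(c(chr1 = 1e5), 100, 0), "positive")
  expect_error(make_windows(c(chr1 = 1e5), 100, 200), "exceed")
})

test_that("windows are invariant to chromosome input order", {
  lens <- c(chr2 = 80000, chr1 = 120000, chr3 = 60000)
  expect_equal(make_windows(lens, 50000, 10000),
               make_windows(rev(lens), 50000, 10000))
})

test_that("usable sites require full calls in focal pops and variation", {
  gm <- genotype_matrix(
    data.frame(chrom = "c", pos = c(10L, 20L, 30L, 40L), ref = "A", alt = "T"),
    c("a1", "a2", "b1", "b2"),
    rbind(c(0L, 1L, 2L, 2L),   # usable
          c(0L, 0L, NA, 0L),   # missing in pop B -> excluded
          c(0L, 0L, 0L, 0L),   # monomorphic ref -> excluded
          c(2L, 2L, 0L, 0L)))  # fixed difference -> usable
  pm <- population_map(list(A = c("a1", "a2"), B = c("b1", "b2")))
  fr <- allele_frequencies(gm, pm)
  w <- data.frame(chrom = "c", start = 0, end = 100)
  expect_equal(usable_sites(w, fr, c("A", "B")), c(1L, 4L))
  # with only pop A focal, the fixed-difference site is monomorphic within
  # A alone, so only the polymorphic site remains
  expect_equal(usable_sites(w, fr, "A"), 1L)
  expect_error(usable_sites(w, fr, character()), "non-empty")
})

test_that("pi matches the single-site worked example and degenerate cases", {
  # one site, 4 allele copies, p = 0.5, L = 1000
  gm <- genotype_matrix(
    data.frame(chrom = "c", pos = 500L, ref = "A", alt = "T"),
    c("x1", "x2"), rbind(c(1L, 1L)))
  pm <- population_map(list(X = c("x1", "x2")))
  fr <- allele_frequencies(gm, pm)
  w <- data.frame(chrom = "c", start = 0, end = 1000)
  expect_equal(pi_window(w, fr, "X"), (4 / 3) * 0.5 / 1000)

  # identical diploids at all sites -> monomorphic within pop -> pi = 0
  gm2 <- genotype_matrix(
    data.frame(chrom = "c", pos = c(5L, 15L), ref = "A", alt = "T"),
    c("x1", "x2", "y1"),
    rbind(c(2L, 2L, 0L), c(2L, 2L, 1L)))
  fr2 <- allele_frequencies(gm2, population_map(
    list(X = c("x1", "x2"), Y = "y1")))
  expect_equal(pi_window(w, fr2, "X"), 0)
})

test_that("dxy matches fixed-difference arithmetic and is symmetric", {
  gm <- genotype_matrix(
    data.frame(chrom = "c", pos = 50L, ref = "A", alt = "T"),
    c("x1", "y1"), rbind(c(2L, 0L)))
  pm <- population_map(list(X = "x1", Y = "y1"))
  fr <- allele_frequencies(gm, pm)
  w <- data.frame(chrom = "c", start = 0, end = 100)
  expect_equal(dxy_window(w, fr, "X", "Y"), 0.01)
  expect_equal(dxy_window(w, fr, "Y", "X"), dxy_window(w, fr, "X", "Y"))
  expect_error(dxy_window(w, fr, "X", "X"), "differ")
})

test_that("dxy between identical populations equals (n-1)/n * pi", {
  # duplicate one population as two labels sharing identical genotypes
  set.seed(3)
  calls <- matrix(sample(0:2, 20, replace = TRUE), 10, 2)
  gm <- genotype_matrix(
    data.frame(chrom = "c", pos = seq(10L, 100L, by = 10L),
               ref = "A", alt = "T"),
    c("x1", "x2", "z1", "z2"), cbind(calls, calls))
  pm <- population_map(list(X = c("x1", "x2"), Z = c("z1", "z2")))
  fr <- allele_frequencies(gm, pm)
  w <- data.frame(chrom = "c", start = 0, end = 200)
  n <- 4
  expect_equal(dxy_window(w, fr, "X", "Z"),
               ((n - 1) / n) * pi_window(w, fr, "X"))
})

test_that("pi and dxy equal brute-force haplotype-pair averages", {
  set.seed(19)
  for (rep in 1:3) {
    gm <- random_gm(60, 8, miss = 0.15, chroms = "chr1")
    pm <- random_popmap(gm, 2)
    fr <- allele_frequencies(gm, pm)
    w <- data.frame(chrom = "chr1", start = 0, end = 1e6)
    for (p in names(pm$populations)) {
      expect_equal(pi_window(w, fr, p),
                   oracle_pi(fr$n_called[, p], fr$p_alt[, p], 1e6),
                   tolerance = 1e-12)
    }
    expect_equal(dxy_window(w, fr, "pop1", "pop2"),
                 oracle_dxy(fr$n_called[, "pop1"], fr$p_alt[, "pop1"],
                            fr$n_called[, "pop2"], fr$p_alt[, "pop2"], 1e6),
                 tolerance = 1e-12)
  }
})

test_that("window stat table flags usability and reports both coordinate systems", {
  set.seed(23)
  gm <- random_gm(80, 6, miss = 0, chroms = "chr1")
  pm <- random_popmap(gm, 2)
  fr <- allele_frequencies(gm, pm)
  w <- make_windows(c(chr1 = 1e6), 5e5, 5e5)
  tab <- window_stat_table(fr, w, min_sites = 10L)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$start1, tab$start + 1)
  expect_equal(tab$end1, tab$end)
  expect_equal(tab$usable, tab$n_variant_usable >= 10L)
  expect_true(all(tab[, grep("^pi_|^dxy_", names(tab))] >= 0))
})
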