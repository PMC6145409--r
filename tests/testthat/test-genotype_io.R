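test_that("read_vcf keeps only biallelic polymorphic SNPs", {
  path <- write_vcf_fixture(withr::local_tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",
    "chr1\t200\t.\tAC\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",   # indel
    "chr1\t300\t.\tG\tC,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",  # triallelic
    "chr1\t400\t.\tG\tA\t.\tPASS\t.\tGT\t0/1\t./.\t0/0\t1/1",
    "chr2\t150\t.\tC\tG\t.\tPASS\t.\tGT\t1/1\t0/1\t1/1\t0/1"))
  gm <- read_vcf(path)
  expect_equal(n_sites(gm), 3L)
  expect_equal(gm$sites$pos, c(100L, 400L, 150L))
  expect_equal(unname(gm$calls[2, ]), c(1L, NA, 0L, 2L))
})

test_that("an all-missing VCF yields an empty matrix with a warning", {
  path <- write_vcf_fixture(withr::local_tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t./.\t./.\t./.\t./.",
    "chr1\t200\t.\tC\tG\t.\tPASS\t.\tGT\t./.\t./.\t./.\t./."))
  expect_warning(gm <- read_vcf(path), "retained")
  expect_equal(n_sites(gm), 0L)
  expect_equal(gm$samples, c("s1", "s2", "s3", "s4"))
})

test_that("monomorphic-after-filter records and sample subsetting behave", {
  path <- write_vcf_fixture(withr::local_tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/0\t./.\t0/0",   # monomorphic
    "chr1\t200\t.\tA\tT\t.\tPASS\t.\tGT\t1/1\t1/1\t1/1\t1/1",   # monomorphic alt
    "chr1\t300\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0\t0/0"))
  gm <- read_vcf(path)
  expect_equal(gm$sites$pos, 300L)
  expect_error(read_vcf(path, samples = c("s1", "nope")), "nope")
})

test_that("genotype matrices round-trip through VCF", {
  set.seed(42)
  gm <- random_gm(40, 6)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotype_vcf(gm, path, contig_lengths = c(chr1 = 1e6, chr2 = 1e6))
  back <- read_vcf(path)
  expect_equal(back$sites$chrom, gm$sites$chrom)
  expect_equal(back$sites$pos, gm$sites$pos)
  expect_equal(back$calls, gm$calls)
  expect_equal(attr(back, "contig_lengths"), c(chr1 = 1e6, chr2 = 1e6))
})

test_that("population map reading validates coverage", {
  set.seed(7)
  gm <- random_gm(10, 6)
  path <- withr::local_tempfile(fileext = ".tsv")

  writeLines(sprintf("%s\tpop%d", gm$samples, rep(1:3, each = 2)), path)
  pm <- read_population_map(path, gm)
  expect_equal(names(pm$populations), c("pop1", "pop2", "pop3"))
  expect_equal(lengths(pm$populations), c(pop1 = 2L, pop2 = 2L, pop3 = 2L))

  writeLines(sprintf("%s\tpop1", gm$samples[-3]), path)
  expect_error(read_population_map(path, gm), gm$samples[3])

  writeLines(c(sprintf("%s\tpop1", gm$samples), "ghost\tpop9"), path)
  expect_warning(pm2 <- read_population_map(path, gm), "ghost")
  expect_false("pop9" %in% names(pm2$populations))

  writeLines(sprintf("%s\tpop1", gm$samples[c(1, seq_along(gm$samples))]),
             path)
  expect_error(read_population_map(path, gm), "duplicate")
})

test_that("allele frequencies handle missingness in the denominator", {
  gm <- genotype_matrix(
    data.frame(chrom = "c", pos = 1:3, ref = "A", alt = "T"),
    c("a", "b"),
    rbind(c(0L, 1L),    # {0/0, 0/1} -> 0.25
          c(2L, 2L),    # {1/1, 1/1} -> 1
          c(1L, NA)))   # {0/1, ./.} -> 0.5 over 2 copies
  pm <- population_map(list(P = c("a", "b")))
  fr <- allele_frequencies(gm, pm)
  expect_equal(unname(fr$p_alt[, "P"]), c(0.25, 1, 0.5))
  expect_equal(unname(fr$n_called[, "P"]), c(4L, 4L, 2L))
})

test_that("frequencies match the brute-force oracle and ignore sample order", {
  set.seed(11)
  for (rep in 1:3) {
    gm <- random_gm(30, 9, miss = 0.2)
    pm <- random_popmap(gm, 3)
    fr <- allele_frequencies(gm, pm)
    orc <- oracle_freqs(gm, pm)
    expect_equal(fr$p_alt, orc$p_alt)
    expect_equal(fr$n_called, orc$n_called)

    shuf <- sample(seq_along(gm$samples))
    gm2 <- genotype_matrix(gm$sites, gm$samples[shuf],
                           gm$calls[, shuf, drop = FALSE])
    fr2 <- allele_frequencies(gm2, pm)
    expect_equal(fr2$p_alt, fr$p_alt)
  }
})

test_that("polarization designates the outgroup-minor allele as derived", {
  gm <- genotype_matrix(
    data.frame(chrom = "c", pos = 1:3, ref = "A", alt = "T"),
    c("p1", "o1", "o2"),
    rbind(c(1L, 0L, 0L),   # out p_alt = 0   -> alt derived, unchanged
          c(1L, 2L, 2L),   # out p_alt = 1   -> ref derived, flipped
          c(1L, 0L, 2L)))  # out p_alt = 0.5 -> tie, alt derived
  pm <- population_map(list(P = "p1", O = c("o1", "o2")))
  fr <- polarize_frequencies(allele_frequencies(gm, pm), "O")
  expect_equal(unname(fr$p_derived[, "P"]), c(0.5, 0.5, 0.5))
  expect_equal(unname(fr$p_derived[, "O"]), c(0, 0, 0.5))
})
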