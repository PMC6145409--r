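test_that("demographic model validation catches broken histories", {
  expect_error(
    demographic_model(c(a = 1e3, b = 1e3), c(a = 2L, b = 2L)),
    "root")
  expect_error(
    demographic_model(c(a = 1e3, b = 1e3), c(a = 2L),
                      splits = data.frame(time = 10, derived = "a",
                                          ancestral = "b"),
                      pulses = data.frame(time = 5, recipient = "a",
                                          donor = "b", fraction = 1.5)),
    "fraction")
  expect_error(
    demographic_model(c(a = 1e3), c(a = 2L, zz = 1L)),
    "zz")
})

test_that("pairwise coalescence time matches the exponential expectation", {
  ne <- 1000
  m <- demographic_model(c(a = ne), c(a = 1L))
  set.seed(101)
  tm <- replicate(2000, simulate_genealogy(m)$time[3])
  expect_equal(mean(tm), 2 * ne, tolerance = 0.05)
})

test_that("mean pairwise differences match theta = 4 Ne mu L", {
  ne <- 1000; mu <- 1e-6; L <- 10000L
  m <- demographic_model(c(a = ne), c(a = 1L), mu = mu)
  set.seed(103)
  diffs <- replicate(2000, {
    sw <- simulate_window(m, L, 1L)
    sum(sw$geno == 1L)  # one diploid: het sites = pairwise differences
  })
  expect_equal(mean(diffs), 4 * ne * mu * L, tolerance = 0.05)
})

test_that("a fraction-1 pulse moves every recipient lineage", {
  # recipient deme is effectively non-coalescing (huge Ne); with f = 1 all
  # lineages must be in the small donor deme just after the pulse, so the
  # TMRCA is the pulse time plus a fast donor coalescence
  m <- demographic_model(
    c(a = 1e9, b = 1), c(a = 3L),
    splits = data.frame(time = 1e8, derived = "a", ancestral = "b"),
    pulses = data.frame(time = 10, recipient = "a", donor = "b",
                        fraction = 1))
  set.seed(107)
  roots <- replicate(50, {
    g <- simulate_genealogy(m)
    g$time[g$root]
  })
  expect_true(all(roots > 10 & roots < 100))
})

test_that("disconnected demes are a fatal error at simulation time", {
  m <- demographic_model(
    c(a = 10, b = 10), c(a = 1L, b = 1L),
    splits = data.frame(time = 1e9, derived = "a", ancestral = "b"))
  m$splits <- NULL  # histories that never join
  set.seed(109)
  expect_error(simulate_genealogy(m), "ancestor")
})

test_that("mutation dropping respects mu = 0 and tree structure", {
  m <- demographic_model(c(a = 100), c(a = 3L), mu = 0)
  set.seed(113)
  sw <- simulate_window(m, 1000L, 1L)
  expect_equal(length(sw$pos), 0L)

  m2 <- demographic_model(c(a = 100), c(a = 4L), mu = 1e-4)
  gen <- simulate_genealogy(m2)
  mut <- drop_mutations(gen, 1e-4, 1000L)
  if (nrow(mut$hap)) {
    carriers <- rowSums(mut$hap)
    expect_true(all(carriers >= 1 & carriers < gen$n_tips))
    expect_false(is.unsorted(mut$pos))
    expect_equal(anyDuplicated(mut$pos), 0L)
  }
})

test_that("windows are reproducible from the seed and differ across seeds", {
  m <- quartet_model()
  set.seed(7); a <- simulate_window(m, 5000L, 2L)
  set.seed(7); b <- simulate_window(m, 5000L, 2L)
  set.seed(8); c <- simulate_window(m, 5000L, 2L)
  expect_identical(a, b)
  expect_false(identical(a$pos, c$pos))
  expect_error(simulate_window(m, 5000L, 3L), "divisible")
})

test_that("sub-block concatenation reduces per-window fd variance", {
  m <- quartet_model()
  qt <- quartet_config("lakeA1", "lakeA3", "rivMM", "out")
  fd_of <- function(blocks) {
    sw <- simulate_window(m, 50000L, blocks)
    introscan:::.sim_window_fd(sw, qt, 50L)
  }
  set.seed(127)
  fd10 <- replicate(250, fd_of(10L))
  fd1 <- replicate(250, fd_of(1L))
  expect_lt(var(fd10, na.rm = TRUE), var(fd1, na.rm = TRUE))
})

test_that("candidate recall rises with the pulse fraction", {
  base <- quartet_model()
  recall_at <- function(f) {
    m <- demographic_model(
      base$ne, base$samples[base$samples > 0], splits = base$splits,
      pulses = data.frame(time = 500, recipient = "lakeA3", donor = "rivMM",
                          fraction = f),
      mu = base$mu, size_changes = base$size_changes)
    qt <- quartet_config("lakeA1", "lakeA3", "rivMM", "out")
    fds <- replicate(50, {
      sw <- simulate_window(m, 50000L, 10L)
      introscan:::.sim_window_fd(sw, qt, 100L)
    })
    mean(!is.na(fds) & fds > 0.2)  # fixed reference threshold
  }
  set.seed(131)
  rec <- vapply(c(0.05, 0.2, 0.8), recall_at, numeric(1))
  expect_true(all(diff(rec) >= 0))
})
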