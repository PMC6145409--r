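# minimal fd-scan-shaped data.frame for region calling
scan_fixture <- function(starts, fds, chrom = "c1", size = 50000) {
  data.frame(chrom = chrom, start = starts, end = starts + size,
             start1 = starts + 1, end1 = starts + size,
             n_sites_used = 200L, usable = TRUE, fd = fds,
             p2 = "spX", donor_label = "MM", stringsAsFactors = FALSE)
}

region_fixture <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("candidate calling merges overlapping and abutting windows", {
  # nothing above threshold
  expect_equal(nrow(call_candidates(scan_fixture(0, 0.1), 0.3)), 0L)

  # three overlapping windows (starts 0, 5k, 10k) -> one region 0-60000
  cand <- call_candidates(scan_fixture(c(0, 5000, 10000),
                                       c(0.4, 0.5, 0.45)), 0.3)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, 0)
  expect_equal(cand$end, 60000)
  expect_equal(cand$start1, 1)
  expect_equal(cand$end1, 60000)
  expect_equal(cand$peak_fd, 0.5)
  expect_equal(cand$focal_species, "spX")

  # a sub-threshold window in between splits the region
  cand2 <- call_candidates(
    scan_fixture(c(0, 60000, 120000), c(0.4, 0.1, 0.45)), 0.3)
  expect_equal(nrow(cand2), 2L)

  # windows with undefined fd are never candidates
  cand3 <- call_candidates(scan_fixture(0, NA_real_), 0.3)
  expect_equal(nrow(cand3), 0L)
})

test_that("region calling is idempotent on its own output", {
  cand <- call_candidates(scan_fixture(c(0, 5000, 100000),
                                       c(0.4, 0.5, 0.6)), 0.3)
  again <- call_candidates(
    data.frame(chrom = cand$chrom, start = cand$start, end = cand$end,
               fd = cand$peak_fd, stringsAsFactors = FALSE), 0.3)
  expect_equal(again$start, cand$start)
  expect_equal(again$end, cand$end)
})

test_that("sharing categories follow overlap and subclade membership", {
  subclades <- c(sp1 = "A", sp2 = "A", sp3 = "B")
  regions <- list(
    sp1 = region_fixture("c1", c(0, 2e5, 4e5), c(5e4, 2.5e5, 4.5e5)),
    sp2 = region_fixture("c1", 0, 5e4),
    sp3 = region_fixture("c1", c(2e5, 4e5), c(2.5e5, 4.5e5)))
  out <- categorize_regions(regions, subclades)
  # region 1: shared with sp2 (same subclade); region 2: with sp3 (other
  # subclade); region 3: with sp3 -> clade-wide
  expect_equal(out$sp1$category,
               c("SHARED_SUBCLADE", "SHARED_CLADE", "SHARED_CLADE"))
  expect_equal(out$sp2$category, "SHARED_SUBCLADE")
  expect_equal(out$sp3$category, c("SHARED_CLADE", "SHARED_CLADE"))

  # clade-wide precedence when both apply
  both <- list(
    sp1 = region_fixture("c1", 0, 5e4),
    sp2 = region_fixture("c1", 0, 5e4),
    sp3 = region_fixture("c1", 40000, 9e4))
  expect_equal(categorize_regions(both, subclades)$sp1$category,
               "SHARED_CLADE")

  # private region, and every region receives exactly one category
  lone <- list(sp1 = region_fixture("c2", 0, 5e4),
               sp2 = region_fixture("c1", 0, 5e4),
               sp3 = region_fixture("c3", 0, 5e4))
  lo <- categorize_regions(lone, subclades)
  expect_equal(lo$sp1$category, "PRIVATE")
  allcat <- unlist(lapply(lo, `[[`, "category"))
  expect_true(all(allcat %in% c("PRIVATE", "SHARED_SUBCLADE",
                                "SHARED_CLADE")))

  expect_error(categorize_regions(list(ghost = region_fixture("c1", 0, 1)),
                                  subclades), "ghost")
})

test_that("dual-donor overlap flags mirror a constructed 19/27 fixture", {
  expect_equal(
    hybrid_swarm_overlap(region_fixture("c1", 0, 5e4),
                         region_fixture("c1", 1e5, 2e5))$mm$hybrid_swarm_overlap,
    FALSE)

  one <- hybrid_swarm_overlap(region_fixture("c1", 0, 5e4),
                              region_fixture("c1", 4e4, 9e4))
  expect_true(one$mm$hybrid_swarm_overlap)
  expect_true(one$cr$hybrid_swarm_overlap)

  # 27 candidate regions from the nearby donor, 19 of which overlap a
  # distant-donor region
  starts <- (0:26) * 1e6
  mm <- region_fixture("c1", starts, starts + 5e4)
  cr <- region_fixture("c1", starts[1:19] + 25000, starts[1:19] + 75000)
  fl <- hybrid_swarm_overlap(mm, cr)
  expect_equal(sum(fl$mm$hybrid_swarm_overlap), 19L)
})

test_that("sweep flags use a strict order-of-magnitude rule", {
  ws <- data.frame(chrom = "c1", start = c(0, 5e4, 1e5), end = c(5e4, 1e5, 1.5e5),
                   usable = TRUE, pi_spX = c(1e-4, 2.95e-3, 2.95e-3),
                   stringsAsFactors = FALSE)
  # linkage-group mean = 2e-3; region window pi = 1e-4 -> flagged
  r1 <- sweep_flag(region_fixture("c1", 0, 5e4), ws, "spX")
  expect_true(r1$sweep_flag)

  ws$pi_spX <- c(1.5e-3, 2.25e-3, 2.25e-3)  # mean 2e-3, region 1.5e-3
  r2 <- sweep_flag(region_fixture("c1", 0, 5e4), ws, "spX")
  expect_false(r2$sweep_flag)

  # exactly 0.1 x mean is not flagged (strict inequality)
  ws$pi_spX <- c(0.2e-3, 2.9e-3, 2.9e-3)  # mean 2e-3, region exactly 2e-4
  r3 <- sweep_flag(region_fixture("c1", 0, 5e4), ws, "spX")
  expect_false(r3$sweep_flag)

  ws$pi_spX <- NA_real_
  expect_warning(r4 <- sweep_flag(region_fixture("c1", 0, 5e4), ws, "spX"),
                 "undefined")
  expect_true(is.na(r4$sweep_flag))
})
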