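# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive every statistic by naive per-genotype loops so that
# the vectorized implementations are checked against a second, simpler path.

# random genotype matrix fixture: n_sites x n_samples with missingness
random_gm <- function(n_sites = 50, n_samples = 8, miss = 0.1,
                      chroms = c("chr1", "chr2")) {
  chrom <- sort(sample(chroms, n_sites, replace = TRUE))
  pos <- integer(n_sites)
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    pos[chrom == ch] <- sort(sample.int(1e6, k))
  }
  calls <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
                  n_sites, n_samples)
  calls[stats::runif(length(calls)) < miss] <- NA
  samples <- sprintf("s%02d", seq_len(n_samples))
  genotype_matrix(
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T"),
    samples, calls)
}

random_popmap <- function(gm, n_pops = 4) {
  ns <- length(gm$samples)
  labels <- paste0("pop", rep_len(seq_len(n_pops), ns))
  population_map(split(gm$samples, labels))
}

# per-genotype frequency count
oracle_freqs <- function(gm, popmap) {
  pops <- names(popmap$populations)
  n_called <- matrix(0L, nrow(gm$sites), length(pops),
                     dimnames = list(NULL, pops))
  p_alt <- matrix(NA_real_, nrow(gm$sites), length(pops),
                  dimnames = list(NULL, pops))
  for (i in seq_len(nrow(gm$sites))) for (p in pops) {
    alt <- 0L; n <- 0L
    for (s in popmap$populations[[p]]) {
      g <- gm$calls[i, s]
      if (!is.na(g)) { n <- n + 2L; alt <- alt + g }
    }
    n_called[i, p] <- n
    if (n > 0L) p_alt[i, p] <- alt / n
  }
  list(n_called = n_called, p_alt = p_alt)
}

# unbiased mean pairwise difference per site, summed / L
oracle_pi <- function(n, p, L) {
  tot <- 0
  for (i in seq_along(n)) {
    if (n[i] >= 2) {
      a <- p[i] * n[i]
      tot <- tot + 2 * a * (n[i] - a) / (n[i] * (n[i] - 1))
    }
  }
  tot / L
}

oracle_dxy <- function(nx, px, ny, py, L) {
  tot <- 0
  for (i in seq_along(nx)) {
    if (nx[i] > 0 && ny[i] > 0) {
      ax <- px[i] * nx[i]; ay <- py[i] * ny[i]
      # average over all cross-population haplotype pairs
      tot <- tot + (ax * (ny[i] - ay) + ay * (nx[i] - ax)) / (nx[i] * ny[i])
    }
  }
  tot / L
}

# site-by-site fd accumulation
oracle_fd <- function(p1, p2, p3, p4) {
  num <- 0; den <- 0; abba <- 0; baba <- 0
  for (i in seq_along(p1)) {
    a <- (1 - p1[i]) * p2[i] * p3[i] * (1 - p4[i])
    b <- p1[i] * (1 - p2[i]) * p3[i] * (1 - p4[i])
    abba <- abba + a; baba <- baba + b
    num <- num + a - b
    pD <- max(p2[i], p3[i])
    den <- den + (1 - p1[i]) * pD * pD * (1 - p4[i]) -
      p1[i] * (1 - pD) * pD * (1 - p4[i])
  }
  list(abba = abba, baba = baba, num = num, den = den,
       fd = if (num > 0 && den > 0) num / den else NA_real_)
}

# jackknife SE rebuilt from raw products, with the documented block rule
# re-stated independently
oracle_jackknife_se <- function(products, chrom, block_size) {
  blocks <- integer(length(products))
  bid <- 0L
  for (ch in rle(chrom)$values) {
    idx <- which(chrom == ch)
    k <- length(idx)
    nb <- k %/% block_size
    rem <- k %% block_size
    if (nb == 0L) {
      bid <- bid + 1L
      blocks[idx] <- bid
    } else {
      for (j in seq_len(nb)) {
        bid <- bid + 1L
        blocks[idx[((j - 1L) * block_size + 1L):(j * block_size)]] <- bid
      }
      if (rem > 0L) {
        tail_idx <- idx[(nb * block_size + 1L):k]
        if (rem >= block_size / 2) {
          bid <- bid + 1L
          blocks[tail_idx] <- bid
        } else {
          blocks[tail_idx] <- bid
        }
      }
    }
  }
  B <- max(blocks)
  loo <- vapply(seq_len(B), function(j) mean(products[blocks != j]),
                numeric(1))
  sqrt(((B - 1) / B) * sum((loo - mean(loo))^2))
}

# write a small VCF text fixture
write_vcf_fixture <- function(path, records,
                              samples = c("s1", "s2", "s3", "s4")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

# quartet-only model used where full-radiation sampling is unnecessary
quartet_model <- function(ne_lake = 2e4, ...) {
  lake_demography(ne_lake = ne_lake, ...,
                  samples = c(lakeA1 = 3L, lakeA3 = 3L, rivMM = 4L,
                              out = 3L))
}
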