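#' Per-site f4 products for a quartet
#'
#' For populations ordered (A, B; C, D) the per-site contribution is
#' `(pA - pB)(pC - pD)`, computed from alternate-allele frequencies (the
#' product is invariant to allele-label polarization). Usable sites are
#' those where all four populations have at least one called genotype.
#'
#' @param freqs a `pop_freqs` object.
#' @param quartet character vector of four population labels (A, B, C, D) or
#'   a [quartet_config()] (interpreted as (P1, P2; P3, O)).
#' @return List with numeric vector `products` and matching character vector
#'   `chrom` in genome order.
#' @export
f4_site_products <- function(freqs, quartet) {
  q <- .quartet_labels(quartet)
  bad <- setdiff(q, freqs$pops)
  if (length(bad)) stop("unknown population(s): ", paste(bad, collapse = ", "))
  nc <- freqs$n_called[, q, drop = FALSE]
  use <- rowSums(nc > 0L) == 4L
  p <- freqs$p_alt[use, q, drop = FALSE]
  list(products = (p[, 1] - p[, 2]) * (p[, 3] - p[, 4]),
       chrom = freqs$sites$chrom[use])
}

.quartet_labels <- function(quartet) {
  if (inherits(quartet, "quartet_config"))
    c(quartet$p1, quartet$p2, quartet$p3, quartet$outgroup)
  else if (is.character(quartet) && length(quartet) == 4L) quartet
  else stop("quartet must be a quartet_config or four population labels")
}

#' Genome-wide f4 point estimate
#'
#' Mean over usable sites of the per-site products `(pA - pB)(pC - pD)`.
#'
#' @param products numeric vector of per-site f4 products.
#' @return The f4 statistic.
#' @export
f4_point <- function(products) {
  if (!length(products)) stop("no usable sites for f4")
  mean(products)
}

#' Delete-one-block jackknife standard error
#'
#' Blocks are consecutive runs of `block_size` usable SNPs in genome order,
#' never spanning chromosomes, so that the resampling respects linkage
#' disequilibrium. A trailing partial block of at least `block_size / 2`
#' SNPs stands as its own block, otherwise it is merged into the previous
#' block (a chromosome shorter than `block_size` forms a single block).
#' With leave-one-block-out estimates `theta_(-j)` and B blocks,
#' \deqn{SE = \sqrt{\frac{B-1}{B} \sum_j (\theta_{-j} - \bar\theta_{-.})^2}.}
#'
#' @param products per-site f4 products in genome order.
#' @param chrom chromosome of each site (same length as `products`); `NULL`
#'   treats all sites as one chromosome.
#' @param block_size SNPs per block (default 1000).
#' @return List with `se`, `n_blocks`, and the leave-one-out estimates
#'   `loo`.
#' @export
block_jackknife <- function(products, chrom = NULL, block_size = 1000L) {
  n <- length(products)
  if (is.null(chrom)) chrom <- rep("1", n)
  if (length(chrom) != n) stop("chrom must match products in length")
  blocks <- .assign_blocks(chrom, block_size)
  B <- max(blocks)
  if (B < 2L)
    stop("fewer than 2 jackknife blocks; use a smaller block_size")
  tot <- sum(products)
  bsum <- vapply(seq_len(B), function(j) sum(products[blocks == j]), numeric(1))
  bn <- tabulate(blocks, B)
  loo <- (tot - bsum) / (n - bn)
  se <- sqrt(((B - 1) / B) * sum((loo - mean(loo))^2))
  list(se = se, n_blocks = B, loo = loo)
}

# consecutive-run block assignment within chromosomes, half-block rule for
# the trailing remainder
.assign_blocks <- function(chrom, block_size) {
  runs <- rle(chrom)
  out <- integer(length(chrom))
  next_id <- 0L
  pos <- 0L
  for (r in seq_along(runs$lengths)) {
    k <- runs$lengths[r]
    ids <- (seq_len(k) - 1L) %/% block_size + 1L
    nb <- k %/% block_size
    rem <- k - nb * block_size
    if (nb == 0L) {
      ids[] <- 1L
    } else if (rem > 0L && rem < block_size / 2) {
      ids[ids == nb + 1L] <- nb
    }
    out[pos + seq_len(k)] <- next_id + ids
    next_id <- max(out)
    pos <- pos + k
  }
  out
}

#' Z-score and two-sided normal p-value for an f4 estimate
#'
#' `z = f4 / se`; `p = 2 * Phi(-|z|)`. A zero standard error is degenerate:
#' the p-value is reported as 0 with a warning.
#'
#' @param f4 point estimate.
#' @param se jackknife standard error.
#' @return List with `z` and `p`.
#' @export
z_and_p <- function(f4, se) {
  if (se <= 0) {
    warning("degenerate jackknife SE (se = 0); p reported as 0")
    return(list(z = if (f4 == 0) 0 else sign(f4) * Inf, p = 0))
  }
  z <- f4 / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Genome-wide f4 test with block-jackknife significance
#'
#' @param freqs a `pop_freqs` object.
#' @param quartet four population labels (A, B, C, D) or a
#'   [quartet_config()].
#' @param block_size SNPs per jackknife block (default 1000).
#' @return One-row data.frame: labels, `f4`, `se`, `z`, `p`, `n_sites`,
#'   `n_blocks`.
#' @export
f4_test <- function(freqs, quartet, block_size = 1000L) {
  q <- .quartet_labels(quartet)
  sp <- f4_site_products(freqs, q)
  f4 <- f4_point(sp$products)
  jk <- block_jackknife(sp$products, sp$chrom, block_size)
  zp <- z_and_p(f4, jk$se)
  data.frame(A = q[1], B = q[2], C = q[3], D = q[4],
             f4 = f4, se = jk$se, z = zp$z, p = zp$p,
             n_sites = length(sp$products), n_blocks = jk$n_blocks,
             stringsAsFactors = FALSE)
}
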