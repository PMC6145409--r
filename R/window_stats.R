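#' Sliding windows over chromosomes
#'
#' Windows are half-open `[start, end)` in 0-based bp coordinates, start at
#' 0 and advance by `step`; a trailing span shorter than `size` emits no
#' window, so every window has exactly `size` bp.
#'
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#' @param size window size in bp.
#' @param step step between window starts in bp (default `size`,
#'   i.e. non-overlapping tiling).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, size, step = size) {
  if (size <= 0 || step <= 0) stop("window size and step must be positive")
  if (step > size) stop("step must not exceed window size")
  chroms <- sort(names(chrom_lengths))
  out <- lapply(chroms, function(ch) {
    L <- chrom_lengths[[ch]]
    if (L < size) return(NULL)
    starts <- seq(0, L - size, by = step)
    data.frame(chrom = ch, start = starts, end = starts + size,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = numeric(), end = numeric())
  rownames(res) <- NULL
  res
}

# indices (into the site table) of sites falling in a half-open window
.sites_in_window <- function(sites, chrom, start, end) {
  which(sites$chrom == chrom & sites$pos > start & sites$pos <= end)
}

#' Usable variant sites within a window
#'
#' A site is usable for a set of focal populations when every member of every
#' focal population has a called genotype (no missing data within a
#' population, read strictly) and the site is still variant across the focal
#' populations: at least one focal population is polymorphic, or two focal
#' populations are fixed for different alleles.
#'
#' @param window one-row data.frame (or list) with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param freqs a `pop_freqs` object.
#' @param focal_pops character vector of population labels.
#' @return Integer vector of site indices into `freqs$sites`.
#' @export
usable_sites <- function(window, freqs, focal_pops) {
  if (!length(focal_pops)) stop("focal_pops must be non-empty")
  bad <- setdiff(focal_pops, freqs$pops)
  if (length(bad)) stop("unknown population(s): ", paste(bad, collapse = ", "))
  idx <- .sites_in_window(freqs$sites, window$chrom, window$start, window$end)
  if (!length(idx)) return(integer())
  nc <- freqs$n_called[idx, focal_pops, drop = FALSE]
  full <- nc == rep(2L * freqs$pop_sizes[focal_pops], each = length(idx))
  all_called <- rowSums(full) == length(focal_pops)
  p <- freqs$p_alt[idx, focal_pops, drop = FALSE]
  pmin_ <- do.call(pmin, c(as.data.frame(p), na.rm = FALSE))
  pmax_ <- do.call(pmax, c(as.data.frame(p), na.rm = FALSE))
  variant <- !is.na(pmin_) & !is.na(pmax_) & (pmax_ - pmin_ > 0 |
    (pmin_ > 0 & pmin_ < 1))
  idx[all_called & variant]
}

#' Nucleotide diversity in a window
#'
#' Unbiased per-site heterozygosity summed over variant sites and divided by
#' the window length in bp:
#' \deqn{\pi = \sum_s \frac{n_s}{n_s - 1} 2 p_s (1 - p_s) / L}
#' with \eqn{n_s} the called allele copies at site s. Sites with fewer than
#' two called copies contribute zero; invariant sites are absent from the
#' matrix and also contribute zero, making this a lower-bound estimator when
#' L is the full window length.
#'
#' @param window one-row data.frame with `chrom`, `start`, `end`.
#' @param freqs a `pop_freqs` object.
#' @param pop population label.
#' @param sites optional site-index restriction (e.g. from [usable_sites()]).
#' @param denom `"window"` (divide by window length, default) or `"sites"`
#'   (divide by the number of contributing variant sites).
#' @return Per-bp diversity, or `NA` if the population is entirely uncalled
#'   in the window.
#' @export
pi_window <- function(window, freqs, pop, sites = NULL, denom = c("window", "sites")) {
  denom <- match.arg(denom)
  idx <- .sites_in_window(freqs$sites, window$chrom, window$start, window$end)
  if (!is.null(sites)) idx <- intersect(idx, sites)
  if (!length(idx)) return(0)
  n <- freqs$n_called[idx, pop]
  p <- freqs$p_alt[idx, pop]
  if (all(n == 0L)) {
    warning("population ", pop, " entirely uncalled in window")
    return(NA_real_)
  }
  use <- n >= 2L
  terms <- (n[use] / (n[use] - 1)) * 2 * p[use] * (1 - p[use])
  L <- if (denom == "window") window$end - window$start else max(sum(use), 1L)
  sum(terms) / L
}

#' Absolute divergence (Dxy) between two populations in a window
#'
#' \deqn{D_{xy} = \sum_s [p_X (1 - p_Y) + p_Y (1 - p_X)] / L}
#' summed over variant sites where both populations have at least one called
#' allele copy.
#'
#' @inheritParams pi_window
#' @param popX,popY distinct population labels.
#' @return Per-bp divergence, or `NA` if either population is entirely
#'   uncalled in the window.
#' @export
dxy_window <- function(window, freqs, popX, popY, sites = NULL,
                       denom = c("window", "sites")) {
  denom <- match.arg(denom)
  if (popX == popY) stop("popX and popY must differ")
  idx <- .sites_in_window(freqs$sites, window$chrom, window$start, window$end)
  if (!is.null(sites)) idx <- intersect(idx, sites)
  if (!length(idx)) return(0)
  nx <- freqs$n_called[idx, popX]
  ny <- freqs$n_called[idx, popY]
  if (all(nx == 0L) || all(ny == 0L)) {
    warning("population entirely uncalled in window")
    return(NA_real_)
  }
  use <- nx > 0L & ny > 0L
  px <- freqs$p_alt[idx, popX][use]
  py <- freqs$p_alt[idx, popY][use]
  L <- if (denom == "window") window$end - window$start else max(sum(use), 1L)
  sum(px * (1 - py) + py * (1 - px)) / L
}

#' Per-window diversity and divergence table
#'
#' Computes, for every window, the usable-site count under the missingness
#' rule of [usable_sites()], a usability flag (`n >= min_sites`), pi for each
#' population and Dxy for each population pair.
#'
#' @param freqs a `pop_freqs` object.
#' @param windows data.frame from [make_windows()].
#' @param pops populations to summarize (default: all).
#' @param min_sites minimum usable variant sites for a window to be flagged
#'   usable (default 100).
#' @param denom passed to [pi_window()] / [dxy_window()].
#' @return data.frame with one row per window: coordinates (both 0-based
#'   half-open `start`/`end` and 1-based inclusive `start1`/`end1`),
#'   `n_variant_usable`, `usable`, `pi_<pop>` and `dxy_<popX>_<popY>` columns.
#' @export
window_stat_table <- function(freqs, windows, pops = freqs$pops,
                              min_sites = 100L, denom = "window") {
  pairs <- if (length(pops) > 1) utils::combn(pops, 2) else
    matrix(character(), 2, 0)
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    us <- usable_sites(w, freqs, pops)
    row <- data.frame(chrom = w$chrom, start = w$start, end = w$end,
                      start1 = w$start + 1, end1 = w$end,
                      n_variant_usable = length(us),
                      usable = length(us) >= min_sites,
                      stringsAsFactors = FALSE)
    for (p in pops)
      row[[paste0("pi_", p)]] <-
        suppressWarnings(pi_window(w, freqs, p, denom = denom))
    if (ncol(pairs))
      for (j in seq_len(ncol(pairs)))
        row[[paste0("dxy_", pairs[1, j], "_", pairs[2, j])]] <-
          suppressWarnings(dxy_window(w, freqs, pairs[1, j], pairs[2, j],
                                      denom = denom))
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
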