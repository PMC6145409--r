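#' Quartet configuration for ABBA-BABA tests
#'
#' Assigns population labels to the quartet roles on the tree
#' `((P1, P2), P3, O)`: P2 is the focal (potential recipient) population,
#' P3 the candidate donor, and O a distant outgroup assumed free of gene
#' flow with the others.
#'
#' @param p1,p2,p3,outgroup distinct population labels.
#' @param donor_label free-text note of which donor lineage P3 represents
#'   (e.g. "MM" or "CR"); defaults to `p3`.
#' @return An object of class `quartet_config`.
#' @export
quartet_config <- function(p1, p2, p3, outgroup, donor_label = p3) {
  labs <- c(p1, p2, p3, outgroup)
  if (anyDuplicated(labs)) stop("quartet roles must be four distinct populations")
  structure(list(p1 = p1, p2 = p2, p3 = p3, outgroup = outgroup,
                 donor_label = donor_label),
            class = "quartet_config")
}

#' @export
print.quartet_config <- function(x, ...) {
  cat(sprintf("quartet ((%s, %s), %s; O = %s) donor=%s\n",
              x$p1, x$p2, x$p3, x$outgroup, x$donor_label))
  invisible(x)
}

#' Per-site ABBA and BABA pattern terms
#'
#' Frequency-weighted pattern products from derived-allele frequencies:
#' `abba = (1 - p1) p2 p3 (1 - p4)` and `baba = p1 (1 - p2) p3 (1 - p4)`.
#' Vectorized over sites.
#'
#' @param p1,p2,p3,p4 derived-allele frequencies in P1, P2, P3 and the
#'   outgroup.
#' @return List with numeric vectors `abba` and `baba`.
#' @export
site_pattern_terms <- function(p1, p2, p3, p4) {
  list(abba = (1 - p1) * p2 * p3 * (1 - p4),
       baba = p1 * (1 - p2) * p3 * (1 - p4))
}

#' D statistic from site pattern terms
#'
#' `D = (sum(abba) - sum(baba)) / (sum(abba) + sum(baba))`; `NA` when the
#' denominator is zero.
#'
#' @param abba,baba numeric vectors of per-site pattern terms.
#' @return The D statistic.
#' @export
d_statistic <- function(abba, baba) {
  den <- sum(abba) + sum(baba)
  if (den == 0) return(NA_real_)
  (sum(abba) - sum(baba)) / den
}

#' Window fd statistic
#'
#' Admixture-fraction estimator for a genomic window: the ABBA-BABA excess is
#' normalized by its value under complete sharing with a dynamic donor,
#' where at each site the donor frequency `pD = max(p2, p3)` replaces both
#' P2 and P3 in the denominator terms. fd is only interpretable for excess
#' sharing in the tested direction, so it is reported `NA` (not a candidate)
#' unless both the numerator and denominator sums are positive.
#'
#' @param p1,p2,p3,p4 derived-allele frequencies at the window's usable sites.
#' @return List with `abba_sum`, `baba_sum`, `d`, `s_num`, `s_den`, `fd`,
#'   `n_sites`.
#' @export
fd_statistic <- function(p1, p2, p3, p4) {
  terms <- site_pattern_terms(p1, p2, p3, p4)
  pD <- pmax(p2, p3)
  den_terms <- site_pattern_terms(p1, pD, pD, p4)
  s_num <- sum(terms$abba) - sum(terms$baba)
  s_den <- sum(den_terms$abba) - sum(den_terms$baba)
  fd <- if (s_num > 0 && s_den > 0) s_num / s_den else NA_real_
  list(abba_sum = sum(terms$abba), baba_sum = sum(terms$baba),
       d = d_statistic(terms$abba, terms$baba),
       s_num = s_num, s_den = s_den, fd = fd, n_sites = length(p1))
}

#' Sliding-window fd scan
#'
#' Computes D and fd per window for one quartet. Sites enter a window's
#' statistics only if every member of P1, P2, P3 and O is called and the
#' site is variant across those populations ([usable_sites()]); windows with
#' fewer than `min_sites` such sites are marked unusable and get `NA`
#' statistics.
#'
#' @param freqs a polarized `pop_freqs` object ([polarize_frequencies()])
#'   whose outgroup matches `quartet$outgroup`.
#' @param windows data.frame from [make_windows()].
#' @param quartet a [quartet_config()].
#' @param min_sites minimum usable variant sites per window (default 100).
#' @return data.frame with one row per window: coordinates, `n_sites_used`,
#'   `usable`, `abba_sum`, `baba_sum`, `d`, `s_num`, `s_den`, `fd`, plus the
#'   quartet labels.
#' @export
fd_scan <- function(freqs, windows, quartet, min_sites = 100L) {
  if (is.null(freqs$p_derived))
    stop("freqs must be polarized; see polarize_frequencies()")
  if (freqs$outgroup != quartet$outgroup)
    stop("freqs polarized on ", freqs$outgroup, " but quartet outgroup is ",
         quartet$outgroup)
  focal <- c(quartet$p1, quartet$p2, quartet$p3, quartet$outgroup)
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    idx <- usable_sites(w, freqs, focal)
    n <- length(idx)
    base <- data.frame(chrom = w$chrom, start = w$start, end = w$end,
                       start1 = w$start + 1, end1 = w$end,
                       n_sites_used = n, usable = n >= min_sites,
                       stringsAsFactors = FALSE)
    if (n < min_sites) {
      base[c("abba_sum", "baba_sum", "d", "s_num", "s_den", "fd")] <- NA_real_
    } else {
      st <- fd_statistic(freqs$p_derived[idx, quartet$p1],
                         freqs$p_derived[idx, quartet$p2],
                         freqs$p_derived[idx, quartet$p3],
                         freqs$p_derived[idx, quartet$outgroup])
      base$abba_sum <- st$abba_sum; base$baba_sum <- st$baba_sum
      base$d <- st$d; base$s_num <- st$s_num; base$s_den <- st$s_den
      base$fd <- st$fd
    }
    base
  })
  out <- do.call(rbind, rows)
  out$p1 <- quartet$p1; out$p2 <- quartet$p2; out$p3 <- quartet$p3
  out$outgroup <- quartet$outgroup; out$donor_label <- quartet$donor_label
  rownames(out) <- NULL
  out
}

#' Manhattan-style plot of an fd scan
#'
#' Base-graphics plot of window fd values by genomic position, chromosomes
#' laid end to end in alternating shades, with an optional significance
#' threshold line.
#'
#' @param scan data.frame from [fd_scan()].
#' @param threshold optional fd threshold to draw (e.g. from
#'   [null_fd_threshold()]).
#' @param ... passed to [graphics::plot()].
#' @export
plot_fd_scan <- function(scan, threshold = NULL, ...) {
  scan <- scan[!is.na(scan$fd), , drop = FALSE]
  chroms <- unique(scan$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(scan$end[scan$chrom == ch]), numeric(1))))
  names(offs) <- c(chroms, "_end")
  x <- (scan$start + scan$end) / 2 + offs[scan$chrom]
  col <- c("grey25", "grey60")[(match(scan$chrom, chroms) %% 2) + 1]
  graphics::plot(x, scan$fd, pch = 16, cex = 0.5, col = col,
                 xlab = "genomic position (bp, chromosomes concatenated)",
                 ylab = expression(f[d]), ...)
  if (!is.null(threshold))
    graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(NULL)
}
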