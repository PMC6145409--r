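#' Call candidate introgressed regions from an fd scan
#'
#' Windows with a defined fd strictly above the threshold are selected;
#' overlapping or abutting selected windows are merged into maximal regions
#' (half-open interval union), recording the peak fd and window count per
#' region.
#'
#' @param scan data.frame from [fd_scan()].
#' @param threshold fd significance threshold, e.g. from
#'   [null_fd_threshold()].
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `start1`, `end1` (1-based inclusive), `peak_fd`,
#'   `n_windows`, plus the scan's quartet labels.
#' @export
call_candidates <- function(scan, threshold) {
  sel <- scan[!is.na(scan$fd) & scan$fd > threshold, , drop = FALSE]
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    start1 = numeric(), end1 = numeric(),
                    peak_fd = numeric(), n_windows = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(sel)) {
    sel <- sel[order(sel$chrom, sel$start), , drop = FALSE]
    regions <- list()
    cur <- NULL
    for (i in seq_len(nrow(sel))) {
      if (!is.null(cur) && cur$chrom == sel$chrom[i] &&
          sel$start[i] <= cur$end) {
        cur$end <- max(cur$end, sel$end[i])
        cur$peak_fd <- max(cur$peak_fd, sel$fd[i])
        cur$n_windows <- cur$n_windows + 1L
      } else {
        if (!is.null(cur)) regions[[length(regions) + 1L]] <- cur
        cur <- list(chrom = sel$chrom[i], start = sel$start[i],
                    end = sel$end[i], peak_fd = sel$fd[i], n_windows = 1L)
      }
    }
    regions[[length(regions) + 1L]] <- cur
    out <- do.call(rbind, lapply(regions, function(r)
      data.frame(chrom = r$chrom, start = r$start, end = r$end,
                 start1 = r$start + 1, end1 = r$end, peak_fd = r$peak_fd,
                 n_windows = r$n_windows, stringsAsFactors = FALSE)))
  }
  for (col in c("p2", "donor_label"))
    if (col %in% names(scan) && nrow(out))
      out[[if (col == "p2") "focal_species" else col]] <- scan[[col]][1]
  out
}

.overlaps_any <- function(chrom, start, end, other) {
  if (!nrow(other)) return(FALSE)
  any(other$chrom == chrom & other$start < end & start < other$end)
}

#' Categorize candidate regions by cross-species sharing
#'
#' Implements the three sharing categories: a region overlapping (by at
#' least 1 bp) a candidate region of another species in a *different*
#' subclade is `SHARED_CLADE`; else one overlapping a region of another
#' species in the *same* subclade is `SHARED_SUBCLADE`; else `PRIVATE`.
#' `SHARED_CLADE` takes precedence because clade-wide sharing subsumes
#' subclade sharing. All per-species scans against the same donor must be
#' supplied together.
#'
#' @param regions_by_species named list (focal species -> data.frame from
#'   [call_candidates()]).
#' @param subclade_map named character vector: species -> subclade label.
#' @return The input list with a `category` column added to each
#'   data.frame.
#' @export
categorize_regions <- function(regions_by_species, subclade_map) {
  species <- names(regions_by_species)
  missing <- setdiff(species, names(subclade_map))
  if (length(missing))
    stop("species missing from subclade_map: ", paste(missing, collapse = ", "))
  for (sp in species) {
    regs <- regions_by_species[[sp]]
    if (!nrow(regs)) {
      regs$category <- character(0)
      regions_by_species[[sp]] <- regs
      next
    }
    cat_out <- character(nrow(regs))
    for (i in seq_len(nrow(regs))) {
      same <- FALSE; diff <- FALSE
      for (other in setdiff(species, sp)) {
        hit <- .overlaps_any(regs$chrom[i], regs$start[i], regs$end[i],
                             regions_by_species[[other]])
        if (!hit) next
        if (subclade_map[[other]] == subclade_map[[sp]]) same <- TRUE
        else diff <- TRUE
      }
      cat_out[i] <- if (diff) "SHARED_CLADE" else
        if (same) "SHARED_SUBCLADE" else "PRIVATE"
    }
    regs$category <- cat_out
    regions_by_species[[sp]] <- regs
  }
  regions_by_species
}

#' Flag hybrid-swarm overlap between donor scans
#'
#' A candidate region from the nearby-donor (MM-like) scans is flagged when
#' its span overlaps any candidate region, for any focal species, from the
#' distant-donor (CR-like) scans, and vice versa — the dual-donor sharing
#' pattern expected under a hybrid-swarm founding.
#'
#' @param regions_mm,regions_cr data.frames of candidate regions from the
#'   two donors' scans (any focal species; rbind per-species results).
#' @return List with both data.frames, each gaining a logical
#'   `hybrid_swarm_overlap` column.
#' @export
hybrid_swarm_overlap <- function(regions_mm, regions_cr) {
  flag <- function(a, b) {
    if (!nrow(a)) { a$hybrid_swarm_overlap <- logical(0); return(a) }
    a$hybrid_swarm_overlap <- vapply(seq_len(nrow(a)), function(i)
      .overlaps_any(a$chrom[i], a$start[i], a$end[i], b), logical(1))
    a
  }
  list(mm = flag(regions_mm, regions_cr), cr = flag(regions_cr, regions_mm))
}

#' Selective-sweep flag for candidate regions
#'
#' A region is flagged when the focal species' mean nucleotide diversity
#' over the region's windows is strictly below one tenth of its mean over
#' all usable windows of the same chromosome (linkage group) — diversity an
#' order of magnitude below the linkage-group average.
#'
#' @param regions data.frame of candidate regions.
#' @param window_stats data.frame from [window_stat_table()] containing a
#'   `pi_<focal_pop>` column.
#' @param focal_pop population label of the focal species.
#' @return `regions` with logical columns `sweep_flag` (NA with a warning
#'   when pi is undefined) plus `region_pi` and `lg_mean_pi`.
#' @export
sweep_flag <- function(regions, window_stats, focal_pop) {
  col <- paste0("pi_", focal_pop)
  if (!col %in% names(window_stats))
    stop("window_stats lacks column ", col)
  n <- nrow(regions)
  regions$region_pi <- NA_real_
  regions$lg_mean_pi <- NA_real_
  regions$sweep_flag <- NA
  for (i in seq_len(n)) {
    inlg <- window_stats$chrom == regions$chrom[i] & window_stats$usable
    inreg <- inlg & window_stats$start < regions$end[i] &
      regions$start[i] < window_stats$end
    rp <- mean(window_stats[[col]][inreg], na.rm = TRUE)
    lp <- mean(window_stats[[col]][inlg], na.rm = TRUE)
    regions$region_pi[i] <- rp
    regions$lg_mean_pi[i] <- lp
    if (is.finite(rp) && is.finite(lp)) {
      regions$sweep_flag[i] <- rp < 0.1 * lp
    } else {
      warning("undefined pi for region ", regions$chrom[i], ":",
              regions$start[i], "-", regions$end[i], "; sweep flag absent")
    }
  }
  regions
}

#' Summarize classified regions as a JSON-ready list
#'
#' Counts per category and flag, echoing the layout of a candidate-region
#' summary table.
#'
#' @param regions data.frame with `category` and optionally
#'   `hybrid_swarm_overlap` / `sweep_flag` columns.
#' @return Named list of counts.
#' @export
region_summary <- function(regions) {
  out <- list(n_regions = nrow(regions),
              by_category = as.list(table(regions$category)))
  if ("hybrid_swarm_overlap" %in% names(regions))
    out$n_hybrid_swarm_overlap <- sum(regions$hybrid_swarm_overlap,
                                      na.rm = TRUE)
  if ("sweep_flag" %in% names(regions))
    out$n_sweep_flagged <- sum(regions$sweep_flag, na.rm = TRUE)
  out
}
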