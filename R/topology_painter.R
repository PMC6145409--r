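#' Pairwise genetic distance matrix for a window
#'
#' Allele-sharing distance between individuals: the mean over co-called
#' variant sites of `|g_i - g_j| / 2`, with `g` the diploid alt-allele
#' count, so distances lie in [0, 1]. Samples are ordered lexicographically
#' so the matrix (and downstream tree) is invariant to input column order.
#' A window is informative only if it holds at least `min_sites` sites and
#' every sample pair shares at least one co-called site.
#'
#' @param gm a [genotype_matrix()].
#' @param window one-row data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), or `NULL` to use all sites.
#' @param min_sites minimum variant sites for an informative window
#'   (default 20).
#' @return List with `labels`, distance matrix `d`, `n_sites`, and logical
#'   `informative`.
#' @export
window_distance <- function(gm, window = NULL, min_sites = 20L) {
  idx <- if (is.null(window)) seq_len(nrow(gm$sites)) else
    .sites_in_window(gm$sites, window$chrom, window$start, window$end)
  labels <- sort(gm$samples)
  g <- gm$calls[idx, labels, drop = FALSE]
  ns <- length(labels)
  d <- matrix(0, ns, ns, dimnames = list(labels, labels))
  informative <- length(idx) >= min_sites
  if (length(idx)) {
    called <- !is.na(g)
    if (!anyNA(g)) {
      d <- as.matrix(stats::dist(t(g), method = "manhattan")) /
        (2 * length(idx))
    } else {
      for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
        co <- called[, i] & called[, j]
        if (!any(co)) {
          informative <- FALSE
          d[i, j] <- d[j, i] <- NA_real_
        } else {
          d[i, j] <- d[j, i] <- mean(abs(g[co, i] - g[co, j]) / 2)
        }
      }
    }
  } else informative <- FALSE
  list(labels = labels, d = d, n_sites = length(idx),
       informative = informative)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]) on the
#' window distance matrix; because [window_distance()] orders samples
#' lexicographically the result is deterministic across runs and input
#' orders.
#'
#' @param dm result of [window_distance()], or a plain symmetric matrix.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  d <- if (is.list(dm)) dm$d else dm
  if (nrow(d) < 4L) stop("neighbor joining needs at least 4 taxa")
  if (any(!is.finite(d))) stop("non-finite distances; window uninformative")
  ape::nj(d)
}

#' Classify the lake-clade topology of a window tree
#'
#' The tree is rooted on the distant outgroup samples; if they are not
#' monophyletic the window is `UNINFORMATIVE`. A window is
#' `LAKE_MONOPHYLETIC` when all lake samples form a clade. Otherwise each
#' configured group (species or subclade, largest first) is tested for
#' grouping with the riverine samples: group `g` matches when for some
#' riverine sample the MRCA of `g` and that sample contains no lake samples
#' outside `g` — the signature of that group being closer to the riverine
#' populations than to the rest of the radiation. If no group matches, the
#' window is `OTHER_POLYPHYLETIC`.
#'
#' @param tree unrooted `phylo` from [nj_tree()].
#' @param lake_samples,riverine_samples,outgroup_samples character vectors
#'   of tip labels.
#' @param groups named list of candidate sample groups (species and
#'   configured subclades).
#' @return List with `class` (one of `"LAKE_MONOPHYLETIC"`,
#'   `"GROUP_WITH_RIVERINE"`, `"OTHER_POLYPHYLETIC"`, `"UNINFORMATIVE"`),
#'   `group` (matched group name or `NA`), and the rooted `tree`.
#' @export
classify_topology <- function(tree, lake_samples, riverine_samples,
                              outgroup_samples, groups = list()) {
  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroup_samples, resolve.root = TRUE),
    error = function(e) NULL)
  if (is.null(rooted) ||
      (length(outgroup_samples) > 1L &&
       !ape::is.monophyletic(rooted, outgroup_samples)))
    return(list(class = "UNINFORMATIVE", group = NA_character_, tree = tree))
  if (ape::is.monophyletic(rooted, lake_samples))
    return(list(class = "LAKE_MONOPHYLETIC", group = NA_character_,
                tree = rooted))
  ord <- order(-lengths(groups), names(groups))
  for (gname in names(groups)[ord]) {
    g <- groups[[gname]]
    if (!all(g %in% rooted$tip.label)) next
    other_lake <- setdiff(lake_samples, g)
    for (r in riverine_samples) {
      mrca <- ape::getMRCA(rooted, c(g, r))
      tips <- ape::extract.clade(rooted, mrca)$tip.label
      if (!any(other_lake %in% tips))
        return(list(class = "GROUP_WITH_RIVERINE", group = gname,
                    tree = rooted))
    }
  }
  list(class = "OTHER_POLYPHYLETIC", group = NA_character_, tree = rooted)
}

#' Paint genomic windows by topology class
#'
#' Runs distance + neighbor joining + classification on every window.
#'
#' @param gm a [genotype_matrix()].
#' @param windows data.frame from [make_windows()].
#' @param lake_samples,riverine_samples,outgroup_samples tip label sets.
#' @param groups named list of candidate groups (see [classify_topology()]).
#' @param min_sites minimum variant sites per informative window.
#' @return data.frame with one row per window: coordinates, `class`,
#'   `group`, `n_sites`.
#' @export
paint_windows <- function(gm, windows, lake_samples, riverine_samples,
                          outgroup_samples, groups = list(),
                          min_sites = 20L) {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    dm <- window_distance(gm, w, min_sites)
    if (!dm$informative) {
      cls <- "UNINFORMATIVE"; grp <- NA_character_
    } else {
      tr <- nj_tree(dm)
      cl <- classify_topology(tr, lake_samples, riverine_samples,
                              outgroup_samples, groups)
      cls <- cl$class; grp <- cl$group
    }
    data.frame(chrom = w$chrom, start = w$start, end = w$end,
               class = cls, group = grp, n_sites = dm$n_sites,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genome proportions and merged runs per topology class
#'
#' Merges adjacent same-class windows into runs and reports the proportion
#' of the painted genome assigned to each class. `UNINFORMATIVE` windows are
#' excluded from the painted span, so proportions are over informative
#' windows and sum to 1 for non-overlapping tilings.
#'
#' @param calls data.frame from [paint_windows()].
#' @return List with `proportions` (named numeric) and `runs` (data.frame of
#'   merged same-class spans, including uninformative runs).
#' @export
paint_genome <- function(calls) {
  calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
  runs <- list()
  for (i in seq_len(nrow(calls))) {
    last <- if (length(runs)) runs[[length(runs)]] else NULL
    if (!is.null(last) && last$chrom == calls$chrom[i] &&
        last$class == calls$class[i] &&
        identical(last$group, calls$group[i]) &&
        calls$start[i] <= last$end) {
      runs[[length(runs)]]$end <- max(last$end, calls$end[i])
    } else {
      runs[[length(runs) + 1L]] <- calls[i, c("chrom", "start", "end",
                                              "class", "group")]
    }
  }
  runs <- do.call(rbind, runs)
  rownames(runs) <- NULL
  painted <- calls[calls$class != "UNINFORMATIVE", , drop = FALSE]
  classes <- unique(painted$class)
  span_of <- function(df) {
    # union of half-open intervals per chromosome
    tot <- 0
    for (ch in unique(df$chrom)) {
      x <- df[df$chrom == ch, , drop = FALSE]
      x <- x[order(x$start), , drop = FALSE]
      cur_s <- x$start[1]; cur_e <- x$end[1]
      for (j in seq_len(nrow(x))[-1]) {
        if (x$start[j] <= cur_e) cur_e <- max(cur_e, x$end[j])
        else { tot <- tot + cur_e - cur_s; cur_s <- x$start[j]; cur_e <- x$end[j] }
      }
      tot <- tot + cur_e - cur_s
    }
    tot
  }
  total <- span_of(painted)
  props <- vapply(classes, function(cl)
    span_of(painted[painted$class == cl, , drop = FALSE]) / total,
    numeric(1))
  list(proportions = props, runs = runs)
}
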