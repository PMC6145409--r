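#' Demographic model for structured-coalescent simulation
#'
#' Describes demes with piecewise-constant diploid effective sizes, split
#' events (backwards in time, all lineages of the derived deme join the
#' ancestral deme), admixture pulses (each lineage of the recipient jumps to
#' the donor independently with probability `fraction`), a per-bp per-
#' generation mutation rate, and diploid sample counts. Time is measured in
#' generations before present; after all splits a single root deme must
#' remain.
#'
#' @param ne named numeric vector: deme -> diploid effective size at time 0.
#' @param samples named integer vector: deme -> sampled diploids (demes may
#'   be omitted or zero).
#' @param splits data.frame with columns `time`, `derived`, `ancestral`, or
#'   `NULL`.
#' @param pulses data.frame with columns `time`, `recipient`, `donor`,
#'   `fraction`, or `NULL`.
#' @param mu mutation rate per bp per generation (default 3.5e-9).
#' @param size_changes data.frame with columns `time`, `deme`, `size` for
#'   piecewise-constant size histories, or `NULL`.
#' @return An object of class `demographic_model`.
#' @export
demographic_model <- function(ne, samples, splits = NULL, pulses = NULL,
                              mu = 3.5e-9, size_changes = NULL) {
  demes <- names(ne)
  if (is.null(demes) || anyDuplicated(demes)) stop("`ne` must be uniquely named")
  if (any(ne <= 0)) stop("effective sizes must be positive")
  s <- stats::setNames(rep(0L, length(demes)), demes)
  if (!is.null(samples)) {
    unk <- setdiff(names(samples), demes)
    if (length(unk)) stop("sampled deme(s) not in model: ",
                          paste(unk, collapse = ", "))
    s[names(samples)] <- as.integer(samples)
  }
  if (!is.null(splits)) {
    stopifnot(all(c("time", "derived", "ancestral") %in% names(splits)))
    unk <- setdiff(c(splits$derived, splits$ancestral), demes)
    if (length(unk)) stop("split deme(s) not in model: ",
                          paste(unk, collapse = ", "))
    if (anyDuplicated(splits$derived))
      stop("a deme may be the derived side of at most one split")
    splits <- splits[order(splits$time), , drop = FALSE]
  }
  if (!is.null(pulses)) {
    stopifnot(all(c("time", "recipient", "donor", "fraction") %in% names(pulses)))
    unk <- setdiff(c(pulses$recipient, pulses$donor), demes)
    if (length(unk)) stop("pulse deme(s) not in model: ",
                          paste(unk, collapse = ", "))
    if (any(pulses$fraction < 0 | pulses$fraction > 1))
      stop("pulse fractions must lie in [0, 1]")
    pulses <- pulses[order(pulses$time), , drop = FALSE]
  }
  if (!is.null(size_changes))
    stopifnot(all(c("time", "deme", "size") %in% names(size_changes)),
              all(size_changes$deme %in% demes), all(size_changes$size > 0))
  # connectivity: every deme must reach a single root through the splits
  merged <- if (is.null(splits)) character() else splits$derived
  roots <- setdiff(demes, merged)
  if (length(roots) != 1L)
    stop("model must leave exactly one root deme after all splits; found: ",
         paste(roots, collapse = ", "))
  structure(list(demes = demes, ne = ne, samples = s, splits = splits,
                 pulses = pulses, mu = mu, size_changes = size_changes,
                 root = roots),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("demographic_model:", length(x$demes), "demes,",
      sum(x$samples), "sampled diploids,",
      if (is.null(x$splits)) 0 else nrow(x$splits), "splits,",
      if (is.null(x$pulses)) 0 else nrow(x$pulses), "pulses, mu =", x$mu, "\n")
  invisible(x)
}

#' Default crater-lake radiation demography
#'
#' A plausible model of a young in-lake radiation in the mould of the
#' Barombi Mbo crater-lake system: five lake species in two subclades — a
#' three-species subclade `lakeA1`/`lakeA2`/`lakeA3` (an earlier-diverging
#' species plus a close species pair, like *Stomatepia*) and a species pair
#' `lakeB1`/`lakeB2` — two riverine source populations (`rivMM` nearby,
#' `rivCR` more distant) and one distant outgroup (`out`). The close pairs
#' split 2,000 generations ago, subclade A's root at 4,000, the lake root
#' at 10,000; the lake was colonized from the `rivMM` lineage at 20,000;
#' the riverine demes split ten times deeper than the radiation (100,000)
#' and the outgroup fifty times deeper (500,000). Lake Ne defaults to 2e4
#' diploids, riverine to 5e4, mutation rate to 3.5e-9 /bp/gen.
#'
#' The three-species subclade matters: a region whose ancestry was sorted
#' on the branch ancestral to the close pair is inherited by both pair
#' members and surfaces as a subclade-shared candidate, whereas sharing
#' between only two sister species is invisible to the within-pair quartet
#' (both carry the donor allele, a BBBA pattern).
#'
#' Colonization of an isolated crater lake is a founder event: the default
#' model gives the lake ancestor a bottleneck (`founder_ne` diploids for the
#' `founder_duration` generations following colonization) before expanding
#' to `ne_lake`. The bottleneck coalesces most lake lineages on the lake
#' stem, which is what makes the radiation predominantly monophyletic
#' genome-wide — the dominant signal in real crater-lake radiations.
#'
#' @param ne_lake,ne_riverine diploid effective sizes.
#' @param mu mutation rate per bp per generation.
#' @param founder_ne diploid size of the founding lake population
#'   (default 500); set to `ne_lake` to disable the bottleneck.
#' @param founder_duration generations the founding population stayed small
#'   after colonization (default 1000).
#' @param samples named integer vector of diploid sample counts (default: 3
#'   per lake species, 4 per riverine deme, 3 outgroup).
#' @return A [demographic_model()]. The lake species, subclade membership
#'   and role labels are attached as attributes `lake_species`,
#'   `subclades`, `donors` and `outgroup`.
#' @export
lake_demography <- function(ne_lake = 2e4, ne_riverine = 5e4, mu = 3.5e-9,
                            founder_ne = 500, founder_duration = 1000,
                            samples = c(lakeA1 = 3L, lakeA2 = 3L,
                                        lakeA3 = 3L, lakeB1 = 3L,
                                        lakeB2 = 3L, rivMM = 4L,
                                        rivCR = 4L, out = 3L)) {
  ne <- c(lakeA1 = ne_lake, lakeA2 = ne_lake, lakeA3 = ne_lake,
          lakeB1 = ne_lake, lakeB2 = ne_lake,
          rivMM = ne_riverine, rivCR = ne_riverine, out = ne_riverine)
  splits <- data.frame(
    time = c(2000, 2000, 4000, 10000, 20000, 100000, 500000),
    derived = c("lakeA3", "lakeB2", "lakeA2", "lakeB1", "lakeA1",
                "rivCR", "rivMM"),
    ancestral = c("lakeA2", "lakeB1", "lakeA1", "lakeA1", "rivMM",
                  "rivMM", "out"),
    stringsAsFactors = FALSE)
  size_changes <- if (founder_ne < ne_lake)
    data.frame(time = 20000 - founder_duration, deme = "lakeA1",
               size = founder_ne, stringsAsFactors = FALSE) else NULL
  m <- demographic_model(ne, samples, splits = splits, mu = mu,
                         size_changes = size_changes)
  attr(m, "lake_species") <- c("lakeA1", "lakeA2", "lakeA3",
                               "lakeB1", "lakeB2")
  attr(m, "subclades") <- c(lakeA1 = "A", lakeA2 = "A", lakeA3 = "A",
                            lakeB1 = "B", lakeB2 = "B")
  attr(m, "donors") <- c(MM = "rivMM", CR = "rivCR")
  attr(m, "outgroup") <- "out"
  m
}

# deme index bookkeeping for the event-driven simulation
.model_events <- function(model) {
  ev <- data.frame(time = numeric(), type = character(), a = character(),
                   b = character(), x = numeric(), stringsAsFactors = FALSE)
  if (!is.null(model$splits))
    ev <- rbind(ev, data.frame(time = model$splits$time, type = "split",
                               a = model$splits$derived,
                               b = model$splits$ancestral, x = NA_real_,
                               stringsAsFactors = FALSE))
  if (!is.null(model$pulses))
    ev <- rbind(ev, data.frame(time = model$pulses$time, type = "pulse",
                               a = model$pulses$recipient,
                               b = model$pulses$donor,
                               x = model$pulses$fraction,
                               stringsAsFactors = FALSE))
  if (!is.null(model$size_changes))
    ev <- rbind(ev, data.frame(time = model$size_changes$time, type = "size",
                               a = model$size_changes$deme, b = NA_character_,
                               x = model$size_changes$size,
                               stringsAsFactors = FALSE))
  # pulses before splits at exactly equal times, otherwise by time
  ord <- order(ev$time, match(ev$type, c("size", "pulse", "split")))
  ev[ord, , drop = FALSE]
}

#' Simulate one genealogy under the structured coalescent
#'
#' Backwards-time Hudson coalescent: within each deme, pairs coalesce at
#' rate `k(k-1)/2 / (2 Ne)` per generation; piecewise-constant sizes are
#' handled by restricting each exponential draw to the current epoch. At a
#' split time all lineages of the derived deme move to the ancestral deme;
#' at a pulse time each lineage of the recipient moves to the donor
#' independently with the pulse fraction. Simulation ends at the grand MRCA.
#'
#' @param model a [demographic_model()] with at least two sampled haploid
#'   lineages.
#' @return A genealogy: list with `n_tips`, `parent` (0 for the root),
#'   `time` (node ages in generations), `tip_deme`, and children pointers
#'   `child1`/`child2` for internal nodes.
#' @export
simulate_genealogy <- function(model) {
  tip_deme <- rep(names(model$samples), 2L * model$samples)
  n <- length(tip_deme)
  if (n < 2L) stop("need at least two sampled lineages")
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  child1 <- integer(n_nodes)
  child2 <- integer(n_nodes)
  time <- numeric(n_nodes)
  di <- match(tip_deme, model$demes)
  nd <- length(model$demes)
  cur_ne <- model$ne
  lin_node <- seq_len(n)
  lin_deme <- di
  ev <- .model_events(model)
  ei <- 1L
  t <- 0
  nxt <- n
  while (length(lin_node) > 1L) {
    k <- tabulate(lin_deme, nd)
    rates <- ifelse(k >= 2L, k * (k - 1L) / 2 / (2 * cur_ne), 0)
    R <- sum(rates)
    t_ev <- if (ei <= nrow(ev)) ev$time[ei] else Inf
    tc <- if (R > 0) t + stats::rexp(1L, R) else Inf
    if (tc < t_ev) {
      d <- sample.int(nd, 1L, prob = rates)
      ids <- which(lin_deme == d)
      pick <- ids[sample.int(length(ids), 2L)]
      nxt <- nxt + 1L
      time[nxt] <- tc
      child1[nxt] <- lin_node[pick[1]]
      child2[nxt] <- lin_node[pick[2]]
      parent[lin_node[pick]] <- nxt
      lin_node <- c(lin_node[-pick], nxt)
      lin_deme <- c(lin_deme[-pick], d)
      t <- tc
    } else if (is.finite(t_ev)) {
      t <- t_ev
      if (ev$type[ei] == "split") {
        from <- match(ev$a[ei], model$demes)
        to <- match(ev$b[ei], model$demes)
        lin_deme[lin_deme == from] <- to
      } else if (ev$type[ei] == "pulse") {
        from <- match(ev$a[ei], model$demes)
        to <- match(ev$b[ei], model$demes)
        mv <- lin_deme == from & stats::runif(length(lin_deme)) < ev$x[ei]
        lin_deme[mv] <- to
      } else {
        cur_ne[ev$a[ei]] <- ev$x[ei]
      }
      ei <- ei + 1L
    } else {
      stop("lineages remain in demes that never share an ancestor")
    }
  }
  list(n_tips = n, parent = parent, time = time, tip_deme = tip_deme,
       child1 = child1, child2 = child2, root = nxt)
}

# tips descended from each node, as a list of integer vectors
.descendant_tips <- function(gen) {
  n <- gen$n_tips
  desc <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) desc[[i]] <- i
  internal <- order(gen$time[(n + 1L):(2L * n - 1L)]) + n
  for (nn in internal)
    desc[[nn]] <- c(desc[[gen$child1[nn]]], desc[[gen$child2[nn]]])
  desc
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Each branch receives `Poisson(mu * block_bp * length)` mutations; each
#' mutation occupies a fresh position (unique within the block, drawn
#' uniformly from `1:block_bp`) and is carried by all tips descending from
#' the branch's child node.
#'
#' @param gen a genealogy from [simulate_genealogy()].
#' @param mu mutation rate per bp per generation.
#' @param block_bp length of the non-recombining block in bp.
#' @return List with integer vector `pos` (sorted, 1-based) and binary
#'   haplotype matrix `hap` (variants x tips).
#' @export
drop_mutations <- function(gen, mu, block_bp) {
  n_nodes <- 2L * gen$n_tips - 1L
  nodes <- seq_len(n_nodes)[-gen$root]
  len <- gen$time[gen$parent[nodes]] - gen$time[nodes]
  m <- stats::rpois(length(nodes), mu * block_bp * len)
  M <- sum(m)
  if (M == 0L)
    return(list(pos = integer(),
                hap = matrix(0L, 0L, gen$n_tips)))
  if (M > block_bp) {
    # infinite-sites saturation; keep one mutation per available position
    keep <- block_bp
    m <- stats::rmultinom(1L, keep, m / M)[, 1]
    M <- keep
  }
  desc <- .descendant_tips(gen)
  carrier_nodes <- rep(nodes, m)
  pos <- sort(sample.int(block_bp, M))
  # mutations are exchangeable; assign sorted positions in branch order
  hap <- matrix(0L, M, gen$n_tips)
  for (i in seq_len(M)) hap[i, desc[[carrier_nodes[i]]]] <- 1L
  list(pos = pos, hap = hap)
}

#' Simulate a genomic window of concatenated coalescent blocks
#'
#' Recombination within a window is approximated by concatenating
#' `blocks_per_window` independent non-recombining blocks of equal length;
#' positions are offset per block. Haplotypes are paired into diploid
#' genotypes in sample order (samples named `<deme>_<i>`).
#'
#' @param model a [demographic_model()].
#' @param window_bp window length in bp (default 50000); must be divisible
#'   by `blocks_per_window`.
#' @param blocks_per_window number of independent blocks (default 10).
#' @return A `sim_window`: list with `pos` (1-based positions), `geno`
#'   (variants x diploid samples alt-count matrix), `samples`, `sample_deme`,
#'   `window_bp`.
#' @export
simulate_window <- function(model, window_bp = 50000L, blocks_per_window = 10L) {
  if (blocks_per_window < 1L) stop("blocks_per_window must be >= 1")
  if (window_bp %% blocks_per_window != 0L)
    stop("window_bp must be divisible by blocks_per_window")
  sub <- window_bp %/% blocks_per_window
  sampled <- model$samples[model$samples > 0L]
  samples <- unlist(lapply(names(sampled), function(d)
    paste0(d, "_", seq_len(sampled[[d]]))), use.names = FALSE)
  sample_deme <- rep(names(sampled), sampled)
  pos_all <- integer()
  geno_all <- list()
  for (b in seq_len(blocks_per_window)) {
    gen <- simulate_genealogy(model)
    mut <- drop_mutations(gen, model$mu, sub)
    if (length(mut$pos)) {
      idx1 <- seq(1L, ncol(mut$hap), by = 2L)
      geno <- mut$hap[, idx1, drop = FALSE] + mut$hap[, idx1 + 1L, drop = FALSE]
      pos_all <- c(pos_all, mut$pos + (b - 1L) * sub)
      geno_all[[length(geno_all) + 1L]] <- geno
    }
  }
  geno <- if (length(geno_all)) do.call(rbind, geno_all) else
    matrix(0L, 0L, length(samples))
  colnames(geno) <- samples
  structure(list(pos = pos_all, geno = geno, samples = samples,
                 sample_deme = sample_deme, window_bp = window_bp),
            class = "sim_window")
}

#' Convert a simulated window to a genotype matrix
#'
#' Monomorphic-in-sample variants (possible when some demes are unsampled)
#' are dropped, matching [read_vcf()] behaviour. Reference/alternate alleles
#' are assigned deterministically from the position.
#'
#' @param sw a `sim_window`.
#' @param chrom chromosome name for the window's sites.
#' @return A [genotype_matrix()].
#' @export
sim_window_genotypes <- function(sw, chrom = "sim_1") {
  keep <- apply(sw$geno, 1L, function(g) any(g != g[1]) || (g[1] %in% 1L))
  pos <- sw$pos[keep]
  geno <- sw$geno[keep, , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  gm <- genotype_matrix(
    data.frame(chrom = rep(chrom, length(pos)), pos = pos,
               ref = bases[(pos %% 4L) + 1L],
               alt = bases[((pos + 1L) %% 4L) + 1L]),
    sw$samples, geno)
  attr(gm, "contig_lengths") <- stats::setNames(sw$window_bp, chrom)
  gm
}

# population map of a model's sampled demes
model_population_map <- function(model) {
  sampled <- model$samples[model$samples > 0L]
  population_map(stats::setNames(
    lapply(names(sampled), function(d) paste0(d, "_", seq_len(sampled[[d]]))),
    names(sampled)))
}

# fd of one simulated window for a quartet (in-memory fast path sharing
# fd_statistic/usable_sites with the VCF route)
.sim_window_fd <- function(sw, quartet, min_sites) {
  gm <- sim_window_genotypes(sw)
  if (nrow(gm$sites) == 0) return(NA_real_)
  freqs <- allele_frequencies(gm, model_population_map_cached(sw))
  freqs <- polarize_frequencies(freqs, quartet$outgroup)
  w <- list(chrom = "sim_1", start = 0, end = sw$window_bp)
  idx <- usable_sites(w, freqs,
                      c(quartet$p1, quartet$p2, quartet$p3, quartet$outgroup))
  if (length(idx) < min_sites) return(NA_real_)
  fd_statistic(freqs$p_derived[idx, quartet$p1],
               freqs$p_derived[idx, quartet$p2],
               freqs$p_derived[idx, quartet$p3],
               freqs$p_derived[idx, quartet$outgroup])$fd
}

model_population_map_cached <- function(sw) {
  demes <- unique(sw$sample_deme)
  population_map(stats::setNames(
    lapply(demes, function(d) sw$samples[sw$sample_deme == d]), demes))
}

#' Null fd threshold from no-migration simulations
#'
#' Simulates `n_windows` windows under a pulse-free model, computes fd for
#' the quartet on each usable window, and returns a significance threshold:
#' either the maximum simulated value (default, i.e. a candidate must exceed
#' every simulated null window) or an upper quantile. Demes outside the
#' quartet are not sampled during the null simulation (with no migration
#' they are exactly marginalizable and do not affect the quartet genealogy).
#'
#' @param model a [demographic_model()] without pulses.
#' @param quartet a [quartet_config()] whose labels are model demes.
#' @param n_windows number of null windows (>= 100).
#' @param rule `"max"` or `"quantile"`.
#' @param q quantile for `rule = "quantile"` (default 0.95).
#' @param window_bp,blocks_per_window window geometry (defaults 50000, 10).
#' @param min_sites minimum usable variant sites per window (default 100).
#' @return List with `threshold`, the simulated `fd_values` (defined values
#'   only), `n_usable`, `rule` and `q`.
#' @export
null_fd_threshold <- function(model, quartet, n_windows = 1000L,
                              rule = c("max", "quantile"), q = 0.95,
                              window_bp = 50000L, blocks_per_window = 10L,
                              min_sites = 100L) {
  rule <- match.arg(rule)
  if (!is.null(model$pulses) && nrow(model$pulses) > 0)
    stop("null model must contain no admixture pulses")
  if (n_windows < 100L) stop("need at least 100 null windows")
  qd <- c(quartet$p1, quartet$p2, quartet$p3, quartet$outgroup)
  keep <- model$samples
  keep[setdiff(names(keep), qd)] <- 0L
  null_model <- model
  null_model$samples <- keep
  fds <- vapply(seq_len(n_windows), function(i) {
    sw <- simulate_window(null_model, window_bp, blocks_per_window)
    .sim_window_fd(sw, quartet, min_sites)
  }, numeric(1))
  fds <- fds[!is.na(fds)]
  if (length(fds) < 50L)
    stop("fewer than 50 usable simulated null windows; increase mu, ",
         "samples or n_windows")
  threshold <- if (rule == "max") max(fds) else
    unname(stats::quantile(fds, q))
  list(threshold = threshold, fd_values = fds, n_usable = length(fds),
       rule = rule, q = if (rule == "quantile") q else NA_real_)
}
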