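#' Scenario specification for synthetic datasets
#'
#' Three study conditions are supported: `"none"` (no gene flow anywhere),
#' `"secondary_pulse"` (a single post-divergence admixture pulse from the
#' nearby riverine deme into one lake species, applied only in truth
#' windows) and `"hybrid_swarm"` (two pre-divergence pulses from both
#' riverine demes into the lake ancestor, applied only in truth windows).
#'
#' Truth windows are the windows that actually carry introgressed material;
#' if `introgressed_window_ids` is not given, `round(prop_truth * n_windows)`
#' windows are drawn at random under `seed`.
#'
#' @param kind one of `"none"`, `"secondary_pulse"`, `"hybrid_swarm"`.
#' @param n_windows number of simulated windows (one contig each).
#' @param window_bp window length in bp (default 50000).
#' @param blocks_per_window independent coalescent blocks per window
#'   (default 10).
#' @param introgressed_window_ids integer vector of truth window ids, or
#'   `NULL` to sample them.
#' @param prop_truth fraction of windows carrying introgression when ids are
#'   sampled (default 0.1).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @param pulse_fraction admixture fraction. For a secondary pulse, the
#'   per-lineage pulse probability (default 0.8). For a hybrid swarm, the
#'   nearby-donor share of the founding mixture (default 0.5): the recent
#'   pulse moves lineages to the nearby donor with this probability and the
#'   older pulse moves all remaining lineages to the distant donor, so the
#'   founding population is entirely a two-source riverine mixture with no
#'   residual third ancestry — the defining feature of a hybrid swarm.
#' @param pulse_time time of the secondary pulse in generations (default
#'   500, i.e. after the close-pair split).
#' @param swarm_times times of the two hybrid-swarm founding pulses
#'   (default 10500 and 10600, just older than the lake root).
#' @param recipient lake species receiving the secondary pulse (default
#'   `"lakeA3"`, a member of the close species pair).
#' @param donors donor demes, nearby first (default `c("rivMM", "rivCR")`).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("none", "secondary_pulse", "hybrid_swarm"),
                          n_windows = 200L, window_bp = 50000L,
                          blocks_per_window = 10L,
                          introgressed_window_ids = NULL, prop_truth = 0.1,
                          seed = 1L, pulse_fraction = NULL, pulse_time = 500,
                          swarm_times = c(10500, 10600),
                          recipient = "lakeA3",
                          donors = c("rivMM", "rivCR")) {
  kind <- match.arg(kind)
  if (is.null(pulse_fraction))
    pulse_fraction <- if (kind == "hybrid_swarm") 0.5 else 0.8
  if (kind == "none") {
    introgressed_window_ids <- integer()
  } else if (is.null(introgressed_window_ids)) {
    set.seed(seed)
    n_truth <- max(1L, round(prop_truth * n_windows))
    introgressed_window_ids <- sort(sample.int(n_windows, n_truth))
  } else {
    introgressed_window_ids <- sort(as.integer(introgressed_window_ids))
    if (any(introgressed_window_ids < 1L |
            introgressed_window_ids > n_windows))
      stop("introgressed_window_ids out of range")
  }
  if (kind == "none" && length(introgressed_window_ids))
    stop("kind = 'none' cannot have truth windows")
  structure(list(kind = kind, n_windows = as.integer(n_windows),
                 window_bp = as.integer(window_bp),
                 blocks_per_window = as.integer(blocks_per_window),
                 introgressed_window_ids = introgressed_window_ids,
                 seed = as.integer(seed), pulse_fraction = pulse_fraction,
                 pulse_time = pulse_time, swarm_times = swarm_times,
                 recipient = recipient, donors = donors),
            class = "scenario_spec")
}

# model with the scenario's pulses added (the truth-window model)
.scenario_truth_model <- function(spec, base_model) {
  if (spec$kind == "none") return(base_model)
  missing <- setdiff(c(spec$recipient, spec$donors), base_model$demes)
  if (length(missing))
    stop("scenario deme(s) missing from base model: ",
         paste(missing, collapse = ", "))
  pulses <- if (spec$kind == "secondary_pulse") {
    data.frame(time = spec$pulse_time, recipient = spec$recipient,
               donor = spec$donors[1], fraction = spec$pulse_fraction,
               stringsAsFactors = FALSE)
  } else {
    # hybrid swarm: the founding lake population is entirely a mixture of
    # the two riverine sources. Backwards in time, lineages of the lake
    # ancestor move to the nearby donor with probability pulse_fraction,
    # and every remaining lineage moves to the distant donor just after.
    anc <- .lake_ancestor_deme(base_model, spec)
    data.frame(time = spec$swarm_times,
               recipient = anc, donor = spec$donors,
               fraction = c(spec$pulse_fraction, 1),
               stringsAsFactors = FALSE)
  }
  demographic_model(base_model$ne, base_model$samples[base_model$samples > 0],
                    splits = base_model$splits, pulses = pulses,
                    mu = base_model$mu, size_changes = base_model$size_changes)
}

.lake_ancestor_deme <- function(model, spec) {
  lake <- attr(model, "lake_species")
  if (is.null(lake))
    stop("base model must carry a 'lake_species' attribute (see lake_demography)")
  # the deme that remains after all intra-lake splits
  sp <- model$splits
  merged_in_lake <- sp$derived[sp$derived %in% lake & sp$ancestral %in% lake]
  anc <- setdiff(lake, merged_in_lake)
  if (length(anc) != 1L) stop("cannot identify the lake ancestor deme")
  anc
}

#' Generate a synthetic scenario dataset
#'
#' Simulates `spec$n_windows` windows (one synthetic contig `sim_<i>` per
#' window), applying the scenario's admixture pulses only in the truth
#' windows, and writes a standards-compliant VCF, a sample-to-population map
#' TSV, a truth BED (0-based half-open) of introgressed windows and a JSON
#' run manifest. Identical spec and seed give byte-identical output.
#'
#' @param spec a [scenario_spec()].
#' @param base_model a pulse-free [demographic_model()], e.g.
#'   [lake_demography()].
#' @param dir output directory (created if needed).
#' @return List with paths (`vcf`, `popmap`, `truth_bed`, `manifest`), the
#'   truth window ids, and `contig_lengths`.
#' @export
generate_scenario <- function(spec, base_model, dir) {
  if (!is.null(base_model$pulses) && nrow(base_model$pulses) > 0)
    stop("base model must be pulse-free; pulses are added per scenario")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth_model <- .scenario_truth_model(spec, base_model)
  set.seed(spec$seed + 1L)
  sites <- vector("list", spec$n_windows)
  genos <- vector("list", spec$n_windows)
  for (w in seq_len(spec$n_windows)) {
    m <- if (w %in% spec$introgressed_window_ids) truth_model else base_model
    sw <- simulate_window(m, spec$window_bp, spec$blocks_per_window)
    gm <- sim_window_genotypes(sw, chrom = paste0("sim_", w))
    sites[[w]] <- gm$sites
    genos[[w]] <- gm$calls
    samples <- gm$samples
  }
  all_sites <- do.call(rbind, sites)
  all_geno <- do.call(rbind, genos)
  # preserve window order: contig names sort as sim_1, sim_2, ... here by
  # construction order, not lexicographically
  gm <- structure(list(sites = all_sites, samples = samples,
                       calls = all_geno), class = "genotype_matrix")
  contig_lengths <- stats::setNames(
    rep(spec$window_bp, spec$n_windows),
    paste0("sim_", seq_len(spec$n_windows)))
  vcf <- file.path(dir, "scenario.vcf")
  write_genotype_vcf(gm, vcf, contig_lengths)

  popmap <- model_population_map(base_model)
  popmap_path <- file.path(dir, "popmap.tsv")
  utils::write.table(
    data.frame(sample = names(popmap$assignments),
               population = unname(popmap$assignments)),
    popmap_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)

  truth_bed <- file.path(dir, "truth.bed")
  tw <- spec$introgressed_window_ids
  bed <- if (length(tw))
    sprintf("sim_%d\t0\t%d", tw, spec$window_bp) else character()
  writeLines(bed, truth_bed)

  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(seed = spec$seed, kind = spec$kind, n_windows = spec$n_windows,
         window_bp = spec$window_bp,
         blocks_per_window = spec$blocks_per_window,
         introgressed_window_ids = spec$introgressed_window_ids,
         pulse_fraction = spec$pulse_fraction,
         recipient = spec$recipient, donors = spec$donors,
         mu = base_model$mu, ne = as.list(base_model$ne),
         samples = as.list(base_model$samples[base_model$samples > 0])),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(vcf = vcf, popmap = popmap_path, truth_bed = truth_bed,
       manifest = manifest, truth_windows = tw,
       contig_lengths = contig_lengths)
}

#' Simulate a scenario dataset (pipeline entry point)
#'
#' Thin orchestration wrapper over [generate_scenario()].
#'
#' @inheritParams generate_scenario
#' @export
run_simulate <- function(spec, base_model = lake_demography(), dir) {
  generate_scenario(spec, base_model, dir)
}

#' Run a full introgression scan
#'
#' End-to-end orchestration: read the VCF and population map, compute
#' allele frequencies, run the fd sliding-window scan and the genome-wide
#' f4 test for each quartet, call candidate regions against the supplied
#' thresholds, and compute the per-window diversity/divergence table.
#' Outputs are deterministic given fixed inputs.
#'
#' @param vcf path to the input VCF.
#' @param popmap path to the sample-to-population TSV.
#' @param quartets list of [quartet_config()] objects.
#' @param thresholds numeric vector of fd thresholds, one per quartet
#'   (recycled), e.g. from [null_fd_threshold()].
#' @param window_size,step window geometry in bp (defaults 50000, 5000).
#' @param min_sites minimum usable variant sites per window (default 100).
#' @param chrom_lengths optional named vector; defaults to the VCF's
#'   `##contig` headers, else the maximum observed position per chromosome.
#' @param out_dir optional directory to write TSV/BED outputs into.
#' @return List with `windows`, `fd_scans` (per quartet), `f4_table`,
#'   `candidates` (per quartet), `window_stats`.
#' @export
run_scan <- function(vcf, popmap, quartets, thresholds,
                     window_size = 50000L, step = 5000L, min_sites = 100L,
                     chrom_lengths = NULL, out_dir = NULL) {
  gm <- read_vcf(vcf)
  pm <- read_population_map(popmap, gm)
  pops_needed <- unique(unlist(lapply(quartets, .quartet_labels)))
  unknown <- setdiff(pops_needed, names(pm$populations))
  if (length(unknown))
    stop("config references unknown population(s): ",
         paste(unknown, collapse = ", "))
  freqs <- allele_frequencies(gm, pm)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- attr(gm, "contig_lengths")
    if (is.null(chrom_lengths))
      chrom_lengths <- tapply(gm$sites$pos, gm$sites$chrom, max)
  }
  windows <- make_windows(chrom_lengths, window_size, step)
  thresholds <- rep_len(thresholds, length(quartets))
  fd_scans <- list()
  candidates <- list()
  f4_rows <- list()
  for (i in seq_along(quartets)) {
    qt <- quartets[[i]]
    pf <- polarize_frequencies(freqs, qt$outgroup)
    scan <- fd_scan(pf, windows, qt, min_sites)
    nm <- paste(qt$p1, qt$p2, qt$p3, sep = "_")
    fd_scans[[nm]] <- scan
    candidates[[nm]] <- call_candidates(scan, thresholds[i])
    f4_rows[[nm]] <- f4_test(freqs, qt)
  }
  f4_table <- do.call(rbind, f4_rows)
  rownames(f4_table) <- NULL
  wstats <- window_stat_table(freqs, windows, pops = pops_needed,
                              min_sites = min_sites)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(wstats, file.path(out_dir, "window_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(f4_table, file.path(out_dir, "f4_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(fd_scans)) {
      utils::write.table(fd_scans[[nm]],
                         file.path(out_dir, paste0("fd_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cand <- candidates[[nm]]
      bed <- sprintf("%s\t%d\t%d", cand$chrom, as.integer(cand$start),
                     as.integer(cand$end))
      writeLines(bed, file.path(out_dir, paste0("candidates_", nm, ".bed")))
    }
  }
  list(windows = windows, fd_scans = fd_scans, f4_table = f4_table,
       candidates = candidates, window_stats = wstats)
}
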