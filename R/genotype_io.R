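#' Construct a genotype matrix
#'
#' The central in-memory container for biallelic SNP genotypes: a site table
#' (chromosome, 1-based position, reference and alternate allele) and an
#' integer matrix of diploid alternate-allele counts (0, 1, 2 or `NA` for a
#' missing call), one row per site and one column per sample.
#'
#' Sites are sorted by (chrom, pos); duplicate positions on a chromosome are
#' an error, as are alleles that are not single nucleotides.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param samples character vector of sample identifiers.
#' @param calls integer matrix, `nrow(sites)` x `length(samples)`, entries in
#'   0:2 or `NA`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, samples, calls) {
  stopifnot(is.data.frame(sites))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites)))
    stop("`sites` must have columns chrom, pos, ref, alt")
  sites <- sites[, need]
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  samples <- as.character(samples)
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(sites) || ncol(calls) != length(samples))
    stop("dimensions of `calls` do not match sites x samples")
  storage.mode(calls) <- "integer"
  if (nrow(sites) > 0) {
    if (any(sites$pos < 1L)) stop("positions must be >= 1")
    bases <- c("A", "C", "G", "T")
    if (!all(sites$ref %in% bases) || !all(sites$alt %in% bases))
      stop("alleles must be single nucleotides (biallelic SNPs only)")
    if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
    ok <- calls[!is.na(calls)]
    if (length(ok) && (min(ok) < 0L || max(ok) > 2L))
      stop("genotype calls must be diploid alt-allele counts in 0:2")
    ord <- order(sites$chrom, sites$pos)
    if (any(ord != seq_len(nrow(sites)))) {
      sites <- sites[ord, , drop = FALSE]
      calls <- calls[ord, , drop = FALSE]
      rownames(sites) <- NULL
    }
    if (anyDuplicated(paste(sites$chrom, sites$pos)))
      stop("duplicate (chrom, pos) entries are not allowed")
  }
  dimnames(calls) <- list(NULL, samples)
  structure(list(sites = sites, samples = samples, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "biallelic SNPs x",
      length(x$samples), "samples on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param x a `genotype_matrix`.
#' @export
n_sites <- function(x) nrow(x$sites)

# GT-string -> alt-allele dosage lookup (phased and unphased)
.gt_lookup <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
                "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)

#' Read a VCF into a genotype matrix
#'
#' Reads a VCF 4.x file (plain or bgzipped) and retains only biallelic SNP
#' records. Indels, multiallelic records, records with fewer than
#' `min_samples_called` called genotypes, and records that are monomorphic
#' across all called samples after filtering are dropped. Only the GT field
#' is used; ploidy other than diploid at a call is treated as missing.
#'
#' Contig lengths found in `##contig` header lines are attached as the
#' `"contig_lengths"` attribute of the result.
#'
#' @param path path to the VCF file.
#' @param min_samples_called minimum number of samples with a called genotype
#'   for a site to be retained (default 1).
#' @param samples optional character vector restricting (and ordering) the
#'   samples; a requested sample absent from the header is a fatal error.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, min_samples_called = 1L, samples = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  all_samples <- colnames(v@gt)[-1]
  if (!is.null(samples)) {
    missing <- setdiff(samples, all_samples)
    if (length(missing))
      stop("sample(s) absent from VCF header: ", paste(missing, collapse = ", "))
  } else {
    samples <- all_samples
  }

  contig_lengths <- .parse_contig_lengths(v@meta)

  if (is.null(fix) || nrow(fix) == 0) {
    warning("VCF contains no records")
    gm <- genotype_matrix(
      data.frame(chrom = character(), pos = integer(),
                 ref = character(), alt = character()),
      samples, matrix(integer(), 0, length(samples)))
    attr(gm, "contig_lengths") <- contig_lengths
    return(gm)
  }

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[, samples, drop = FALSE]
  calls <- matrix(.gt_lookup[gt], nrow = nrow(gt), ncol = ncol(gt))

  called <- rowSums(!is.na(calls))
  mono <- apply(calls, 1L, function(g) {
    g <- g[!is.na(g)]
    length(g) == 0L || all(g == 0L) || all(g == 2L)
  })
  keep <- snp & called >= min_samples_called & !mono
  if (!any(keep))
    warning("no biallelic polymorphic SNPs retained from ", path)

  gm <- genotype_matrix(
    data.frame(chrom = fix[keep, "CHROM"],
               pos = as.integer(fix[keep, "POS"]),
               ref = ref[keep], alt = alt[keep]),
    samples,
    calls[keep, , drop = FALSE])
  attr(gm, "contig_lengths") <- contig_lengths
  gm
}

.parse_contig_lengths <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  if (!length(ln)) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", ln)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ln)))
  names(lens) <- ids
  lens[!is.na(lens)]
}

#' Read a sample-to-population map
#'
#' Two-column tab-separated file without header: sample identifier, population
#' label. Every sample of `matrix` must be mapped exactly once; samples in the
#' file that are absent from the matrix are ignored with a warning.
#' Populations are ordered lexicographically, members in matrix sample order.
#'
#' @param path path to the TSV file.
#' @param matrix a [genotype_matrix()].
#' @return An object of class `population_map` with elements `assignments`
#'   (named character, sample -> population) and `populations` (named list,
#'   population -> member samples).
#' @export
read_population_map <- function(path, matrix) {
  if (!file.exists(path)) stop("cannot read population map: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("sample", "population"),
                          colClasses = "character")
  if (anyDuplicated(df$sample))
    stop("duplicate sample line(s) in population map: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  extra <- setdiff(df$sample, matrix$samples)
  if (length(extra)) {
    warning("population map samples not in VCF ignored: ",
            paste(extra, collapse = ", "))
    df <- df[!df$sample %in% extra, , drop = FALSE]
  }
  unmapped <- setdiff(matrix$samples, df$sample)
  if (length(unmapped))
    stop("sample(s) missing from population map: ",
         paste(unmapped, collapse = ", "))
  assignments <- stats::setNames(df$population, df$sample)[matrix$samples]
  pops <- sort(unique(unname(assignments)))
  populations <- lapply(pops, function(p)
    matrix$samples[assignments[matrix$samples] == p])
  names(populations) <- pops
  structure(list(assignments = assignments, populations = populations),
            class = "population_map")
}

#' Build a population map from a named list
#'
#' Programmatic counterpart of [read_population_map()] for simulated data.
#'
#' @param populations named list: population label -> character vector of
#'   member samples.
#' @return A `population_map`.
#' @export
population_map <- function(populations) {
  populations <- populations[order(names(populations))]
  if (any(lengths(populations) == 0)) stop("empty population in map")
  samples <- unlist(populations, use.names = FALSE)
  if (anyDuplicated(samples)) stop("sample assigned to more than one population")
  assignments <- stats::setNames(
    rep(names(populations), lengths(populations)), samples)
  structure(list(assignments = assignments, populations = populations),
            class = "population_map")
}

#' Per-population allele counts and frequencies
#'
#' For every site and population, counts the called allele copies and the
#' alternate-allele frequency. Missing genotypes are excluded from the
#' denominator; a population with no called genotype at a site has an
#' undefined frequency (`NA`).
#'
#' @param matrix a [genotype_matrix()].
#' @param popmap a `population_map` covering the matrix samples.
#' @return An object of class `pop_freqs`: site table plus matrices
#'   `n_called` (called allele copies) and `p_alt` (alt-allele frequency),
#'   one column per population, and `pop_sizes` (diploid members per
#'   population).
#' @export
allele_frequencies <- function(matrix, popmap) {
  unk <- setdiff(matrix$samples, names(popmap$assignments))
  if (length(unk))
    stop("samples not covered by population map: ", paste(unk, collapse = ", "))
  pops <- names(popmap$populations)
  ns <- nrow(matrix$sites)
  n_called <- matrix(0L, ns, length(pops), dimnames = list(NULL, pops))
  alt_count <- matrix(0L, ns, length(pops), dimnames = list(NULL, pops))
  for (p in pops) {
    cols <- matrix$calls[, popmap$populations[[p]], drop = FALSE]
    n_called[, p] <- 2L * as.integer(rowSums(!is.na(cols)))
    alt_count[, p] <- as.integer(rowSums(cols, na.rm = TRUE))
  }
  p_alt <- alt_count / n_called
  p_alt[n_called == 0L] <- NA_real_
  structure(list(sites = matrix$sites, pops = pops,
                 n_called = n_called, p_alt = p_alt,
                 pop_sizes = stats::setNames(
                   lengths(popmap$populations), pops)),
            class = "pop_freqs")
}

#' Polarize frequencies by a distant outgroup
#'
#' Designates as "derived" the allele that is minor (frequency < 0.5) in the
#' outgroup population; at an exact tie (outgroup frequency 0.5) the alternate
#' allele is treated as derived, which makes polarization deterministic.
#' Sites where the outgroup is entirely uncalled cannot be polarized and get
#' `NA` derived frequencies in every population.
#'
#' @param freqs a `pop_freqs` object from [allele_frequencies()].
#' @param outgroup population label of the distant outgroup.
#' @return `freqs` with an added `p_derived` matrix and the `outgroup` label.
#' @export
polarize_frequencies <- function(freqs, outgroup) {
  if (!outgroup %in% freqs$pops)
    stop("outgroup population not found: ", outgroup)
  p_o <- freqs$p_alt[, outgroup]
  flip <- !is.na(p_o) & p_o > 0.5
  p_derived <- freqs$p_alt
  p_derived[flip, ] <- 1 - p_derived[flip, , drop = FALSE]
  p_derived[is.na(p_o), ] <- NA_real_
  freqs$p_derived <- p_derived
  freqs$outgroup <- outgroup
  freqs
}

#' @export
print.pop_freqs <- function(x, ...) {
  cat("pop_freqs:", nrow(x$sites), "sites x", length(x$pops), "populations",
      if (!is.null(x$outgroup)) paste0("(polarized on ", x$outgroup, ")"),
      "\n")
  invisible(x)
}

#' Write a genotype matrix to a VCF file
#'
#' Minimal standards-compliant VCF 4.2 writer (GT-only) used for simulated
#' datasets and test fixtures.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param contig_lengths optional named vector of contig lengths for the
#'   header (defaults to the `"contig_lengths"` attribute of `gm`).
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path, contig_lengths = NULL) {
  if (is.null(contig_lengths)) contig_lengths <- attr(gm, "contig_lengths")
  header <- c("##fileformat=VCFv4.2",
              "##source=introscan",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_lengths))
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contig_lengths),
                                as.integer(contig_lengths)))
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", gm$samples),
                            collapse = "\t"))
  gt_str <- c("0/0", "0/1", "1/1")
  body <- character(nrow(gm$sites))
  if (nrow(gm$sites) > 0) {
    gt <- matrix("./.", nrow(gm$calls), ncol(gm$calls))
    ok <- !is.na(gm$calls)
    gt[ok] <- gt_str[gm$calls[ok] + 1L]
    body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                  gm$sites$alt, ".", "PASS", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
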