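# Core containers: haplotype panels and population maps.
#
# Site coordinates follow the half-open 0-based convention used throughout the
# package: a span [s, e) covers site indices s .. e-1. Population indices are
# 1-based, matching R's factor-level convention.

#' Phased haplotype panel
#'
#' An ordered set of phased binary haplotypes over `N` biallelic sites on one
#' chromosome. Rows are haplotypes (two consecutive rows per diploid sample:
#' `<sample>_0` then `<sample>_1`), columns are sites in strictly increasing
#' physical order.
#'
#' @param alleles integer or numeric matrix of 0/1 values, one row per
#'   haplotype, one column per site.
#' @param positions strictly increasing physical coordinates (bp), one per
#'   column of `alleles`.
#' @param chrom chromosome identifier (single string).
#' @param sample_ids ordered sample identifiers; each sample owns two
#'   consecutive haplotype rows. Defaults to `s1, s2, ...`.
#' @param ref,alt reference/alternate alleles per site (used to key site
#'   harmonization and to write VCF). Default `"A"`/`"C"`.
#'
#' @return An object of class `haplotype_panel` with fields `alleles`,
#'   `positions`, `chrom`, `ref`, `alt`, `hap_ids`, `sample_ids`.
#' @export
haplotype_panel <- function(alleles, positions, chrom = "1",
                            sample_ids = NULL, ref = NULL, alt = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  M <- nrow(alleles)
  N <- ncol(alleles)
  if (N < 1L || M < 2L)
    stop("a haplotype panel needs at least 2 haplotypes and 1 site")
  if (M %% 2L != 0L)
    stop("odd number of haplotype rows: every sample must contribute exactly 2")
  if (anyNA(alleles) || !all(alleles == 0L | alleles == 1L))
    stop("alleles must all be 0 or 1 (phased biallelic)")
  positions <- as.integer(positions)
  if (length(positions) != N)
    stop("length(positions) must equal ncol(alleles)")
  if (N > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(M %/% 2L))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != M %/% 2L)
    stop("need exactly one sample id per pair of haplotype rows")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids")
  if (is.null(ref)) ref <- rep("A", N)
  if (is.null(alt)) alt <- rep("C", N)
  hap_ids <- as.vector(rbind(paste0(sample_ids, "_0"), paste0(sample_ids, "_1")))
  rownames(alleles) <- hap_ids
  structure(
    list(alleles = alleles, positions = positions, chrom = as.character(chrom),
         ref = as.character(ref), alt = as.character(alt),
         hap_ids = hap_ids, sample_ids = sample_ids),
    class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes (%d samples) x %d sites, chrom %s\n",
              nrow(x$alleles), length(x$sample_ids), ncol(x$alleles), x$chrom))
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$alleles)

n_sites <- function(panel) ncol(panel$alleles)
n_haps  <- function(panel) nrow(panel$alleles)

#' Restrict a panel to a subset of site columns
#'
#' @param panel a [haplotype_panel()].
#' @param idx integer vector of 1-based column indices, in the order to keep.
#' @return a `haplotype_panel` over the selected sites.
#' @export
subset_sites <- function(panel, idx) {
  idx <- as.integer(idx)
  if (length(idx) < 1L) stop("cannot subset a panel down to zero sites")
  haplotype_panel(panel$alleles[, idx, drop = FALSE], panel$positions[idx],
                  chrom = panel$chrom, sample_ids = panel$sample_ids,
                  ref = panel$ref[idx], alt = panel$alt[idx])
}

#' Remove low minor-allele-frequency sites
#'
#' Retains exactly the sites whose minor allele frequency across all panel
#' haplotypes is at least `threshold`; site order is preserved. Idempotent.
#' With `threshold = 0` the panel is returned unchanged.
#'
#' @param panel a [haplotype_panel()].
#' @param threshold MAF threshold in `[0, 0.5)`.
#' @return the filtered `haplotype_panel` (possibly with zero sites, in which
#'   case an error is raised by the panel constructor only when you try to
#'   rebuild it; here an empty result is signalled with an error since a
#'   panel cannot be empty).
#' @export
maf_filter <- function(panel, threshold) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (threshold < 0 || threshold >= 0.5)
    stop("MAF threshold must be in [0, 0.5)")
  if (threshold == 0) return(panel)
  freq <- colMeans(panel$alleles)
  maf <- pmin(freq, 1 - freq)
  keep <- which(maf >= threshold)
  if (length(keep) == 0L)
    stop("MAF filter at threshold ", threshold, " removed every site")
  if (length(keep) == n_sites(panel)) return(panel)
  subset_sites(panel, keep)
}

#' Restrict two panels to their shared sites
#'
#' Sites are matched on (position, ref, alt); both panels are reduced to the
#' intersection in ascending position order, so their columns align exactly.
#'
#' @param query,ref two [haplotype_panel()]s on the same chromosome.
#' @return a list with elements `query`, `ref` (the harmonized panels) and
#'   `dropped`, a named integer vector giving the number of sites removed
#'   from each side.
#' @export
harmonize_sites <- function(query, ref) {
  stopifnot(inherits(query, "haplotype_panel"), inherits(ref, "haplotype_panel"))
  if (!identical(query$chrom, ref$chrom))
    stop("panels are on different chromosomes: ", query$chrom, " vs ", ref$chrom)
  key_q <- paste(query$positions, query$ref, query$alt)
  key_r <- paste(ref$positions, ref$ref, ref$alt)
  shared <- intersect(key_q, key_r)
  if (length(shared) == 0L)
    stop("no shared sites between the two panels (position + alleles)")
  iq <- which(key_q %in% shared)
  ir <- match(key_q[iq], key_r)
  list(query = if (length(iq) == n_sites(query)) query else subset_sites(query, iq),
       ref = if (identical(ir, seq_len(n_sites(ref)))) ref else subset_sites(ref, ir),
       dropped = c(query = n_sites(query) - length(iq),
                   ref = n_sites(ref) - length(ir)))
}

#' Population map for a labelled reference panel
#'
#' Maps every reference haplotype to one of `K` populations. Populations are
#' kept in a fixed order (first appearance in the label source) and sizes are
#' counted in haplotypes by default.
#'
#' @param populations ordered character vector of unique population labels.
#' @param hap_pop named integer vector: haplotype id -> population index
#'   (1-based, into `populations`).
#' @return An object of class `population_map` with fields `populations`,
#'   `hap_pop`, `pop_size` (haplotype counts per population) and `K`.
#' @export
population_map <- function(populations, hap_pop) {
  populations <- as.character(populations)
  K <- length(populations)
  if (K < 1L) stop("need at least one population")
  if (anyDuplicated(populations)) stop("population labels must be unique")
  if (is.null(names(hap_pop))) stop("hap_pop must be named by haplotype id")
  hap_pop <- stats::setNames(as.integer(hap_pop), names(hap_pop))
  if (anyNA(hap_pop) || any(hap_pop < 1L | hap_pop > K))
    stop("every haplotype must map to a population index in 1..K")
  pop_size <- tabulate(hap_pop, nbins = K)
  if (any(pop_size < 1L))
    stop("population(s) with no haplotypes: ",
         paste(populations[pop_size < 1L], collapse = ", "))
  structure(list(populations = populations, hap_pop = hap_pop,
                 pop_size = pop_size, K = K),
            class = "population_map")
}

#' @export
print.population_map <- function(x, ...) {
  cat(sprintf("population_map: %d populations, %d haplotypes\n",
              x$K, length(x$hap_pop)))
  print(stats::setNames(x$pop_size, x$populations))
  invisible(x)
}

#' Build a population map from per-sample labels
#'
#' Both haplotypes of a sample receive the sample's population. Populations
#' are ordered by first appearance; sizes are computed from the panel
#' actually supplied.
#'
#' @param sample_pops named character vector: sample id -> population label.
#' @param panel the [haplotype_panel()] holding the labelled haplotypes.
#' @return a [population_map()].
#' @export
population_map_from_samples <- function(sample_pops, panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  missing <- setdiff(panel$sample_ids, names(sample_pops))
  if (length(missing) > 0L)
    stop("panel sample(s) without a population label: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(sample_pops), panel$sample_ids)
  if (length(extra) > 0L)
    warning("label(s) for sample(s) absent from the panel are ignored: ",
            paste(extra, collapse = ", "))
  lab <- sample_pops[panel$sample_ids]
  populations <- unique(unname(lab))
  pop_idx <- match(lab, populations)
  hap_pop <- rep(pop_idx, each = 2L)
  names(hap_pop) <- panel$hap_ids
  population_map(populations, hap_pop)
}
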