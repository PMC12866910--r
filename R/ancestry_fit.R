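# User-facing estimator: infer_ancestry() fits ancestry proportions for a
# query panel against a labelled reference panel and returns a classed object
# with the usual accessor methods.

#' Infer global ancestry proportions for a query panel
#'
#' The main fitting function. Long exact haplotype matches of at least `L`
#' sites are called between every query haplotype and the reference panel
#' with a PBWT long-match engine; match coverage is converted into per-site
#' ancestry dosage via a population-by-site score matrix (column
#' normalization, then reference-population size adjustment), aggregated over
#' the genome and over the individual's two haplotypes, and rescaled into
#' ancestry proportions.
#'
#' @param query a [haplotype_panel()] or list of per-chromosome panels.
#' @param ref a [haplotype_panel()] or list of per-chromosome panels.
#' @param labels a [population_map()] for the reference panel, or the path of
#'   a sample-to-population TSV.
#' @param L minimum match length in sites (default 500).
#' @param maf optional minor-allele-frequency threshold applied to the
#'   reference panel's site set before harmonization (e.g. 0.05); `NULL`
#'   disables the filter.
#' @param harmonize if `TRUE` (default) restrict both panels to their shared
#'   sites first.
#' @param size_unit how reference population sizes are counted for the
#'   sample-size adjustment; see [adjust_for_panel_size()].
#' @param return_dosage keep per-haplotype site-wise dosage matrices in the
#'   fit (memory-heavy; needed only to export dosage for panel refinement).
#' @return an object of class `ancestry_fit` with components `proportions`
#'   (individuals x K; `NA` rows for individuals with no matches),
#'   `covered_fraction`, `n_matches`, `populations`, `pop_size`, `L`,
#'   `n_sites`, `na` (logical), `call`, and optionally `dosage`.
#' @seealso [evaluate_estimates()] to score a fit against known truth,
#'   [refine_panel()] to homogenize a heterogeneous reference panel.
#' @examples
#' cfg <- sim_config(K = 2, n_sites = 600, n_query = 5, n_reference = 20,
#'                   admix = list(type = "dirichlet", alpha = c(0.5, 0.5)),
#'                   seed = 7)
#' ds <- make_dataset(cfg)
#' fit <- infer_ancestry(ds$query, ds$ref, ds$popmap, L = 100)
#' coef(fit)
#' @export
infer_ancestry <- function(query, ref, labels, L = 500, maf = NULL,
                           harmonize = TRUE,
                           size_unit = c("haplotypes", "samples"),
                           return_dosage = FALSE) {
  size_unit <- match.arg(size_unit)
  cl <- match.call()
  if (inherits(query, "haplotype_panel")) query <- list(query)
  if (inherits(ref, "haplotype_panel")) ref <- list(ref)
  if (!is.null(maf))
    ref <- lapply(ref, maf_filter, threshold = maf)
  if (harmonize) {
    for (ci in seq_along(query)) {
      h <- harmonize_sites(query[[ci]], ref[[ci]])
      query[[ci]] <- h$query
      ref[[ci]] <- h$ref
    }
  }
  popmap <- if (inherits(labels, "population_map")) labels
            else read_labels(labels, ref[[1L]])
  est <- estimate_ancestry(query, ref, popmap, L = L, size_unit = size_unit,
                           return_dosage = return_dosage)
  structure(list(proportions = est$proportions,
                 covered_fraction = est$covered_fraction,
                 n_matches = est$n_matches,
                 populations = est$populations,
                 pop_size = popmap$pop_size,
                 L = L,
                 n_sites = sum(vapply(query, n_sites, integer(1))),
                 na = apply(est$proportions, 1L, function(r) any(is.na(r))),
                 dosage = est$dosage,
                 call = cl),
            class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, digits = 4, ...) {
  cat("Global ancestry fit (long-haplotype-match estimator)\n")
  cat(sprintf("  %d individuals, %d reference populations, L = %d sites, %d sites\n",
              nrow(x$proportions), length(x$populations), x$L, x$n_sites))
  if (any(x$na))
    cat(sprintf("  %d individual(s) with no matches (NA)\n", sum(x$na)))
  n_show <- min(6L, nrow(x$proportions))
  print(round(x$proportions[seq_len(n_show), , drop = FALSE], digits))
  if (nrow(x$proportions) > n_show)
    cat(sprintf("  ... %d more individuals\n", nrow(x$proportions) - n_show))
  invisible(x)
}

#' @export
summary.ancestry_fit <- function(object, ...) {
  ok <- !object$na
  means <- colMeans(object$proportions[ok, , drop = FALSE])
  structure(list(n = nrow(object$proportions), n_na = sum(object$na),
                 populations = object$populations, mean_proportions = means,
                 mean_covered = mean(object$covered_fraction),
                 L = object$L, n_sites = object$n_sites),
            class = "summary.ancestry_fit")
}

#' @export
print.summary.ancestry_fit <- function(x, ...) {
  cat("Global ancestry fit summary\n")
  cat(sprintf("  individuals: %d (NA: %d); sites: %d; L = %d\n",
              x$n, x$n_na, x$n_sites, x$L))
  cat(sprintf("  mean covered fraction: %.3f\n", x$mean_covered))
  cat("  mean ancestry proportions:\n")
  print(round(x$mean_proportions, 4))
  invisible(x)
}

#' @export
coef.ancestry_fit <- function(object, ...) object$proportions

#' Stacked ancestry-proportion barplot
#'
#' One bar per individual, stacked by reference population; individuals with
#' no matches are left blank.
#'
#' @param x an `ancestry_fit`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ancestry_fit <- function(x, ...) {
  p <- t(x$proportions)
  p[is.na(p)] <- 0
  cols <- grDevices::hcl.colors(max(3L, nrow(p)), "Dark 3")[seq_len(nrow(p))]
  graphics::barplot(p, col = cols, border = NA, space = 0,
                    ylab = "ancestry proportion", xlab = "individual",
                    legend.text = x$populations,
                    args.legend = list(x = "topright", bg = "white"), ...)
  invisible(x)
}
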