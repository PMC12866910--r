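# Score-matrix ancestry dosage and aggregation into per-individual
# proportions.
#
# For one query haplotype on one chromosome, a K x N score matrix S counts,
# at every site, how many long matches from each reference population cover
# that site. Columns are then normalized to per-site ancestry dosages (votes
# split across populations), rows are divided by reference population size
# to remove sampling bias, dosages are aggregated over all sites of all
# chromosomes, and the two haplotypes of an individual are combined and
# rescaled into ancestry proportions.

#' Create an empty score matrix
#'
#' @param K number of reference populations.
#' @param N number of sites on the chromosome.
#' @return an object of class `score_matrix` in state `"raw"` with fields
#'   `values` (K x N), `c` (matches processed) and `state`.
#' @export
score_matrix <- function(K, N) {
  stopifnot(K >= 1, N >= 1)
  structure(list(values = matrix(0, nrow = K, ncol = N), c = 0L,
                 state = "raw"),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d populations x %d sites, %d matches, state %s\n",
              nrow(x$values), ncol(x$values), x$c, x$state))
  invisible(x)
}

#' Accumulate one long match into a raw score matrix
#'
#' Adds 1 to row `pop` at every site index in `[start, end)`: exactly
#' `end - start` cells change.
#'
#' @param S a [score_matrix()] in state `"raw"`.
#' @param pop 1-based population index of the matched reference haplotype.
#' @param start,end half-open 0-based site span of the match.
#' @return the updated `score_matrix`.
#' @export
accumulate_match <- function(S, pop, start, end) {
  stopifnot(inherits(S, "score_matrix"))
  if (S$state != "raw") stop("matches can only be accumulated in state 'raw'")
  K <- nrow(S$values); N <- ncol(S$values)
  if (pop < 1L || pop > K) stop("population index out of range")
  if (start < 0L || end > N || start >= end) stop("invalid match span")
  S$values[pop, (start + 1L):end] <- S$values[pop, (start + 1L):end] + 1
  S$c <- S$c + 1L
  S
}

#' Accumulate a whole match list into a raw score matrix
#'
#' Equivalent to calling [accumulate_match()] once per row (addition
#' commutes, so any order gives the same result) but computed per population
#' with a difference-array cumulative sum, which is much faster for large
#' match lists.
#'
#' @param S a [score_matrix()] in state `"raw"`.
#' @param matches data frame with columns `pop`, `start`, `end`.
#' @return the updated `score_matrix`.
#' @export
accumulate_matches <- function(S, matches) {
  stopifnot(inherits(S, "score_matrix"))
  if (S$state != "raw") stop("matches can only be accumulated in state 'raw'")
  if (nrow(matches) == 0L) return(S)
  K <- nrow(S$values); N <- ncol(S$values)
  if (any(matches$pop < 1L | matches$pop > K)) stop("population index out of range")
  if (any(matches$start < 0L | matches$end > N | matches$start >= matches$end))
    stop("invalid match span")
  for (k in sort(unique(matches$pop))) {
    rows <- matches$pop == k
    delta <- tabulate(matches$start[rows] + 1L, nbins = N) -
             c(0, tabulate(matches$end[rows], nbins = N))[seq_len(N)]
    # +1 at start, -1 at end: cumulative sum gives per-site coverage
    S$values[k, ] <- S$values[k, ] + cumsum(delta)
  }
  S$c <- S$c + nrow(matches)
  S
}

#' Normalize score-matrix columns into per-site ancestry dosages
#'
#' Every column with a positive sum is divided by its sum (covered sites then
#' sum to 1 across populations); all-zero columns — sites covered by no match
#' — are left untouched.
#'
#' @param S a [score_matrix()] in state `"raw"`.
#' @return the matrix in state `"column_normalized"`.
#' @export
normalize_columns <- function(S) {
  stopifnot(inherits(S, "score_matrix"))
  if (S$state != "raw") stop("normalize_columns expects state 'raw'")
  cs <- colSums(S$values)
  pos <- cs > 0
  if (any(pos))
    S$values[, pos] <- sweep(S$values[, pos, drop = FALSE], 2L, cs[pos], "/")
  S$state <- "column_normalized"
  S
}

#' Adjust dosages for uneven reference population sizes
#'
#' Divides row `k` by the size of population `k`, so that a population is not
#' favoured merely because it contributes more haplotypes to the panel.
#'
#' @param S a [score_matrix()] in state `"column_normalized"`.
#' @param popmap a [population_map()].
#' @param size_unit `"haplotypes"` (default) or `"samples"`. For diploid
#'   panels the two differ by a global factor of 2 which cancels in the final
#'   proportion step, so the choice only matters when mixing conventions
#'   across panels.
#' @return the matrix in state `"size_adjusted"`.
#' @export
adjust_for_panel_size <- function(S, popmap,
                                  size_unit = c("haplotypes", "samples")) {
  stopifnot(inherits(S, "score_matrix"), inherits(popmap, "population_map"))
  size_unit <- match.arg(size_unit)
  if (S$state != "column_normalized")
    stop("adjust_for_panel_size expects state 'column_normalized'")
  sizes <- popmap$pop_size
  if (size_unit == "samples") sizes <- sizes / 2
  if (any(sizes <= 0)) stop("population sizes must be positive")
  if (length(sizes) != nrow(S$values))
    stop("population map does not match the score matrix")
  S$values <- S$values / sizes
  S$state <- "size_adjusted"
  S
}

#' Aggregate size-adjusted scores over the genome
#'
#' Sums each population's scores over all sites of all chromosomes and
#' divides by the total site count. The site-count denominator cancels in
#' the final proportion step but is kept so that per-haplotype aggregated
#' scores are comparable across genomes of different length.
#'
#' @param per_chrom list of `score_matrix` objects in state
#'   `"size_adjusted"`, one per chromosome.
#' @return length-`K` numeric vector of genome-normalized scores.
#' @export
aggregate_genome <- function(per_chrom) {
  stopifnot(length(per_chrom) >= 1L)
  K <- nrow(per_chrom[[1L]]$values)
  total <- numeric(K)
  n_tot <- 0L
  for (S in per_chrom) {
    stopifnot(inherits(S, "score_matrix"))
    if (S$state != "size_adjusted")
      stop("aggregate_genome expects state 'size_adjusted'")
    if (nrow(S$values) != K) stop("inconsistent population count across chromosomes")
    total <- total + rowSums(S$values)
    n_tot <- n_tot + ncol(S$values)
  }
  total / n_tot
}

#' Combine a diploid pair of haplotype scores into ancestry proportions
#'
#' The two genome-aggregated score vectors are summed (evidence-weighted:
#' a haplotype with more matched coverage contributes more) and rescaled to
#' sum to 1. An individual whose haplotypes carry no matches at all gets an
#' `NA` estimate — a uniform vector would be indistinguishable from a
#' genuinely even admixture call.
#'
#' @param hap_scores list of 2 length-`K` non-negative vectors.
#' @return length-`K` proportion vector, or all-`NA` when there is no
#'   evidence.
#' @export
to_proportions <- function(hap_scores) {
  stopifnot(length(hap_scores) == 2L)
  v <- hap_scores[[1L]] + hap_scores[[2L]]
  if (any(v < 0)) stop("scores must be non-negative")
  tot <- sum(v)
  if (tot == 0) return(rep(NA_real_, length(v)))
  v / tot
}

# Full scoring chain for one query haplotype on one chromosome.
# Returns list(agg_input = size-adjusted score matrix, covered = logical N).
score_one_haplotype <- function(matches, K, N, popmap, size_unit) {
  S <- score_matrix(K, N)
  S <- accumulate_matches(S, matches)
  covered <- colSums(S$values) > 0
  S <- normalize_columns(S)
  S <- adjust_for_panel_size(S, popmap, size_unit)
  list(S = S, covered = covered)
}

#' Estimate ancestry proportions for every query individual
#'
#' Orchestrates the full pipeline: one PBWT index per chromosome, long-match
#' queries for every query haplotype, the scoring chain (accumulate,
#' column-normalize, size-adjust, genome-aggregate) and the diploid
#' proportion conversion. Deterministic for fixed inputs.
#'
#' @param query,ref single [haplotype_panel()]s or lists of per-chromosome
#'   panels (site-harmonized with each other).
#' @param popmap a [population_map()] labelling the reference haplotypes.
#' @param L minimum match length in sites (default 500).
#' @param size_unit passed to [adjust_for_panel_size()].
#' @param return_dosage if `TRUE`, also return the per-haplotype site-wise
#'   ancestry dosage matrices (state `"column_normalized"`), one K x N matrix
#'   per query haplotype per chromosome. Memory-heavy for large inputs.
#' @return a list with components `proportions` (individuals x K matrix, rows
#'   `NA` for individuals without matches), `covered_fraction` (fraction of
#'   haplotype-site slots covered by at least one match, per individual),
#'   `n_matches` (per individual), `populations`, and optionally `dosage`.
#' @export
estimate_ancestry <- function(query, ref, popmap, L = 500,
                              size_unit = c("haplotypes", "samples"),
                              return_dosage = FALSE) {
  size_unit <- match.arg(size_unit)
  if (inherits(query, "haplotype_panel")) query <- list(query)
  if (inherits(ref, "haplotype_panel")) ref <- list(ref)
  stopifnot(length(query) == length(ref), length(query) >= 1L)
  K <- popmap$K
  samples <- query[[1L]]$sample_ids
  n_ind <- length(samples)
  hap_scores <- vector("list", 2L * n_ind)  # per hap: list of per-chrom S
  for (h in seq_len(2L * n_ind)) hap_scores[[h]] <- vector("list", length(query))
  covered_slots <- numeric(n_ind)
  n_matches <- integer(n_ind)
  dosage <- if (return_dosage) list() else NULL
  total_sites <- 0L
  for (ci in seq_along(query)) {
    qp <- query[[ci]]; rp <- ref[[ci]]
    if (!identical(qp$sample_ids, samples))
      stop("query chromosome panels must share the same samples")
    if (n_sites(qp) != n_sites(rp) || !identical(qp$positions, rp$positions))
      stop("query and reference panels are not site-harmonized on chromosome ",
           qp$chrom)
    N <- n_sites(qp)
    total_sites <- total_sites + N
    index <- build_pbwt_index(rp)
    pop_of_row <- unname(popmap$hap_pop[rp$hap_ids])
    if (anyNA(pop_of_row))
      stop("reference haplotype(s) missing from the population map")
    for (h in seq_len(2L * n_ind)) {
      m <- query_long_matches(index, qp$alleles[h, ], L)
      m$pop <- pop_of_row[m$ref_row]
      sc <- score_one_haplotype(m, K, N, popmap, size_unit)
      hap_scores[[h]][[ci]] <- sc$S
      ind <- (h + 1L) %/% 2L
      covered_slots[ind] <- covered_slots[ind] + sum(sc$covered)
      n_matches[ind] <- n_matches[ind] + nrow(m)
      if (return_dosage) {
        Sd <- score_matrix(K, N)
        Sd <- accumulate_matches(Sd, m)
        dosage[[paste0(qp$hap_ids[h], "@", qp$chrom)]] <-
          normalize_columns(Sd)$values
      }
    }
  }
  agg <- lapply(hap_scores, aggregate_genome)
  proportions <- matrix(NA_real_, nrow = n_ind, ncol = K,
                        dimnames = list(samples, popmap$populations))
  for (i in seq_len(n_ind))
    proportions[i, ] <- to_proportions(agg[c(2L * i - 1L, 2L * i)])
  out <- list(proportions = proportions,
              covered_fraction = covered_slots / (2L * total_sites),
              n_matches = n_matches,
              populations = popmap$populations)
  if (return_dosage) out$dosage <- dosage
  out
}
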