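# Long exact haplotype matches (IBD proxies) between query haplotypes and a
# reference panel. The engine is a positional Burrows-Wheeler transform with
# Durbin-style long-match reporting for out-of-panel queries; a brute-force
# scan over equality runs serves as the independent correctness oracle.

as_allele_matrix <- function(x) {
  if (inherits(x, "haplotype_panel")) return(x$alleles)
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  x
}

#' Build a PBWT index over a reference panel
#'
#' Constructs per-site sorted prefix orders, divergence values and rank
#' counts in O(MN) time. The index is immutable and supports repeated
#' long-match queries whose cost does not grow with the number of reference
#' haplotypes.
#'
#' @param ref a [haplotype_panel()] or a bare 0/1 matrix (rows = haplotypes).
#' @return an object of class `pbwt_index`.
#' @export
build_pbwt_index <- function(ref) {
  alleles <- as_allele_matrix(ref)
  idx <- pbwt_build_cpp(alleles)
  idx$alleles <- alleles
  idx$hap_ids <- rownames(alleles)
  class(idx) <- "pbwt_index"
  idx
}

#' @export
print.pbwt_index <- function(x, ...) {
  cat(sprintf("pbwt_index: %d haplotypes x %d sites\n", x$M, x$N))
  invisible(x)
}

#' Find all long matches between one query haplotype and the indexed panel
#'
#' Returns every maximal exact match of length at least `L` sites between the
#' query and each reference haplotype. A match `[start, end)` is maximal:
#' extending it one site left or right either breaks allele equality or runs
#' off the chromosome. Output is deterministic, sorted by `start` then
#' reference row.
#'
#' @param index a [build_pbwt_index()] result.
#' @param query length-`N` 0/1 vector.
#' @param L minimum match length in sites (`1 <= L <= N`).
#' @return data frame with columns `ref_row` (1-based panel row), `start`,
#'   `end` (0-based half-open site indices).
#' @export
query_long_matches <- function(index, query, L) {
  stopifnot(inherits(index, "pbwt_index"))
  query <- as.integer(query)
  if (L < 1) stop("L must be at least 1")
  if (L > index$N)  # no match longer than the chromosome can exist
    return(data.frame(ref_row = integer(0), start = integer(0),
                      end = integer(0)))
  res <- pbwt_query_cpp(index[c("a", "d", "u", "cnt", "M", "N")],
                        index$alleles, query, as.integer(L))
  res$ref_row <- res$ref_row + 1L
  res[order(res$start, res$ref_row), , drop = FALSE]
}

#' Brute-force long-match oracle
#'
#' Independently enumerates maximal equality runs of length >= `L` between
#' the query and every reference row by scanning the full equality mask.
#' O(MN) per query; used to validate the PBWT engine.
#'
#' @inheritParams query_long_matches
#' @param ref a [haplotype_panel()] or 0/1 matrix.
#' @return data frame in the same format and order as [query_long_matches()].
#' @export
brute_force_long_matches <- function(ref, query, L) {
  alleles <- as_allele_matrix(ref)
  query <- as.integer(query)
  N <- ncol(alleles)
  if (length(query) != N) stop("query length must equal panel site count")
  if (L < 1) stop("L must be at least 1")
  if (L > N)
    return(data.frame(ref_row = integer(0), start = integer(0),
                      end = integer(0)))
  out_ref <- integer(0); out_s <- integer(0); out_e <- integer(0)
  for (j in seq_len(nrow(alleles))) {
    eq <- alleles[j, ] == query
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    keep <- r$values & r$lengths >= L
    if (any(keep)) {
      out_ref <- c(out_ref, rep(j, sum(keep)))
      out_s <- c(out_s, starts[keep])
      out_e <- c(out_e, ends[keep])
    }
  }
  res <- data.frame(ref_row = out_ref, start = out_s, end = out_e)
  res[order(res$start, res$ref_row), , drop = FALSE]
}

#' Find all long matches between a query panel and a labelled reference panel
#'
#' Convenience driver: builds the PBWT index once, queries every query
#' haplotype, and annotates matches with haplotype ids and (optionally)
#' reference population indices.
#'
#' @param query a [haplotype_panel()] of query haplotypes.
#' @param ref a [haplotype_panel()] reference panel (same sites as `query`).
#' @param L minimum match length in sites.
#' @param popmap optional [population_map()] for the reference panel; adds a
#'   `pop` column (1-based population index).
#' @param engine `"pbwt"` (default) or `"brute"` (oracle, for testing).
#' @return data frame with columns `query_hap`, `query_row`, `ref_hap`,
#'   `ref_row`, `start`, `end` and, with `popmap`, `pop`.
#' @export
find_long_matches <- function(query, ref, L, popmap = NULL,
                              engine = c("pbwt", "brute")) {
  engine <- match.arg(engine)
  if (n_sites(query) != n_sites(ref))
    stop("query and reference panels must cover the same sites; ",
         "run harmonize_sites() first")
  index <- if (engine == "pbwt") build_pbwt_index(ref) else NULL
  per_hap <- lapply(seq_len(n_haps(query)), function(i) {
    z <- query$alleles[i, ]
    m <- if (engine == "pbwt") query_long_matches(index, z, L)
         else brute_force_long_matches(ref, z, L)
    if (nrow(m) > 0L) m$query_row <- i
    m
  })
  res <- do.call(rbind, per_hap[vapply(per_hap, nrow, integer(1)) > 0L])
  if (is.null(res))
    res <- data.frame(ref_row = integer(0), start = integer(0),
                      end = integer(0), query_row = integer(0))
  res$query_hap <- query$hap_ids[res$query_row]
  res$ref_hap <- ref$hap_ids[res$ref_row]
  if (!is.null(popmap)) {
    pop <- popmap$hap_pop[res$ref_hap]
    if (anyNA(pop)) stop("reference haplotype(s) missing from the population map")
    res$pop <- unname(pop)
  }
  rownames(res) <- NULL
  res
}
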