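# Reference panel refinement: replace ambiguously admixed reference
# haplotypes with synthetic, ancestry-homogeneous mosaics built by windowed
# sampling from candidate haplotypes that meet a minimum per-window ancestry
# dosage cutoff.

#' Per-haplotype site-wise ancestry dosage panel
#'
#' Soft per-site ancestry assignments for a set of haplotypes: at every site
#' each haplotype carries a length-`K` dosage vector summing to 1. Sources
#' can be simulator truth ([dosage_from_labels()]), the scoring module's
#' dosage output, or an external table ([read_dosage()]).
#'
#' @param hap_ids haplotype identifiers (length `H`).
#' @param dosage list of `K` numeric `H x N` matrices, one per population,
#'   in population order; `dosage[[k]][h, j]` is haplotype `h`'s dosage for
#'   population `k` at site `j`.
#' @return an object of class `dosage_panel`.
#' @export
dosage_panel <- function(hap_ids, dosage) {
  stopifnot(is.list(dosage), length(dosage) >= 1L)
  H <- length(hap_ids)
  N <- ncol(dosage[[1L]])
  for (m in dosage)
    if (nrow(m) != H || ncol(m) != N) stop("inconsistent dosage dimensions")
  tot <- Reduce(`+`, dosage)
  if (any(abs(tot - 1) > 1e-6))
    stop("per-site dosage vectors must sum to 1 within 1e-6")
  dosage <- lapply(dosage, function(m) { rownames(m) <- hap_ids; m })
  structure(list(hap_ids = as.character(hap_ids), dosage = dosage,
                 K = length(dosage)),
            class = "dosage_panel")
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat(sprintf("dosage_panel: %d haplotypes x %d sites, %d populations\n",
              length(x$hap_ids), ncol(x$dosage[[1L]]), x$K))
  invisible(x)
}

#' One-hot dosage panel from hard local-ancestry labels
#'
#' @param labels integer `H x N` matrix of 1-based population labels (e.g.
#'   simulator truth); rownames are haplotype ids.
#' @param K number of populations.
#' @return a [dosage_panel()] with 0/1 dosages.
#' @export
dosage_from_labels <- function(labels, K) {
  hap_ids <- rownames(labels)
  if (is.null(hap_ids)) hap_ids <- paste0("h", seq_len(nrow(labels)))
  dosage_panel(hap_ids, lapply(seq_len(K), function(k) (labels == k) * 1))
}

#' Partition a chromosome into non-overlapping windows
#'
#' `ceiling(N / W)` contiguous half-open 0-based index ranges, all of width
#' `W` except possibly a shorter last window.
#'
#' @param N number of sites.
#' @param W window size in sites (`1 <= W <= N`).
#' @return data frame with columns `start`, `end` (half-open, 0-based).
#' @export
window_partition <- function(N, W) {
  if (W < 1L) stop("window size must be at least 1")
  if (W > N) stop("window size exceeds the number of sites")
  N <- as.integer(N)
  W <- as.integer(W)
  starts <- seq.int(0L, N - 1L, by = W)
  data.frame(start = starts, end = pmin(starts + W, N))
}

# Window-mean dosage of population `target_pop` for a set of haplotype rows:
# pool x n_windows matrix.
window_mean_dosage <- function(dosage, target_pop, pool_rows, windows) {
  m <- dosage$dosage[[target_pop]][pool_rows, , drop = FALSE]
  vapply(seq_len(nrow(windows)), function(w)
    rowMeans(m[, (windows$start[w] + 1L):windows$end[w], drop = FALSE]),
    numeric(length(pool_rows)))
}

#' Candidate haplotypes for one synthesis window
#'
#' Pool members whose mean target-population dosage over the window's sites
#' reaches the cutoff.
#'
#' @param dosage a [dosage_panel()].
#' @param window a list/row with `start`, `end` (half-open, 0-based).
#' @param target_pop 1-based target population index.
#' @param cutoff minimum mean dosage in `(0, 1]`.
#' @param pool haplotype ids eligible as contributors (the target
#'   population's haplotypes).
#' @return character vector of qualifying haplotype ids (possibly empty).
#' @export
window_candidates <- function(dosage, window, target_pop, cutoff, pool) {
  stopifnot(inherits(dosage, "dosage_panel"))
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  if (length(pool) == 0L) stop("empty candidate pool")
  rows <- match(pool, dosage$hap_ids)
  if (anyNA(rows)) stop("pool haplotype(s) missing from the dosage panel")
  m <- dosage$dosage[[target_pop]][rows, , drop = FALSE]
  mean_dos <- rowMeans(m[, (window$start + 1L):window$end, drop = FALSE])
  pool[mean_dos >= cutoff]
}

#' Synthesize one ancestry-homogeneous mosaic haplotype
#'
#' For each window, one contributor is drawn uniformly from the window's
#' candidates ([window_candidates()]); if no candidate exists, the
#' contributor is drawn uniformly from all target-population haplotypes and
#' the window index is recorded in `fallback_windows`. Alleles are copied
#' window-wise from the chosen contributor. When no window falls back, the
#' synthetic haplotype's genome-wide target dosage is at least the cutoff
#' (up to the short-last-window width effect).
#'
#' Draws consume the current R random number stream in window order; seed the
#' stream (or use [refine_panel()]) for reproducibility.
#'
#' @param ref the reference [haplotype_panel()].
#' @param dosage a [dosage_panel()] aligned with `ref` (same haplotypes and
#'   sites).
#' @param target_pop 1-based target population index.
#' @param pool haplotype ids of the target population.
#' @param cutoff minimum per-window mean target dosage in `(0, 1]`.
#' @param W window size in sites.
#' @return list with `alleles` (length-`N` 0/1 vector), `target_pop`,
#'   `provenance` (contributor haplotype id per window) and
#'   `fallback_windows` (1-based window indices that fell back).
#' @export
synthesize_haplotype <- function(ref, dosage, target_pop, pool, cutoff, W) {
  stopifnot(inherits(ref, "haplotype_panel"))
  if (length(pool) == 0L) stop("target population has no haplotypes")
  N <- n_sites(ref)
  windows <- window_partition(N, W)
  alleles <- integer(N)
  provenance <- character(nrow(windows))
  fallback <- integer(0)
  for (w in seq_len(nrow(windows))) {
    cand <- window_candidates(dosage, windows[w, ], target_pop, cutoff, pool)
    if (length(cand) == 0L) {
      cand <- pool
      fallback <- c(fallback, w)
    }
    src <- cand[sample.int(length(cand), 1L)]
    provenance[w] <- src
    span <- (windows$start[w] + 1L):windows$end[w]
    alleles[span] <- ref$alleles[src, span]
  }
  list(alleles = alleles, target_pop = target_pop, provenance = provenance,
       fallback_windows = fallback)
}

#' Refine a reference panel with synthetic homogeneous haplotypes
#'
#' Emits `count_per_pop` synthetic haplotypes per population, each a windowed
#' mosaic of existing haplotypes of that population whose per-window ancestry
#' dosage meets the cutoff. Synthetic haplotypes are paired arbitrarily into
#' pseudo-samples. Deterministic for a fixed seed.
#'
#' @param ref the reference [haplotype_panel()].
#' @param dosage a [dosage_panel()] aligned with `ref`.
#' @param popmap the [population_map()] of `ref`.
#' @param count_per_pop synthetic haplotypes per population (even number,
#'   so they pair into pseudo-samples).
#' @param cutoff minimum per-window mean target dosage (default 0.7).
#' @param W window size in sites (default 200).
#' @param seed integer seed.
#' @return list with `panel` (the refined [haplotype_panel()]), `popmap`
#'   (labels for the synthetic haplotypes), and `provenance` (data frame:
#'   one row per synthetic haplotype and window, with contributor id and a
#'   fallback flag).
#' @export
refine_panel <- function(ref, dosage, popmap, count_per_pop, cutoff = 0.7,
                         W = 200, seed = 1L) {
  stopifnot(inherits(ref, "haplotype_panel"), inherits(popmap, "population_map"))
  if (count_per_pop %% 2L != 0L)
    stop("count_per_pop must be even so synthetic haplotypes pair into samples")
  N <- n_sites(ref)
  windows <- window_partition(N, W)
  n_win <- nrow(windows)
  K <- popmap$K
  if (count_per_pop == 0L) stop("count_per_pop must be positive")
  set.seed(as.integer(seed))
  all_alleles <- NULL
  sample_ids <- character(0)
  hap_pop_lab <- character(0)
  prov <- list()
  for (k in seq_len(K)) {
    pool <- names(popmap$hap_pop)[popmap$hap_pop == k]
    pool_rows <- match(pool, dosage$hap_ids)
    if (anyNA(pool_rows)) stop("dosage panel does not cover population ",
                               popmap$populations[k])
    wm <- window_mean_dosage(dosage, k, pool_rows, windows)  # pool x n_win
    cand_per_win <- lapply(seq_len(n_win), function(w) pool[wm[, w] >= cutoff])
    pop_alleles <- matrix(0L, nrow = count_per_pop, ncol = N)
    pop_prov <- matrix("", nrow = count_per_pop, ncol = n_win)
    pop_fb <- matrix(FALSE, nrow = count_per_pop, ncol = n_win)
    for (h in seq_len(count_per_pop)) {
      for (w in seq_len(n_win)) {
        cand <- cand_per_win[[w]]
        fb <- length(cand) == 0L
        if (fb) cand <- pool
        src <- cand[sample.int(length(cand), 1L)]
        span <- (windows$start[w] + 1L):windows$end[w]
        pop_alleles[h, span] <- ref$alleles[src, span]
        pop_prov[h, w] <- src
        pop_fb[h, w] <- fb
      }
    }
    lab <- popmap$populations[k]
    ids <- sprintf("syn_%s_%d", lab, seq_len(count_per_pop %/% 2L))
    hids <- as.vector(rbind(paste0(ids, "_0"), paste0(ids, "_1")))
    all_alleles <- rbind(all_alleles, pop_alleles)
    sample_ids <- c(sample_ids, ids)
    hap_pop_lab <- c(hap_pop_lab, rep(lab, count_per_pop))
    prov[[k]] <- data.frame(
      hap_id = rep(hids, each = n_win),
      window = rep(seq_len(n_win), times = count_per_pop),
      source_hap = as.vector(t(pop_prov)),
      fallback = as.vector(t(pop_fb)))
  }
  panel <- haplotype_panel(all_alleles, ref$positions, chrom = ref$chrom,
                           sample_ids = sample_ids,
                           ref = ref$ref, alt = ref$alt)
  hap_pop <- stats::setNames(match(hap_pop_lab, popmap$populations),
                             panel$hap_ids)
  list(panel = panel,
       popmap = population_map(popmap$populations, hap_pop),
       provenance = do.call(rbind, prov))
}

#' Retain only ancestry-homogeneous haplotypes
#'
#' Haplotypes whose genome-wide mean dosage for their own labelled population
#' reaches the cutoff.
#'
#' @param dosage a [dosage_panel()].
#' @param popmap a [population_map()] covering the dosage haplotypes.
#' @param cutoff homogeneity cutoff in `[0.5, 1]`.
#' @return character vector of retained haplotype ids.
#' @export
filter_homogeneous <- function(dosage, popmap, cutoff) {
  stopifnot(inherits(dosage, "dosage_panel"))
  if (cutoff < 0.5 || cutoff > 1) stop("cutoff must be in [0.5, 1]")
  own <- vapply(dosage$hap_ids, function(h) {
    k <- popmap$hap_pop[[h]]
    mean(dosage$dosage[[k]][match(h, dosage$hap_ids), ])
  }, numeric(1))
  dosage$hap_ids[own >= cutoff]
}
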