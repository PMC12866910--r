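# Mosaic admixture simulator with known local-ancestry truth.
#
# Emulates a K-way admixed population descended from a small founder pool —
# the regime in which exact long haplotype matches are abundant — without a
# full forward or coalescent simulation: founder haplotypes are drawn from
# Balding-Nichols-differentiated population allele frequencies, and each
# admixed haplotype is a Markov mosaic of founder-copied segments, so long
# exact shared haplotypes and exact per-site ancestry truth exist by
# construction.

#' Simulation configuration
#'
#' @param K number of ancestral populations.
#' @param founders_per_pop founder haplotypes per population (>= 2). Fewer
#'   founders means longer exact shared segments (higher IBD sharing).
#' @param n_sites number of biallelic sites on the simulated chromosome.
#' @param fst differentiation of population allele frequencies around the
#'   shared ancestral frequency (Balding-Nichols F); 0 makes populations
#'   indistinguishable.
#' @param admix admixture proportion sampler: either
#'   `list(type = "dirichlet", alpha = <length-K>)` — each individual's
#'   proportion vector is an independent Dirichlet draw — or
#'   `list(type = "groups", props = <list of length-K vectors>)` — each
#'   individual is assigned one of the fixed base vectors, cycling through
#'   the groups (used for the 2-way biased designs, e.g. 55:45 both ways).
#' @param switch_prob per-site probability that an ancestry segment ends;
#'   segment lengths are geometric with this rate. On a switch the new
#'   segment's ancestry is drawn from the individual's proportion vector and
#'   its alleles are copied from a random founder haplotype of that ancestry.
#' @param n_query,n_reference individuals in the query / reference split.
#' @param g per-allele genotyping error (flip) rate.
#' @param seed master seed; named substreams (founders, mosaics, errors,
#'   split) are derived from it.
#' @param pop_names population names (default `POP1..POPK`).
#' @param spacing_bp physical distance between adjacent sites.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(K = 3, founders_per_pop = 5, n_sites = 10000,
                       fst = 0.15,
                       admix = list(type = "dirichlet", alpha = rep(0.2, K)),
                       switch_prob = 0.002, n_query = 100, n_reference = 400,
                       g = 0, seed = 1L, pop_names = paste0("POP", seq_len(K)),
                       spacing_bp = 100L) {
  stopifnot(K >= 1, founders_per_pop >= 2, n_sites >= 1,
            fst >= 0, fst < 1, g >= 0, g <= 1,
            switch_prob > 0, switch_prob < 1,
            n_query >= 1, n_reference >= 1)
  if (!admix$type %in% c("dirichlet", "groups"))
    stop("admix$type must be 'dirichlet' or 'groups'")
  if (admix$type == "dirichlet" && length(admix$alpha) != K)
    stop("admix$alpha must have length K")
  if (admix$type == "groups") {
    if (!all(vapply(admix$props, length, integer(1)) == K))
      stop("every admix group vector must have length K")
    if (any(abs(vapply(admix$props, sum, numeric(1)) - 1) > 1e-9))
      stop("admix group vectors must sum to 1")
  }
  structure(list(K = as.integer(K), founders_per_pop = as.integer(founders_per_pop),
                 n_sites = as.integer(n_sites), fst = fst, admix = admix,
                 switch_prob = switch_prob, n_query = as.integer(n_query),
                 n_reference = as.integer(n_reference), g = g,
                 seed = as.integer(seed), pop_names = pop_names,
                 spacing_bp = as.integer(spacing_bp)),
            class = "sim_config")
}

# substream offsets kept small so seed + offset stays far below 2^31
substream <- function(config, name) {
  off <- c(founders = 11L, mosaics = 23L, errors = 37L, split = 53L)[[name]]
  set.seed(config$seed + off)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  while (sum(x) == 0) x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Simulate founder haplotypes
#'
#' For each site a shared ancestral frequency is drawn uniformly on
#' (0.05, 0.95), then per-population frequencies are perturbed around it with
#' a Balding-Nichols Beta draw of differentiation `fst`; founder alleles are
#' independent Bernoulli draws from the population frequency. With `fst = 0`
#' all populations share the ancestral frequency exactly.
#'
#' @param config a [sim_config()].
#' @return list with `alleles` (stacked founder haplotype matrix,
#'   `K * founders_per_pop` rows), `pop` (1-based population of each founder
#'   row) and `freq` (K x N population frequencies).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  substream(config, "founders")
  N <- config$n_sites; K <- config$K; Fst <- config$fst
  p0 <- stats::runif(N, 0.05, 0.95)
  freq <- matrix(0, nrow = K, ncol = N)
  for (k in seq_len(K)) {
    freq[k, ] <- if (Fst == 0) p0
    else stats::rbeta(N, p0 * (1 - Fst) / Fst, (1 - p0) * (1 - Fst) / Fst)
  }
  nf <- config$founders_per_pop
  alleles <- matrix(0L, nrow = K * nf, ncol = N)
  for (k in seq_len(K))
    for (j in seq_len(nf))
      alleles[(k - 1L) * nf + j, ] <- stats::rbinom(N, 1L, freq[k, ])
  list(alleles = alleles, pop = rep(seq_len(K), each = nf), freq = freq)
}

# one mosaic haplotype: ancestry labels + alleles
mosaic_haplotype <- function(founders, props, config) {
  N <- config$n_sites
  lens <- integer(0)
  while (sum(lens) < N)
    lens <- c(lens, stats::rgeom(max(16L, ceiling(N * config$switch_prob)),
                                 config$switch_prob) + 1L)
  cut <- which(cumsum(lens) >= N)[1L]
  lens <- lens[seq_len(cut)]
  lens[cut] <- lens[cut] - (sum(lens) - N)
  n_seg <- length(lens)
  anc <- sample.int(config$K, n_seg, replace = TRUE, prob = props)
  fidx <- (anc - 1L) * config$founders_per_pop +
    sample.int(config$founders_per_pop, n_seg, replace = TRUE)
  anc_site <- rep(anc, lens)
  src_site <- rep(fidx, lens)
  list(labels = anc_site,
       alleles = founders$alleles[cbind(src_site, seq_len(N))])
}

#' Simulate admixed individuals from founder haplotypes
#'
#' Each haplotype is a Markov mosaic along the chromosome: segment lengths
#' are geometric with rate `switch_prob`; each segment's ancestry is drawn
#' from the individual's proportion vector and its alleles are copied intact
#' from a uniformly chosen founder haplotype of that ancestry. Truth is
#' recorded per site.
#'
#' @param founders output of [simulate_founders()].
#' @param config a [sim_config()].
#' @param n number of individuals to simulate.
#' @param props_list optional list of per-individual proportion vectors; by
#'   default drawn from `config$admix`.
#' @return list with `panel` (a [haplotype_panel()], 2n haplotypes),
#'   `truth_p` (n x K realized ancestry proportions: site-average of the
#'   one-hot labels over both haplotypes), `labels` (2n x N true per-site
#'   ancestry, rownames = haplotype ids) and `props` (the sampled proportion
#'   vectors).
#' @export
simulate_admixed <- function(founders, config, n, props_list = NULL) {
  stopifnot(inherits(config, "sim_config"))
  substream(config, "mosaics")
  K <- config$K; N <- config$n_sites
  if (is.null(props_list)) {
    props_list <- if (config$admix$type == "dirichlet")
      lapply(seq_len(n), function(i) rdirichlet1(config$admix$alpha))
    else
      config$admix$props[((seq_len(n) - 1L) %% length(config$admix$props)) + 1L]
  }
  stopifnot(length(props_list) == n)
  alleles <- matrix(0L, nrow = 2L * n, ncol = N)
  labels <- matrix(0L, nrow = 2L * n, ncol = N)
  for (i in seq_len(n)) {
    for (h in 1:2) {
      hp <- mosaic_haplotype(founders, props_list[[i]], config)
      alleles[2L * (i - 1L) + h, ] <- hp$alleles
      labels[2L * (i - 1L) + h, ] <- hp$labels
    }
  }
  panel <- haplotype_panel(alleles, seq_len(N) * config$spacing_bp,
                           chrom = "1", sample_ids = paste0("ind", seq_len(n)))
  rownames(labels) <- panel$hap_ids
  truth_p <- t(vapply(seq_len(n), function(i) {
    lab <- labels[c(2L * i - 1L, 2L * i), ]
    vapply(seq_len(K), function(k) mean(lab == k), numeric(1))
  }, numeric(K)))
  colnames(truth_p) <- config$pop_names
  rownames(truth_p) <- panel$sample_ids
  list(panel = panel, truth_p = truth_p, labels = labels, props = props_list)
}

#' Inject genotyping errors
#'
#' Flips each allele independently with probability `g`.
#'
#' @param panel a [haplotype_panel()].
#' @param g flip probability in `[0, 1]`.
#' @param seed integer seed.
#' @return the perturbed `haplotype_panel`.
#' @export
inject_errors <- function(panel, g, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"), g >= 0, g <= 1)
  if (g == 0) return(panel)
  set.seed(as.integer(seed))
  flip <- matrix(stats::runif(length(panel$alleles)) < g,
                 nrow = nrow(panel$alleles))
  panel$alleles <- (panel$alleles + flip) %% 2L
  storage.mode(panel$alleles) <- "integer"
  rownames(panel$alleles) <- panel$hap_ids
  panel
}

#' Generate a complete simulated dataset
#'
#' Simulates founders and `n_query + n_reference` admixed individuals, splits
#' them into disjoint query and reference panels, labels reference
#' individuals (by majority true ancestry for Dirichlet sampling, by designed
#' bias group for fixed-group sampling), injects genotyping error into both
#' panels, and returns truth for the query individuals plus a ground-truth
#' one-hot [dosage_panel()] for the reference haplotypes.
#'
#' @param config a [sim_config()].
#' @return list with `query`, `ref` (error-injected [haplotype_panel()]s),
#'   `popmap` (reference labels), `truth` (query truth: `p` matrix and
#'   per-site `labels`), `ref_truth` (same for reference individuals),
#'   `ref_dosage` (one-hot truth [dosage_panel()] for reference haplotypes)
#'   and `config`.
#' @export
make_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  founders <- simulate_founders(config)
  n_tot <- config$n_query + config$n_reference
  group_of <- NULL
  props_list <- NULL
  if (config$admix$type == "groups") {
    n_groups <- length(config$admix$props)
    group_of <- ((seq_len(n_tot) - 1L) %% n_groups) + 1L
    props_list <- config$admix$props[group_of]
  }
  sim <- simulate_admixed(founders, config, n_tot, props_list = props_list)
  substream(config, "split")
  qi <- sort(sample.int(n_tot, config$n_query))
  ri <- setdiff(seq_len(n_tot), qi)
  split_panel <- function(ind) {
    rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
    haplotype_panel(sim$panel$alleles[rows, , drop = FALSE],
                    sim$panel$positions, chrom = sim$panel$chrom,
                    sample_ids = sim$panel$sample_ids[ind],
                    ref = sim$panel$ref, alt = sim$panel$alt)
  }
  query <- split_panel(qi)
  ref <- split_panel(ri)
  # reference labels
  pop_lab <- if (config$admix$type == "groups") {
    grp <- group_of[ri]
    maj <- vapply(config$admix$props, which.max, integer(1))
    config$pop_names[maj[grp]]
  } else {
    config$pop_names[apply(sim$truth_p[ri, , drop = FALSE], 1L, which.max)]
  }
  popmap <- population_map_from_samples(
    stats::setNames(pop_lab, ref$sample_ids), ref)
  # genotyping error on both panels (after truth is recorded)
  query <- inject_errors(query, config$g, seed = config$seed + 37L)
  ref <- inject_errors(ref, config$g, seed = config$seed + 41L)
  ref_rows <- as.vector(rbind(2L * ri - 1L, 2L * ri))
  ref_labels <- sim$labels[ref_rows, , drop = FALSE]
  rownames(ref_labels) <- ref$hap_ids
  query_rows <- as.vector(rbind(2L * qi - 1L, 2L * qi))
  query_labels <- sim$labels[query_rows, , drop = FALSE]
  rownames(query_labels) <- query$hap_ids
  list(query = query, ref = ref, popmap = popmap,
       truth = list(p = sim$truth_p[qi, , drop = FALSE], labels = query_labels),
       ref_truth = list(p = sim$truth_p[ri, , drop = FALSE], labels = ref_labels),
       ref_dosage = dosage_from_labels(ref_labels, config$K),
       config = config)
}
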