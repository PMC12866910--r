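# Windowed synthesis of ancestry-homogeneous reference haplotypes.

test_that("window partition is exhaustive, non-overlapping, remainder-aware", {
  w <- window_partition(15, 3)
  expect_identical(w$start, c(0L, 3L, 6L, 9L, 12L))
  expect_identical(w$end, c(3L, 6L, 9L, 12L, 15L))
  w2 <- window_partition(10, 3)
  expect_identical(nrow(w2), 4L)
  expect_identical(w2$start[4], 9L)
  expect_identical(w2$end[4], 10L)
  expect_identical(nrow(window_partition(7, 7)), 1L)
  expect_error(window_partition(10, 0), "at least 1")
  expect_error(window_partition(5, 6), "exceeds")
})

test_that("window candidates are the pool members meeting the mean-dosage cutoff", {
  # 4 pool haplotypes over 15 sites, windows of 3; per-window target dosage
  # chosen so that in window 1 H0, H1, H3 reach 0.6 but H2 does not, and in
  # window 3 only H1 qualifies
  wd <- rbind(H0 = c(1.0, 0.8, 0.2, 1.0, 0.4),
              H1 = c(0.7, 1.0, 0.9, 0.2, 1.0),
              H2 = c(0.4, 0.6, 0.5, 0.8, 0.9),
              H3 = c(0.6, 0.3, 0.3, 0.6, 0.8))
  dp <- block_dosage(rownames(wd), wd, W = 3, N = 15, K = 3, target = 1)
  wins <- window_partition(15, 3)
  pool <- rownames(wd)
  expect_identical(window_candidates(dp, wins[1, ], 1, 0.6, pool),
                   c("H0", "H1", "H3"))
  expect_identical(window_candidates(dp, wins[3, ], 1, 0.6, pool), "H1")
  # cutoff 1 excludes any haplotype below full dosage in the window
  expect_identical(window_candidates(dp, wins[1, ], 1, 1.0, pool), "H0")
  expect_identical(window_candidates(dp, wins[4, ], 1, 1.0, pool), "H0")
  # nobody qualifies: empty set, not an error
  wd0 <- wd; wd0[] <- 0.1
  dp0 <- block_dosage(rownames(wd0), wd0, W = 3, N = 15, K = 3, target = 1)
  expect_length(window_candidates(dp0, wins[1, ], 1, 0.6, pool), 0L)
})

test_that("synthesis copies windows from candidates and records provenance", {
  set.seed(41)
  ref <- random_hap_panel(6, 30)
  ids <- ref$hap_ids
  # fully target-pure pool: no fallback, dosage 1 by construction
  labels <- matrix(1L, 6, 30, dimnames = list(ids, NULL))
  dp <- dosage_from_labels(labels, K = 2)
  syn <- synthesize_haplotype(ref, dp, target_pop = 1, pool = ids,
                              cutoff = 0.7, W = 10)
  expect_length(syn$fallback_windows, 0L)
  expect_identical(length(syn$provenance), 3L)
  # provenance reconstruction reproduces the alleles exactly
  wins <- window_partition(30, 10)
  rebuilt <- integer(30)
  for (w in seq_len(nrow(wins))) {
    span <- (wins$start[w] + 1):wins$end[w]
    rebuilt[span] <- ref$alleles[syn$provenance[w], span]
  }
  expect_identical(syn$alleles, rebuilt)
  # a pool of one: the synthetic haplotype equals that haplotype
  syn1 <- synthesize_haplotype(ref, dp, 1, pool = ids[2], cutoff = 0.7, W = 10)
  expect_identical(syn1$alleles, unname(ref$alleles[ids[2], ]))
})

test_that("per-window cutoff guarantees genome-wide dosage when no window falls back", {
  set.seed(42)
  ref <- random_hap_panel(8, 40)
  ids <- ref$hap_ids
  # mixed-ancestry haplotypes, but every window keeps at least one candidate
  labels <- matrix(2L, 8, 40, dimnames = list(ids, NULL))
  labels[1:4, ] <- 1L          # four pure target haplotypes
  labels[5, 1:30] <- 1L        # 75% target
  dp <- dosage_from_labels(labels, K = 2)
  for (rep in 1:10) {
    syn <- synthesize_haplotype(ref, dp, 1, pool = ids, cutoff = 0.7, W = 8)
    expect_length(syn$fallback_windows, 0L)
    # recompute realized dosage from provenance truth
    wins <- window_partition(40, 8)
    realized <- mean(vapply(seq_len(nrow(wins)), function(w)
      mean(labels[syn$provenance[w],
                  (wins$start[w] + 1):wins$end[w]] == 1L), numeric(1)))
    expect_gte(realized, 0.7)
  }
})

test_that("panel refinement is deterministic, labelled, and provenance-complete", {
  set.seed(43)
  cfg <- sim_config(K = 2, founders_per_pop = 4, n_sites = 400, n_query = 2,
                    n_reference = 20, seed = 9,
                    admix = list(type = "groups",
                                 props = list(c(0.55, 0.45), c(0.45, 0.55))))
  ds <- make_dataset(cfg)
  r1 <- refine_panel(ds$ref, ds$ref_dosage, ds$popmap, count_per_pop = 6,
                     cutoff = 0.6, W = 50, seed = 77)
  r2 <- refine_panel(ds$ref, ds$ref_dosage, ds$popmap, count_per_pop = 6,
                     cutoff = 0.6, W = 50, seed = 77)
  expect_identical(r1$panel$alleles, r2$panel$alleles)
  expect_identical(r1$provenance, r2$provenance)
  expect_identical(nrow(r1$panel$alleles), 12L)
  expect_identical(r1$popmap$pop_size, c(6L, 6L))
  # every window's contributor belongs to the target population
  pools <- split(names(ds$popmap$hap_pop), ds$popmap$hap_pop)
  for (k in 1:2) {
    hp <- r1$popmap$hap_pop
    syn_ids <- names(hp)[hp == k]
    src <- r1$provenance$source_hap[r1$provenance$hap_id %in% syn_ids]
    expect_true(all(src %in% pools[[k]]))
  }
  expect_error(refine_panel(ds$ref, ds$ref_dosage, ds$popmap, 5), "even")
})

test_that("refinement increases mean own-population dosage of the panel", {
  set.seed(44)
  cfg <- sim_config(K = 2, founders_per_pop = 4, n_sites = 1000, n_query = 2,
                    n_reference = 40, seed = 10,
                    admix = list(type = "groups",
                                 props = list(c(0.55, 0.45), c(0.45, 0.55))))
  ds <- make_dataset(cfg)
  own_before <- mean(apply(ds$ref_truth$p, 1, max))
  r <- refine_panel(ds$ref, ds$ref_dosage, ds$popmap, count_per_pop = 20,
                    cutoff = 0.7, W = 100, seed = 3)
  # realized own-pop dosage of each synthetic haplotype from provenance truth
  wins <- window_partition(1000, 100)
  prov <- r$provenance
  own_syn <- vapply(unique(prov$hap_id), function(h) {
    rows <- prov[prov$hap_id == h, ]
    k <- r$popmap$hap_pop[[h]]
    mean(vapply(seq_len(nrow(rows)), function(i) {
      w <- rows$window[i]
      mean(ds$ref_truth$labels[rows$source_hap[i],
                               (wins$start[w] + 1):wins$end[w]] == k)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean(own_syn), own_before)
})

test_that("homogeneity filtering applies the genome-wide own-dosage rule", {
  ids <- paste0("h", 1:3)
  N <- 20
  d1 <- rbind(rep(0.8, N), rep(0.55, N), rep(0.5, N))
  rownames(d1) <- ids
  dp <- dosage_panel(ids, list(d1, 1 - d1))
  pm <- population_map("A", stats::setNames(c(1, 1, 1), ids))
  expect_identical(filter_homogeneous(dp, pm, 0.7), "h1")
  expect_identical(filter_homogeneous(dp, pm, 0.5), ids)
})
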