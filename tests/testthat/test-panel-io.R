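# Reading/writing panels, labels, proportions, matches and dosage tables.

test_that("phased biallelic VCF parses into a haplotype panel and round-trips", {
  set.seed(11)
  alleles <- random_alleles(6, 10)
  path <- write_vcf_lines(gt_from_alleles(alleles))
  res <- read_phased_vcf(path)
  expect_length(res$panels, 1L)
  p <- res$panels[[1L]]
  expect_identical(dim(p$alleles), c(6L, 10L))
  expect_identical(unname(p$alleles), alleles)
  expect_identical(p$sample_ids, paste0("s", 1:3))
  expect_identical(sum(res$skipped), 0L)

  # write -> read reproduces alleles, positions and sample order exactly
  out <- tempfile(fileext = ".vcf")
  write_phased_vcf(p, out)
  p2 <- read_phased_vcf(out)$panels[[1L]]
  expect_identical(p2$alleles, p$alleles)
  expect_identical(p2$positions, p$positions)
  expect_identical(p2$sample_ids, p$sample_ids)
})

test_that("multiallelic, indel, missing and unphased sites are dropped and counted", {
  set.seed(12)
  alleles <- random_alleles(4, 10)
  gt <- gt_from_alleles(alleles)
  alt <- rep("C", 10)
  ref <- rep("A", 10)
  alt[3] <- "C,T"          # multiallelic
  ref[5] <- "AT"           # indel
  gt[7, 1] <- ".|."        # missing genotype
  gt[9, 2] <- "0/1"        # unphased
  path <- write_vcf_lines(gt, ref = ref, alt = alt)
  res <- read_phased_vcf(path)
  expect_identical(res$skipped,
                   c(multiallelic = 1L, indel = 1L, missing = 1L, unphased = 1L))
  p <- res$panels[[1L]]
  expect_identical(ncol(p$alleles), 6L)
  expect_identical(p$positions, c(1L, 2L, 4L, 6L, 8L, 10L) * 100L)
  # all sites filtered away is an explicit error naming the filters
  gt_bad <- gt_from_alleles(random_alleles(4, 2))
  gt_bad[] <- "0/1"
  expect_error(read_phased_vcf(write_vcf_lines(gt_bad)), "unphased")
})

test_that("MAF filtering retains boundary sites, drops monomorphic, is idempotent", {
  m <- random_alleles(8, 5, af = 0.5)
  m[, 2] <- c(1L, rep(0L, 7))  # MAF 1/8 = 0.125 >= 0.05: retained
  m[, 4] <- 0L                 # monomorphic: dropped for any threshold > 0
  p <- haplotype_panel(m, 1:5)
  f <- maf_filter(p, 0.05)
  expect_true(2L %in% f$positions)
  expect_false(4L %in% f$positions)
  expect_identical(maf_filter(p, 0), p)
  expect_identical(maf_filter(f, 0.05), f)  # idempotent
  expect_error(maf_filter(p, 0.5), "threshold")
})

test_that("sample labels expand to haplotypes in first-appearance order", {
  p <- random_hap_panel(8, 6)
  path <- tempfile()
  writeLines(c("# labels", "s1\tA", "s2\tA", "s3\tB", "s4\tB"), path)
  pm <- read_labels(path, p)
  expect_identical(pm$populations, c("A", "B"))
  expect_identical(pm$pop_size, c(4L, 4L))
  expect_identical(unname(pm$hap_pop[c("s1_0", "s1_1", "s3_0")]), c(1L, 1L, 2L))

  writeLines(c("s1\tX", "s2\tX", "s3\tX", "s4\tX"), path)
  expect_identical(read_labels(path, p)$K, 1L)

  writeLines(c("s1\tA", "s2\tA", "s3\tB"), path)
  expect_error(read_labels(path, p), "s4")

  writeLines(c("s1\tA", "s2\tA", "s3\tB", "s4\tB", "s99\tC"), path)
  expect_warning(read_labels(path, p), "s99")
})

test_that("site harmonization intersects on position and alleles, symmetrically", {
  set.seed(13)
  q <- random_hap_panel(4, 8)
  r <- random_hap_panel(6, 8)
  h <- harmonize_sites(q, r)
  expect_identical(h$query$alleles, q$alleles)
  expect_identical(h$ref$alleles, r$alleles)
  expect_identical(unname(h$dropped), c(0L, 0L))

  r_sub <- subset_sites(r, c(2, 3, 5, 8))
  h2 <- harmonize_sites(q, r_sub)
  expect_identical(h2$query$positions, r_sub$positions)
  expect_identical(h2$ref$positions, h2$query$positions)
  expect_identical(unname(h2$dropped["query"]), 4L)

  r_far <- haplotype_panel(r$alleles, r$positions + 100000L)
  expect_error(harmonize_sites(q, r_far), "no shared sites")
})

test_that("proportion tables are written at fixed precision and round-trip", {
  m <- matrix(c(0.5, 0.5), nrow = 1, dimnames = list("s1", NULL))
  path <- tempfile()
  write_proportions(m, c("A", "B"), path)
  expect_identical(readLines(path)[2], "s1\t0.500000\t0.500000")
  m2 <- rbind(m, s2 = c(NA, NA))
  expect_warning(write_proportions(m2, c("A", "B"), path), "no matches")
  got <- read_proportions(path)
  expect_equal(got["s1", ], c(A = 0.5, B = 0.5))
  expect_true(all(is.na(got["s2", ])))
  expect_error(write_proportions(m, c("A", "B", "C"), path), "populations")
})

test_that("match lists and dosage tables round-trip through TSV", {
  set.seed(14)
  ref <- random_hap_panel(6, 20)
  query <- random_hap_panel(4, 20)
  pm <- population_map_from_samples(
    stats::setNames(c("A", "A", "B"), ref$sample_ids), ref)
  m <- find_long_matches(query, ref, L = 3, popmap = pm)
  path <- tempfile()
  write_matches(m, ref, pm, path)
  back <- read_matches(path, pm)
  expect_identical(back$start, m$start)
  expect_identical(back$end, m$end)
  expect_identical(back$pop, m$pop)
  expect_identical(back$query_hap, m$query_hap)

  labels <- matrix(sample(1:2, 4 * 20, replace = TRUE), nrow = 4,
                   dimnames = list(paste0("h", 1:4), NULL))
  dp <- dosage_from_labels(labels, K = 2)
  dpath <- tempfile()
  write_dosage(dp, c("A", "B"), dpath)
  dp2 <- read_dosage(dpath)
  expect_identical(dp2$hap_ids, dp$hap_ids)
  expect_equal(unname(dp2$dosage[[1L]]), unname(dp$dosage[[1L]]))
})
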