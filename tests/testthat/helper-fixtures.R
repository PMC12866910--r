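# Shared fixtures: all test inputs are built in code.

random_alleles <- function(M, N, af = 0.5) {
  matrix(rbinom(M * N, 1L, af), nrow = M)
}

random_hap_panel <- function(M, N, af = 0.5) {
  haplotype_panel(random_alleles(M, N, af), seq_len(N) * 10L)
}

# a minimal phased VCF as text lines for n diploid samples
vcf_lines <- function(gt, chrom = "1", pos = NULL, ref = NULL, alt = NULL,
                      samples = NULL) {
  n_site <- nrow(gt)
  n_samp <- ncol(gt)
  if (is.null(pos)) pos <- seq_len(n_site) * 100L
  if (is.null(ref)) ref <- rep("A", n_site)
  if (is.null(alt)) alt <- rep("C", n_site)
  if (is.null(samples)) samples <- paste0("s", seq_len(n_samp))
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    vapply(seq_len(n_site), function(i)
      paste(c(chrom, pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT",
              gt[i, ]), collapse = "\t"), character(1)))
}

write_vcf_lines <- function(...) {
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf_lines(...), path)
  path
}

# uniform diploid GT matrix (sites x samples) from a haplotype matrix
gt_from_alleles <- function(alleles) {
  h0 <- alleles[seq(1L, nrow(alleles), by = 2L), , drop = FALSE]
  h1 <- alleles[seq(2L, nrow(alleles), by = 2L), , drop = FALSE]
  t(matrix(paste0(h0, "|", h1), nrow = nrow(h0)))
}

# dosage panel with prescribed per-hap constant target dosage per window
# (used to reproduce known candidate sets)
block_dosage <- function(hap_ids, target_window_dosage, W, N, K = 2,
                         target = 1L) {
  H <- length(hap_ids)
  d_target <- matrix(0, H, N)
  for (h in seq_len(H)) {
    wins <- window_partition(N, W)
    for (w in seq_len(nrow(wins)))
      d_target[h, (wins$start[w] + 1L):wins$end[w]] <- target_window_dosage[h, w]
  }
  mats <- vector("list", K)
  rest <- (1 - d_target) / (K - 1)
  for (k in seq_len(K)) mats[[k]] <- if (k == target) d_target else rest
  dosage_panel(hap_ids, mats)
}
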