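# On-disk artifacts: phased VCF panels, label tables, match lists,
# proportion tables, dosage tables.

#' Read phased biallelic haplotypes from a VCF
#'
#' Parses a (plain or bgzipped) VCF with `vcfR` and extracts fully phased
#' biallelic SNP genotypes into one [haplotype_panel()] per chromosome.
#' Multiallelic sites, indels/non-SNPs, and sites with any missing or
#' unphased genotype are dropped and counted in a skip report. Haplotype
#' expansion is fixed: haplotype `<sample>_0` is the first allele of the GT
#' field, `<sample>_1` the second.
#'
#' @param path path to the VCF file.
#' @param region optional chromosome identifier; only that chromosome is
#'   returned.
#' @return a list with elements `panels` (named list of `haplotype_panel`,
#'   one per chromosome) and `skipped` (named integer vector with counts of
#'   `multiallelic`, `indel`, `missing`, `unphased` sites dropped).
#' @export
read_phased_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep_chrom <- rep(TRUE, length(chrom))
  if (!is.null(region)) {
    keep_chrom <- chrom == region
    if (!any(keep_chrom)) stop("no sites on requested chromosome ", region)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  samples <- colnames(vcfR::extract.gt(vcf))
  snp <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  multi <- grepl(",", alt, fixed = TRUE)
  miss <- apply(gt, 1L, function(g) any(is.na(g) | grepl(".", g, fixed = TRUE)))
  unph <- apply(gt, 1L, function(g) any(grepl("/", g, fixed = TRUE)))
  # classify each dropped site once, in priority order
  drop_multi <- keep_chrom & multi
  drop_indel <- keep_chrom & !drop_multi & !snp
  drop_miss  <- keep_chrom & !drop_multi & !drop_indel & miss
  drop_unph  <- keep_chrom & !drop_multi & !drop_indel & !drop_miss & unph
  skipped <- c(multiallelic = sum(drop_multi), indel = sum(drop_indel),
               missing = sum(drop_miss), unphased = sum(drop_unph))
  keep <- keep_chrom & !drop_multi & !drop_indel & !drop_miss & !drop_unph
  if (!any(keep))
    stop("no phased biallelic SNP sites remain after filtering (skipped: ",
         paste(names(skipped), skipped, sep = "=", collapse = ", "), ")")
  panels <- list()
  for (cm in unique(chrom[keep])) {
    idx <- which(keep & chrom == cm)
    idx <- idx[order(pos[idx])]
    g <- gt[idx, , drop = FALSE]
    if (any(nchar(g) != 3L))
      stop("non-diploid GT field encountered on chromosome ", cm)
    h0 <- substr(g, 1L, 1L)
    h1 <- substr(g, 3L, 3L)
    if (!all(c(h0, h1) %in% c("0", "1")))
      stop("unexpected allele codes in GT (expected 0/1) on chromosome ", cm)
    M <- 2L * length(samples)
    N <- length(idx)
    alleles <- matrix(0L, nrow = M, ncol = N)
    # h0/h1 are sites x samples; interleave into sample_0, sample_1 rows
    alleles[seq(1L, M, by = 2L), ] <- t(h0 == "1")
    alleles[seq(2L, M, by = 2L), ] <- t(h1 == "1")
    panels[[cm]] <- haplotype_panel(alleles, pos[idx], chrom = cm,
                                    sample_ids = samples,
                                    ref = ref[idx], alt = alt[idx])
  }
  list(panels = panels, skipped = skipped)
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal deterministic plain-text VCF 4.2 with GT-only phased
#' genotypes, suitable for round-tripping through [read_phased_vcf()].
#'
#' @param panel a [haplotype_panel()] or a list of them (one per chromosome,
#'   written in list order).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  panels <- if (inherits(panel, "haplotype_panel")) list(panel) else panel
  stopifnot(all(vapply(panels, inherits, logical(1), "haplotype_panel")))
  samples <- panels[[1L]]$sample_ids
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ibdancestry",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  for (p in panels) {
    if (!identical(p$sample_ids, samples))
      stop("all per-chromosome panels must share the same samples")
    h0 <- p$alleles[seq(1L, nrow(p$alleles), by = 2L), , drop = FALSE]
    h1 <- p$alleles[seq(2L, nrow(p$alleles), by = 2L), , drop = FALSE]
    gt <- matrix(paste0(h0, "|", h1), nrow = nrow(h0))  # samples x sites
    lines <- paste(p$chrom, p$positions, ".", p$ref, p$alt, ".", "PASS", ".",
                   "GT", apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a sample-to-population label table
#'
#' Two tab-separated columns (`sample_id`, `population`), no header required;
#' lines starting with `#` are comments. Both haplotypes of a sample receive
#' the sample's population. Errors if any panel sample is unlabelled; labels
#' for samples absent from the panel are ignored with a warning.
#'
#' @param path path to the TSV.
#' @param panel the [haplotype_panel()] the labels apply to.
#' @return a [population_map()].
#' @export
read_labels <- function(path, panel) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character"))
  if (ncol(tab) != 2L) stop("label table must have exactly two columns")
  if (identical(tolower(tab[1L, 1L]), "sample_id")) tab <- tab[-1L, , drop = FALSE]
  if (anyDuplicated(tab[[1L]])) stop("duplicated sample ids in label table")
  population_map_from_samples(stats::setNames(tab[[2L]], tab[[1L]]), panel)
}

#' Write a sample-to-population label table
#'
#' @param sample_ids character vector of sample ids.
#' @param pops population label for each sample.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(sample_ids, pops, path) {
  stopifnot(length(sample_ids) == length(pops))
  utils::write.table(data.frame(sample_ids, pops), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write per-individual ancestry proportions
#'
#' TSV with header `sample_id` + population names; proportions formatted to
#' 6 decimals. Individuals with no matches (all-`NA` estimates) get an `NA`
#' row and trigger a warning.
#'
#' @param proportions numeric matrix, one row per individual, `K` columns;
#'   rownames are sample ids. Rows may be all-`NA`.
#' @param populations length-`K` population names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(proportions, populations, path) {
  proportions <- as.matrix(proportions)
  if (ncol(proportions) != length(populations))
    stop("proportions have ", ncol(proportions), " columns but ",
         length(populations), " populations were given")
  na_row <- apply(proportions, 1L, function(r) all(is.na(r)))
  if (any(!na_row)) {
    sums <- rowSums(proportions[!na_row, , drop = FALSE])
    if (any(abs(sums - 1) > 1e-6))
      stop("non-NA proportion rows must sum to 1 within 1e-6")
  }
  if (any(na_row))
    warning(sum(na_row), " individual(s) with no matches written as NA")
  ids <- rownames(proportions)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(proportions)))
  lines <- c(paste(c("sample_id", populations), collapse = "\t"),
             vapply(seq_len(nrow(proportions)), function(i) {
               vals <- if (na_row[i]) rep("NA", ncol(proportions))
                       else sprintf("%.6f", proportions[i, ])
               paste(c(ids[i], vals), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ancestry proportion table written by [write_proportions()]
#'
#' @param path path to the TSV.
#' @return numeric matrix with sample-id rownames and population colnames.
#' @export
read_proportions <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  m
}

#' Write a long-match list
#'
#' One row per maximal match: `query_hap`, `ref_hap`, `ref_population`,
#' `start_index`, `end_index` (half-open, 0-based site indices), `n_sites`,
#' `start_bp`, `end_bp` (physical coordinates of the first and last matched
#' site).
#'
#' @param matches a match data frame as returned by [find_long_matches()]
#'   (columns `query_hap`, `ref_hap`, `pop`, `start`, `end`).
#' @param panel the reference [haplotype_panel()] (for physical coordinates).
#' @param popmap the [population_map()] (for population labels).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, panel, popmap, path) {
  out <- data.frame(
    query_hap = matches$query_hap,
    ref_hap = matches$ref_hap,
    ref_population = popmap$populations[matches$pop],
    start_index = matches$start,
    end_index = matches$end,
    n_sites = matches$end - matches$start,
    start_bp = panel$positions[matches$start + 1L],
    end_bp = panel$positions[matches$end])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-match list written by [write_matches()]
#'
#' Enables externally produced match lists (any IBD caller emitting the same
#' columns) to feed the scoring module.
#'
#' @param path path to the TSV.
#' @param popmap optional [population_map()]; when given, the
#'   `ref_population` column is converted back to 1-based `pop` indices.
#' @return a match data frame with columns `query_hap`, `ref_hap`, `pop`
#'   (if resolvable), `start`, `end`.
#' @export
read_matches <- function(path, popmap = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  out <- data.frame(query_hap = tab$query_hap, ref_hap = tab$ref_hap,
                    start = as.integer(tab$start_index),
                    end = as.integer(tab$end_index),
                    stringsAsFactors = FALSE)
  if (!is.null(popmap)) {
    out$pop <- match(tab$ref_population, popmap$populations)
    if (anyNA(out$pop)) stop("match list names populations absent from the map")
  }
  out
}

#' Write a per-haplotype site-wise ancestry dosage table
#'
#' Long format: `hap_id`, `site_index` (0-based), then one dosage column per
#' population.
#'
#' @param dosage a [dosage_panel()].
#' @param populations population names for the dosage columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage <- function(dosage, populations, path) {
  stopifnot(inherits(dosage, "dosage_panel"))
  H <- length(dosage$hap_ids)
  N <- ncol(dosage$dosage[[1L]])
  out <- data.frame(hap_id = rep(dosage$hap_ids, each = N),
                    site_index = rep(seq_len(N) - 1L, times = H))
  for (k in seq_along(dosage$dosage))
    out[[populations[k]]] <- as.vector(t(dosage$dosage[[k]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage table written by [write_dosage()]
#'
#' @param path path to the TSV.
#' @return a [dosage_panel()]; population names are taken from the header.
#' @export
read_dosage <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  hap_ids <- unique(tab$hap_id)
  N <- max(tab$site_index) + 1L
  pops <- setdiff(colnames(tab), c("hap_id", "site_index"))
  ord <- order(match(tab$hap_id, hap_ids), tab$site_index)
  tab <- tab[ord, ]
  mats <- lapply(pops, function(p)
    matrix(tab[[p]], nrow = length(hap_ids), ncol = N, byrow = TRUE,
           dimnames = list(hap_ids, NULL)))
  names(mats) <- pops
  dosage_panel(hap_ids, mats)
}
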