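# Accuracy metrics against known ancestry truth: per-individual RMSE and
# Kullback-Leibler divergence, and cohort summaries.

#' Root mean squared error between two proportion vectors
#'
#' `sqrt(mean((estimate - truth)^2))`; symmetric in its arguments.
#'
#' @param estimate,truth length-`k` proportion vectors (each summing to 1
#'   within 1e-6).
#' @return non-negative scalar in `[0, 1]`.
#' @export
rmse <- function(estimate, truth) {
  if (length(estimate) != length(truth))
    stop("proportion vectors differ in length")
  if (abs(sum(estimate) - 1) > 1e-6 || abs(sum(truth) - 1) > 1e-6)
    stop("proportion vectors must sum to 1")
  sqrt(mean((estimate - truth)^2))
}

#' Kullback-Leibler divergence between truth and estimate
#'
#' Default is the standard non-negative divergence with the truth as the
#' reference distribution, `sum(p * log(p / max(p~, epsilon)))` in natural
#' log (terms with `p == 0` contribute zero); zero estimate entries are
#' clamped at `epsilon`. `direction = "estimate_vs_truth"` instead evaluates
#' `sum(p * log(max(p~, epsilon) / p))`, the negated orientation some tools
#' report; it is non-positive.
#'
#' @param estimate,truth length-`k` proportion vectors.
#' @param epsilon clamp for zero estimate entries (default 1e-9).
#' @param direction `"truth_vs_estimate"` (default, standard KL) or
#'   `"estimate_vs_truth"`.
#' @return divergence in nats; 0 when the vectors are equal.
#' @export
kl_divergence <- function(estimate, truth, epsilon = 1e-9,
                          direction = c("truth_vs_estimate",
                                        "estimate_vs_truth")) {
  direction <- match.arg(direction)
  if (length(estimate) != length(truth))
    stop("proportion vectors differ in length")
  if (epsilon <= 0) stop("epsilon must be positive")
  pos <- truth > 0
  val <- sum(truth[pos] * log(truth[pos] / pmax(estimate[pos], epsilon)))
  if (direction == "estimate_vs_truth") -val else val
}

#' Summarize estimation accuracy against truth
#'
#' Computes per-individual RMSE and KL divergence for every query individual
#' present in both the estimates and the truth. `NA` estimates (individuals
#' with no matches) are excluded from the means/medians and counted in
#' `n_na`.
#'
#' @param estimates numeric matrix of estimated proportions (rownames =
#'   sample ids) or an `ancestry_fit` object.
#' @param truth numeric matrix of true proportions (rownames = sample ids).
#' @param epsilon passed to [kl_divergence()].
#' @return an object of class `eval_report`: data frame `per_individual`
#'   (sample_id, rmse, kl) plus `mean_rmse`, `median_rmse`, `mean_kl`,
#'   `median_kl`, `n_evaluated`, `n_na`.
#' @export
evaluate_estimates <- function(estimates, truth, epsilon = 1e-9) {
  if (inherits(estimates, "ancestry_fit")) estimates <- estimates$proportions
  estimates <- as.matrix(estimates)
  truth <- as.matrix(truth)
  shared <- intersect(rownames(estimates), rownames(truth))
  if (length(shared) == 0L) stop("no overlapping samples between estimates and truth")
  est <- estimates[shared, , drop = FALSE]
  tru <- truth[shared, , drop = FALSE]
  if (ncol(est) != ncol(tru)) stop("population counts differ")
  if (!is.null(colnames(est)) && !is.null(colnames(tru))) {
    if (!setequal(colnames(est), colnames(tru)))
      stop("estimates and truth name different populations")
    tru <- tru[, colnames(est), drop = FALSE]
  }
  is_na <- apply(est, 1L, function(r) any(is.na(r)))
  per <- data.frame(sample_id = shared,
                    rmse = NA_real_, kl = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in which(!is_na)) {
    per$rmse[i] <- rmse(est[i, ], tru[i, ])
    per$kl[i] <- kl_divergence(est[i, ], tru[i, ], epsilon = epsilon)
  }
  ok <- !is_na
  structure(list(per_individual = per,
                 mean_rmse = mean(per$rmse[ok]),
                 median_rmse = stats::median(per$rmse[ok]),
                 mean_kl = mean(per$kl[ok]),
                 median_kl = stats::median(per$kl[ok]),
                 n_evaluated = sum(ok), n_na = sum(is_na)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("ancestry accuracy report\n")
  cat(sprintf("  individuals evaluated: %d (NA: %d)\n", x$n_evaluated, x$n_na))
  cat(sprintf("  RMSE  mean %.4f  median %.4f\n", x$mean_rmse, x$median_rmse))
  cat(sprintf("  KL    mean %.4f  median %.4f\n", x$mean_kl, x$median_kl))
  invisible(x)
}

#' Write an accuracy report to TSV
#'
#' Per-individual rows followed by `#`-prefixed summary lines; deterministic
#' for identical inputs.
#'
#' @param report an [evaluate_estimates()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("sample_id\trmse\tkl", con)
  p <- report$per_individual
  writeLines(sprintf("%s\t%s\t%s", p$sample_id,
                     ifelse(is.na(p$rmse), "NA", sprintf("%.6f", p$rmse)),
                     ifelse(is.na(p$kl), "NA", sprintf("%.6f", p$kl))), con)
  writeLines(sprintf("# mean_rmse=%.6f median_rmse=%.6f mean_kl=%.6f median_kl=%.6f n_evaluated=%d n_na=%d",
                     report$mean_rmse, report$median_rmse, report$mean_kl,
                     report$median_kl, report$n_evaluated, report$n_na), con)
  invisible(path)
}
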