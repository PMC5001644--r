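# Empirical-null thresholds, exceedance fractions and enrichment testing.

#' Decision threshold at a nominal false positive rate
#'
#' The threshold is the `ceiling((1 - fpr) * n)`-th order statistic of the
#' null (putatively neutral) score distribution. Exceedance uses a
#' strictly-greater comparison, so the null's own exceedance never
#' exceeds `fpr`, with equality when `n * fpr` is integral and the scores
#' are tie-free.
#'
#' @param null_scores Nonempty numeric vector of scores from the neutral
#'   set.
#' @param fpr Nominal false positive rate in (0, 1) (default 0.01).
#' @return The threshold score.
#' @export
fpr_threshold <- function(null_scores, fpr = 0.01) {
  if (!length(null_scores)) stop("empty null distribution")
  stopifnot(fpr > 0, fpr < 1)
  s <- sort(null_scores)
  s[ceiling((1 - fpr) * length(s))]
}

#' Exceedance percentage over a threshold
#'
#' Percentage of scores strictly greater than the threshold; ties at the
#' threshold count as non-exceeding.
#'
#' @param scores Nonempty numeric vector.
#' @param threshold Scalar threshold.
#' @return Percentage in [0, 100].
#' @export
exceedance <- function(scores, threshold) {
  if (!length(scores)) stop("empty score set")
  100 * mean(scores > threshold)
}

#' One-tailed Fisher's exact test for enrichment
#'
#' Hypergeometric tail probability that the first row of the 2x2 table
#' (conventionally the disease cohort) is enriched in exceedances.
#'
#' @param tab 2x2 matrix of nonnegative integer counts; rows are cohorts,
#'   columns are exceed / not-exceed.
#' @return The one-tailed p-value.
#' @export
fisher_one_tailed <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must contain nonnegative integer counts")
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Bonferroni-corrected significance cutoff
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param k Number of tests in the family (>= 1).
#' @return `alpha / k`.
#' @export
bonferroni_cutoff <- function(alpha = 0.05, k) {
  if (k < 1) stop("family size must be at least 1")
  alpha / k
}

#' Empirical p-value of a single score against a null sample
#'
#' Add-one estimator `(1 + #\{null >= score\}) / (1 + n_null)`, which never
#' returns zero.
#'
#' @param score Scalar score.
#' @param null_scores Null sample.
#' @return Empirical p-value in (0, 1].
#' @export
empirical_pvalue <- function(score, null_scores) {
  if (!length(null_scores)) stop("empty null distribution")
  (1 + sum(null_scores >= score)) / (1 + length(null_scores))
}

#' Cohort enrichment table over empirical-null thresholds
#'
#' For each (function, score column) cell: derives the threshold from the
#' neutral cohort at the nominal FPR, computes disease and neutral
#' exceedance percentages, tests enrichment with a one-tailed Fisher's
#' exact test, and flags significance at the Bonferroni-corrected cutoff.
#' Single-function rows form one family of size `2 * #functions` (loss and
#' gain jointly, per score column); rows whose function id is listed in
#' `combined_funs` form a separate family of size 4.
#'
#' @param disease,neutral data.frames with columns `fun`, `column`
#'   (e.g. `"loss_stable"`), `score`; the two cohorts must cover identical
#'   (fun, column) pairs.
#' @param fpr Nominal false positive rate (default 0.01).
#' @param alpha Family-wise error rate (default 0.05).
#' @param combined_funs Function ids to treat as combined-model rows
#'   (family of 4).
#' @return data.frame of class `enrichment_table` with one row per
#'   (fun, column): threshold, exceedance percentages, 2x2 counts,
#'   p-value, family size, corrected alpha and significance flag.
#' @export
enrichment_table <- function(disease, neutral, fpr = 0.01, alpha = 0.05,
                             combined_funs = character()) {
  need <- c("fun", "column", "score")
  stopifnot(all(need %in% names(disease)), all(need %in% names(neutral)))
  dk <- sort(unique(paste(disease$fun, disease$column, sep = "\r")))
  nk <- sort(unique(paste(neutral$fun, neutral$column, sep = "\r")))
  if (!identical(dk, nk))
    stop("disease and neutral cohorts cover different (fun, column) pairs")

  cells <- unique(disease[, c("fun", "column")])
  single_funs <- setdiff(unique(cells$fun), combined_funs)
  fam_single <- 2L * length(single_funs)
  fam_combined <- 4L

  out <- lapply(seq_len(nrow(cells)), function(i) {
    f <- cells$fun[i]; col <- cells$column[i]
    ds <- disease$score[disease$fun == f & disease$column == col]
    ns <- neutral$score[neutral$fun == f & neutral$column == col]
    thr <- fpr_threshold(ns, fpr)
    a <- sum(ds > thr); b <- length(ds) - a
    c_ <- sum(ns > thr); d <- length(ns) - c_
    p <- fisher_one_tailed(matrix(c(a, c_, b, d), 2, 2))
    fam <- if (f %in% combined_funs) fam_combined else fam_single
    cutoff <- bonferroni_cutoff(alpha, fam)
    data.frame(fun = f, column = col, threshold = thr,
               disease_pct = exceedance(ds, thr),
               neutral_pct = exceedance(ns, thr),
               n_disease_exceed = a, n_disease = length(ds),
               n_neutral_exceed = c_, n_neutral = length(ns),
               p = p, family = fam, alpha_corrected = cutoff,
               significant = p < cutoff, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "fpr") <- fpr
  attr(res, "alpha") <- alpha
  attr(res, "families") <- c(single = fam_single, combined = fam_combined)
  class(res) <- c("enrichment_table", "data.frame")
  res
}

#' Write an enrichment table as TSV plus a JSON sidecar
#'
#' The TSV mirrors the table; the JSON records the thresholds, nominal
#' FPR, alpha and family sizes.
#'
#' @param x An `enrichment_table`.
#' @param path TSV output path; the JSON is written next to it with
#'   extension `.json`.
#' @return The TSV path, invisibly.
#' @export
write_enrichment <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(fpr = attr(x, "fpr"), alpha = attr(x, "alpha"),
               families = as.list(attr(x, "families")),
               thresholds = stats::setNames(
                 as.list(x$threshold), paste(x$fun, x$column, sep = ":")))
  jsonlite::write_json(meta, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
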