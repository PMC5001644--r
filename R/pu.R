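# Positive-unlabeled learning: non-traditional kernel SVM, Platt
# calibration, class-prior conversion, and the fitted-model object.

#' Train a non-traditional (labeled vs unlabeled) kernel classifier
#'
#' Fits a large-margin classifier on a precomputed kernel matrix that
#' separates labeled items (+1) from unlabeled items (-1). The fit is
#' deterministic given the data and capacity.
#'
#' @param K Symmetric positive-semidefinite kernel matrix over all items
#'   (labeled rows first or in any order consistent with `y`).
#' @param y Vector in \{+1, -1\}: +1 for labeled, -1 for unlabeled.
#' @param C Capacity (cost) parameter; default 1, the standard default
#'   heuristic for a normalized kernel with unit diagonal.
#' @return List with `decision` (scores over all items, labeled high),
#'   `sv_index`, `sv_coef`, `b`, and `C`.
#' @export
train_nontraditional <- function(K, y, C = 1) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K), length(y) == nrow(K),
            all(y %in% c(-1, 1)), C > 0)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("kernel matrix is not positive semidefinite; ",
         "consider adding jitter to the diagonal (K + eps * I)")
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), factor(y, levels = c(-1, 1)),
                       type = "C-svc", C = C, scaled = FALSE)
  svi <- kernlab::SVindex(fit)
  co <- kernlab::coef(fit)[[1]]
  b <- kernlab::b(fit)
  dec <- as.vector(K[, svi, drop = FALSE] %*% co - b)
  # orient so that labeled items score high
  if (mean(dec[y == 1]) < mean(dec[y == -1])) {
    dec <- -dec; co <- -co; b <- -b
  }
  list(decision = dec, sv_index = svi, sv_coef = co, b = b, C = C)
}

#' Platt calibration of decision scores
#'
#' Fits the sigmoid \eqn{P(l=+1|s) = 1 / (1 + exp(A s + B))} to decision
#' scores by regularized maximum likelihood with the standard smoothed
#' targets \eqn{t_+ = (N_+ + 1)/(N_+ + 2)}, \eqn{t_- = 1/(N_- + 2)}
#' (Newton iteration with backtracking).
#'
#' @param scores Numeric decision values.
#' @param labels Vector in \{+1, -1\} (or logical), both classes present.
#' @return List with elements `A` and `B`.
#' @export
platt_calibrate <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, 1, -1)
  stopifnot(length(scores) == length(labels), all(labels %in% c(-1, 1)))
  pos <- labels == 1
  if (!any(pos) || all(pos)) stop("both classes must be present")
  n1 <- sum(pos); n0 <- sum(!pos)
  t <- ifelse(pos, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))

  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  obj <- function(A, B) {
    f <- A * scores + B
    # stable -sum(t*log(p) + (1-t)*log(1-p))
    sum(ifelse(f >= 0, t * f + log1p(exp(-f)), (t - 1) * f + log1p(exp(f))))
  }
  val <- obj(A, B)
  for (it in 1:100) {
    f <- A * scores + B
    p <- 1 / (1 + exp(f))          # P(+1) = p here since sigmoid is 1/(1+e^f)
    d1 <- t - p                     # dL/df
    d2 <- p * (1 - p)
    g <- c(sum(d1 * scores), sum(d1))
    H <- matrix(c(sum(d2 * scores^2), sum(d2 * scores),
                  sum(d2 * scores), sum(d2)), 2, 2)
    H <- H + diag(1e-12, 2)
    step <- solve(H, g)
    if (max(abs(g)) < 1e-10) break
    stepsize <- 1
    repeat {
      A2 <- A - stepsize * step[1]; B2 <- B - stepsize * step[2]
      v2 <- obj(A2, B2)
      if (v2 < val + 1e-12 || stepsize < 1e-10) break
      stepsize <- stepsize / 2
    }
    if (abs(val - v2) < 1e-12 && max(abs(g)) < 1e-6) { A <- A2; B <- B2; break }
    A <- A2; B <- B2; val <- v2
  }
  list(A = A, B = B)
}

#' Apply a Platt sigmoid
#' @param scores Numeric decision values.
#' @param sigmoid List with `A`, `B` from [platt_calibrate()].
#' @return Calibrated probabilities in (0, 1).
#' @export
platt_apply <- function(scores, sigmoid) {
  1 / (1 + exp(sigmoid$A * scores + sigmoid$B))
}

#' Convert a non-traditional posterior to a traditional posterior
#'
#' \eqn{P(y=+1|x) = P(y=+1) \cdot (n/m) \cdot P(l=+1|x) / (1 - P(l=+1|x))},
#' clipped into [0, 1]; the formula is valid under mild assumptions and is
#' unbounded, so values above 1 are truncated. `p_l = 1` maps to 1.
#'
#' @param p_l Calibrated non-traditional posterior(s) in [0, 1].
#' @param alpha Class prior \eqn{P(y=+1)} of the unlabeled set.
#' @param m,n Sizes of the labeled and unlabeled sets.
#' @return Posterior probabilities in [0, 1].
#' @export
pu_convert <- function(p_l, alpha, m, n) {
  stopifnot(all(p_l >= 0 & p_l <= 1), alpha >= 0, alpha <= 1, m >= 1, n >= 1)
  out <- ifelse(p_l >= 1, 1, pmin(1, alpha * (n / m) * p_l / (1 - p_l)))
  pmax(out, 0)
}

#' Estimate the class prior of the unlabeled set
#'
#' `method = "given"` passes through a user-supplied value (e.g. an
#' externally estimated prior). `method = "elkan_noto_e1"` is the
#' mean-posterior-ratio baseline: \eqn{\hat\alpha =
#' \bar{p}_l(\mathrm{unlabeled}) / \bar{p}_l(\mathrm{labeled})}, clipped to
#' [0, 1]. More elaborate mixture-based estimators can be plugged in via
#' the same interface.
#'
#' @param labeled_scores,unlabeled_scores Calibrated non-traditional
#'   posteriors of the labeled / unlabeled items.
#' @param method `"elkan_noto_e1"` or `"given"`.
#' @param value Prior value when `method = "given"`.
#' @return The estimated class prior in [0, 1].
#' @export
estimate_class_prior <- function(labeled_scores, unlabeled_scores,
                                 method = c("elkan_noto_e1", "given"),
                                 value = NULL) {
  method <- match.arg(method)
  if (method == "given") {
    stopifnot(is.numeric(value), value >= 0, value <= 1)
    return(value)
  }
  if (!length(labeled_scores) || !length(unlabeled_scores))
    stop("score sets must be nonempty")
  ml <- mean(labeled_scores)
  if (ml <= 0) stop("labeled scores have zero mean; prior unidentifiable")
  min(1, max(0, mean(unlabeled_scores) / ml))
}

#' Estimate the class prior from raw score samples
#'
#' Convenience route for one-dimensional score data (e.g. the synthetic
#' Beta-mixture generator): fits a non-traditional labeled-vs-unlabeled
#' logistic classifier on the log-scale sufficient statistics
#' `log(s)` and `log(1 - s)` (natural for Beta-distributed scores),
#' producing calibrated \eqn{P(l=+1|s)}, and applies the
#' mean-posterior-ratio estimator of [estimate_class_prior()]. The ratio
#' is close to the true prior whenever the classifier's posterior nearly
#' vanishes on the background component.
#'
#' @param labeled_scores,unlabeled_scores Scores in [0, 1].
#' @return Estimated class prior in [0, 1].
#' @export
pu_prior_from_scores <- function(labeled_scores, unlabeled_scores) {
  if (!length(labeled_scores) || !length(unlabeled_scores))
    stop("score sets must be nonempty")
  s <- c(labeled_scores, unlabeled_scores)
  s <- pmin(pmax(s, 1e-12), 1 - 1e-12)
  y01 <- c(rep(1, length(labeled_scores)), rep(0, length(unlabeled_scores)))
  fit <- suppressWarnings(
    stats::glm(y01 ~ log(s) + log1p(-s), family = stats::binomial()))
  p_l <- stats::fitted(fit)
  estimate_class_prior(p_l[y01 == 1], p_l[y01 == 0])
}

#' Empirical frequency of the positive phenomenon in a data set
#'
#' The arithmetic mean of converted posteriors \eqn{P(y=+1|x)} over the
#' items: the model-based estimate of the fraction of positives.
#'
#' @param posteriors Converted posterior probabilities.
#' @return Their mean.
#' @export
empirical_frequency <- function(posteriors) {
  if (!length(posteriors)) stop("empty item set")
  stopifnot(all(posteriors >= 0 & posteriors <= 1))
  mean(posteriors)
}

#' Fit a positive-unlabeled kernel model
#'
#' The central fitting routine: trains the non-traditional labeled-vs-
#' unlabeled SVM on a precomputed kernel matrix, calibrates the decision
#' values with Platt's sigmoid, estimates (or accepts) the class prior and
#' stores everything needed to produce traditional posteriors
#' \eqn{P(y=+1|x)} for new items.
#'
#' @param K Kernel matrix over all items (labeled and unlabeled).
#' @param labeled Indices (or logical mask) of the labeled items; all
#'   labeled items are positives.
#' @param C Capacity parameter of the SVM (default 1).
#' @param prior Class prior of the unlabeled set, or `NULL` to estimate it
#'   with `prior_method`.
#' @param prior_method Prior estimator when `prior` is `NULL`
#'   (see [estimate_class_prior()]).
#' @param kernel_spec Optional kernel spec to record (list).
#' @return An object of class `pu_model`.
#' @export
pu_fit <- function(K, labeled, C = 1, prior = NULL,
                   prior_method = "elkan_noto_e1", kernel_spec = NULL) {
  nit <- nrow(K)
  if (is.logical(labeled)) labeled <- which(labeled)
  stopifnot(length(labeled) >= 1, length(labeled) < nit)
  y <- rep(-1, nit); y[labeled] <- 1
  svm <- train_nontraditional(K, y, C = C)
  sig <- platt_calibrate(svm$decision, y)
  p_l <- platt_apply(svm$decision, sig)
  alpha <- if (!is.null(prior)) {
    estimate_class_prior(method = "given", value = prior)
  } else {
    estimate_class_prior(p_l[y == 1], p_l[y == -1], method = prior_method)
  }
  m <- sum(y == 1); n <- sum(y == -1)
  structure(list(
    svm = svm, sigmoid = sig, alpha = alpha, m = m, n = n,
    labeled = labeled, kernel_spec = kernel_spec,
    p_l = p_l, posterior = pu_convert(p_l, alpha, m, n)
  ), class = "pu_model")
}

#' @export
print.pu_model <- function(x, ...) {
  cat(sprintf("<pu_model> m = %d labeled, n = %d unlabeled, C = %g\n",
              x$m, x$n, x$svm$C))
  cat(sprintf("  class prior alpha = %.4f; Platt (A, B) = (%.4f, %.4f)\n",
              x$alpha, x$sigmoid$A, x$sigmoid$B))
  cat(sprintf("  support vectors: %d\n", length(x$svm$sv_index)))
  invisible(x)
}

#' @export
summary.pu_model <- function(object, ...) {
  post_u <- object$posterior[-object$labeled]
  out <- list(
    m = object$m, n = object$n, alpha = object$alpha,
    sigmoid = object$sigmoid, n_sv = length(object$svm$sv_index),
    empirical_frequency_unlabeled = mean(post_u)
  )
  class(out) <- "summary.pu_model"
  out
}

#' @export
print.summary.pu_model <- function(x, ...) {
  cat(sprintf("PU kernel model: m = %d, n = %d\n", x$m, x$n))
  cat(sprintf("  class prior alpha:            %.4f\n", x$alpha))
  cat(sprintf("  Platt sigmoid (A, B):         (%.4f, %.4f)\n",
              x$sigmoid$A, x$sigmoid$B))
  cat(sprintf("  support vectors:              %d\n", x$n_sv))
  cat(sprintf("  mean posterior on unlabeled:  %.4f\n",
              x$empirical_frequency_unlabeled))
  invisible(x)
}

#' @export
coef.pu_model <- function(object, ...) {
  stats::setNames(object$svm$sv_coef,
                  paste0("item", object$svm$sv_index))
}

#' Predict posteriors from a fitted PU model
#'
#' @param object A `pu_model`.
#' @param K_new Matrix of kernel values between new items (rows) and the
#'   training items (columns, in training order). Omit to return fitted
#'   values for the training items.
#' @param type `"posterior"` for the converted \eqn{P(y=+1|x)},
#'   `"calibrated"` for the non-traditional \eqn{P(l=+1|x)}, `"decision"`
#'   for raw SVM scores.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pu_model <- function(object, K_new = NULL,
                             type = c("posterior", "calibrated", "decision"),
                             ...) {
  type <- match.arg(type)
  if (is.null(K_new)) {
    dec <- object$svm$decision
  } else {
    dec <- as.vector(K_new[, object$svm$sv_index, drop = FALSE] %*%
                       object$svm$sv_coef - object$svm$b)
  }
  if (type == "decision") return(dec)
  p_l <- platt_apply(dec, object$sigmoid)
  if (type == "calibrated") return(p_l)
  pu_convert(p_l, object$alpha, object$m, object$n)
}

#' Save / load a PU model bundle as plain-text files
#'
#' A directory with `kernel_spec.json`, `coefficients.tsv` (support-vector
#' indices and coefficients plus the offset), `platt.json` and
#' `prior.json`.
#'
#' @param model A `pu_model`.
#' @param dir Directory path.
#' @return `save_pu_model` the directory, invisibly; `load_pu_model` a
#'   `pu_model` (without training decision values).
#' @export
save_pu_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    if (is.null(model$kernel_spec)) list() else model$kernel_spec,
    file.path(dir, "kernel_spec.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(sv_index = model$svm$sv_index, coef = model$svm$sv_coef),
    file.path(dir, "coefficients.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(list(A = model$sigmoid$A, B = model$sigmoid$B,
                            b = model$svm$b, C = model$svm$C),
                       file.path(dir, "platt.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(list(alpha = model$alpha, m = model$m, n = model$n),
                       file.path(dir, "prior.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_pu_model
#' @export
load_pu_model <- function(dir) {
  spec <- jsonlite::fromJSON(file.path(dir, "kernel_spec.json"))
  co <- utils::read.delim(file.path(dir, "coefficients.tsv"))
  pl <- jsonlite::fromJSON(file.path(dir, "platt.json"))
  pr <- jsonlite::fromJSON(file.path(dir, "prior.json"))
  structure(list(
    svm = list(decision = NULL, sv_index = co$sv_index, sv_coef = co$coef,
               b = pl$b, C = pl$C),
    sigmoid = list(A = pl$A, B = pl$B),
    alpha = pr$alpha, m = pr$m, n = pr$n, labeled = NULL,
    kernel_spec = if (length(spec)) spec else NULL,
    p_l = NULL, posterior = NULL
  ), class = "pu_model")
}
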