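# End-to-end functional-site predictor: graphlet profiles + PU kernel model.

#' Fit a functional-site predictor on residue microenvironments
#'
#' Convenience wrapper over the full training path: graphlet profiles of
#' the environments under a kernel spec, normalized kernel matrix, and the
#' positive-unlabeled fit ([pu_fit()]). The returned object can score new
#' microenvironments directly.
#'
#' @param envs Named list of `rooted_env` items (positives and unlabeled).
#' @param labeled Indices (or logical mask) of the labeled positives.
#' @param N Maximum graphlet order (default 4).
#' @param m Edit budget (default 0, the standard graphlet kernel).
#' @param mode Edit mode (default `"label_sub"`).
#' @param C SVM capacity (default 1).
#' @param prior Class prior, or `NULL` to estimate.
#' @param prior_method Prior estimator when `prior` is `NULL`.
#' @return Object of class `site_predictor`.
#' @export
fit_site_predictor <- function(envs, labeled, N = 4, m = 0,
                               mode = "label_sub", C = 1, prior = NULL,
                               prior_method = "elkan_noto_e1") {
  stopifnot(length(envs) >= 2)
  profs <- lapply(envs, function(e)
    smooth_profile(count_graphlets(e, N = N), m = m, mode = mode))
  K <- kernel_matrix(profs, normalize = TRUE)
  spec <- attr(K, "spec")
  pu <- pu_fit(K, labeled, C = C, prior = prior,
               prior_method = prior_method, kernel_spec = spec)
  structure(list(pu = pu, profiles = profs, spec = spec),
            class = "site_predictor")
}

#' @export
print.site_predictor <- function(x, ...) {
  cat(sprintf("<site_predictor> N = %d, m = %d, mode = %s, |Sigma| = %d\n",
              x$spec$N, x$spec$m, x$spec$mode, length(x$spec$alphabet)))
  print(x$pu)
  invisible(x)
}

#' Predict functional posteriors for residue microenvironments
#'
#' @param object A `site_predictor`.
#' @param envs A `rooted_env` or list of them; omit for fitted values.
#' @param type Passed to [predict.pu_model()].
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.site_predictor <- function(object, envs = NULL,
                                   type = "posterior", ...) {
  if (is.null(envs)) return(predict(object$pu, type = type))
  if (inherits(envs, "rooted_env")) envs <- list(envs)
  profs <- lapply(envs, function(e)
    smooth_profile(count_graphlets(e, N = object$spec$N),
                   m = object$spec$m, mode = object$spec$mode))
  Kx <- kernel_cross(profs, object$profiles,
                     normalize = isTRUE(object$spec$normalized))
  predict(object$pu, K_new = Kx, type = type)
}
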