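# Loss/gain-of-function probability calculus: products of wild-type and
# mutant functional posteriors, combined over the stability strata and over
# multiple function types.

.check_prob <- function(..., .names = NULL) {
  vals <- list(...)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop("probability argument out of [0, 1]",
           if (!is.null(.names)) paste0(": ", .names[i]) else "")
  }
  invisible(TRUE)
}

# a * (1 - b), in log space when b is very close to 1 to avoid cancellation
.prod_1m <- function(a, b) {
  ifelse(a == 0, 0,
         ifelse(b > 0.999, exp(log(a) + log1p(-b)), a * (1 - b)))
}

#' Loss of function probability, stability unchanged
#'
#' \eqn{P(\mathrm{loss\ of\ } f | \bar S, x) = P(f|x'_{wt}) (1 - P(f|x'_{mt}))}:
#' the residue was functional in the wild type and is not in the mutant.
#'
#' @param p_wt,p_mt Posterior probabilities that the wild-type / mutant
#'   residue is functional, in [0, 1].
#' @return Probability in [0, 1]. Vectorized.
#' @export
loss_given_stable <- function(p_wt, p_mt) {
  .check_prob(p_wt, p_mt, .names = c("p_wt", "p_mt"))
  .prod_1m(p_wt, p_mt)
}

#' Gain of function probability, stability unchanged
#'
#' \eqn{P(\mathrm{gain\ of\ } f | \bar S, x) = (1 - P(f|x'_{wt})) P(f|x'_{mt})}.
#'
#' @inheritParams loss_given_stable
#' @return Probability in [0, 1]. Vectorized.
#' @export
gain_given_stable <- function(p_wt, p_mt) {
  .check_prob(p_wt, p_mt, .names = c("p_wt", "p_mt"))
  .prod_1m(p_mt, p_wt)
}

#' Marginal loss of function probability
#'
#' Marginalizes the two stability strata:
#' \eqn{P(\mathrm{loss}|x) = P(\mathrm{loss}|S,x) P(S|x) +
#' P(\mathrm{loss}|\bar S,x) P(\bar S|x)} with the approximation
#' \eqn{P(\mathrm{loss}|S,x) \approx P(f|x'_{wt})} (a large stability
#' disruption abolishes the residue's function, so the loss probability is
#' the probability it was functional in the first place).
#'
#' @inheritParams loss_given_stable
#' @param p_S Posterior probability of significant stability disruption.
#' @return Probability in [0, 1]. Vectorized.
#' @export
loss_marginal <- function(p_wt, p_mt, p_S) {
  .check_prob(p_wt, p_mt, p_S, .names = c("p_wt", "p_mt", "p_S"))
  p_wt * p_S + .prod_1m(loss_given_stable(p_wt, p_mt), p_S)
}

#' Marginal gain of function probability
#'
#' Under the approximation \eqn{P(\mathrm{gain}|S,x) \approx 0} (a large
#' stability disruption essentially never creates a functional residue)
#' only the stable stratum contributes:
#' \eqn{P(\mathrm{gain}|x) = (1 - P(f|x'_{wt})) P(f|x'_{mt}) (1 - P(S|x))}.
#'
#' @inheritParams loss_marginal
#' @return Probability in [0, 1]. Vectorized.
#' @export
gain_marginal <- function(p_wt, p_mt, p_S) {
  .check_prob(p_wt, p_mt, p_S, .names = c("p_wt", "p_mt", "p_S"))
  .prod_1m(gain_given_stable(p_wt, p_mt), p_S)
}

#' Combine per-function probabilities: independence model
#'
#' Probability that at least one function in the set is altered, treating
#' functions as independent: \eqn{1 - \prod_f (1 - v_f)}. Tends to
#' overestimate when functions are correlated.
#'
#' @param values Numeric vector of per-function probabilities (nonempty).
#' @return Probability in [0, 1].
#' @export
combine_independence <- function(values) {
  if (!length(values)) stop("empty function set")
  .check_prob(values, .names = "values")
  -expm1(sum(log1p(-values)))
}

#' Combine per-function probabilities: max model
#'
#' The conservative alternative to [combine_independence()]: the maximum
#' per-function probability. Always bounded above by the independence
#' model.
#'
#' @inheritParams combine_independence
#' @return Probability in [0, 1].
#' @export
combine_max <- function(values) {
  if (!length(values)) stop("empty function set")
  .check_prob(values, .names = "values")
  max(values)
}

#' All six mechanism probabilities from a posterior pair
#'
#' Computes, for one function, the six prediction outputs: loss and gain
#' given no stability disruption, their joint versions with the stable
#' stratum, and their marginals.
#'
#' @inheritParams loss_marginal
#' @return Named numeric vector: `loss_stable`, `loss_joint`,
#'   `loss_marginal`, `gain_stable`, `gain_joint`, `gain_marginal`.
#' @export
mechanism_probabilities <- function(p_wt, p_mt, p_S) {
  ls <- loss_given_stable(p_wt, p_mt)
  gs <- gain_given_stable(p_wt, p_mt)
  c(loss_stable = ls,
    loss_joint = .prod_1m(ls, p_S),
    loss_marginal = loss_marginal(p_wt, p_mt, p_S),
    gain_stable = gs,
    gain_joint = .prod_1m(gs, p_S),
    gain_marginal = gain_marginal(p_wt, p_mt, p_S))
}

#' Score a mapped variant against a set of functional-site predictors
#'
#' Applies each per-function site predictor to the wild-type residue
#' microenvironment and to the mutant environment (the same graph with
#' only the root's label replaced; the mutant root inherits the wild
#' type's conservation class), then evaluates the loss/gain calculus per
#' function and the two combination models per category and overall.
#' PTM residue restrictions make loss infeasible when the wild-type
#' residue is not modifiable and gain infeasible when the mutant residue
#' is not; infeasible events are exact zeros with a reason tag.
#'
#' @param env Wild-type `rooted_env` of the variant residue.
#' @param mt_aa One-letter mutant amino acid.
#' @param models Named list of fitted site predictors
#'   (see [fit_site_predictor()]), names being function ids.
#' @param p_S Posterior probability of stability disruption for this
#'   variant.
#' @param registry Function registry.
#' @return Object of class `mechanism_scores`: data.frame `per_function`
#'   (function, p_wt, p_mt, the six probabilities, reason), data.frame
#'   `combined` (set, model, loss, gain), and the inputs.
#' @export
score_variant <- function(env, mt_aa, models, p_S,
                          registry = function_registry()) {
  stopifnot(inherits(env, "rooted_env"), mt_aa %in% aa_alphabet())
  .check_prob(p_S, .names = "p_S")
  wt_aa <- env$graph$vertices$aa[env$root]
  if (wt_aa == mt_aa) stop("mutant amino acid equals wild type")
  mt_env <- mutate_root(env, mt_aa)

  rows <- list()
  for (fun in names(models)) {
    restr <- .registry_restriction(fun, registry)
    p_wt <- predict(models[[fun]], env)
    p_mt <- predict(models[[fun]], mt_env)
    reason <- NA_character_
    if (length(restr)) {
      if (!(wt_aa %in% restr)) { p_wt <- 0; reason <- "wt residue not modifiable" }
      if (!(mt_aa %in% restr)) {
        p_mt <- 0
        reason <- if (is.na(reason)) "mt residue not modifiable"
                  else "wt and mt residues not modifiable"
      }
    }
    pr <- mechanism_probabilities(p_wt, p_mt, p_S)
    rows[[fun]] <- data.frame(fun = fun, p_wt = p_wt, p_mt = p_mt,
                              t(pr), reason = reason,
                              stringsAsFactors = FALSE)
  }
  per_fun <- do.call(rbind, rows)
  rownames(per_fun) <- NULL

  sets <- c(list(all = per_fun$fun),
            split(per_fun$fun,
                  registry$category[match(per_fun$fun, registry$id)]))
  comb <- do.call(rbind, lapply(names(sets), function(s) {
    idx <- match(sets[[s]], per_fun$fun)
    data.frame(
      set = s,
      model = c("independence", "max"),
      loss_stable = c(combine_independence(per_fun$loss_stable[idx]),
                      combine_max(per_fun$loss_stable[idx])),
      loss_marginal = c(combine_independence(per_fun$loss_marginal[idx]),
                        combine_max(per_fun$loss_marginal[idx])),
      gain_stable = c(combine_independence(per_fun$gain_stable[idx]),
                      combine_max(per_fun$gain_stable[idx])),
      gain_marginal = c(combine_independence(per_fun$gain_marginal[idx]),
                        combine_max(per_fun$gain_marginal[idx])),
      stringsAsFactors = FALSE)
  }))

  structure(list(per_function = per_fun, combined = comb,
                 wt_aa = wt_aa, mt_aa = mt_aa, p_S = p_S),
            class = "mechanism_scores")
}

#' @export
print.mechanism_scores <- function(x, digits = 4, ...) {
  cat(sprintf("<mechanism_scores> %s -> %s, P(S|x) = %.3g\n",
              x$wt_aa, x$mt_aa, x$p_S))
  df <- x$per_function
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Substitute the root residue of a microenvironment
#'
#' Returns the mutant environment: identical graph topology, with only the
#' root vertex's amino acid (and its label, preserving any conservation
#' case) replaced.
#'
#' @param env A `rooted_env`.
#' @param mt_aa One-letter mutant amino acid.
#' @return A `rooted_env`.
#' @export
mutate_root <- function(env, mt_aa) {
  stopifnot(inherits(env, "rooted_env"), mt_aa %in% aa_alphabet())
  old_label <- env$graph$vertices$label[env$root]
  conserved <- old_label %in% aa_alphabet()  # uppercase = conserved class
  env$graph$vertices$aa[env$root] <- mt_aa
  env$graph$vertices$label[env$root] <-
    if (length(env$graph$alphabet) == 40 && !conserved) tolower(mt_aa) else mt_aa
  env
}

#' Write mechanism scores as TSV
#'
#' One row per (variant, function) with the six probabilities, plus the
#' combined-model rows tagged in the `fun` column.
#'
#' @param scores A `mechanism_scores` object or list of them (named by
#'   variant id).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mechanism_tsv <- function(scores, path) {
  if (inherits(scores, "mechanism_scores")) scores <- list(variant = scores)
  rows <- lapply(names(scores), function(vid) {
    s <- scores[[vid]]
    pf <- cbind(variant = vid, s$per_function)
    cb <- data.frame(variant = vid,
                     fun = paste(s$combined$set, s$combined$model, sep = ":"),
                     p_wt = NA, p_mt = NA,
                     loss_stable = s$combined$loss_stable,
                     loss_joint = NA,
                     loss_marginal = s$combined$loss_marginal,
                     gain_stable = s$combined$gain_stable,
                     gain_joint = NA,
                     gain_marginal = s$combined$gain_marginal,
                     reason = NA, stringsAsFactors = FALSE)
    rbind(pf, cb)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
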