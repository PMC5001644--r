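# Function-type registry, cross-validation plans, evaluation metrics,
# training-set assembly and the model-selection grid.

#' Registry of residue function types
#'
#' The thirty site types handled by the framework: the stability stratum
#' plus twenty-nine residue functions grouped into six categories (metal
#' binding, PTMs, catalytic activity, macromolecular binding, ligand
#' binding, allosteric regulation). PTM types carry residue restrictions:
#' N-linked glycosylation applies to asparagine only, phosphorylation to
#' serine/threonine/tyrosine.
#'
#' @return data.frame with columns `id`, `category`, `restriction`
#'   (comma-separated one-letter codes, `""` for none).
#' @export
function_registry <- function() {
  reg <- rbind(
    data.frame(id = "S", category = "stability", restriction = ""),
    data.frame(id = c("Ca", "Cd", "Co", "Cu", "Fe", "K", "Mg", "Mn", "Na",
                      "Ni", "Zn"),
               category = "metal", restriction = ""),
    data.frame(id = c("Nglyco", "Phos"), category = "PTM",
               restriction = c("N", "S,T,Y")),
    data.frame(id = "Cat", category = "catalytic", restriction = ""),
    data.frame(id = c("DNA", "RNA", "PPI", "Hotspot"),
               category = "macromolecular", restriction = ""),
    data.frame(id = c("ADP", "ATP", "FAD", "FMN", "GDP", "GTP", "HEM",
                      "NAD", "PLP", "UDP"),
               category = "ligand", restriction = ""),
    data.frame(id = "Allo", category = "allosteric", restriction = "")
  )
  rownames(reg) <- NULL
  reg
}

.registry_restriction <- function(fun, registry = function_registry()) {
  r <- registry$restriction[match(fun, registry$id)]
  if (is.na(r)) stop("unknown function type: ", fun)
  if (r == "") character() else strsplit(r, ",", fixed = TRUE)[[1]]
}

#' Per-chain cross-validation plan
#'
#' Partitions protein chains into `k` near-balanced folds (sizes differing
#' by at most one) so that all residues of a chain share a fold;
#' deterministic for a given seed.
#'
#' @param chains Character vector of chain identifiers (unique).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Named integer vector: fold index (1..k) per chain.
#' @export
make_cv_plan <- function(chains, k = 10, seed = 1) {
  chains <- unique(chains)
  if (length(chains) < k)
    stop("fewer chains (", length(chains), ") than folds (", k, ")")
  rng <- .with_seed(seed, sample(length(chains)))
  folds <- rep_len(seq_len(k), length(chains))
  stats::setNames(folds[order(rng)], chains)
}

# evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Classification metrics at 99% specificity
#'
#' AUC by the rank statistic with tie-averaging, plus sensitivity and the
#' Matthews correlation coefficient at the decision threshold chosen as
#' the smallest score achieving specificity of at least `sp_target` over
#' the negative (or unlabeled-as-negative) items; predictions are
#' strictly-greater-than-threshold.
#'
#' @param scores Numeric prediction scores.
#' @param labels Vector in \{+1, -1\} or logical; both classes required.
#' @param sp_target Target specificity (default 0.99).
#' @return List with `auc`, `mcc`, `sn`, `sp`, `threshold`.
#' @export
evaluate_scores <- function(scores, labels, sp_target = 0.99) {
  if (is.logical(labels)) labels <- ifelse(labels, 1, -1)
  stopifnot(length(scores) == length(labels), all(labels %in% c(-1, 1)))
  pos <- labels == 1
  if (!any(pos) || all(pos)) stop("both classes must be present")
  npos <- sum(pos); nneg <- sum(!pos)

  r <- rank(scores)
  auc <- (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)

  neg_sorted <- sort(scores[!pos])
  thr <- neg_sorted[ceiling(sp_target * nneg)]
  pred <- scores > thr
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  sn <- tp / npos
  sp <- tn / nneg
  den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
  list(auc = auc, mcc = mcc, sn = sn, sp = sp, threshold = thr)
}

#' Assemble a positive-unlabeled training set for a function type
#'
#' Draws a deterministic random sample of unlabeled residues from a pool,
#' honoring the function's residue restriction (e.g. only Ser/Thr/Tyr for
#' phosphorylation) and excluding the positives from the draw.
#'
#' @param fun Function type id (see [function_registry()]).
#' @param positives Character vector of positive residue ids.
#' @param pool data.frame of candidate unlabeled residues with columns
#'   `id` and `aa`.
#' @param size Number of unlabeled residues to sample (default 10000).
#' @param seed Integer seed.
#' @param registry Function registry.
#' @return List with `labeled` (positive ids) and `unlabeled` (sampled
#'   ids).
#' @export
assemble_training_set <- function(fun, positives, pool, size = 10000,
                                  seed = 1, registry = function_registry()) {
  restr <- .registry_restriction(fun, registry)
  cand <- pool[!(pool$id %in% positives), , drop = FALSE]
  if (length(restr)) cand <- cand[cand$aa %in% restr, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("residue restriction for ", fun, " empties the unlabeled pool")
  if (nrow(cand) < size)
    stop("unlabeled pool (", nrow(cand), ") smaller than requested sample (",
         size, ")")
  take <- .with_seed(seed, sample(nrow(cand), size))
  list(labeled = positives, unlabeled = cand$id[sort(take)])
}

# mean per-chain CV AUC of a PU fit on a precomputed kernel matrix
.cv_auc <- function(K, labeled_idx, chain_of, plan, C = 1) {
  folds <- sort(unique(plan))
  aucs <- numeric(0)
  y <- rep(-1, nrow(K)); y[labeled_idx] <- 1
  for (f in folds) {
    test <- which(plan[chain_of] == f)
    train <- setdiff(seq_len(nrow(K)), test)
    if (length(unique(y[train])) < 2 || length(unique(y[test])) < 2) next
    svm <- train_nontraditional(K[train, train, drop = FALSE], y[train], C = C)
    dec <- as.vector(K[test, train, drop = FALSE][, svm$sv_index, drop = FALSE] %*%
                       svm$sv_coef - svm$b)
    aucs <- c(aucs, evaluate_scores(dec, y[test])$auc)
  }
  if (!length(aucs)) NA_real_ else mean(aucs)
}

#' Model-selection grid over kernel specifications
#'
#' Evaluates each kernel specification (alphabet size, edit budget m,
#' maximum graphlet order N, edit mode) by mean per-chain cross-validated
#' AUC of the labeled-vs-unlabeled fit and returns the best; ties are
#' broken toward smaller (N, m, |Sigma|) for parsimony.
#'
#' @param envs Named list of `rooted_env` microenvironments (labels on the
#'   20-letter alphabet).
#' @param labeled Indices of labeled (positive) items in `envs`.
#' @param chain_of Chain id per item (for the per-chain CV plan).
#' @param conservation Named per-residue conservation scores (required for
#'   the 40-symbol alphabet rows of the grid) or `NULL` to restrict the
#'   grid to 20 symbols.
#' @param grid data.frame with columns `sigma` (20/40), `m`, `N`, `mode`;
#'   default: the full search grid.
#' @param k,seed CV folds and seed.
#' @param C SVM capacity.
#' @return List with `best` (row of the grid), `results` (grid with an
#'   `auc` column), and `kernel` (the kernel matrix of the best spec).
#' @export
grid_search <- function(envs, labeled, chain_of, conservation = NULL,
                        grid = NULL, k = 10, seed = 1, C = 1) {
  if (is.null(grid)) {
    grid <- expand.grid(sigma = if (is.null(conservation)) 20 else c(20, 40),
                        m = c(0, 1), N = c(4, 5),
                        mode = c("full", "label_sub", "edge_indel"),
                        stringsAsFactors = FALSE)
    grid <- grid[!(grid$m == 0 & grid$mode != "full"), , drop = FALSE]
  }
  stopifnot(length(labeled) >= 1, length(chain_of) == length(envs))
  plan <- make_cv_plan(unique(chain_of), k = k, seed = seed)

  pivot <- if (!is.null(conservation)) stats::median(conservation) else NA
  grid$auc <- NA_real_
  kernels <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    es <- envs
    if (g$sigma == 40) {
      es <- lapply(es, split_alphabet_by_conservation,
                   scores = conservation, pivot = pivot)
    }
    profs <- lapply(es, function(e)
      smooth_profile(count_graphlets(e, N = g$N), m = g$m, mode = g$mode))
    K <- kernel_matrix(profs, normalize = TRUE)
    kernels[[i]] <- K
    grid$auc[i] <- .cv_auc(K, labeled, chain_of, plan, C = C)
  }
  ord <- order(-round(grid$auc, 10), grid$N, grid$m, grid$sigma)
  best <- ord[1]
  list(best = grid[best, , drop = FALSE], results = grid,
       kernel = kernels[[best]])
}
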