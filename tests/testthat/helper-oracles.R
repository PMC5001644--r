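# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals beyond the
# public canonical-id function (itself checked against permutation-level
# isomorphism testing below).

# adjacency matrix of a rooted_env / contact_graph
oracle_adjmat <- function(g) {
  if (inherits(g, "rooted_env")) g <- g$graph
  nv <- nrow(g$vertices)
  A <- matrix(FALSE, nv, nv)
  e <- g$edges
  if (nrow(e)) {
    A[e] <- TRUE
    A[e[, c(2, 1), drop = FALSE]] <- TRUE
  }
  A
}

oracle_connected_subset <- function(A, subset) {
  if (length(subset) == 1) return(TRUE)
  S <- A[subset, subset, drop = FALSE]
  seen <- c(1L)
  repeat {
    nb <- which(apply(S[, seen, drop = FALSE], 1, any))
    new <- setdiff(nb, seen)
    if (!length(new)) break
    seen <- c(seen, new)
  }
  length(seen) == length(subset)
}

# exhaustive enumeration of connected induced root-containing subgraphs
oracle_count_graphlets <- function(env, N) {
  g <- env$graph
  A <- oracle_adjmat(g)
  nv <- nrow(g$vertices)
  root <- env$root
  others <- setdiff(seq_len(nv), root)
  counts <- list()
  for (n in seq_len(min(N, nv))) {
    subs <- if (n == 1) matrix(integer(), nrow = 0, ncol = 0) else NULL
    combos <- if (n == 1) list(integer()) else
      asplit(utils::combn(others, n - 1), 2)
    for (extra in combos) {
      subset <- c(root, as.integer(extra))
      if (!oracle_connected_subset(A, subset)) next
      labs <- g$vertices$label[subset]
      S <- A[subset, subset, drop = FALSE]
      ed <- which(S & upper.tri(S), arr.ind = TRUE)
      id <- canonical_graphlet(labs, ed, g$alphabet)
      counts[[id]] <- (counts[[id]] %||% 0) + 1
    }
  }
  unlist(counts)[order(names(counts))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rooted, label-preserving isomorphism by trying every root-fixing bijection
oracle_rooted_isomorphic <- function(lab1, ed1, lab2, ed2) {
  n <- length(lab1)
  if (n != length(lab2)) return(FALSE)
  A1 <- matrix(FALSE, n, n); A2 <- matrix(FALSE, n, n)
  if (length(ed1)) { ed1 <- matrix(ed1, ncol = 2); A1[ed1] <- TRUE; A1[ed1[, 2:1, drop = FALSE]] <- TRUE }
  if (length(ed2)) { ed2 <- matrix(ed2, ncol = 2); A2[ed2] <- TRUE; A2[ed2[, 2:1, drop = FALSE]] <- TRUE }
  perms <- if (n == 1) list(1L) else {
    base <- .perm_all(seq.int(2L, n))
    lapply(seq_len(nrow(base)), function(i) c(1L, base[i, ]))
  }
  for (p in perms) {
    if (!all(lab2 == lab1[p])) next
    ok <- TRUE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (A2[i, j] != A1[p[i], p[j]]) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

.perm_all <- function(x) {
  if (length(x) <= 1) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x)) out <- rbind(out, cbind(x[i], .perm_all(x[-i])))
  out
}

# BFS ball by hand
oracle_bfs_ball <- function(g, root, level) {
  A <- oracle_adjmat(g)
  dist <- rep(Inf, nrow(A)); dist[root] <- 0
  frontier <- root
  d <- 0
  while (length(frontier) && d < level) {
    nxt <- setdiff(which(apply(A[, frontier, drop = FALSE], 1, any)),
                   which(is.finite(dist)))
    dist[nxt] <- d + 1
    frontier <- nxt
    d <- d + 1
  }
  sort(which(is.finite(dist)))
}

# AUC by exhaustive pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == -1]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# one-tailed (greater) Fisher p by full hypergeometric enumeration
oracle_fisher_greater <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(ks, function(k)
    choose(r1, k) * choose(n - r1, c1 - k) / choose(n, c1), 0)
  sum(probs[ks >= a])
}

# random rooted environment fixture (uniform labels, spanning tree + extras)
random_test_env <- function(size, alphabet = c("A", "C", "D"), p_edge = 0.3,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- sample(alphabet, size, replace = TRUE)
  edges <- NULL
  for (v in seq_len(size)[-1]) edges <- rbind(edges, c(sample(v - 1, 1), v))
  if (size >= 3) {
    pairs <- t(utils::combn(size, 2))
    extra <- pairs[stats::runif(nrow(pairs)) < p_edge, , drop = FALSE]
    edges <- unique(rbind(edges, extra))
  }
  make_env(labels, edges, alphabet = alphabet)
}

# minimal hand-written PDB fixture builder
pdb_line <- function(record, serial, elety, resid, chain, resno, x, y, z,
                     occ = 1, alt = " ", element = substr(elety, 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", elety), alt, resid, chain, resno,
          x, y, z, occ, 0, element)
}
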