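# Vertex-labeled rooted graphlets: canonical ids, exact enumeration in
# rooted microenvironments, and edit-distance neighborhoods.
#
# A graphlet is held internally as (n, lab, mask): n vertices with the root
# at position 1, integer labels `lab` indexing the vertex alphabet, and an
# edge bitmask `mask` over the vertex pairs of `combn(n, 2)` in column
# order. Canonical form minimizes (lab, mask) lexicographically over all
# root-fixing permutations (at most 4! = 24 for n = 5).

.GRAPHLET_MAX <- 5L

# package-level caches: pair tables, root-fixing permutations, neighborhoods
.graphlet_env <- new.env(parent = emptyenv())

# vertex pairs in nested order -- (1,2), (1,3), (2,3), (1,4), ... -- so the
# pair positions of an n-vertex graphlet are a prefix of those of an
# (n+1)-vertex graphlet (vertex insertion keeps existing edge bits in place)
.pairs_tab <- function(n) {
  key <- paste0("pairs", n)
  if (is.null(.graphlet_env[[key]])) {
    pr <- matrix(integer(), ncol = 2)
    if (n >= 2L) {
      for (j in 2:n) pr <- rbind(pr, cbind(seq_len(j - 1L), j))
    }
    .graphlet_env[[key]] <- pr
  }
  .graphlet_env[[key]]
}

.root_perms <- function(n) {
  key <- paste0("perm", n)
  if (is.null(.graphlet_env[[key]])) {
    if (n == 1L) {
      p <- matrix(1L, 1, 1)
    } else {
      rest <- .permutations(seq.int(2L, n))
      p <- cbind(1L, rest)
    }
    .graphlet_env[[key]] <- p
  }
  .graphlet_env[[key]]
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(matrix(x, nrow = 1L))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], .permutations(x[-i])))
  out
}

# n x n matrix giving the combn pair position of each vertex pair
.pair_index <- function(n) {
  key <- paste0("pidx", n)
  if (is.null(.graphlet_env[[key]])) {
    pm <- matrix(0L, n, n)
    pt <- .pairs_tab(n)
    for (p in seq_len(nrow(pt)))
      pm[pt[p, 1], pt[p, 2]] <- pm[pt[p, 2], pt[p, 1]] <- p
    .graphlet_env[[key]] <- pm
  }
  .graphlet_env[[key]]
}

# per-permutation remapping of pair positions (old pair pos -> new pair pos)
.perm_pair_maps <- function(n) {
  key <- paste0("ppm", n)
  if (is.null(.graphlet_env[[key]])) {
    perms <- .root_perms(n)
    pt <- .pairs_tab(n)
    pm <- .pair_index(n)
    maps <- vector("list", nrow(perms))
    for (r in seq_len(nrow(perms))) {
      inv <- integer(n); inv[perms[r, ]] <- seq_len(n)
      maps[[r]] <- vapply(seq_len(nrow(pt)), function(p)
        pm[inv[pt[p, 1]], inv[pt[p, 2]]], 0L)
    }
    .graphlet_env[[key]] <- maps
  }
  .graphlet_env[[key]]
}

# edge bitmask after applying permutation `perm` (new position -> old vertex)
.permute_mask <- function(n, mask, perm) {
  if (n < 2L || mask == 0) return(mask)
  pm <- .pair_index(n)
  pt <- .pairs_tab(n)
  inv <- integer(n); inv[perm] <- seq_len(n)   # old vertex -> new position
  new_mask <- 0
  for (p in seq_len(nrow(pt))) {
    if (bitwAnd(mask, bitwShiftL(1L, p - 1L)) != 0L)
      new_mask <- new_mask +
        bitwShiftL(1L, pm[inv[pt[p, 1]], inv[pt[p, 2]]] - 1L)
  }
  new_mask
}

.mask_connected <- function(n, mask) {
  if (n == 1L) return(TRUE)
  pt <- .pairs_tab(n)
  adj <- matrix(FALSE, n, n)
  for (p in seq_len(nrow(pt))) {
    if (bitwAnd(mask, bitwShiftL(1L, p - 1L)) != 0L)
      adj[pt[p, 1], pt[p, 2]] <- adj[pt[p, 2], pt[p, 1]] <- TRUE
  }
  seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nxt <- which(apply(adj[, frontier, drop = FALSE], 1, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

.mask_degrees <- function(n, mask) {
  deg <- integer(n)
  if (n < 2L) return(deg)
  pt <- .pairs_tab(n)
  for (p in seq_len(nrow(pt))) {
    if (bitwAnd(mask, bitwShiftL(1L, p - 1L)) != 0L) {
      deg[pt[p, 1]] <- deg[pt[p, 1]] + 1L
      deg[pt[p, 2]] <- deg[pt[p, 2]] + 1L
    }
  }
  deg
}

# canonical (lab, mask) over root-fixing permutations; returns list(lab, mask)
.canon_form <- function(n, lab, mask, nsigma) {
  if (n == 1L) return(list(lab = lab, mask = 0))
  perms <- .root_perms(n)
  maps <- .perm_pair_maps(n)
  base <- nsigma + 1
  bits <- if (mask > 0) which(bitwAnd(as.integer(mask),
                                      bitwShiftL(1L, seq_len(10L) - 1L)) != 0L)
          else integer()
  pw <- base^seq.int(n, 1) * 1024
  best_key <- Inf; best <- NULL
  for (r in seq_len(nrow(perms))) {
    lab2 <- lab[perms[r, ]]
    mask2 <- sum(2^(maps[[r]][bits] - 1L))
    key <- sum(lab2 * pw) + mask2
    if (key < best_key) { best_key <- key; best <- list(lab = lab2, mask = mask2) }
  }
  best
}

.graphlet_id <- function(n, lab, mask, alphabet) {
  paste0(n, "|", paste(alphabet[lab], collapse = ","), "|", mask)
}

.decode_id <- function(id, alphabet) {
  parts <- strsplit(id, "|", fixed = TRUE)[[1]]
  n <- as.integer(parts[1])
  lab <- match(strsplit(parts[2], ",", fixed = TRUE)[[1]], alphabet)
  if (anyNA(lab)) stop("graphlet id labels not in alphabet: ", id)
  list(n = n, lab = lab, mask = as.numeric(parts[3]))
}

#' Canonical identifier of a rooted labeled graphlet
#'
#' Two rooted vertex-labeled graphs receive the same identifier exactly
#' when there is a root-preserving, label-preserving isomorphism between
#' them. Canonicalization fixes the root at position one and minimizes the
#' (label vector, edge bitmask) pair over all permutations of the
#' remaining vertices.
#'
#' @param labels Character vector of vertex labels, the root first.
#' @param edges Two-column matrix of vertex indices (may have zero rows for
#'   the 1-graphlet).
#' @param alphabet Vertex alphabet the labels are drawn from.
#' @return A single string identifier of the form `"n|labels|mask"`.
#' @export
canonical_graphlet <- function(labels, edges, alphabet = aa_alphabet()) {
  n <- length(labels)
  if (n < 1L || n > .GRAPHLET_MAX)
    stop("graphlets must have between 1 and ", .GRAPHLET_MAX, " vertices")
  lab <- match(labels, alphabet)
  if (anyNA(lab)) stop("labels outside alphabet: ",
                       paste(labels[is.na(lab)], collapse = ", "))
  edges <- matrix(as.integer(edges), ncol = 2)
  mask <- 0
  if (nrow(edges)) {
    pt <- .pairs_tab(n)
    for (r in seq_len(nrow(edges))) {
      a <- min(edges[r, ]); b <- max(edges[r, ])
      if (a == b) stop("self-loops are not allowed")
      p <- which(pt[, 1] == a & pt[, 2] == b)
      if (!length(p)) stop("edge endpoint out of range")
      mask <- bitwOr(as.integer(mask), bitwShiftL(1L, p - 1L))
    }
  }
  if (!.mask_connected(n, mask)) stop("graphlet must be connected")
  cf <- .canon_form(n, lab, mask, length(alphabet))
  .graphlet_id(n, cf$lab, cf$mask, alphabet)
}

#' Count rooted labeled graphlets in a residue microenvironment
#'
#' Exactly enumerates every connected induced subgraph of the environment
#' that contains the root and has at most `N` vertices, counting each under
#' its canonical rooted-labeled-graphlet identifier.
#'
#' @param env A `rooted_env` (or a `contact_graph` plus `root` index).
#' @param N Maximum graphlet order, between 1 and 5 (default 4).
#' @param root Root vertex index when `env` is a bare `contact_graph`.
#' @return An object of class `graphlet_profile` with the raw counts in
#'   `phi` (named numeric), an empty `psi`, and the counting `spec`.
#' @export
count_graphlets <- function(env, N = 4, root = NULL) {
  if (inherits(env, "contact_graph")) {
    stopifnot(!is.null(root))
    env <- list(graph = env, root = as.integer(root))
  }
  g <- env$graph
  r <- env$root
  stopifnot(N >= 1, N <= .GRAPHLET_MAX)
  alphabet <- g$alphabet
  lab_all <- match(g$vertices$label, alphabet)
  if (anyNA(lab_all))
    stop("vertex labels outside the graph alphabet")
  adj <- .adjlist(g)
  nv <- nrow(g$vertices)

  counts <- new.env(parent = emptyenv())
  record <- function(sub) {
    n <- length(sub)
    mask <- 0
    if (n >= 2L) {
      pt <- .pairs_tab(n)
      for (p in seq_len(nrow(pt))) {
        u <- sub[pt[p, 1]]; v <- sub[pt[p, 2]]
        if (v %in% adj[[u]])
          mask <- mask + bitwShiftL(1L, p - 1L)
      }
    }
    cf <- .canon_form(n, lab_all[sub], mask, length(alphabet))
    id <- .graphlet_id(n, cf$lab, cf$mask, alphabet)
    counts[[id]] <- (if (is.null(counts[[id]])) 0 else counts[[id]]) + 1
  }

  # enumerate connected induced subgraphs containing the root exactly once:
  # grow from {root}; `ext` holds admissible extension vertices, `forb` the
  # vertices already expanded at an enclosing level (never re-admitted).
  recurse <- function(sub, ext, forb) {
    record(sub)
    if (length(sub) == N) return(invisible())
    while (length(ext)) {
      w <- ext[1L]; ext <- ext[-1L]
      new_nb <- setdiff(adj[[w]], c(sub, ext, forb, w))
      recurse(c(sub, w), c(ext, new_nb), forb)
      forb <- c(forb, w)
    }
  }
  recurse(r, setdiff(adj[[r]], r), integer())

  phi <- unlist(as.list(counts))
  if (is.null(phi)) phi <- stats::setNames(numeric(), character())
  structure(list(phi = phi[order(names(phi))], psi = NULL,
                 spec = list(N = as.integer(N), m = NA_integer_,
                             mode = NA_character_, alphabet = alphabet)),
            class = "graphlet_profile")
}

#' @export
print.graphlet_profile <- function(x, ...) {
  cat(sprintf("<graphlet_profile> N = %d, %d distinct graphlets, total count %g",
              x$spec$N, length(x$phi), sum(x$phi)))
  if (!is.na(x$spec$m))
    cat(sprintf("; smoothed (m = %d, mode = %s)", x$spec$m, x$spec$mode))
  cat("\n")
  invisible(x)
}

#' Edit neighborhood of a graphlet
#'
#' All valid graphlets reachable from the center within at most `m`
#' single edit operations. Modes: `"label_sub"` allows only vertex-label
#' substitutions; `"edge_indel"` only edge insertions and deletions that
#' keep the graph connected; `"full"` additionally allows vertex
#' insertion (a new leaf attached by one edge, any label in the alphabet,
#' respecting the order cap `N`) and vertex deletion (a non-root leaf).
#' Edge-label substitutions are vacuous since edges carry no labels. The
#' center itself (distance 0) is always a member.
#'
#' @param id Canonical graphlet id (see [canonical_graphlet()]).
#' @param m Edit budget, 0 or 1.
#' @param mode One of `"full"`, `"label_sub"`, `"edge_indel"`.
#' @param alphabet Vertex alphabet.
#' @param N Maximum graphlet order for vertex insertion (default 5).
#' @return Character vector of canonical member ids (center included).
#' @export
edit_neighborhood <- function(id, m = 1,
                              mode = c("full", "label_sub", "edge_indel"),
                              alphabet = aa_alphabet(), N = .GRAPHLET_MAX) {
  mode <- match.arg(mode)
  stopifnot(m %in% c(0L, 1L))
  if (m == 0L) return(id)
  ck <- paste(id, m, mode, N, length(alphabet),
              paste(alphabet[1], alphabet[length(alphabet)]), sep = "\r")
  cache <- .graphlet_env
  if (!is.null(cache[[ck]])) return(cache[[ck]])

  gd <- .decode_id(id, alphabet)
  n <- gd$n; lab <- gd$lab; mask <- gd$mask
  nsig <- length(alphabet)
  out <- id

  add <- function(n2, lab2, mask2) {
    cf <- .canon_form(n2, lab2, mask2, nsig)
    out[[length(out) + 1L]] <<- .graphlet_id(n2, cf$lab, cf$mask, alphabet)
  }

  if (mode %in% c("full", "label_sub")) {
    for (v in seq_len(n)) for (l in seq_len(nsig)) {
      if (l == lab[v]) next
      lab2 <- lab; lab2[v] <- l
      add(n, lab2, mask)
    }
  }
  if (mode %in% c("full", "edge_indel") && n >= 2L) {
    npairs <- nrow(.pairs_tab(n))
    for (p in seq_len(npairs)) {
      bit <- bitwShiftL(1L, p - 1L)
      present <- bitwAnd(as.integer(mask), bit) != 0L
      mask2 <- if (present) mask - bit else mask + bit
      if (present && !.mask_connected(n, mask2)) next
      add(n, lab, mask2)
    }
  }
  if (mode == "full") {
    if (n < N) {  # insert a leaf attached to each existing vertex
      ptn <- .pairs_tab(n + 1L)
      for (a in seq_len(n)) {
        p <- which(ptn[, 1] == a & ptn[, 2] == n + 1L)
        bit <- bitwShiftL(1L, p - 1L)
        for (l in seq_len(nsig)) add(n + 1L, c(lab, l), mask + bit)
      }
    }
    if (n > 1L) {  # delete a non-root leaf
      deg <- .mask_degrees(n, mask)
      pt <- .pairs_tab(n)
      for (v in seq.int(2L, n)) {
        if (deg[v] != 1L) next
        keep <- setdiff(seq_len(n), v)
        remap <- integer(n); remap[keep] <- seq_len(n - 1L)
        mask2 <- 0
        if (n - 1L >= 2L) {
          pt2 <- .pairs_tab(n - 1L)
          for (p in seq_len(nrow(pt))) {
            if (bitwAnd(as.integer(mask), bitwShiftL(1L, p - 1L)) == 0L) next
            u <- pt[p, 1]; w <- pt[p, 2]
            if (u == v || w == v) next
            a <- remap[u]; b <- remap[w]
            q <- which(pt2[, 1] == min(a, b) & pt2[, 2] == max(a, b))
            mask2 <- mask2 + bitwShiftL(1L, q - 1L)
          }
        }
        add(n - 1L, lab[keep], mask2)
      }
    }
  }
  res <- unique(unlist(out))
  cache[[ck]] <- res
  res
}

#' Smooth a graphlet profile over edit neighborhoods
#'
#' Fills the smoothed counts: for each graphlet the smoothed entry is the
#' sum of raw counts over its edit neighborhood (unit weights). With
#' `m = 0` the smoothed counts equal the raw counts.
#'
#' @param profile A `graphlet_profile` with raw counts.
#' @param m Edit budget, 0 or 1.
#' @param mode Edit mode (see [edit_neighborhood()]).
#' @return The profile with `psi` filled and `spec` updated.
#' @export
smooth_profile <- function(profile, m = 0,
                           mode = c("full", "label_sub", "edge_indel")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "graphlet_profile"), m %in% c(0L, 1L))
  profile$spec$m <- as.integer(m)
  profile$spec$mode <- mode
  if (m == 0L || length(profile$phi) == 0L) {
    profile$psi <- profile$phi
    return(profile)
  }
  acc <- new.env(parent = emptyenv())
  # the edit relation is symmetric, so accumulating each raw count into the
  # neighborhood of its own graphlet equals summing each target's
  # neighborhood over the raw counts
  for (id in names(profile$phi)) {
    nb <- edit_neighborhood(id, m = m, mode = mode,
                            alphabet = profile$spec$alphabet,
                            N = profile$spec$N)
    for (b in nb)
      acc[[b]] <- (if (is.null(acc[[b]])) 0 else acc[[b]]) + profile$phi[[id]]
  }
  psi <- unlist(as.list(acc))
  profile$psi <- psi[order(names(psi))]
  profile
}
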