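# Graphlet kernel families: inner products of (smoothed) count vectors,
# kernel matrices and normalization.

.profile_vec <- function(p) {
  if (is.null(p$psi)) stop("profile has no smoothed counts; call smooth_profile()")
  p$psi
}

.check_spec_match <- function(a, b) {
  sa <- a$spec; sb <- b$spec
  if (!identical(sa$N, sb$N) || !identical(sa$m, sb$m) ||
      !identical(sa$mode, sb$mode) || !identical(sa$alphabet, sb$alphabet))
    stop("graphlet profile specs do not match (N, m, mode, alphabet)")
}

#' Graphlet kernel between two profiles
#'
#' The edit-distance graphlet kernel is the inner product of the smoothed
#' count vectors, summed over graphlet orders 1..N. With `m = 0` this is
#' the standard labeled graphlet kernel. The normalized variant divides by
#' the geometric mean of the self-similarities (0/0 is defined as 0).
#'
#' @param u,v `graphlet_profile` objects with identical specs, smoothed.
#' @param normalize Logical; return the normalized kernel value.
#' @return A single numeric kernel value.
#' @export
graphlet_kernel <- function(u, v, normalize = FALSE) {
  stopifnot(inherits(u, "graphlet_profile"), inherits(v, "graphlet_profile"))
  .check_spec_match(u, v)
  x <- .profile_vec(u); y <- .profile_vec(v)
  shared <- intersect(names(x), names(y))
  k <- sum(x[shared] * y[shared])
  if (!normalize) return(k)
  den <- sqrt(sum(x^2) * sum(y^2))
  if (den == 0) 0 else k / den
}

# profiles -> sparse item x feature matrix of smoothed counts
.profile_matrix <- function(profiles) {
  vecs <- lapply(profiles, .profile_vec)
  feats <- sort(unique(unlist(lapply(vecs, names))))
  i <- integer(); j <- integer(); x <- numeric()
  for (r in seq_along(vecs)) {
    v <- vecs[[r]]
    if (!length(v)) next
    i <- c(i, rep.int(r, length(v)))
    j <- c(j, match(names(v), feats))
    x <- c(x, unname(v))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(vecs), length(feats)),
                       dimnames = list(names(profiles), feats))
}

#' Graphlet kernel matrix over a set of items
#'
#' @param profiles Named list of smoothed `graphlet_profile` objects with
#'   identical specs.
#' @param normalize Logical; normalize to unit diagonal (default TRUE).
#' @return A symmetric numeric matrix with the item names as dimnames and
#'   the kernel spec in `attr(, "spec")`.
#' @export
kernel_matrix <- function(profiles, normalize = TRUE) {
  stopifnot(length(profiles) >= 1)
  for (p in profiles[-1]) .check_spec_match(profiles[[1]], p)
  X <- .profile_matrix(profiles)
  K <- as.matrix(Matrix::tcrossprod(X))
  if (normalize) {
    d <- sqrt(diag(K))
    d[d == 0] <- 1  # all-zero profiles keep kernel value 0
    K <- K / outer(d, d)
  }
  K <- (K + t(K)) / 2
  spec <- profiles[[1]]$spec
  spec$normalized <- normalize
  attr(K, "spec") <- spec
  K
}

#' Cross-kernel between new items and training items
#'
#' @param new_profiles,train_profiles Named lists of smoothed profiles with
#'   identical specs.
#' @param normalize Logical; normalize by the items' self-similarities.
#' @return A `length(new) x length(train)` matrix.
#' @export
kernel_cross <- function(new_profiles, train_profiles, normalize = TRUE) {
  for (p in c(new_profiles, train_profiles[-1]))
    .check_spec_match(train_profiles[[1]], p)
  vecs_n <- lapply(new_profiles, .profile_vec)
  vecs_t <- lapply(train_profiles, .profile_vec)
  feats <- sort(unique(c(unlist(lapply(vecs_n, names)),
                         unlist(lapply(vecs_t, names)))))
  tovec <- function(v) {
    out <- numeric(length(feats))
    out[match(names(v), feats)] <- v
    out
  }
  Xn <- do.call(rbind, lapply(vecs_n, tovec))
  Xt <- do.call(rbind, lapply(vecs_t, tovec))
  K <- Xn %*% t(Xt)
  if (normalize) {
    dn <- sqrt(rowSums(Xn^2)); dt <- sqrt(rowSums(Xt^2))
    dn[dn == 0] <- 1; dt[dt == 0] <- 1
    K <- K / outer(dn, dt)
  }
  dimnames(K) <- list(names(new_profiles), names(train_profiles))
  K
}

#' Write a kernel matrix as TSV
#'
#' Tab-separated with a header row of item ids and the ids as the first
#' column.
#'
#' @param K Kernel matrix (with dimnames).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_kernel_matrix <- function(K, path) {
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a graphlet profile to JSON
#'
#' @param profile A `graphlet_profile`.
#' @param path Optional output path; if omitted the JSON string is
#'   returned.
#' @return JSON string or the path, invisibly.
#' @export
profile_to_json <- function(profile, path = NULL) {
  obj <- list(
    spec = list(N = profile$spec$N, m = profile$spec$m,
                mode = profile$spec$mode,
                alphabet = profile$spec$alphabet),
    phi = as.list(profile$phi),
    psi = if (is.null(profile$psi)) NULL else as.list(profile$psi)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname profile_to_json
#' @param json JSON string or path to a JSON file.
#' @export
profile_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  spec <- obj$spec
  empty <- stats::setNames(numeric(), character())
  structure(list(
    phi = if (length(obj$phi)) unlist(obj$phi) else empty,
    psi = if (is.null(obj$psi)) NULL
          else if (length(obj$psi)) unlist(obj$psi) else empty,
    spec = list(N = as.integer(spec$N),
                m = if (is.null(spec$m) || is.na(spec$m)) NA_integer_
                    else as.integer(spec$m),
                mode = if (is.null(spec$mode)) NA_character_ else spec$mode,
                alphabet = spec$alphabet)
  ), class = "graphlet_profile")
}
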