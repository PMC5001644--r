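# Vertex-labeled protein contact graphs and rooted residue microenvironments.

#' Build a protein contact graph
#'
#' Vertices are the polymer residues of the structure; two residues are
#' joined when they are spatially close under the chosen rule:
#' `"any_atom"` joins residues whose closest pair of atoms is within
#' `threshold` Angstrom (default 4.5), `"c_alpha"` joins residues whose
#' C-alpha atoms are within `threshold` (conventionally 6.0). The graph is
#' simple and undirected; initial vertex labels are the 20-letter amino
#' acid alphabet.
#'
#' @param s A `protein_structure`.
#' @param rule Contact rule, `"any_atom"` or `"c_alpha"`.
#' @param threshold Distance cutoff in Angstrom (> 0). Defaults to 4.5 for
#'   `any_atom` and 6.0 for `c_alpha`.
#' @return An object of class `contact_graph`: list with `vertices`
#'   (data.frame: `key`, `chain`, `resindex`, `aa`, `label`), `edges`
#'   (two-column integer matrix of vertex indices, `u < v`), `alphabet`,
#'   `rule`, `threshold`.
#' @export
build_contact_graph <- function(s, rule = c("any_atom", "c_alpha"),
                                threshold = NULL) {
  stopifnot(inherits(s, "protein_structure"))
  rule <- match.arg(rule)
  if (is.null(threshold)) threshold <- if (rule == "any_atom") 4.5 else 6.0
  stopifnot(is.numeric(threshold), threshold > 0)

  res <- s$residues
  nv <- nrow(res)

  if (rule == "c_alpha") {
    ca <- s$atoms[s$atoms$elety == "CA", , drop = FALSE]
    ca <- ca[!duplicated(ca$key), , drop = FALSE]
    missing <- setdiff(res$key, ca$key)
    if (length(missing))
      stop("residues without C-alpha atoms under c_alpha rule: ",
           paste(missing, collapse = ", "))
    xyz <- as.matrix(ca[match(res$key, ca$key), c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    adj <- d <= threshold
    diag(adj) <- FALSE
  } else {
    at <- s$atoms
    vi <- match(at$key, res$key)
    d <- as.matrix(stats::dist(as.matrix(at[, c("x", "y", "z")])))
    close <- which(d <= threshold & upper.tri(d), arr.ind = TRUE)
    adj <- matrix(FALSE, nv, nv)
    if (nrow(close)) {
      ru <- vi[close[, 1]]; rv <- vi[close[, 2]]
      keep <- ru != rv
      adj[cbind(ru[keep], rv[keep])] <- TRUE
      adj <- adj | t(adj)
    }
  }

  e <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- matrix(as.integer(e), ncol = 2,
                  dimnames = list(NULL, c("u", "v")))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]

  structure(list(
    vertices = data.frame(key = res$key, chain = res$chain,
                          resindex = res$resindex, aa = res$aa,
                          label = res$aa, stringsAsFactors = FALSE),
    edges = edges,
    alphabet = aa_alphabet(),
    rule = rule,
    threshold = threshold
  ), class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> %d vertices, %d edges (%s, %.1f A), |Sigma| = %d\n",
              nrow(x$vertices), nrow(x$edges), x$rule, x$threshold,
              length(x$alphabet)))
  invisible(x)
}

#' @export
plot.contact_graph <- function(x, ...) {
  plot(as_igraph(x), vertex.label = x$vertices$label, ...)
}

#' Convert a contact graph to an igraph object
#' @param g A `contact_graph` or `rooted_env`.
#' @return An `igraph` graph with vertex attributes `key`, `aa`, `label`.
#' @export
as_igraph <- function(g) {
  if (inherits(g, "rooted_env")) g <- g$graph
  ig <- igraph::make_empty_graph(n = nrow(g$vertices), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "key", value = g$vertices$key)
  ig <- igraph::set_vertex_attr(ig, "aa", value = g$vertices$aa)
  ig <- igraph::set_vertex_attr(ig, "label", value = g$vertices$label)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, t(g$edges))
  ig
}

# adjacency list (integer indices) of a contact graph
.adjlist <- function(g) {
  nv <- nrow(g$vertices)
  adj <- vector("list", nv)
  if (nrow(g$edges)) {
    for (i in seq_len(nrow(g$edges))) {
      u <- g$edges[i, 1]; v <- g$edges[i, 2]
      adj[[u]] <- c(adj[[u]], v)
      adj[[v]] <- c(adj[[v]], u)
    }
  }
  adj
}

.vertex_index <- function(g, root) {
  if (is.character(root)) {
    i <- match(root, g$vertices$key)
    if (is.na(i)) stop("root vertex not found: ", root)
    i
  } else {
    root <- as.integer(root)
    if (root < 1L || root > nrow(g$vertices)) stop("root vertex out of range")
    root
  }
}

#' Extract the rooted microenvironment of a residue
#'
#' Returns the induced subgraph on all vertices within `level` hops of the
#' root vertex (a BFS ball), with the root marked. Level 0 is the root
#' alone; `Inf` gives the connected component of the root.
#'
#' @param g A `contact_graph`.
#' @param root Vertex key (`"chain:resindex"`) or integer vertex index.
#' @param level Non-negative BFS depth (default 3).
#' @return An object of class `rooted_env`: list with `graph` (the induced
#'   `contact_graph`), `root` (index of the root within it) and `level`.
#' @export
extract_environment <- function(g, root, level = 3) {
  stopifnot(inherits(g, "contact_graph"), level >= 0)
  ri <- .vertex_index(g, root)
  ig <- as_igraph(g)
  d <- as.vector(igraph::distances(ig, v = ri))
  keep <- which(is.finite(d) & d <= level)
  keep <- keep[order(d[keep], keep)]  # root first, then by hop distance
  idx <- match(seq_len(nrow(g$vertices)), keep)
  sub_edges <- g$edges[g$edges[, 1] %in% keep & g$edges[, 2] %in% keep, ,
                       drop = FALSE]
  e2 <- matrix(as.integer(idx[sub_edges]), ncol = 2,
               dimnames = list(NULL, c("u", "v")))
  e2 <- cbind(u = pmin(e2[, 1], e2[, 2]), v = pmax(e2[, 1], e2[, 2]))
  sub <- structure(list(
    vertices = g$vertices[keep, , drop = FALSE],
    edges = e2[order(e2[, 1], e2[, 2]), , drop = FALSE],
    alphabet = g$alphabet, rule = g$rule, threshold = g$threshold
  ), class = "contact_graph")
  rownames(sub$vertices) <- NULL
  structure(list(graph = sub, root = 1L, level = level),
            class = "rooted_env")
}

#' @export
print.rooted_env <- function(x, ...) {
  cat(sprintf("<rooted_env> level %s, root %s, %d vertices, %d edges\n",
              format(x$level), x$graph$vertices$key[x$root],
              nrow(x$graph$vertices), nrow(x$graph$edges)))
  invisible(x)
}

#' Split the vertex alphabet by residue conservation
#'
#' Extends the 20-letter amino acid alphabet to 40 symbols: residues with
#' conservation score at or above the pivot keep the uppercase letter
#' (conserved class), residues below it are recoded to lowercase. The pivot
#' is conventionally the median conservation over the entire training
#' collection, not per chain; ties at the pivot go to the conserved class.
#'
#' @param g A `contact_graph` (or `rooted_env`).
#' @param scores Named numeric vector of per-residue conservation scores;
#'   names are vertex keys. Every vertex must have a score.
#' @param pivot Scalar threshold separating the two classes.
#' @return The graph with a 40-symbol alphabet and relabeled vertices; the
#'   underlying amino acid stays available in `vertices$aa`.
#' @export
split_alphabet_by_conservation <- function(g, scores, pivot) {
  if (inherits(g, "rooted_env")) {
    g$graph <- split_alphabet_by_conservation(g$graph, scores, pivot)
    return(g)
  }
  stopifnot(inherits(g, "contact_graph"), is.numeric(pivot), length(pivot) == 1)
  sc <- scores[g$vertices$key]
  if (anyNA(sc))
    stop("missing conservation score for residues: ",
         paste(g$vertices$key[is.na(sc)], collapse = ", "))
  conserved <- sc >= pivot
  g$vertices$label <- ifelse(conserved, g$vertices$aa,
                             tolower(g$vertices$aa))
  g$alphabet <- aa_alphabet40()
  g
}

#' Write / read a contact graph as plain-text tables
#'
#' `write_contact_graph` writes `<prefix>.vertices.tsv` (`key`, `aa`,
#' `label`) and `<prefix>.edges.tsv` (`u_key`, `v_key`);
#' `read_contact_graph` reconstructs the graph from them.
#'
#' @param g A `contact_graph`.
#' @param prefix Output path prefix.
#' @return `write_contact_graph` the prefix, invisibly;
#'   `read_contact_graph` a `contact_graph`.
#' @export
write_contact_graph <- function(g, prefix) {
  stopifnot(inherits(g, "contact_graph"))
  utils::write.table(g$vertices[, c("key", "aa", "label")],
                     paste0(prefix, ".vertices.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ek <- data.frame(u_key = g$vertices$key[g$edges[, 1]],
                   v_key = g$vertices$key[g$edges[, 2]])
  utils::write.table(ek, paste0(prefix, ".edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_contact_graph
#' @export
read_contact_graph <- function(prefix) {
  v <- utils::read.delim(paste0(prefix, ".vertices.tsv"),
                         stringsAsFactors = FALSE)
  e <- utils::read.delim(paste0(prefix, ".edges.tsv"),
                         stringsAsFactors = FALSE)
  ck <- strsplit(v$key, ":", fixed = TRUE)
  verts <- data.frame(key = v$key,
                      chain = vapply(ck, `[`, "", 1L),
                      resindex = vapply(ck, `[`, "", 2L),
                      aa = v$aa, label = v$label, stringsAsFactors = FALSE)
  em <- cbind(u = match(e$u_key, v$key), v = match(e$v_key, v$key))
  em <- cbind(u = pmin(em[, 1], em[, 2]), v = pmax(em[, 1], em[, 2]))
  alphabet <- if (any(v$label %in% tolower(aa_alphabet())))
    aa_alphabet40() else aa_alphabet()
  structure(list(vertices = verts,
                 edges = matrix(as.integer(em), ncol = 2,
                                dimnames = list(NULL, c("u", "v"))),
                 alphabet = alphabet, rule = NA_character_,
                 threshold = NA_real_),
            class = "contact_graph")
}
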