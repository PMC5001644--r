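# Synthetic data generators: toy structures with planted metal-site
# geometry, PU score mixtures with a known class prior, planted-motif graph
# datasets, and enrichment cohorts. Every generator is a pure function of
# its parameters and seed.

#' Generate a synthetic protein structure as PDB text
#'
#' Builds a self-avoiding C-alpha backbone walk (3.8 Angstrom steps) with
#' backbone N/C/O atoms and a C-beta pseudo side chain. Optionally plants
#' a metal site: a Zn heteroatom with `motif$k` coordinating residues
#' whose side-chain S atoms sit 2.0-2.9 Angstrom from the ion while every
#' other residue's N/O/S atoms stay more than 3.5 Angstrom away. The
#' geometry is deliberately coarse: only interatomic distances matter to
#' the downstream rules, not stereochemistry.
#'
#' @param n_residues Number of residues (>= 3).
#' @param motif `NULL`, or a list with `k` (number of coordinating
#'   residues, default 4).
#' @param seed Integer seed; identical seeds give byte-identical text.
#' @param chain Chain identifier (default `"A"`).
#' @param id Structure id written to the HEADER line.
#' @param resolution Resolution written to the REMARK 2 record.
#' @return Character vector of PDB-format lines.
#' @export
synth_structure <- function(n_residues, motif = NULL, seed = 1,
                            chain = "A", id = "SYNT", resolution = 1.8) {
  stopifnot(n_residues >= 3)
  .with_seed(seed, {
    for (attempt in 1:200) {
      out <- .try_synth_structure(n_residues, motif, chain, id, resolution)
      if (!is.null(out)) return(out)
    }
    stop("could not realize the requested geometry after bounded retries")
  })
}

.try_synth_structure <- function(n_residues, motif, chain, id, resolution) {
  # self-avoiding CA walk
  ca <- matrix(NA_real_, n_residues, 3)
  ca[1, ] <- c(0, 0, 0)
  for (i in 2:n_residues) {
    ok <- FALSE
    for (try in 1:50) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- ca[i - 1, ] + 3.8 * u
      d <- sqrt(rowSums((ca[seq_len(i - 1), , drop = FALSE] -
                           matrix(cand, i - 1, 3, byrow = TRUE))^2))
      if (all(d > 3.5)) { ca[i, ] <- cand; ok <- TRUE; break }
    }
    if (!ok) return(NULL)
  }
  aas <- sample(aa_alphabet(), n_residues, replace = TRUE)

  zn <- NULL; site <- integer()
  if (!is.null(motif)) {
    k <- if (is.null(motif$k)) 4L else as.integer(motif$k)
    anchor <- sample(n_residues, 1)
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    zn <- ca[anchor, ] + 6.0 * u
    dzn <- sqrt(rowSums((ca - matrix(zn, n_residues, 3, byrow = TRUE))^2))
    site <- order(dzn)[seq_len(k)]
    aas[site] <- "C"  # cysteines coordinate through the side-chain S
  }

  # atom placement: backbone N/C/O near the CA, CB toward the metal for
  # site residues (carrying the coordinating S), away otherwise
  atoms <- list()
  push <- function(elety, element, resno, resid, xyz) {
    atoms[[length(atoms) + 1L]] <<- list(elety = elety, element = element,
                                         resno = resno, resid = resid,
                                         xyz = xyz)
  }
  for (i in seq_len(n_residues)) {
    resid <- AA_ONE2THREE[aas[i]]
    dirn <- if (i > 1) ca[i, ] - ca[i - 1, ] else c(1, 0, 0)
    dirn <- dirn / sqrt(sum(dirn^2))
    push("N", "N", i, resid, ca[i, ] - 1.46 * dirn)
    push("CA", "C", i, resid, ca[i, ])
    push("C", "C", i, resid, ca[i, ] + 1.52 * dirn)
    push("O", "O", i, resid, ca[i, ] + 1.52 * dirn + c(0, 1.23, 0))
    if (aas[i] != "G") {
      perp <- c(-dirn[2], dirn[1], dirn[3])
      perp <- perp / sqrt(sum(perp^2))
      push("CB", "C", i, resid, ca[i, ] + 1.53 * perp)
      if (i %in% site) {
        v <- ca[i, ] - zn; v <- v / sqrt(sum(v^2))
        push("SG", "S", i, resid, zn + stats::runif(1, 2.0, 2.9) * v)
      }
    }
  }

  if (!is.null(zn)) {
    # every non-site residue's N/O/S atom must stay clear of the ion
    for (a in atoms) {
      if (a$resno %in% site) next
      if (!(a$element %in% c("N", "O", "S"))) next
      if (sqrt(sum((a$xyz - zn)^2)) <= 3.5) return(NULL)
    }
  }

  lines <- c(
    sprintf("HEADER    SYNTHETIC STRUCTURE                     01-JAN-00   %s", id),
    "EXPDTA    X-RAY DIFFRACTION",
    sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", resolution))
  serial <- 0L
  for (a in atoms) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, paste0(" ", a$elety), " ", a$resid, chain, a$resno, " ",
      a$xyz[1], a$xyz[2], a$xyz[3], 1.00, 0.00, a$element))
  }
  if (!is.null(zn)) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "HETATM%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, "ZN  ", " ", " ZN", chain, n_residues + 100L, " ",
      zn[1], zn[2], zn[3], 1.00, 0.00, "ZN"))
  }
  c(lines, "END")
}

#' Generate positive-unlabeled score mixtures with a known class prior
#'
#' Labeled scores are drawn from the positive component; unlabeled scores
#' from the `alpha`-mixture of the positive and background components.
#' Components are Beta distributions bounded to [0, 1] like calibrated
#' posteriors (defaults: positive Beta(9, 1), background Beta(1, 9)).
#'
#' @param alpha True class prior of the unlabeled set, in [0, 1].
#' @param m,n Sizes of the labeled and unlabeled sets.
#' @param pos_shape,bg_shape Length-2 Beta shape parameters.
#' @param seed Integer seed.
#' @return List with `labeled`, `unlabeled`, `unlabeled_is_positive`
#'   (logical ground truth), and the generating parameters.
#' @export
synth_pu_scores <- function(alpha, m, n, pos_shape = c(9, 1),
                            bg_shape = c(1, 9), seed = 1) {
  stopifnot(alpha >= 0, alpha <= 1, m >= 1, n >= 1)
  if (identical(pos_shape, bg_shape))
    warning("positive and background components are identical; ",
            "the class prior is unidentifiable")
  .with_seed(seed, {
    labeled <- stats::rbeta(m, pos_shape[1], pos_shape[2])
    is_pos <- stats::runif(n) < alpha
    unlabeled <- ifelse(is_pos,
                        stats::rbeta(n, pos_shape[1], pos_shape[2]),
                        stats::rbeta(n, bg_shape[1], bg_shape[2]))
    list(labeled = labeled, unlabeled = unlabeled,
         unlabeled_is_positive = is_pos,
         params = list(alpha = alpha, m = m, n = n,
                       pos_shape = pos_shape, bg_shape = bg_shape,
                       seed = seed))
  })
}

# random connected vertex-labeled environment on `size` vertices
.random_env <- function(size, alphabet, p_edge = 0.25) {
  labels <- sample(alphabet, size, replace = TRUE)
  edges <- NULL
  for (v in seq_len(size)[-1]) {          # random spanning tree
    u <- sample(v - 1L, 1)
    edges <- rbind(edges, c(u, v))
  }
  if (size >= 3) {
    pairs <- t(utils::combn(size, 2))
    have <- paste(edges[, 1], edges[, 2])
    extra <- pairs[stats::runif(nrow(pairs)) < p_edge, , drop = FALSE]
    extra <- extra[!(paste(extra[, 1], extra[, 2]) %in% have), , drop = FALSE]
    edges <- rbind(edges, extra)
  }
  make_env(labels, edges, alphabet = alphabet)
}

#' Construct a rooted environment directly from labels and edges
#'
#' Test and simulation helper: builds a `rooted_env` whose root is vertex
#' 1, without going through a structure.
#'
#' @param labels Character vector of vertex labels (root first).
#' @param edges Two-column matrix of vertex indices (`NULL` for none).
#' @param alphabet Vertex alphabet (default 20 amino acids).
#' @param level Nominal BFS depth tag (default `NA`).
#' @return A `rooted_env`.
#' @export
make_env <- function(labels, edges = NULL, alphabet = aa_alphabet(),
                     level = NA) {
  nv <- length(labels)
  stopifnot(all(labels %in% alphabet))
  if (is.null(edges) || !length(edges)) {
    edges <- matrix(integer(), ncol = 2)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2)
    edges <- cbind(pmin(edges[, 1], edges[, 2]),
                   pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    stopifnot(all(edges >= 1), all(edges <= nv), all(edges[, 1] != edges[, 2]))
  }
  colnames(edges) <- c("u", "v")
  g <- structure(list(
    vertices = data.frame(key = paste0("X:", seq_len(nv)),
                          chain = "X", resindex = as.character(seq_len(nv)),
                          aa = toupper(labels), label = labels,
                          stringsAsFactors = FALSE),
    edges = edges[order(edges[, 1], edges[, 2]), , drop = FALSE],
    alphabet = alphabet, rule = NA_character_, threshold = NA_real_
  ), class = "contact_graph")
  structure(list(graph = g, root = 1L, level = level), class = "rooted_env")
}

#' Generate a planted-motif graph dataset
#'
#' Positives are random rooted environments that contain the motif (a
#' rooted labeled graphlet) as an induced subgraph at the root; negatives
#' are matched random environments verified not to contain it. With
#' `noise > 0`, random extra edges are added inside the motif vertices of
#' positives, which can destroy induced-subgraph presence.
#'
#' @param n_pos,n_neg Class sizes.
#' @param motif List with `labels` (character, root first) and `edges`
#'   (two-column matrix); default: a Cys-rooted Cys-His-His triangle,
#'   reminiscent of a zinc coordination patch.
#' @param size Environment order (default 10).
#' @param noise Probability of a corrupting extra edge per motif pair
#'   (default 0).
#' @param alphabet Vertex alphabet.
#' @param seed Integer seed.
#' @return List with `envs` (list of `rooted_env`), `y` (+1/-1), and
#'   `motif_id` (canonical id of the motif).
#' @export
synth_motif_graphs <- function(n_pos, n_neg, motif = NULL, size = 10,
                               noise = 0, alphabet = aa_alphabet(),
                               seed = 1) {
  if (is.null(motif))
    motif <- list(labels = c("C", "H", "H"),
                  edges = rbind(c(1, 2), c(1, 3), c(2, 3)))
  k <- length(motif$labels)
  stopifnot(k <= 5, k <= size)
  motif_id <- canonical_graphlet(motif$labels, motif$edges, alphabet)

  has_motif <- function(env) {
    prof <- count_graphlets(env, N = k)
    motif_id %in% names(prof$phi) && prof$phi[[motif_id]] > 0
  }

  .with_seed(seed, {
    envs <- vector("list", n_pos + n_neg)
    y <- c(rep(1, n_pos), rep(-1, n_neg))
    for (i in seq_len(n_pos)) {
      repeat {
        e <- .random_env(size, alphabet)
        # overwrite the first k vertices with the motif, exactly
        e$graph$vertices$label[seq_len(k)] <- motif$labels
        e$graph$vertices$aa[seq_len(k)] <- toupper(motif$labels)
        ed <- e$graph$edges
        inside <- ed[, 1] <= k & ed[, 2] <= k
        ed <- ed[!inside, , drop = FALSE]
        ed <- rbind(ed, cbind(pmin(motif$edges[, 1], motif$edges[, 2]),
                              pmax(motif$edges[, 1], motif$edges[, 2])))
        if (noise > 0 && k >= 2) {
          pairs <- t(utils::combn(k, 2))
          add <- pairs[stats::runif(nrow(pairs)) < noise, , drop = FALSE]
          ed <- unique(rbind(ed, add))
        }
        colnames(ed) <- c("u", "v")
        e$graph$edges <- ed[order(ed[, 1], ed[, 2]), , drop = FALSE]
        # the rewrite may disconnect vertex 1 from the rest; require the
        # environment to stay connected through the root
        if (.env_connected(e)) break
      }
      envs[[i]] <- e
    }
    for (i in seq_len(n_neg)) {
      repeat {
        e <- .random_env(size, alphabet)
        if (!has_motif(e)) break
      }
      envs[[n_pos + i]] <- e
    }
    names(envs) <- paste0("env", seq_along(envs))
    list(envs = envs, y = y, motif_id = motif_id)
  })
}

.env_connected <- function(env) {
  ig <- as_igraph(env$graph)
  igraph::components(ig)$no == 1
}

#' Generate disease / neutral score cohorts
#'
#' Neutral scores come from a background Beta(1, 9) distribution; disease
#' scores from a mixture that raises the tail mass so that the expected
#' exceedance at the neutral 1% FPR threshold approximates
#' `exceedance_effect` (a proportion; 0 gives a null cohort).
#'
#' @param n_disease,n_neutral Cohort sizes (>= 100).
#' @param exceedance_effect Target disease exceedance proportion at the 1%
#'   neutral threshold (default 0.05).
#' @param seed Integer seed.
#' @return List with `disease` and `neutral` score vectors and `params`.
#' @export
synth_cohorts <- function(n_disease, n_neutral, exceedance_effect = 0.05,
                          seed = 1) {
  stopifnot(n_disease >= 100, n_neutral >= 100,
            exceedance_effect >= 0, exceedance_effect <= 1)
  pi_mix <- max(0, (exceedance_effect - 0.01) / 0.99)
  .with_seed(seed, {
    neutral <- stats::rbeta(n_neutral, 1, 9)
    hot <- stats::runif(n_disease) < pi_mix
    disease <- ifelse(hot, stats::rbeta(n_disease, 9, 1),
                      stats::rbeta(n_disease, 1, 9))
    list(disease = disease, neutral = neutral,
         params = list(n_disease = n_disease, n_neutral = n_neutral,
                       exceedance_effect = exceedance_effect,
                       pi_mix = pi_mix, seed = seed))
  })
}
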