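# Parsing of PDB-format structures into the residue/atom tables the rest of
# the package consumes.

#' Parse a PDB-format structure
#'
#' Reads ATOM and HETATM records into a `protein_structure` object.
#' Alternate-location conformers are resolved to the highest-occupancy
#' conformer per atom (ties broken by altLoc identifier). Non-standard
#' polymer residues are dropped with a warning. HETATM records (ligands,
#' metals, waters) are retained in a separate table.
#'
#' @param x Path to a PDB file, or a character vector of PDB-format lines.
#' @param id Structure identifier; defaults to the file base name or
#'   `"structure"` for literal text.
#' @return An object of class `protein_structure` with elements
#'   `id`, `resolution` (Angstrom, `NA` if not recorded), `experiment`,
#'   `atoms` (polymer atom table), `residues` (one row per residue, with
#'   one-letter `aa`), and `het` (heteroatom table).
#' @export
parse_structure <- function(x, id = NULL) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    path <- x
    lines <- readLines(path, warn = FALSE)
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  } else {
    lines <- unlist(strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path), add = TRUE)
    if (is.null(id)) id <- "structure"
  }

  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(rec == "ATOM  "))
    stop("no ATOM records found in input")
  # validate coordinate fields before handing off to the reader so malformed
  # records are reported with their line number
  for (i in which(is_atom)) {
    coords <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    val <- suppressWarnings(as.numeric(coords))
    if (anyNA(val) || nchar(lines[i]) < 54)
      stop(sprintf("malformed ATOM/HETATM record at line %d: %s",
                   i, trimws(lines[i])))
  }

  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # resolve altLocs: keep the highest-occupancy conformer of each atom
  akey <- paste(at$type, at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(akey, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(akey[ord]), , drop = FALSE]
  at <- at[order(at$eleno), , drop = FALSE]

  poly <- at[at$type == "ATOM", , drop = FALSE]
  het <- at[at$type == "HETATM", , drop = FALSE]

  std <- poly$resid %in% names(AA_THREE2ONE)
  if (any(!std)) {
    bad <- unique(poly$resid[!std])
    warning(sprintf("dropping %d non-standard residue type(s): %s",
                    length(bad), paste(bad, collapse = ", ")))
    poly <- poly[std, , drop = FALSE]
  }
  if (nrow(poly) == 0L)
    stop("no standard polymer residues after filtering")

  resindex <- paste0(poly$resno, poly$insert)
  rkey <- paste(poly$chain, resindex, sep = ":")
  first <- !duplicated(rkey)
  residues <- data.frame(
    chain = poly$chain[first],
    resno = poly$resno[first],
    inscode = poly$insert[first],
    resindex = resindex[first],
    key = rkey[first],
    aa = unname(AA_THREE2ONE[poly$resid[first]]),
    stringsAsFactors = FALSE
  )

  atoms <- data.frame(
    chain = poly$chain, resno = poly$resno, inscode = poly$insert,
    resindex = resindex, key = rkey, elety = poly$elety,
    element = toupper(trimws(poly$elesy)),
    x = poly$x, y = poly$y, z = poly$z, occupancy = poly$o,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite atom coordinates")

  het_tab <- if (nrow(het)) data.frame(
    chain = het$chain, resno = het$resno, resid = trimws(het$resid),
    elety = het$elety, element = toupper(trimws(het$elesy)),
    x = het$x, y = het$y, z = het$z,
    stringsAsFactors = FALSE
  ) else data.frame(chain = character(), resno = integer(),
                    resid = character(), elety = character(),
                    element = character(), x = numeric(), y = numeric(),
                    z = numeric(), stringsAsFactors = FALSE)

  structure(list(
    id = id,
    resolution = .parse_resolution(lines),
    experiment = .parse_expdta(lines),
    atoms = atoms,
    residues = residues,
    het = het_tab
  ), class = "protein_structure")
}

.parse_resolution <- function(lines) {
  r2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(r2)) return(NA_real_)
  m <- regmatches(r2[1], regexpr("[0-9]+\\.[0-9]+", r2[1]))
  if (!length(m)) NA_real_ else as.numeric(m)
}

.parse_expdta <- function(lines) {
  e <- grep("^EXPDTA", lines, value = TRUE)
  if (!length(e)) return(NA_character_)
  trimws(substr(e[1], 11, nchar(e[1])))
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s\n", x$id))
  cat(sprintf("  chains: %s\n", paste(unique(x$residues$chain), collapse = ", ")))
  cat(sprintf("  residues: %d   polymer atoms: %d   heteroatoms: %d\n",
              nrow(x$residues), nrow(x$atoms), nrow(x$het)))
  if (!is.na(x$resolution))
    cat(sprintf("  resolution: %.2f A\n", x$resolution))
  invisible(x)
}

#' Derive metal-binding site labels from structure geometry
#'
#' A residue is labeled as binding a metal ion when at least one of its
#' heavy atoms of element N, O or S lies within `within` Angstrom of the
#' ion. Carbon and hydrogen never coordinate under this rule.
#'
#' @param s A `protein_structure`.
#' @param metal_codes Named character vector mapping heteroatom residue
#'   codes to function identifiers (default: the common biological metals,
#'   e.g. `c(ZN = "Zn")`).
#' @param within Coordination distance cutoff in Angstrom (default 3).
#' @return A data.frame of site labels with columns `chain`, `resindex`,
#'   `fun`, `evidence`; zero rows when no metal is present.
#' @export
label_metal_sites <- function(s, metal_codes = METAL_CODES, within = 3) {
  stopifnot(inherits(s, "protein_structure"))
  empty <- data.frame(chain = character(), resindex = character(),
                      fun = character(), evidence = character(),
                      stringsAsFactors = FALSE)
  met <- s$het[s$het$resid %in% names(metal_codes) &
                 s$het$element %in% toupper(names(metal_codes)), , drop = FALSE]
  if (nrow(met) == 0L) return(empty)

  heavy <- s$atoms[s$atoms$element %in% c("N", "O", "S"), , drop = FALSE]
  if (nrow(heavy) == 0L) return(empty)

  out <- empty
  for (i in seq_len(nrow(met))) {
    d2 <- (heavy$x - met$x[i])^2 + (heavy$y - met$y[i])^2 +
      (heavy$z - met$z[i])^2
    hit <- heavy[d2 <= within^2, c("chain", "resindex"), drop = FALSE]
    if (nrow(hit)) {
      hit <- unique(hit)
      hit$fun <- unname(metal_codes[met$resid[i]])
      hit$evidence <- "geometry"
      out <- rbind(out, hit)
    }
  }
  unique(out[order(out$chain, out$resindex), , drop = FALSE])
}

# per-chain one-letter sequences from ATOM records, in residue order
.chain_sequences <- function(s) {
  res <- s$residues
  lapply(split(res, res$chain), function(r) {
    r <- r[order(r$resno, r$inscode), , drop = FALSE]
    list(seq = paste(r$aa, collapse = ""), keys = r$key, aa = r$aa)
  })
}
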