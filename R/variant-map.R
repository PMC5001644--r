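# Mapping of sequence variants onto structure residues by exact-window search.

#' Build a structure sequence index for variant mapping
#'
#' Collects the ATOM-record-derived chain sequences of a set of structures
#' that pass the quality filters (X-ray-style resolution cutoff and minimum
#' chain length), for use by [map_variants()].
#'
#' @param structures List of `protein_structure` objects.
#' @param max_resolution Keep only structures with resolution strictly below
#'   this value in Angstrom (default 2.5); structures with unknown
#'   resolution are excluded.
#' @param min_length Minimum chain length in residues (default 50,
#'   exclusive).
#' @return An object of class `structure_seq_index`.
#' @export
structure_seq_index <- function(structures, max_resolution = 2.5,
                                min_length = 50) {
  entries <- list()
  for (s in structures) {
    stopifnot(inherits(s, "protein_structure"))
    if (is.na(s$resolution) || s$resolution >= max_resolution) next
    for (ch in names(chs <- .chain_sequences(s))) {
      if (nchar(chs[[ch]]$seq) <= min_length) next
      entries[[paste(s$id, ch, sep = "/")]] <- list(
        structure_id = s$id, chain = ch, resolution = s$resolution,
        seq = chs[[ch]]$seq, keys = chs[[ch]]$keys, aa = chs[[ch]]$aa)
    }
  }
  structure(list(entries = entries), class = "structure_seq_index")
}

#' Map missense variants onto structure residues
#'
#' For each variant a window of `window` residues (default 51) centered on
#' the variant position is cut from the protein sequence (clamped, not
#' padded, at the termini) and searched for verbatim in every indexed chain
#' sequence; only 100% identity matches count. Among multiple matching
#' structures the one with the best (lowest) resolution wins, ties broken
#' by lexicographic structure id then chain. Unmapped variants are flagged
#' with a reason, never dropped.
#'
#' @param variants data.frame with columns `protein`, `position` (1-based),
#'   `wt`, `mt` (one-letter amino acids).
#' @param index A [structure_seq_index()].
#' @param protein_seqs Named character vector of protein sequences, names
#'   matching `variants$protein`.
#' @param window Odd window length (default 51).
#' @return The input data.frame with added columns `structure_id`, `chain`,
#'   `resindex`, `mapped` (logical) and `reason`.
#' @export
map_variants <- function(variants, index, protein_seqs, window = 51) {
  stopifnot(inherits(index, "structure_seq_index"),
            all(c("protein", "position", "wt", "mt") %in% names(variants)))
  if (any(variants$wt == variants$mt))
    stop("wild-type and mutant amino acids must differ")
  half <- (window - 1) %/% 2

  out <- variants
  out$structure_id <- NA_character_
  out$chain <- NA_character_
  out$resindex <- NA_character_
  out$mapped <- FALSE
  out$reason <- NA_character_

  for (i in seq_len(nrow(variants))) {
    prot <- variants$protein[i]
    pos <- variants$position[i]
    pseq <- protein_seqs[[prot]]
    if (is.null(pseq) || is.na(pseq)) {
      out$reason[i] <- "protein sequence unavailable"; next
    }
    if (pos < 1 || pos > nchar(pseq)) {
      out$reason[i] <- "position outside protein sequence"; next
    }
    if (substr(pseq, pos, pos) != variants$wt[i]) {
      out$reason[i] <- sprintf(
        "wild-type mismatch: sequence has %s at position %d",
        substr(pseq, pos, pos), pos)
      next
    }
    lo <- max(1, pos - half)
    hi <- min(nchar(pseq), pos + half)
    win <- substr(pseq, lo, hi)
    offset <- pos - lo  # 0-based offset of the variant within the window

    hits <- list()
    for (ent in index$entries) {
      starts <- gregexpr(win, ent$seq, fixed = TRUE)[[1]]
      if (starts[1] == -1L) next
      for (st in as.integer(starts)) {
        ri <- st + offset
        if (ent$aa[ri] != variants$wt[i]) next  # defensive; exact match implies equality
        hits[[length(hits) + 1L]] <- list(
          structure_id = ent$structure_id, chain = ent$chain,
          key = ent$keys[ri], resolution = ent$resolution)
      }
    }
    if (!length(hits)) {
      out$reason[i] <- "no exact-match window in indexed structures"; next
    }
    resn <- vapply(hits, `[[`, 0, "resolution")
    sid <- vapply(hits, `[[`, "", "structure_id")
    chn <- vapply(hits, `[[`, "", "chain")
    best <- order(resn, sid, chn)[1]
    out$structure_id[i] <- hits[[best]]$structure_id
    out$chain[i] <- hits[[best]]$chain
    out$resindex[i] <- sub("^[^:]*:", "", hits[[best]]$key)
    out$mapped[i] <- TRUE
  }
  out
}

#' Read / write variant tables
#'
#' Tab-separated with columns `protein`, `position`, `wt`, `mt` (extra
#' columns preserved).
#'
#' @param path File path.
#' @param variants data.frame of variants.
#' @return `read_variants` a data.frame; `write_variants` the path,
#'   invisibly.
#' @export
read_variants <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "position", "wt", "mt")
  if (!all(need %in% names(v)))
    stop("variant file must have columns: ", paste(need, collapse = ", "))
  v$position <- as.integer(v$position)
  v
}

#' @rdname read_variants
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
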