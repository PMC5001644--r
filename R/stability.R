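# Stability mutation records: positive labeling and the 33-dimensional
# mutation feature encoding used by the stability predictor.

#' Label stability records as positives
#'
#' A mutation is a stability positive (significantly stabilizing or
#' destabilizing) when `|ddG| > cutoff` kcal/mol; the boundary value is
#' excluded.
#'
#' @param ddG Numeric vector of free-energy changes in kcal/mol.
#' @param cutoff Threshold (default 0.5).
#' @return Logical vector.
#' @export
label_stability_positives <- function(ddG, cutoff = 0.5) {
  stopifnot(all(is.finite(ddG)))
  abs(ddG) > cutoff
}

#' Mutation feature vector for the stability predictor
#'
#' Thirty-three features per substitution: a 20-slot amino acid indicator
#' block (-1 at the wild-type residue, +1 at the mutant residue, 0
#' elsewhere) followed by 13 physicochemical property differences
#' (mutant minus wild type).
#'
#' @param wt_aa,mt_aa One-letter wild-type and mutant amino acids
#'   (must differ).
#' @param property_table A 20 x 13 numeric matrix with amino acid row
#'   names; defaults to [aa_property_table()].
#' @return Named numeric vector of length 33.
#' @export
stability_features <- function(wt_aa, mt_aa,
                               property_table = aa_property_table()) {
  aas <- aa_alphabet()
  if (!(wt_aa %in% aas)) stop("unknown wild-type amino acid: ", wt_aa)
  if (!(mt_aa %in% aas)) stop("unknown mutant amino acid: ", mt_aa)
  if (wt_aa == mt_aa) stop("wild-type and mutant amino acids must differ")
  stopifnot(is.matrix(property_table), ncol(property_table) == 13,
            all(aas %in% rownames(property_table)))
  ind <- stats::setNames(numeric(20), aas)
  ind[wt_aa] <- -1
  ind[mt_aa] <- 1
  delta <- property_table[mt_aa, ] - property_table[wt_aa, ]
  names(delta) <- paste0("d_", colnames(property_table))
  c(ind, delta)
}

#' Read stability mutation records
#'
#' Tab-separated with columns `protein`, `position`, `wt`, `mt`, `ddG`
#' (kcal/mol); extra columns such as solvent accessibility, pH and
#' temperature are preserved.
#'
#' @param path File path.
#' @return data.frame with an added logical `positive` column
#'   (`|ddG| > 0.5`).
#' @export
read_stability_records <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "position", "wt", "mt", "ddG")
  if (!all(need %in% names(d)))
    stop("stability file must have columns: ", paste(need, collapse = ", "))
  d$positive <- label_stability_positives(d$ddG)
  d
}
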