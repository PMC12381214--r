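#' Percent change between two values
#'
#' 100 * (value - reference) / reference. Positive for an increase,
#' negative for a decrease.
#'
#' @param reference Reference (old) value.
#' @param value New value.
#' @return Percent change.
#' @examples
#' percent_change(1372, 2210)  # ~61
#' @export
percent_change <- function(reference, value) {
  100 * (value - reference) / reference
}

#' Fold change between two values
#'
#' @param reference Reference value.
#' @param value New value.
#' @return value / reference.
#' @export
fold_change <- function(reference, value) {
  value / reference
}

#' Contour-length increment of an unfolding polypeptide segment
#'
#' Number of residues times the contour rise per residue (0.365 nm for a
#' fully extended polypeptide backbone). Used, e.g., to predict the
#' contour gain from unfolding a helix up to the nearest disulfide.
#'
#' @param n_residues Number of residues released by the unfolding.
#' @param rise_per_residue Contour length per residue in nm
#'   (default 0.365).
#' @return Contour increment in nm.
#' @examples
#' residue_contour_length(21)  # ~7.7 nm
#' @export
residue_contour_length <- function(n_residues, rise_per_residue = 0.365) {
  n_residues * rise_per_residue
}
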