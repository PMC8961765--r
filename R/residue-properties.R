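## Canonical one-letter amino-acid alphabet, alphabetical by code.
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Residue volumes (cubic Angstrom) on the Richards scale.
RICHARDS_VOLUME <- c(
  A =  88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
  Q = 143.8, E = 138.4, G =  60.1, H = 153.2, I = 166.7,
  L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
  S =  89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

## Seven strongly hydrophobic residues (default configuration).
STRONG_HYDROPHOBIC <- c("V", "I", "L", "F", "M", "W", "C")

## Side-chain charge at physiological pH.
AA_CHARGE <- c(
  A = "neutral", C = "neutral", D = "negative", E = "negative",
  F = "neutral", G = "neutral", H = "positive", I = "neutral",
  K = "positive", L = "neutral", M = "neutral", N = "neutral",
  P = "neutral", Q = "neutral", R = "positive", S = "neutral",
  T = "neutral", V = "neutral", W = "neutral", Y = "neutral")

AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

#' Residue physicochemical property table
#'
#' Bundles the per-residue constants used by the sequence-feature
#' operations: side-chain volumes on the Richards scale (cubic Angstrom),
#' the set of seven strongly hydrophobic residues, and side-chain charge
#' classes.  All three components can be overridden, e.g. to explore an
#' alternative hydrophobicity scale.
#'
#' @param volume named numeric vector, one value per canonical residue.
#' @param hydrophobic_strong character vector of strongly hydrophobic
#'   one-letter codes (the default scale defines exactly seven).
#' @param charge named character vector mapping each residue to
#'   `"positive"`, `"negative"` or `"neutral"`.
#' @return An object of class `residue_property_table`.
#' @export
#' @examples
#' tab <- residue_property_table()
#' tab$volume[["W"]] - tab$volume[["G"]]
residue_property_table <- function(volume = RICHARDS_VOLUME,
                                   hydrophobic_strong = STRONG_HYDROPHOBIC,
                                   charge = AA_CHARGE) {
  missing_vol <- setdiff(AA_CODES, names(volume))
  if (length(missing_vol) > 0L)
    stop("volume table lacks residues: ", paste(missing_vol, collapse = ", "))
  bad <- setdiff(hydrophobic_strong, AA_CODES)
  if (length(bad) > 0L)
    stop("non-canonical residues in hydrophobic set: ",
         paste(bad, collapse = ", "))
  structure(
    list(volume = volume,
         hydrophobic_strong = hydrophobic_strong,
         charge = charge),
    class = "residue_property_table")
}

check_residue <- function(aa, arg = "residue") {
  bad <- !(aa %in% AA_CODES)
  if (any(bad))
    stop("non-canonical ", arg, ": ",
         paste(unique(aa[bad]), collapse = ", "), call. = FALSE)
  invisible(aa)
}
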