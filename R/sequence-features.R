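## Sequence-level variant features: conservation lookup, Richards-scale
## volume change, hydrophobicity transition, charge change, linear
## clustering and the special physicochemical residue rules.

#' Residue volume change
#'
#' Signed side-chain volume difference (alternate minus reference) on the
#' Richards scale, with a three-way category: `large_increase` when the
#' change exceeds `cutoff`, `large_decrease` when it falls below
#' `-cutoff`, `small` otherwise.
#'
#' @param ref_aa,alt_aa one-letter residue codes (vectorised).
#' @param table a [residue_property_table()].
#' @param cutoff absolute volume change (cubic Angstrom) separating small
#'   from large changes; default 40.
#' @return list with `delta` (numeric) and `category` (character).
#' @export
#' @examples
#' volume_change("G", "W")$delta   # largest possible increase
volume_change <- function(ref_aa, alt_aa, table = residue_property_table(),
                          cutoff = 40) {
  check_residue(ref_aa, "ref")
  check_residue(alt_aa, "alt")
  delta <- unname(table$volume[alt_aa] - table$volume[ref_aa])
  category <- ifelse(delta > cutoff, "large_increase",
              ifelse(delta < -cutoff, "large_decrease", "small"))
  list(delta = delta, category = category)
}

#' Hydrophobicity transition
#'
#' Classifies a substitution with respect to the set of seven strongly
#' hydrophobic residues: `hydrophobic_to_polar` when the reference is in
#' the set and the alternate is not, `polar_to_hydrophobic` for the
#' converse, `none` otherwise.
#'
#' @inheritParams volume_change
#' @return character vector.
#' @export
hydrophobicity_transition <- function(ref_aa, alt_aa,
                                      table = residue_property_table()) {
  check_residue(ref_aa, "ref")
  check_residue(alt_aa, "alt")
  hs <- table$hydrophobic_strong
  ref_in <- ref_aa %in% hs
  alt_in <- alt_aa %in% hs
  ifelse(ref_in & !alt_in, "hydrophobic_to_polar",
  ifelse(!ref_in & alt_in, "polar_to_hydrophobic", "none"))
}

#' Charge change flag
#'
#' TRUE when reference and alternate residues belong to different charge
#' classes (positive / negative / neutral).
#'
#' @inheritParams volume_change
#' @return logical vector.
#' @export
charge_change <- function(ref_aa, alt_aa, table = residue_property_table()) {
  check_residue(ref_aa, "ref")
  check_residue(alt_aa, "alt")
  unname(table$charge[ref_aa] != table$charge[alt_aa])
}

#' Conservation grade lookup
#'
#' Returns the evolutionary conservation grade (1 = variable ... 9 = most
#' conserved) at a position from the context's conservation track, NA
#' when the track has no value there.
#'
#' @param position 1-based residue position(s).
#' @param context a [protein_context()].
#' @return integer vector in 1..9 with NA for missing.
#' @export
conservation_lookup <- function(position, context) {
  n <- length(context$sequence)
  if (any(position < 1L | position > n))
    stop("position outside 1..", n)
  tr <- context$tracks$conservation_grade
  if (is.null(tr)) return(rep(NA_integer_, length(position)))
  as.integer(tr[position])
}

#' Special physicochemical residue rules
#'
#' Three boolean flags for substitutions with outsized structural
#' consequences: proline introduced onto a beta-strand, glycine gained or
#' lost in the buried core, and cysteine gained or lost in an
#' extracellular region (potential disulfide disruption).  A missing
#' prerequisite (no secondary structure, burial or topology information)
#' yields FALSE for the corresponding flag.
#'
#' @param ref_aa,alt_aa one-letter residue codes (scalar).
#' @param secondary_structure "H", "E", "C" or NA at the variant site.
#' @param burial burial category at the site ("buried", "intermediate",
#'   "exposed" or "missing"/NA).
#' @param topology membrane topology at the site ("extracellular",
#'   "transmembrane", "cytoplasmic", "unknown" or NA).
#' @return named logical vector: proline_into_strand, glycine_core_change,
#'   cysteine_extracellular_change.
#' @export
special_rules <- function(ref_aa, alt_aa, secondary_structure = NA,
                          burial = NA, topology = NA) {
  check_residue(ref_aa, "ref")
  check_residue(alt_aa, "alt")
  pro <- !is.na(secondary_structure) && alt_aa == "P" &&
    secondary_structure == "E"
  gly <- !is.na(burial) && burial == "buried" &&
    (ref_aa == "G" || alt_aa == "G")
  cys <- !is.na(topology) && topology == "extracellular" &&
    (ref_aa == "C" || alt_aa == "C")
  c(proline_into_strand = pro, glycine_core_change = gly,
    cysteine_extracellular_change = cys)
}

#' Linear (sequence) clustering of pathogenic variants
#'
#' Number of other pathogenic variant positions within a +/- `window`
#' residue window of the query position.  The query variant itself is
#' excluded (leave-one-out), so the feature never encodes its own label.
#'
#' @param position query position (scalar).
#' @param pathogenic_positions integer vector of pathogenic variant
#'   positions; may contain the query.
#' @param window half-width in residues (default 5).
#' @param self_index optional index into `pathogenic_positions` that is
#'   the query variant itself and must be excluded.
#' @return non-negative integer count.
#' @export
cluster1d_count <- function(position, pathogenic_positions, window = 5L,
                            self_index = NA_integer_) {
  pp <- pathogenic_positions
  if (!is.na(self_index)) pp <- pp[-self_index]
  sum(abs(pp - position) <= window)
}
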