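## Structure-derived variant features: molecular goodness-of-fit,
## secondary structure (track or dihedral fallback), modelled status,
## 3D pathogenic-variant clustering, and the disorder flag.

#' Molecular goodness-of-fit violation
#'
#' TRUE when a substantially larger side chain is forced into a buried
#' (volume-constrained) site: burial is `buried` and the signed volume
#' change exceeds `cutoff` cubic Angstrom.  Missing burial yields FALSE.
#'
#' @param burial burial category at the site.
#' @param volume_delta signed volume change (alt - ref), cubic Angstrom.
#' @param cutoff minimum increase considered a poor fit (default 40).
#' @return logical vector.
#' @export
goodness_of_fit <- function(burial, volume_delta, cutoff = 40) {
  out <- !is.na(burial) & burial == "buried" &
    !is.na(volume_delta) & volume_delta > cutoff
  unname(out)
}

#' Per-position secondary structure
#'
#' Uses the context's secondary-structure track when present (values
#' returned verbatim).  Otherwise falls back to a geometric assignment
#' from backbone phi/psi dihedrals: helix (H) for runs of at least 4
#' residues with phi in (-100, -30) and psi in (-80, -5); strand (E) for
#' runs of at least 3 residues with phi in (-180, -80) and psi in
#' (60, 180); coil (C) elsewhere.  With neither track nor coordinates,
#' all positions are NA.
#'
#' @param context a [protein_context()].
#' @return character vector over positions 1..length(sequence) with
#'   values "H", "E", "C" or NA.
#' @export
assign_secondary_structure <- function(context) {
  n <- length(context$sequence)
  tr <- context$tracks$secondary_structure
  if (!is.null(tr)) return(as.character(tr))
  if (is.null(context$structure)) return(rep(NA_character_, n))
  tor <- backbone_torsions(context$structure$atoms)
  ss <- rep(NA_character_, n)
  in_h <- !is.na(tor$phi) & !is.na(tor$psi) &
    tor$phi > -100 & tor$phi < -30 & tor$psi > -80 & tor$psi < -5
  in_e <- !is.na(tor$phi) & !is.na(tor$psi) &
    tor$phi > -180 & tor$phi < -80 & tor$psi > 60 & tor$psi < 180
  assign_runs <- function(flags, min_run, code, current) {
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] && r$lengths[j] >= min_run)
        current[starts[j]:ends[j]] <- code
    }
    current
  }
  lab <- rep("C", nrow(tor))
  lab <- assign_runs(in_e, 3L, "E", lab)
  lab <- assign_runs(in_h, 4L, "H", lab)
  ss[tor$resno] <- lab
  ss
}

#' Modelled status of a position
#'
#' TRUE when the position is present in the structural model.  Unmodelled
#' variants receive sequence-based features only; all structure-derived
#' features are missing for them.
#'
#' @param position 1-based position(s).
#' @param context a [protein_context()].
#' @return logical vector.
#' @export
modelled_status <- function(position, context) {
  position %in% context$modelled_positions
}

#' 3D clustering of pathogenic variants
#'
#' Number of other pathogenic variants whose C-alpha atom lies within
#' `radius` Angstrom of the query position's C-alpha.  The query variant
#' itself is always excluded (leave-one-out), so for a pathogenic query
#' the count never reflects its own record.  Unmodelled query or
#' pathogenic positions are skipped; an unmodelled query returns NA.
#'
#' @param position query position (scalar).
#' @param pathogenic_positions integer vector of pathogenic variant
#'   positions.
#' @param structure result of [read_structure()].
#' @param radius C-alpha distance cutoff in Angstrom (default 8).
#' @param self_index optional index into `pathogenic_positions`
#'   identifying the query variant's own record, excluded from the count.
#' @return integer count, or NA when the query is unmodelled.
#' @export
cluster3d_count <- function(position, pathogenic_positions, structure,
                            radius = 8.0, self_index = NA_integer_) {
  if (is.null(structure) || !(position %in% structure$modelled_positions))
    return(NA_integer_)
  ca <- structure$atoms[structure$atoms$elety == "CA", , drop = FALSE]
  ca_xyz <- function(p) {
    r <- ca[ca$resno == p, c("x", "y", "z")]
    if (nrow(r) == 0L) return(NULL)
    as.numeric(r[1L, ])
  }
  q <- ca_xyz(position)
  if (is.null(q)) return(NA_integer_)
  pp <- pathogenic_positions
  if (!is.na(self_index)) pp <- pp[-self_index]
  cnt <- 0L
  for (p in pp) {
    xyz <- ca_xyz(p)
    if (is.null(xyz)) next
    if (sqrt(sum((xyz - q)^2)) <= radius) cnt <- cnt + 1L
  }
  cnt
}

#' Disorder flag
#'
#' TRUE when the predicted disorder probability at the position reaches
#' `cutoff` (closed cutoff: a value equal to the cutoff counts as
#' disordered).  Missing track or value yields NA.
#'
#' @param position 1-based position(s).
#' @param context a [protein_context()].
#' @param cutoff disorder probability cutoff (default 0.5).
#' @return logical vector with NA for missing.
#' @export
disordered_flag <- function(position, context, cutoff = 0.5) {
  tr <- context$tracks$disorder_prob
  if (is.null(tr)) return(rep(NA, length(position)))
  tr[position] >= cutoff
}
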