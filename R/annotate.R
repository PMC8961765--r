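## Assembly of the full per-variant feature matrix.  The catalogue is
## fixed at 22 features: sequence-derived, structure-derived and
## annotation-track features, with explicit missingness throughout.

FEATURE_CATALOGUE <- c(
  "conservation_grade", "volume_change", "volume_change_category",
  "hydro_transition", "charge_change", "rel_sasa_sidechain", "burial",
  "goodness_of_fit_violation", "disorder_prob", "disordered_flag",
  "stability_effect", "ppi_effect", "proline_into_strand",
  "glycine_core_change", "cysteine_extracellular_change", "modelled",
  "secondary_structure", "functional_site_flag", "domain_id", "topology",
  "cluster3d_count", "cluster1d_count")

#' The full feature catalogue
#'
#' Names of the 22 features a fully annotated variant carries, in the
#' column order emitted by [annotate_gene()].
#'
#' @return character vector of length 22.
#' @export
feature_catalogue <- function() FEATURE_CATALOGUE

#' Annotate variants of one gene with the 22-feature catalogue
#'
#' Computes every sequence- and structure-derived feature for each
#' variant of a gene.  Unmodelled variants (position absent from the
#' structure) receive sequence features only; their structure-derived
#' features are missing.  Pathogenic-variant clustering (3D and linear)
#' is leave-one-out: a variant's own record never contributes to its
#' count.
#'
#' @param variants data.frame as from [read_variant_table()] (single
#'   gene).
#' @param context the gene's [protein_context()].
#' @param table a [residue_property_table()].
#' @param config list of tunables: `volume_cutoff`, `fit_cutoff`
#'   (cubic Angstrom), `sasa_probe_radius`, `sasa_n_points`,
#'   `burial_buried_max`, `burial_exposed_min` (percent),
#'   `cluster_radius` (Angstrom), `cluster_window` (residues),
#'   `disorder_cutoff`.
#' @return data.frame: gene, position, ref, alt, label, then the 22
#'   feature columns, then `n_missing` (count of missing feature values
#'   per variant).
#' @export
annotate_gene <- function(variants, context,
                          table = residue_property_table(),
                          config = list()) {
  cfg <- utils::modifyList(list(
    volume_cutoff = 40, fit_cutoff = 40, sasa_probe_radius = 1.4,
    sasa_n_points = 256L, burial_buried_max = 9, burial_exposed_min = 36,
    cluster_radius = 8.0, cluster_window = 5L, disorder_cutoff = 0.5),
    config)
  stopifnot(nrow(variants) > 0L)
  n <- nrow(variants)
  pos <- variants$position
  seq_len_aa <- length(context$sequence)
  if (any(pos < 1L | pos > seq_len_aa))
    stop("variant position outside 1..", seq_len_aa)
  ## cross-check reference residues against the sequence
  mism <- which(context$sequence[pos] != variants$ref)
  if (length(mism) > 0L)
    stop("reference residue mismatch with sequence at position(s): ",
         paste(utils::head(pos[mism], 5L), collapse = ", "))

  vc <- volume_change(variants$ref, variants$alt, table,
                      cutoff = cfg$volume_cutoff)
  ss_all <- assign_secondary_structure(context)
  modelled <- modelled_status(pos, context)
  rel_sasa <- rep(NA_real_, n)
  if (!is.null(context$structure)) {
    todo <- which(modelled)
    if (length(todo) > 0L) {
      upos <- unique(pos[todo])
      us <- compute_rel_sasa(context$structure, upos,
                             probe_radius = cfg$sasa_probe_radius,
                             n_points = cfg$sasa_n_points)
      rel_sasa[todo] <- us[match(pos[todo], upos)]
    }
  }
  burial <- burial_category(rel_sasa, cfg$burial_buried_max,
                            cfg$burial_exposed_min)
  burial[!modelled] <- "missing"
  ## structure-only features are missing wherever the position is
  ## unmodelled, even when a sequence-level SS track exists
  ss <- ss_all[pos]
  ss[!modelled] <- NA

  ## leave-one-out clustering, vectorised over variants: a pathogenic
  ## variant's own record never contributes to its count
  path_idx <- which(variants$label == "pathogenic")
  path_pos <- pos[path_idx]
  self_col <- match(seq_len(n), path_idx)   # NA for non-pathogenic
  d1 <- abs(outer(pos, path_pos, "-")) <= cfg$cluster_window
  c1 <- rowSums(d1)
  c3 <- rep(NA_integer_, n)
  if (!is.null(context$structure) && length(path_idx) >= 0L) {
    at <- context$structure$atoms
    ca <- at[at$elety == "CA", , drop = FALSE]
    ca_row <- match(pos, ca$resno)          # NA if unmodelled
    pp_row <- match(path_pos, ca$resno)
    q_ok <- which(modelled & !is.na(ca_row))
    if (length(q_ok) > 0L) {
      if (length(pp_row) > 0L && any(!is.na(pp_row))) {
        qm <- as.matrix(ca[ca_row[q_ok], c("x", "y", "z")])
        pm <- as.matrix(ca[pp_row[!is.na(pp_row)], c("x", "y", "z")])
        d2 <- outer(rowSums(qm^2), rep(1, nrow(pm))) +
          outer(rep(1, nrow(qm)), rowSums(pm^2)) - 2 * qm %*% t(pm)
        near <- d2 <= cfg$cluster_radius^2 + 1e-9
        c3[q_ok] <- rowSums(near)
      } else {
        c3[q_ok] <- 0L
      }
    }
  }
  ## subtract the self record where it was counted
  is_path <- !is.na(self_col)
  c1[is_path] <- c1[is_path] - 1L
  self_modelled <- is_path & modelled & !is.na(c3)
  c3[self_modelled] <- c3[self_modelled] - 1L

  tr <- context$tracks
  track_at <- function(nm, default = NA) {
    if (is.null(tr[[nm]])) rep(default, n) else tr[[nm]][pos]
  }
  disord <- disordered_flag(pos, context, cutoff = cfg$disorder_cutoff)

  flags <- t(mapply(function(r, a, s, b, tp) {
    special_rules(r, a, secondary_structure = s, burial = b, topology = tp)
  }, variants$ref, variants$alt, ss,
     ifelse(burial == "missing", NA, burial), track_at("topology")))

  out <- data.frame(
    gene = variants$gene, position = pos, ref = variants$ref,
    alt = variants$alt, label = variants$label,
    conservation_grade = conservation_lookup(pos, context),
    volume_change = vc$delta,
    volume_change_category = vc$category,
    hydro_transition = hydrophobicity_transition(variants$ref,
                                                 variants$alt, table),
    charge_change = charge_change(variants$ref, variants$alt, table),
    rel_sasa_sidechain = rel_sasa,
    burial = burial,
    goodness_of_fit_violation = goodness_of_fit(
      ifelse(burial == "missing", NA, burial), vc$delta, cfg$fit_cutoff),
    disorder_prob = track_at("disorder_prob", NA_real_),
    disordered_flag = disord,
    stability_effect = track_at("stability_effect", NA_real_),
    ppi_effect = track_at("ppi_effect", NA_real_),
    proline_into_strand = unname(flags[, "proline_into_strand"]),
    glycine_core_change = unname(flags[, "glycine_core_change"]),
    cysteine_extracellular_change =
      unname(flags[, "cysteine_extracellular_change"]),
    modelled = modelled,
    secondary_structure = ss,
    functional_site_flag = as.logical(track_at("functional_site")),
    domain_id = as.character(track_at("domain_id", NA_character_)),
    topology = as.character(track_at("topology", NA_character_)),
    cluster3d_count = c3,
    cluster1d_count = c1,
    stringsAsFactors = FALSE)
  out$burial[out$burial == "missing"] <- NA
  out$n_missing <- rowSums(is.na(out[, FEATURE_CATALOGUE, drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Per-gene missingness report
#'
#' Counts missing values per feature over an annotated matrix.
#'
#' @param features output of [annotate_gene()].
#' @return data.frame with columns feature, n_missing, fraction.
#' @export
missingness_report <- function(features) {
  miss <- vapply(FEATURE_CATALOGUE,
                 function(f) sum(is.na(features[[f]])), integer(1L))
  data.frame(feature = FEATURE_CATALOGUE, n_missing = unname(miss),
             fraction = unname(miss) / nrow(features),
             stringsAsFactors = FALSE)
}
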