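## Core data types and table readers/writers.
##
## Variant tables, per-position annotation tracks and external predictor
## score tables are plain TSV; structures are single-chain PDB.  All
## readers validate on the way in and fail loudly with the offending line.

TRACK_NAMES <- c("conservation_grade", "disorder_prob", "stability_effect",
                 "ppi_effect", "secondary_structure", "domain_id",
                 "topology", "functional_site")

VALID_LABELS <- c("pathogenic", "benign", "unknown")
VALID_TOPOLOGY <- c("extracellular", "transmembrane", "cytoplasmic", "unknown")

variant_key <- function(v) paste(v$gene, v$position, v$ref, v$alt, sep = ":")

#' Read a missense variant table
#'
#' Parses a TSV with header columns `gene`, `position`, `ref`, `alt`,
#' `label` into a validated variant data frame.  `position` is the 1-based
#' protein residue index, `ref`/`alt` are one-letter amino-acid codes and
#' `label` is one of `pathogenic`, `benign` or `unknown`.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns gene, position, ref, alt, label and
#'   source (the file name), one row per variant, input order preserved.
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("gene", "position", "ref", "alt", "label")
  if (!all(need %in% names(tab)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  validate_variants(data.frame(
    gene = tab$gene,
    position = suppressWarnings(as.integer(tab$position)),
    ref = tab$ref, alt = tab$alt, label = tab$label,
    source = basename(path),
    stringsAsFactors = FALSE), path = path)
}

validate_variants <- function(v, path = "<data>") {
  line <- seq_len(nrow(v)) + 1L   # header is line 1
  bad <- which(is.na(v$position) | v$position < 1L)
  if (length(bad) > 0L)
    stop(sprintf("%s line %d: invalid position '%s'", path, line[bad[1L]],
                 v$position[bad[1L]]))
  bad <- which(!(v$ref %in% AA_CODES) | !(v$alt %in% AA_CODES))
  if (length(bad) > 0L)
    stop(sprintf("%s line %d: non-canonical residue in %s>%s", path,
                 line[bad[1L]], v$ref[bad[1L]], v$alt[bad[1L]]))
  bad <- which(v$ref == v$alt)
  if (length(bad) > 0L)
    stop(sprintf("%s line %d: ref equals alt (%s)", path, line[bad[1L]],
                 v$ref[bad[1L]]))
  bad <- which(!(v$label %in% VALID_LABELS))
  if (length(bad) > 0L)
    stop(sprintf("%s line %d: unknown label '%s'", path, line[bad[1L]],
                 v$label[bad[1L]]))
  dup <- duplicated(variant_key(list(gene = v$gene, position = v$position,
                                     ref = v$ref, alt = v$alt)))
  if (any(dup))
    stop(sprintf("%s line %d: duplicate variant key %s:%d:%s>%s", path,
                 line[which(dup)[1L]], v$gene[which(dup)[1L]],
                 v$position[which(dup)[1L]], v$ref[which(dup)[1L]],
                 v$alt[which(dup)[1L]]))
  v
}

#' Apply the cohort-level dataset filters
#'
#' Implements the two curation rules used to assemble per-gene training
#' sets: any benign variant whose (gene, position, ref, alt) key also
#' occurs in the pathogenic set is removed from the benign set (overlap
#' removal), and genes with fewer than `min_pathogenic` pathogenic
#' variants are excluded entirely.
#'
#' @param variants_p data.frame of pathogenic-cohort variants.
#' @param variants_b data.frame of benign-cohort variants.
#' @param min_pathogenic minimum pathogenic variant count per gene
#'   (default 70).
#' @return list with `variants` (the combined filtered data.frame),
#'   `removed_overlap` (benign rows dropped), `excluded_genes`.
#' @export
apply_dataset_filters <- function(variants_p, variants_b,
                                  min_pathogenic = 70L) {
  kp <- variant_key(list(gene = variants_p$gene, position = variants_p$position,
                         ref = variants_p$ref, alt = variants_p$alt))
  kb <- variant_key(list(gene = variants_b$gene, position = variants_b$position,
                         ref = variants_b$ref, alt = variants_b$alt))
  overlap <- kb %in% kp
  removed <- variants_b[overlap, , drop = FALSE]
  b_keep <- variants_b[!overlap, , drop = FALSE]
  counts <- table(variants_p$gene)
  keep_genes <- names(counts)[counts >= min_pathogenic]
  excluded <- setdiff(unique(c(variants_p$gene, b_keep$gene)), keep_genes)
  out <- rbind(variants_p[variants_p$gene %in% keep_genes, , drop = FALSE],
               b_keep[b_keep$gene %in% keep_genes, , drop = FALSE])
  rownames(out) <- NULL
  list(variants = out, removed_overlap = removed, excluded_genes = excluded)
}

#' Read a single-chain protein structure
#'
#' Reads ATOM records from a PDB file (via [bio3d::read.pdb]) for one
#' chain.  Alternate-location conflicts are resolved by keeping the
#' conformer with the highest occupancy, first-listed on ties.  PDB
#' residue numbers are taken as protein positions; a constant
#' `residue_offset` is added when the structure numbering is shifted
#' relative to the protein sequence.
#'
#' @param path PDB file path.
#' @param chain chain identifier; default the first chain in the file.
#' @param residue_offset constant added to PDB residue numbers.
#' @return list with `atoms` (data.frame: resno, resid, elety, elesy,
#'   x, y, z) and `modelled_positions` (sorted integer vector).
#' @export
read_structure <- function(path, chain = NULL, residue_offset = 0L) {
  if (!file.exists(path)) stop("cannot read structure: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                          rm.alt = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' not present in ", path)
  ## altloc resolution: highest occupancy, then first listed
  at$o[is.na(at$o)] <- 1
  key <- paste(at$resno, at$elety)
  ord <- order(key, -at$o, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$elety)), , drop = FALSE]
  at <- at[order(at$resno, at$eleno), , drop = FALSE]
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy) | elesy == ""))
    elesy <- substr(gsub("[0-9]", "", at$elety), 1L, 1L)
  atoms <- data.frame(
    resno = at$resno + as.integer(residue_offset),
    resid = at$resid, elety = at$elety, elesy = elesy,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  list(atoms = atoms, modelled_positions = sort(unique(atoms$resno)))
}

## Minimal PDB ATOM-record writer for the synthetic structures.
write_pdb <- function(atoms, path, chain = "A") {
  lines <- sprintf(
    "ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)), atoms$elety, "", atoms$resid, chain,
    atoms$resno, "", atoms$x, atoms$y, atoms$z, 1, 0, atoms$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Assemble a per-gene protein context
#'
#' Bundles the protein sequence, structure coordinates and per-position
#' annotation tracks for one gene.  Tracks are validated against the
#' sequence length; the residue identity at modelled positions is checked
#' against the sequence.
#'
#' @param gene_id gene symbol.
#' @param sequence amino-acid string (one-letter codes).
#' @param structure result of [read_structure()], or NULL when no
#'   structure is available.
#' @param tracks named list of per-position vectors (length = sequence
#'   length, NA allowed), as returned by [read_tracks()].
#' @return object of class `protein_context`.
#' @export
protein_context <- function(gene_id, sequence, structure = NULL,
                            tracks = list()) {
  seq_vec <- strsplit(sequence, "")[[1L]]
  check_residue(seq_vec, "sequence residue")
  n <- length(seq_vec)
  if (!is.null(structure)) {
    mp <- structure$modelled_positions
    if (any(mp < 1L | mp > n))
      stop("modelled positions outside 1..", n)
    ## cross-check residue identity where the structure names residues
    at <- structure$atoms
    res <- at[!duplicated(at$resno), c("resno", "resid")]
    res <- res[res$resid %in% names(AA_ONE), , drop = FALSE]
    mism <- res$resno[AA_ONE[res$resid] != seq_vec[res$resno]]
    if (length(mism) > 0L)
      stop("structure residue identity mismatch at position(s): ",
           paste(utils::head(mism, 5L), collapse = ", "))
  }
  bad_tracks <- setdiff(names(tracks), TRACK_NAMES)
  if (length(bad_tracks) > 0L)
    stop("unknown track(s): ", paste(bad_tracks, collapse = ", "))
  for (nm in names(tracks)) {
    if (length(tracks[[nm]]) != n)
      stop("track '", nm, "' length ", length(tracks[[nm]]),
           " != sequence length ", n)
    validate_track(nm, tracks[[nm]])
  }
  structure(
    list(gene_id = gene_id, sequence = seq_vec, structure = structure,
         modelled_positions = if (is.null(structure)) integer(0)
                              else structure$modelled_positions,
         tracks = tracks),
    class = "protein_context")
}

#' @export
print.protein_context <- function(x, ...) {
  cat(sprintf("<protein_context> %s: %d residues, %d modelled, tracks: %s\n",
              x$gene_id, length(x$sequence), length(x$modelled_positions),
              if (length(x$tracks)) paste(names(x$tracks), collapse = ", ")
              else "none"))
  invisible(x)
}

validate_track <- function(name, values) {
  ok <- !is.na(values)
  if (name == "conservation_grade") {
    if (any(ok & (values < 1 | values > 9 | values != round(values))))
      stop("conservation grade outside 1..9")
  } else if (name %in% c("disorder_prob", "stability_effect", "ppi_effect")) {
    if (any(ok & (values < 0 | values > 1)))
      stop("track '", name, "' outside [0,1]")
  } else if (name == "secondary_structure") {
    if (any(ok & !(values %in% c("H", "E", "C"))))
      stop("secondary structure values must be H/E/C")
  } else if (name == "topology") {
    if (any(ok & !(values %in% VALID_TOPOLOGY)))
      stop("topology values must be one of ",
           paste(VALID_TOPOLOGY, collapse = "/"))
  } else if (name == "functional_site") {
    if (any(ok & !(values %in% c(TRUE, FALSE, 0, 1))))
      stop("functional_site must be logical")
  }
  invisible(values)
}

#' Read per-position annotation tracks
#'
#' Reads a wide-format TSV with a `position` column plus one column per
#' track (any of `r paste(TRACK_NAMES, collapse = ", ")`).  Positions not
#' listed get NA.  Values are validated (conservation grade in 1..9,
#' probabilities in \[0,1\]).
#'
#' @param path TSV path.
#' @param seq_length protein length; track vectors are expanded to it.
#' @return named list of per-position vectors of length `seq_length`.
#' @export
read_tracks <- function(path, seq_length) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"position" %in% names(tab))
    stop("track table must have a 'position' column")
  pos <- as.integer(tab$position)
  if (any(is.na(pos) | pos < 1L | pos > seq_length))
    stop("track position outside 1..", seq_length)
  out <- list()
  for (nm in setdiff(names(tab), "position")) {
    if (!nm %in% TRACK_NAMES) stop("unknown track column: ", nm)
    raw <- tab[[nm]]
    if (nm %in% c("secondary_structure", "domain_id", "topology")) {
      v <- rep(NA_character_, seq_length)
      raw <- as.character(raw)
      raw[raw == ""] <- NA_character_
    } else if (nm == "functional_site") {
      v <- rep(NA, seq_length)
      raw <- as.logical(raw)
    } else {
      v <- rep(NA_real_, seq_length)
      raw <- as.numeric(raw)
    }
    v[pos] <- raw
    validate_track(nm, v)
    out[[nm]] <- v
  }
  out
}

#' Write per-position annotation tracks
#'
#' Inverse of [read_tracks()]: writes the wide-format TSV, one row per
#' position that carries at least one non-missing value.
#'
#' @param tracks named list of per-position vectors.
#' @param path output TSV path.
#' @export
write_tracks <- function(tracks, path) {
  n <- length(tracks[[1L]])
  df <- data.frame(position = seq_len(n))
  for (nm in names(tracks)) df[[nm]] <- tracks[[nm]]
  keep <- rowSums(!is.na(df[, -1L, drop = FALSE])) > 0L
  utils::write.table(df[keep, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an external predictor score table
#'
#' TSV with columns gene, position, ref, alt, score; scores must lie in
#' \[0,1\].  The tool name and its published default pathogenicity
#' threshold are attached as metadata.
#'
#' @param path TSV path.
#' @param tool_name predictor name (free text).
#' @param default_threshold the tool's suggested threshold in \[0,1\].
#' @return data.frame with attributes `tool_name`, `default_threshold`.
#' @export
read_score_table <- function(path, tool_name = "tool",
                             default_threshold = 0.5) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "position", "ref", "alt", "score")
  if (!all(need %in% names(tab)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  tab$score <- as.numeric(tab$score)
  bad <- which(is.na(tab$score) | tab$score < 0 | tab$score > 1)
  if (length(bad) > 0L)
    stop(sprintf("%s line %d: score outside [0,1]", path, bad[1L] + 1L))
  key <- variant_key(list(gene = tab$gene, position = tab$position,
                          ref = tab$ref, alt = tab$alt))
  if (anyDuplicated(key))
    stop("duplicate variant key in score table: ", key[anyDuplicated(key)])
  if (default_threshold < 0 || default_threshold > 1)
    stop("default_threshold outside [0,1]")
  score_table(tab, tool_name, default_threshold)
}

score_table <- function(tab, tool_name, default_threshold) {
  attr(tab, "tool_name") <- tool_name
  attr(tab, "default_threshold") <- default_threshold
  tab
}

#' Write / read a variant feature matrix
#'
#' `write_feature_matrix()` serialises an annotated feature matrix to TSV
#' with full double precision; `read_feature_matrix()` reads it back so
#' that write-then-read is the identity (categoricals exact, reals to
#' better than 1e-12).
#'
#' @param features data.frame as produced by [annotate_gene()].
#' @param path TSV path.
#' @return the path (write) or the data.frame (read).
#' @export
write_feature_matrix <- function(features, path) {
  df <- features
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- sprintf("%.17g", df[[nm]])
    if (is.logical(df[[nm]])) df[[nm]] <- ifelse(is.na(df[[nm]]), NA,
                                                 ifelse(df[[nm]], "TRUE", "FALSE"))
  }
  for (nm in names(df)) df[[nm]][is.na(features[[nm]])] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  for (nm in intersect(names(df), c("modelled", "proline_into_strand",
                                    "glycine_core_change",
                                    "cysteine_extracellular_change",
                                    "charge_change", "disordered_flag",
                                    "goodness_of_fit_violation",
                                    "functional_site_flag"))) {
    df[[nm]] <- as.logical(df[[nm]])
  }
  df
}
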