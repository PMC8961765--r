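## Deterministic synthetic-data generation: toy protein structures with
## controllable burial, class-conditional per-gene variant cohorts with
## annotation tracks, and Beta-distributed external predictor scores
## with a known optimal threshold.  Everything the pipeline consumes can
## be generated here, with no downloads.

#' Build a toy protein structure
#'
#' Generates an idealised backbone (N, CA, C, O and a CB side-chain
#' pseudo-atom) for one of three folds: `helix` (phi = -57, psi = -47),
#' `strand` (phi = -120, psi = 130) or `packed_globule` (an antiparallel
#' four-helix bundle, giving genuinely buried core residues).  The
#' result parses back through [read_structure()].
#'
#' @param n_residues chain length (>= 5).
#' @param fold one of `"helix"`, `"strand"`, `"packed_globule"`.
#' @param seed seed for the random sequence (ignored when `sequence`
#'   given).
#' @param sequence optional one-letter sequence of length `n_residues`.
#' @param bundle_spacing centre-to-centre helix spacing (Angstrom) of
#'   the globule fold (default 10).
#' @return list with `atoms` (data.frame as in [read_structure()]),
#'   `modelled_positions`, `sequence`.
#' @export
make_toy_structure <- function(n_residues,
                               fold = c("helix", "strand",
                                        "packed_globule"),
                               seed = 1L, sequence = NULL,
                               bundle_spacing = 10) {
  fold <- match.arg(fold)
  stopifnot(n_residues >= 5L)
  if (is.null(sequence)) {
    sequence <- with_seed(seed,
      sample(AA_CODES, n_residues, replace = TRUE))
  } else if (is.character(sequence) && length(sequence) == 1L) {
    sequence <- strsplit(sequence, "")[[1L]]
  }
  stopifnot(length(sequence) == n_residues)
  if (fold == "helix") {
    atoms <- build_backbone(rep(-57, n_residues), rep(-47, n_residues),
                            sequence)
  } else if (fold == "strand") {
    atoms <- build_backbone(rep(-120, n_residues), rep(130, n_residues),
                            sequence)
  } else {
    atoms <- build_bundle(n_residues, sequence, bundle_spacing)
  }
  list(atoms = atoms, modelled_positions = sort(unique(atoms$resno)),
       sequence = sequence)
}

## Antiparallel four-helix bundle with continuous residue numbering.
build_bundle <- function(n_residues, sequence, spacing) {
  n_helix <- 4L
  per <- ceiling(n_residues / n_helix)
  offsets <- list(c(0, 0, 0), c(spacing, 0, 0),
                  c(0, spacing, 0), c(spacing, spacing, 0))
  segs <- list()
  start <- 1L
  for (h in seq_len(n_helix)) {
    end <- min(start + per - 1L, n_residues)
    if (start > end) break
    seq_h <- sequence[start:end]
    seg <- build_backbone(rep(-57, length(seq_h)), rep(-47, length(seq_h)),
                          seq_h)
    xyz <- as.matrix(seg[, c("x", "y", "z")])
    ## align the helix axis (first-to-last CA) with z
    ca <- xyz[seg$elety == "CA", , drop = FALSE]
    axis <- ca[nrow(ca), ] - ca[1L, ]
    xyz <- xyz %*% t(rotation_to_z(axis))
    if (h %% 2L == 0L) {  # antiparallel: flip alternate helices
      xyz[, 3L] <- -xyz[, 3L]
      xyz[, 1L] <- -xyz[, 1L]
    }
    xyz <- sweep(xyz, 2L, colMeans(xyz), "-")
    xyz <- sweep(xyz, 2L, unlist(offsets[[h]]), "+")
    seg$x <- xyz[, 1L]; seg$y <- xyz[, 2L]; seg$z <- xyz[, 3L]
    seg$resno <- seg$resno + start - 1L
    segs[[h]] <- seg
    start <- end + 1L
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

## Rotation matrix sending `axis` to the +z direction (Rodrigues).
rotation_to_z <- function(axis) {
  a <- unitv(axis)
  z <- c(0, 0, 1)
  v <- cross3(a, z)
  s <- vnorm(v)
  c_ <- sum(a * z)
  if (s < 1e-12)
    return(diag(3) * ifelse(c_ > 0, 1, -1))
  vx <- matrix(c(0, -v[3L], v[2L], v[3L], 0, -v[1L], -v[2L], v[1L], 0),
               3L, 3L, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

#' Specification for one synthetic gene cohort
#'
#' Collects the generator's knobs: cohort sizes, sequence length, the
#' class-conditional effect profile and the unmodelled fraction.  The
#' effect probabilities give, per class, the chance that a variant is
#' placed at a highly conserved (grade 8-9) position, at a buried
#' position, and that its substitution is drastic (large volume change).
#' Equal probabilities across classes mean no signal.
#'
#' @param gene_id gene symbol.
#' @param n_pathogenic,n_benign cohort sizes.
#' @param seq_length protein length (default 240).
#' @param p_high_cons length-2 named vector (pathogenic, benign).
#' @param p_buried length-2 named vector (pathogenic, benign).
#' @param p_drastic length-2 named vector (pathogenic, benign).
#' @param stability_beta list of length-2 Beta parameters per class for
#'   the stability/PPI tracks at variant-favoured positions.
#' @param unmodelled_fraction fraction of C-terminal positions absent
#'   from the structure (default 0.2).
#' @param seed integer seed.
#' @return list of class `gene_sim_spec`.
#' @export
gene_sim_spec <- function(gene_id = "GENE1", n_pathogenic = 100L,
                          n_benign = 60L, seq_length = 240L,
                          p_high_cons = c(pathogenic = 0.9, benign = 0.2),
                          p_buried = c(pathogenic = 0.6, benign = 0.15),
                          p_drastic = c(pathogenic = 0.5, benign = 0.15),
                          stability_beta = list(high = c(5, 2),
                                                low = c(2, 5)),
                          unmodelled_fraction = 0.2, seed = 1L) {
  stopifnot(n_pathogenic > 0L, n_benign > 0L, seq_length >= 40L,
            unmodelled_fraction >= 0, unmodelled_fraction < 1)
  structure(list(gene_id = gene_id, n_pathogenic = n_pathogenic,
                 n_benign = n_benign, seq_length = seq_length,
                 p_high_cons = p_high_cons, p_buried = p_buried,
                 p_drastic = p_drastic, stability_beta = stability_beta,
                 unmodelled_fraction = unmodelled_fraction, seed = seed),
            class = "gene_sim_spec")
}

#' Simulate one gene's variant cohort with context
#'
#' Draws a random protein sequence, builds a four-helix-bundle structure
#' over the modelled region (the C-terminal `unmodelled_fraction` of the
#' protein is left without coordinates), generates annotation tracks
#' (conservation grades, disorder probabilities, stability and
#' interaction effects, domains, topology, functional sites) and samples
#' pathogenic and benign variants whose positions follow the
#' class-conditional effect profile: pathogenic variants favour
#' conserved and buried positions, benign variants variable and exposed
#' ones.  Fully deterministic given the spec's seed.
#'
#' @param spec a [gene_sim_spec()].
#' @return list: `variants` (data.frame gene/position/ref/alt/label),
#'   `context` ([protein_context()]), `spec`.
#' @export
simulate_gene_dataset <- function(spec) {
  stopifnot(inherits(spec, "gene_sim_spec"))
  with_seed(spec$seed, {
    L <- spec$seq_length
    sequence <- sample(AA_CODES, L, replace = TRUE)
    n_model <- round(L * (1 - spec$unmodelled_fraction))
    struct <- NULL
    burial <- rep(NA_character_, L)
    if (n_model >= 20L) {
      toy <- make_toy_structure(n_model, "packed_globule",
                                sequence = sequence[seq_len(n_model)])
      struct <- list(atoms = toy$atoms,
                     modelled_positions = toy$modelled_positions)
      rs <- compute_rel_sasa(struct, seq_len(n_model))
      burial[seq_len(n_model)] <- burial_category(rs)
    }
    ## tracks
    high_cons <- runif(L) < 0.35
    grade <- ifelse(high_cons, sample(8:9, L, replace = TRUE),
                    sample(1:7, L, replace = TRUE))
    disorder <- ifelse(seq_len(L) <= n_model,
                       stats::rbeta(L, 2, 8), stats::rbeta(L, 6, 3))
    sb_hi <- spec$stability_beta$high
    sb_lo <- spec$stability_beta$low
    stability <- ifelse(high_cons, stats::rbeta(L, sb_hi[1L], sb_hi[2L]),
                        stats::rbeta(L, sb_lo[1L], sb_lo[2L]))
    ppi <- ifelse(high_cons, stats::rbeta(L, sb_hi[1L], sb_hi[2L]),
                  stats::rbeta(L, sb_lo[1L], sb_lo[2L]))
    third <- floor(L / 3)
    topology <- c(rep("extracellular", third),
                  rep("transmembrane", floor(L / 6)),
                  rep("cytoplasmic", L - third - floor(L / 6)))
    domain <- paste0("D", pmin(3L, 1L + (seq_len(L) - 1L) %/% ceiling(L / 3)))
    fsite <- runif(L) < 0.05
    tracks <- list(conservation_grade = grade, disorder_prob = disorder,
                   stability_effect = stability, ppi_effect = ppi,
                   domain_id = domain, topology = topology,
                   functional_site = fsite)
    ## class-conditional position weights
    pos_weight <- function(class) {
      phc <- spec$p_high_cons[[class]]
      pbu <- spec$p_buried[[class]]
      w_cons <- ifelse(grade >= 8, phc, 1 - phc)
      is_buried <- !is.na(burial) & burial == "buried"
      w_bur <- ifelse(is_buried, pbu, 1 - pbu)
      w <- w_cons * w_bur
      w / sum(w)
    }
    keys <- character(0)   # (pos, ref, alt) unique across both classes
    draw_variants <- function(n, class, label) {
      w <- pos_weight(class)
      pd <- spec$p_drastic[[class]]
      out <- list()
      guard <- 0L
      while (length(out) < n && guard < 50L * n) {
        guard <- guard + 1L
        pos <- sample.int(L, 1L, prob = w)
        ref <- sequence[pos]
        drastic <- runif(1) < pd
        cand <- setdiff(AA_CODES, ref)
        if (drastic) {
          big <- cand[abs(RICHARDS_VOLUME[cand] -
                            RICHARDS_VOLUME[[ref]]) > 40]
          if (length(big) > 0L) cand <- big
        }
        alt <- sample(cand, 1L)
        key <- paste(pos, ref, alt)
        if (key %in% keys) next
        keys <<- c(keys, key)
        out[[length(out) + 1L]] <- data.frame(
          gene = spec$gene_id, position = pos, ref = ref, alt = alt,
          label = label, stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }
    variants <- rbind(draw_variants(spec$n_pathogenic, "pathogenic",
                                    "pathogenic"),
                      draw_variants(spec$n_benign, "benign", "benign"))
    rownames(variants) <- NULL
    context <- protein_context(spec$gene_id,
                               paste(sequence, collapse = ""),
                               structure = struct, tracks = tracks)
    list(variants = variants, context = context, spec = spec)
  })
}

#' Simulate an external predictor score table
#'
#' Class-conditional Beta-distributed scores with a known optimal
#' threshold: pathogenic scores ~ Beta(a_P, b_P), benign scores ~
#' Beta(a_B, b_B).  The analytic crossing point of the two densities
#' (the Bayes cut under equal priors) is attached as attribute
#' `crossing`.
#'
#' @param n_path,n_benign cohort sizes.
#' @param beta_path,beta_benign length-2 shape parameter vectors.
#' @param seed integer seed.
#' @param gene_id gene symbol attached to the table.
#' @return data.frame with columns gene, score, label (1 = pathogenic)
#'   and attribute `crossing`.
#' @export
simulate_score_table <- function(n_path, n_benign, beta_path = c(8, 2),
                                 beta_benign = c(2, 8), seed = 1L,
                                 gene_id = "GENE1") {
  stopifnot(all(beta_path > 0), all(beta_benign > 0))
  out <- with_seed(seed, data.frame(
    gene = gene_id,
    score = c(stats::rbeta(n_path, beta_path[1L], beta_path[2L]),
              stats::rbeta(n_benign, beta_benign[1L], beta_benign[2L])),
    label = rep(c(1L, 0L), c(n_path, n_benign)),
    stringsAsFactors = FALSE))
  attr(out, "crossing") <- beta_density_crossing(beta_path, beta_benign)
  out
}

## Crossing point of two Beta densities in (0, 1), if any.
beta_density_crossing <- function(p1, p2) {
  f <- function(x) {
    stats::dbeta(x, p1[1L], p1[2L], log = TRUE) -
      stats::dbeta(x, p2[1L], p2[2L], log = TRUE)
  }
  grid <- seq(0.001, 0.999, length.out = 999)
  v <- f(grid)
  sw <- which(diff(sign(v)) != 0)
  if (length(sw) == 0L) return(NA_real_)
  stats::uniroot(f, c(grid[sw[1L]], grid[sw[1L] + 1L]))$root
}

#' Simulate a multi-gene panel
#'
#' Generates a panel of synthetic gene cohorts spanning realistic
#' imbalance: per-gene pathogenic counts drawn from 70-600 and benign
#' counts from 15-200, with gene-to-gene variation in effect strength
#' and per-gene external predictor score tables whose generating optimal
#' threshold varies across genes.
#'
#' @param n_genes number of genes (default 21).
#' @param seed integer seed.
#' @param seq_length protein length for all genes.
#' @return named list (per gene) of lists with elements `data`
#'   (from [simulate_gene_dataset()]) and `scores`
#'   (from [simulate_score_table()]).
#' @export
simulate_gene_panel <- function(n_genes = 21L, seed = 1L,
                                seq_length = 240L) {
  cfg <- with_seed(seed, data.frame(
    n_path = sample(70:600, n_genes, replace = TRUE),
    n_benign = sample(15:200, n_genes, replace = TRUE),
    phc_path = runif(n_genes, 0.75, 0.95),
    phc_ben = runif(n_genes, 0.1, 0.3),
    a_path = runif(n_genes, 4, 12),
    b_path = runif(n_genes, 1.5, 4),
    gene_seed = sample.int(1e6, n_genes)))
  out <- list()
  for (i in seq_len(n_genes)) {
    gid <- sprintf("SYN%02d", i)
    spec <- gene_sim_spec(
      gene_id = gid, n_pathogenic = cfg$n_path[i],
      n_benign = cfg$n_benign[i], seq_length = seq_length,
      p_high_cons = c(pathogenic = cfg$phc_path[i],
                      benign = cfg$phc_ben[i]),
      seed = cfg$gene_seed[i])
    dat <- simulate_gene_dataset(spec)
    scores <- simulate_score_table(
      cfg$n_path[i], cfg$n_benign[i],
      beta_path = c(cfg$a_path[i], cfg$b_path[i]),
      beta_benign = c(cfg$b_path[i], cfg$a_path[i]),
      seed = cfg$gene_seed[i] + 1L, gene_id = gid)
    out[[gid]] <- list(data = dat, scores = scores)
  }
  out
}

#' Write a simulated gene cohort to a ready-to-run directory
#'
#' Serialises one simulated gene to the plain-text formats the readers
#' consume: `variants.tsv`, `structure.pdb`, `tracks.tsv`,
#' `scores_<tool>.tsv` and `spec.yaml`.
#'
#' @param sim result of [simulate_gene_dataset()].
#' @param dir output directory (created if needed).
#' @param scores optional data.frame from [simulate_score_table()].
#' @param tool_name name used in the score file name.
#' @return the directory path.
#' @export
write_gene_dataset <- function(sim, dir, scores = NULL,
                               tool_name = "simtool") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(sim$variants[, c("gene", "position", "ref", "alt",
                                      "label")],
                     file.path(dir, "variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$context$structure))
    write_pdb(sim$context$structure$atoms, file.path(dir, "structure.pdb"))
  write_tracks(sim$context$tracks, file.path(dir, "tracks.tsv"))
  writeLines(paste(sim$context$sequence, collapse = ""),
             file.path(dir, "sequence.txt"))
  if (!is.null(scores)) {
    ## attach scores to variant keys in order (pathogenic then benign)
    sc <- data.frame(gene = sim$variants$gene,
                     position = sim$variants$position,
                     ref = sim$variants$ref, alt = sim$variants$alt,
                     score = NA_real_)
    lab <- as.integer(sim$variants$label == "pathogenic")
    sc$score[lab == 1L] <- scores$score[scores$label == 1L][
      seq_len(sum(lab == 1L))]
    sc$score[lab == 0L] <- scores$score[scores$label == 0L][
      seq_len(sum(lab == 0L))]
    utils::write.table(sc, file.path(dir,
                                     sprintf("scores_%s.tsv", tool_name)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sp <- sim$spec
  yaml::write_yaml(lapply(unclass(sp), function(x)
    if (is.numeric(x)) unname(x) else x), file.path(dir, "spec.yaml"))
  invisible(dir)
}
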