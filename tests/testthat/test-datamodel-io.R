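test_that("variant tables parse, validate and preserve order", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  rows <- data.frame(
    gene = "G6PD", position = c(68, 10, 20, 30, 40, 50, 60, 70, 80, 90),
    ref = c("V", "A", "L", "G", "R", "C", "P", "W", "T", "S"),
    alt = c("M", "T", "P", "D", "H", "Y", "L", "R", "I", "N"),
    label = rep(c("pathogenic", "benign"), 5))
  write.table(rows, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  v <- read_variant_table(tmp)
  expect_equal(nrow(v), 10L)
  expect_equal(v$position, rows$position)   # order preserved
  expect_equal(v$gene[1], "G6PD")
  expect_equal(v$ref[1], "V")
  expect_equal(v$label[1], "pathogenic")

  # duplicate key rejected
  write.table(rows[c(1:3, 1), ], tmp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_variant_table(tmp), "duplicate")

  # non-canonical residue, ref == alt, bad label all rejected with line
  bad <- rows[1:2, ]; bad$ref[2] <- "X"
  write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_variant_table(tmp), "line 3.*non-canonical")
  bad <- rows[1:2, ]; bad$alt[1] <- bad$ref[1]
  write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_variant_table(tmp), "ref equals alt")
})

test_that("dataset filters remove P/B overlap and low-count genes", {
  mkv <- function(gene, pos, ref, alt, label)
    data.frame(gene = gene, position = pos, ref = ref, alt = alt,
               label = label, stringsAsFactors = FALSE)
  P <- mkv("g", 10, "A", "V", "pathogenic")
  B <- rbind(mkv("g", 10, "A", "V", "benign"),
             mkv("g", 12, "L", "P", "benign"))
  res <- apply_dataset_filters(P, B, min_pathogenic = 1L)
  expect_equal(nrow(res$removed_overlap), 1L)
  kept_b <- res$variants[res$variants$label == "benign", ]
  expect_equal(kept_b$position, 12)

  # boundary: 69 pathogenic excluded at threshold 70, 70 retained
  p69 <- mkv("gA", 1:69, "A", "V", "pathogenic")
  p70 <- mkv("gB", 1:70, "A", "V", "pathogenic")
  res2 <- apply_dataset_filters(rbind(p69, p70), B[0, ])
  expect_equal(res2$excluded_genes, "gA")
  expect_true(all(res2$variants$gene == "gB"))

  # counting against the threshold across three genes
  panel <- rbind(mkv("x1", 1:80, "A", "V", "pathogenic"),
                 mkv("x2", 1:70, "A", "V", "pathogenic"),
                 mkv("x3", 1:50, "A", "V", "pathogenic"))
  res3 <- apply_dataset_filters(panel, B[0, ])
  expect_setequal(unique(res3$variants$gene), c("x1", "x2"))

  # idempotence
  res4 <- apply_dataset_filters(
    res3$variants[res3$variants$label == "pathogenic", ], B[0, ])
  expect_equal(res4$variants, res3$variants)
})

test_that("PDB structures read back with altloc and offset handling", {
  toy <- make_toy_structure(30, "helix", seed = 1)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  prospr:::write_pdb(toy$atoms, tmp)
  st <- read_structure(tmp)
  expect_equal(st$modelled_positions, 1:30)
  expect_equal(nrow(st$atoms), nrow(toy$atoms))
  expect_equal(st$atoms$x, toy$atoms$x, tolerance = 1e-3)

  # a gap: residues 5..20 of a 40-residue protein
  sub <- toy$atoms[toy$atoms$resno %in% 5:20, ]
  prospr:::write_pdb(sub, tmp)
  expect_equal(read_structure(tmp)$modelled_positions, 5:20)

  # constant offset
  expect_equal(read_structure(tmp, residue_offset = 3L)$modelled_positions,
               8:23)

  # altloc conflict: keep highest occupancy
  lines <- readLines(tmp)
  ca <- grep("ATOM", lines)[2]   # a CA record
  a1 <- lines[ca]; substr(a1, 17, 17) <- "A"
  substr(a1, 55, 60) <- "  0.30"
  a2 <- a1; substr(a2, 17, 17) <- "B"
  substr(a2, 55, 60) <- "  0.70"
  substr(a2, 31, 38) <- "  99.000"
  writeLines(c(lines[seq_len(ca - 1)], a1, a2,
               lines[seq(ca + 1, length(lines))]), tmp)
  st2 <- read_structure(tmp)
  picked <- st2$atoms[st2$atoms$resno == 5 & st2$atoms$elety == "CA", ]
  expect_equal(nrow(picked), 1L)
  expect_equal(picked$x, 99)

  expect_error(read_structure(tmp, chain = "Z"), "chain")
  expect_error(read_structure("no/such/file.pdb"))
})

test_that("tracks validate ranges and round-trip exactly", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tconservation_grade", "12\t9"), tmp)
  tr <- read_tracks(tmp, seq_length = 20)
  expect_equal(tr$conservation_grade[12], 9)
  expect_true(is.na(tr$conservation_grade[1]))

  writeLines(c("position\tconservation_grade", "3\t12"), tmp)
  expect_error(read_tracks(tmp, 20), "grade")
  writeLines(c("position\tdisorder_prob", "3\t1.2"), tmp)
  expect_error(read_tracks(tmp, 20), "\\[0,1\\]")

  full <- list(conservation_grade = c(1, 9, NA, 5),
               disorder_prob = c(0.25, NA, 1, 0),
               secondary_structure = c("H", "E", "C", NA))
  write_tracks(full, tmp)
  back <- read_tracks(tmp, 4)
  expect_identical(back$conservation_grade, full$conservation_grade)
  expect_identical(back$disorder_prob, full$disorder_prob)
  expect_identical(back$secondary_structure, full$secondary_structure)
})

test_that("score tables validate range and uniqueness", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene = "g", position = c(1, 2), ref = c("A", "L"),
                   alt = c("V", "P"), score = c(0.2, 0.9))
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  st <- read_score_table(tmp, tool_name = "VEST4", default_threshold = 0.5)
  expect_equal(attr(st, "tool_name"), "VEST4")
  expect_equal(st$score, c(0.2, 0.9))

  df$score[2] <- 1.2
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_score_table(tmp), "line 3.*\\[0,1\\]")
})

test_that("feature matrices round-trip through TSV exactly", {
  sim <- simulate_gene_dataset(gene_sim_spec(n_pathogenic = 15,
                                             n_benign = 10,
                                             seq_length = 60,
                                             seed = 2))
  ann <- annotate_gene(sim$variants, sim$context)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(ann, tmp)
  back <- read_feature_matrix(tmp)
  for (nm in feature_catalogue()) {
    if (is.numeric(ann[[nm]])) {
      expect_equal(back[[nm]], as.numeric(ann[[nm]]), tolerance = 1e-14,
                   label = nm)
    } else {
      expect_identical(as.character(back[[nm]]), as.character(ann[[nm]]),
                       label = nm)
    }
  }
  # serialisation idempotence: a second write is byte-identical
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("protein context enforces track and structure consistency", {
  toy <- make_toy_structure(10, "helix", seed = 3)
  seq_str <- paste(toy$sequence, collapse = "")
  ctx <- protein_context("g", seq_str,
                         structure = list(atoms = toy$atoms,
                                          modelled_positions = 1:10))
  expect_s3_class(ctx, "protein_context")
  # residue identity mismatch is caught
  wrong <- seq_str
  substr(wrong, 1, 1) <- setdiff(c("A", "G"), substr(seq_str, 1, 1))[1]
  expect_error(protein_context("g", wrong,
                               structure = list(atoms = toy$atoms,
                                                modelled_positions = 1:10)),
               "mismatch")
  expect_error(protein_context("g", seq_str,
                               tracks = list(conservation_grade = 1:3)),
               "length")
})
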