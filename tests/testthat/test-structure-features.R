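test_that("relative side-chain accessibility behaves like an exposure scale", {
  # a single isolated residue is at least as exposed as the tripeptide
  # reference state
  iso <- make_toy_structure(5, "strand", seed = 8)
  st <- list(atoms = iso$atoms[iso$atoms$resno == 3, ],
             modelled_positions = 3L)
  expect_gte(compute_rel_sasa(st, 3), 95)

  # buried core residues of a packed bundle drop below 10%
  g <- make_toy_structure(80, "packed_globule", seed = 2)
  stg <- list(atoms = g$atoms, modelled_positions = g$modelled_positions)
  rs <- compute_rel_sasa(stg, 1:80)
  expect_gte(sum(rs < 10), 3L)
  expect_true(all(rs >= 0))

  # unmodelled position gives NA
  expect_true(is.na(compute_rel_sasa(stg, 81)))
})

test_that("accessibility is invariant under rigid transforms", {
  g <- make_toy_structure(40, "packed_globule", seed = 5)
  st <- list(atoms = g$atoms, modelled_positions = g$modelled_positions)
  base <- compute_rel_sasa(st, c(3, 11, 22, 37))
  set.seed(99)
  for (rep in 1:3) {
    th <- runif(3, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                   0, sin(th[1]), cos(th[1])), 3, 3, byrow = TRUE)
    Rz <- matrix(c(cos(th[2]), -sin(th[2]), 0,
                   sin(th[2]), cos(th[2]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    a2 <- g$atoms
    xyz <- as.matrix(a2[, c("x", "y", "z")]) %*% (Rx %*% Rz)
    xyz <- sweep(xyz, 2, runif(3, -20, 20), "+")
    a2$x <- xyz[, 1]; a2$y <- xyz[, 2]; a2$z <- xyz[, 3]
    moved <- compute_rel_sasa(list(atoms = a2,
                                   modelled_positions = st$modelled_positions),
                              c(3, 11, 22, 37))
    expect_lt(max(abs(moved - base) / pmax(base, 1)), 1e-6)
  }
})

test_that("doubling the sphere-point count moves values by < 2 points", {
  for (fold in c("helix", "strand", "packed_globule")) {
    s <- make_toy_structure(40, fold, seed = 7)
    st <- list(atoms = s$atoms, modelled_positions = s$modelled_positions)
    a <- compute_rel_sasa(st, 1:40, n_points = 256L)
    b <- compute_rel_sasa(st, 1:40, n_points = 512L)
    expect_lt(max(abs(b - a)), 2)
  }
})

test_that("burial bins follow the 9/36 convention with closed right edge", {
  expect_equal(burial_category(5), "buried")
  expect_equal(burial_category(9), "intermediate")
  expect_equal(burial_category(36), "intermediate")
  expect_equal(burial_category(36.01), "exposed")
  expect_equal(burial_category(NA), "missing")
  expect_error(burial_category(-1), "negative")
})

test_that("goodness of fit flags large residues forced into buried sites", {
  gw <- volume_change("G", "W")$delta
  expect_true(goodness_of_fit("buried", gw))
  expect_false(goodness_of_fit("exposed", gw))
  ts <- volume_change("T", "S")$delta
  expect_false(goodness_of_fit("buried", ts))
  expect_false(goodness_of_fit(NA, gw))
})

test_that("secondary structure uses the track first, dihedrals otherwise", {
  # track precedence: values returned verbatim
  ctx <- toy_context(12)
  ctx$tracks$secondary_structure <- rep(c("H", "E", "C"), 4)
  expect_equal(assign_secondary_structure(ctx), rep(c("H", "E", "C"), 4))

  # ideal helix -> interior H
  hel <- toy_context(20, tracks = FALSE)
  ss <- assign_secondary_structure(hel)
  expect_true(all(ss[3:18] == "H"))

  # ideal strand -> E
  str_ctx <- toy_context(12, fold = "strand", tracks = FALSE)
  ss2 <- assign_secondary_structure(str_ctx)
  expect_true(all(ss2[2:11] == "E"))

  # no track, no structure -> all missing
  bare <- toy_context(10, tracks = FALSE, structure = FALSE)
  expect_true(all(is.na(assign_secondary_structure(bare))))
})

test_that("modelled status reflects structure coverage", {
  ctx <- toy_context(30)
  expect_true(modelled_status(10, ctx))
  mp <- ctx$structure$modelled_positions
  ctx$structure$modelled_positions <- mp[mp >= 5 & mp <= 20]
  ctx$modelled_positions <- ctx$structure$modelled_positions
  expect_true(modelled_status(10, ctx))
  expect_false(modelled_status(30, ctx))
  bare <- toy_context(10, structure = FALSE)
  expect_false(any(modelled_status(1:10, bare)))
})

test_that("3D clustering counts neighbours leave-one-out and matches brute force", {
  hel <- make_toy_structure(30, "helix", seed = 4)
  st <- list(atoms = hel$atoms, modelled_positions = hel$modelled_positions)
  # no other pathogenic variants
  expect_equal(cluster3d_count(10, integer(0), st), 0L)

  # unmodelled query
  expect_true(is.na(cluster3d_count(31, c(1, 2), st)))

  # brute-force agreement on a packed structure with many sites
  g <- make_toy_structure(50, "packed_globule", seed = 6)
  stg <- list(atoms = g$atoms, modelled_positions = g$modelled_positions)
  ca <- g$atoms[g$atoms$elety == "CA", ]
  set.seed(11)
  sites <- sample(1:50, 20)
  for (q in c(5, 17, 33, 44)) {
    mine <- cluster3d_count(q, sites, stg, radius = 8)
    qxyz <- as.numeric(ca[ca$resno == q, c("x", "y", "z")])
    oxyz <- as.matrix(ca[match(sites, ca$resno), c("x", "y", "z")])
    expect_equal(mine, oracle_cluster3d(qxyz, oxyz, 8))
  }

  # leave-one-out: the query's own record never changes its count
  sites2 <- c(10, 12, 20)
  with_self <- cluster3d_count(12, sites2, stg, self_index = 2L)
  without <- cluster3d_count(12, c(10, 20), stg)
  expect_equal(with_self, without)
})

test_that("disorder flag applies the closed 0.5 cutoff", {
  ctx <- toy_context(30)
  ctx$tracks$disorder_prob <- c(0.9, 0.5, 0.49, rep(NA, 27))
  expect_true(disordered_flag(1, ctx))
  expect_true(disordered_flag(2, ctx))
  expect_false(disordered_flag(3, ctx))
  expect_true(is.na(disordered_flag(4, ctx)))
  bare <- toy_context(10, tracks = FALSE)
  expect_true(is.na(disordered_flag(1, bare)))
})

test_that("annotation emits the full catalogue with structure-missing logic", {
  sim <- simulate_gene_dataset(gene_sim_spec(n_pathogenic = 20,
                                             n_benign = 15,
                                             seq_length = 80,
                                             unmodelled_fraction = 0.3,
                                             seed = 9))
  ann <- annotate_gene(sim$variants, sim$context)
  expect_true(all(feature_catalogue() %in% names(ann)))
  expect_length(feature_catalogue(), 22L)

  # unmodelled variants: structure-only features all missing
  un <- ann[!ann$modelled, ]
  if (nrow(un) > 0) {
    expect_true(all(is.na(un$rel_sasa_sidechain)))
    expect_true(all(is.na(un$burial)))
    expect_true(all(is.na(un$secondary_structure)))
    expect_true(all(is.na(un$cluster3d_count)))
  }
  # modelled variants carry accessibility and burial
  mo <- ann[ann$modelled, ]
  expect_true(all(!is.na(mo$rel_sasa_sidechain)))
  expect_true(all(mo$burial %in% c("buried", "intermediate", "exposed")))

  # determinism
  ann2 <- annotate_gene(sim$variants, sim$context)
  expect_identical(ann, ann2)

  # missingness report covers every feature
  rep_ <- missingness_report(ann)
  expect_equal(rep_$feature, feature_catalogue())
  expect_true(all(rep_$n_missing[rep_$feature == "rel_sasa_sidechain"] ==
                    sum(!ann$modelled)))
})
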