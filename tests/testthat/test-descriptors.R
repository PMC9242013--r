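# Descriptors: bond perception, PEOE, EState, Sterimol, buried volume,
# SASA, and their invariances.

test_that("perceive_bonds applies the covalent-radius rule", {
  near <- qc_structure(c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)))
  far <- qc_structure(c("C", "C"), rbind(c(0, 0, 0), c(3.0, 0, 0)))
  expect_equal(nrow(perceive_bonds(near, 1.2)), 1L)
  expect_equal(nrow(perceive_bonds(far, 1.2)), 0L)
})

test_that("generated fixtures reproduce their intended bond graph", {
  gen <- generate_reactions(3, out_dir = withr::local_tempdir(), seed = 8,
                            noise_sd = 0)
  rx <- load_manifest(gen$manifest_path)
  for (id in names(rx)) {
    ma <- get_record(rx[[id]], "DFT", "MA")$structure
    got <- perceive_bonds(ma)
    want <- gen$ground_truth[[id]]$bonds_ma
    canon <- function(b) {
      b <- cbind(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
      b[order(b[, 1], b[, 2]), , drop = FALSE]
    }
    expect_equal(canon(unclass(got)[, 1:2]), canon(as.matrix(want)),
                 ignore_attr = TRUE)
  }
})

test_that("PEOE charges: symmetry, conservation, reference values", {
  # homonuclear diatomic: both zero by symmetry
  h2 <- qc_structure(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
  expect_equal(peoe_charges(h2), c(0, 0), tolerance = 1e-12)

  # conservation for arbitrary fixtures, including charged species
  gen <- generate_reactions(2, out_dir = withr::local_tempdir(), seed = 2,
                            noise_sd = 0)
  rx <- load_manifest(gen$manifest_path)
  for (role in c("MA", "nucleophile")) {
    s <- get_record(rx[[1]], "DFT", role)$structure
    q <- peoe_charges(s)
    expect_equal(sum(q), s$net_charge, tolerance = 1e-6)
  }

  # carbonyl fixture vs an independent reference implementation
  # (frozen values computed with RDKit's ComputeGasteigerCharges):
  # formaldehyde C 0.10637, O -0.30714, H 0.10038 x2
  ch2o <- qc_structure(c("C", "O", "H", "H"),
                       rbind(c(0, 0, 0), c(1.21, 0, 0),
                             c(-0.55, 0.94, 0), c(-0.55, -0.94, 0)))
  q <- peoe_charges(ch2o, n_iter = 12)
  expect_lt(abs(q[1] - 0.10637), 1e-3)
  expect_lt(abs(q[2] - (-0.30714)), 1e-3)
  expect_lt(abs(q[3] - 0.10038), 1e-3)
  expect_gt(q[1], 0)  # carbonyl C positive, O negative
  expect_lt(q[2], 0)

  # methanol: C 0.03192, O -0.39965, H(C) 0.05270, H(O) 0.20964
  meoh <- qc_structure(c("C", "O", "H", "H", "H", "H"),
                       rbind(c(0, 0, 0), c(1.43, 0, 0), c(-0.36, 1.03, 0),
                             c(-0.36, -0.51, 0.89), c(-0.36, -0.51, -0.89),
                             c(1.76, 0.87, 0)))
  q2 <- peoe_charges(meoh, n_iter = 12)
  expect_equal(q2, c(0.03192, -0.39965, 0.0527, 0.0527, 0.0527, 0.20964),
               tolerance = 1e-3)

  # unparameterized element
  si <- qc_structure(c("Si", "H"), rbind(c(0, 0, 0), c(1.48, 0, 0)))
  expect_error(peoe_charges(si), "Si")
})

test_that("EState indices: symmetry, zero-sum perturbation, hand oracle", {
  # ethane: both carbons identical
  eth <- qc_structure(c("C", "C", "H", "H", "H", "H", "H", "H"),
                      rbind(c(0, 0, 0), c(1.54, 0, 0),
                            c(-0.36, -1.02, 0), c(-0.36, 0.51, 0.88),
                            c(-0.36, 0.51, -0.88), c(1.9, 1.02, 0),
                            c(1.9, -0.51, 0.88), c(1.9, -0.51, -0.88)))
  s <- estate_indices(eth)
  expect_equal(s[1], s[2], tolerance = 1e-12)

  # propanal: frozen hand computation from the Kier-Hall formulas.
  # I: C1 2, C2 1.5, C3 2, O 7; perturbed: 1.8125, 0.63889, 0.875, 9.17361
  prop <- qc_structure(c("C", "C", "C", "O", "H", "H", "H", "H", "H", "H"),
                       rbind(c(0, 0, 0), c(1.53, 0, 0), c(2.25, 1.25, 0),
                             c(3.47, 1.30, 0), c(-0.36, -1.02, 0),
                             c(-0.36, 0.51, 0.88), c(-0.36, 0.51, -0.88),
                             c(1.89, -0.51, 0.88), c(1.89, -0.51, -0.88),
                             c(1.74, 2.20, 0)))
  sp <- estate_indices(prop)
  expect_equal(unname(sp[1:4]),
               c(1.8125, 0.6388889, 0.875, 9.1736111), tolerance = 1e-6)
  # perturbations are antisymmetric: sum(S) = sum(I)
  expect_equal(sum(sp[1:4]), 2 + 1.5 + 2 + 7, tolerance = 1e-10)
  expect_true(all(is.na(sp[5:10])))  # hydrogens carry no index
})

test_that("Sterimol: one-sphere geometry, B1 <= B5, dense-scan oracle", {
  # single-atom substituent at distance d with radius r
  s <- qc_structure(c("C", "Cl"), rbind(c(0, 0, 0), c(1.77, 0, 0)))
  st <- sterimol(s, 1, 2)
  expect_equal(unname(st["L"]), 1.77 + 1.75, tolerance = 1e-9)
  expect_equal(unname(st["B1"]), 1.75, tolerance = 1e-6)
  expect_equal(unname(st["B5"]), 1.75, tolerance = 1e-9)

  # B1 <= B5 over random multi-atom substituents
  set.seed(42)
  for (i in 1:200) {
    n_sub <- sample(2:5, 1)
    xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0),
                 matrix(stats::rnorm(3 * n_sub, sd = 1.2), ncol = 3) +
                   matrix(rep(c(2.5, 0, 0), each = n_sub), ncol = 3))
    st2 <- tryCatch(
      sterimol(qc_structure(rep("C", n_sub + 2), xyz), 1, 2,
               bonds = structure(cbind(i = c(1, rep(2, n_sub)),
                                       j = 2:(n_sub + 2)),
                                 n = n_sub + 2L)),
      error = function(e) NULL)
    if (!is.null(st2)) expect_lte(st2["B1"], st2["B5"] + 1e-9)
  }

  # tert-butyl-like fixture against the brute-force scan oracle
  tb <- qc_structure(rep("C", 5),
                     rbind(c(0, 0, 0), c(1.54, 0, 0), c(2.1, 1.4, 0.2),
                           c(2.1, -0.8, 1.2), c(2.1, -0.7, -1.3)))
  bonds <- structure(cbind(i = c(1, 2, 2, 2), j = c(2, 3, 4, 5)), n = 5L)
  got <- sterimol(tb, 1, 2, bonds = bonds)
  want <- oracle_sterimol(tb$coords, vdw_radius(tb$elements), 1, 2, 2:5)
  expect_equal(got, want, tolerance = 0.01)

  expect_error(sterimol(qc_structure(c("C", "C"),
                                     rbind(c(0, 0, 0), c(0, 0, 0) + 1e-12)),
                        1, 2), "zero")
})

test_that("percent buried volume: analytic single sphere and locality", {
  lone <- qc_structure("C", matrix(0, 1, 3))
  pbv <- percent_buried_volume(lone, 1, sphere_radius = 3.5,
                               radii_scale = 1.0)
  expect_lt(abs(pbv - 100 * (1.70 / 3.5)^3), 0.1)
  # a remote atom beyond R + r_max changes nothing
  pair <- qc_structure(c("C", "C"),
                       rbind(c(0, 0, 0), c(12, 0, 0)))
  expect_equal(percent_buried_volume(pair, 1),
               percent_buried_volume(lone, 1), tolerance = 1e-12)
  expect_error(percent_buried_volume(lone, 1, sphere_radius = -1),
               "positive")
})

test_that("SASA: analytic sphere, additivity, occlusion", {
  lone <- qc_structure("C", matrix(0, 1, 3))
  sa <- sasa(lone)
  expect_lt(abs(sa$total - 4 * pi * (1.70 + 1.4)^2) /
              (4 * pi * (1.70 + 1.4)^2), 0.01)
  # two far-apart atoms: areas add
  pair <- qc_structure(c("C", "O"), rbind(c(0, 0, 0), c(25, 0, 0)))
  sp <- sasa(pair)
  expect_equal(sp$total, 4 * pi * (1.7 + 1.4)^2 + 4 * pi * (1.52 + 1.4)^2,
               tolerance = 1e-6)
  expect_equal(sum(sp$atom_area), sp$total, tolerance = 1e-9)
  # an atom fully enclosed by a tight shell has zero accessible area
  dirs <- deltabarrier:::.golden_spiral(30)
  shell <- qc_structure(c("C", rep("Cl", 30)),
                        rbind(c(0, 0, 0), dirs * 2.2))
  expect_equal(sasa(shell)$atom_area[1], 0)
  expect_error(sasa(lone, n_points = 5), "at least 10")
})

test_that("geometric descriptors are rigid-motion invariant", {
  gen <- generate_reactions(1, out_dir = withr::local_tempdir(), seed = 4,
                            noise_sd = 0)
  rx <- load_manifest(gen$manifest_path)
  ts <- get_record(rx[[1]], "DFT", "TS")$structure
  ka <- rx[[1]]$key_atoms
  bonds <- perceive_bonds(ts)
  moved <- ts
  moved$coords <- random_rigid_motion(ts$coords, seed = 11)
  expect_equal(percent_buried_volume(moved, ka$nu_c),
               percent_buried_volume(ts, ka$nu_c), tolerance = 1e-6)
  expect_equal(sasa(moved)$total, sasa(ts)$total, tolerance = 1e-6)
  att <- ka$attach[1]
  anchor <- intersect(deltabarrier:::.adjacency(bonds, n_atoms(ts))[[att]],
                      ka$core)[1]
  expect_equal(sterimol(moved, anchor, att, bonds = bonds),
               sterimol(ts, anchor, att, bonds = bonds), tolerance = 1e-6)
  # graph-derived descriptors ignore coordinates given fixed connectivity
  expect_equal(peoe_charges(moved, bonds), peoe_charges(ts, bonds),
               tolerance = 1e-12)
  expect_equal(estate_indices(moved, bonds), estate_indices(ts, bonds),
               tolerance = 1e-12)
})

test_that("descriptor_set bundles families and validates dispersion", {
  gen <- generate_reactions(1, out_dir = withr::local_tempdir(), seed = 6,
                            noise_sd = 0)
  rx <- load_manifest(gen$manifest_path)
  rec <- get_record(rx[[1]], "DFT", "TS")
  ds <- descriptor_set(rec, rx[[1]]$key_atoms)
  expect_s3_class(ds, "descriptor_set")
  expect_equal(sum(ds$peoe), rec$structure$net_charge, tolerance = 1e-6)
  expect_true(all(ds$sasa_atom >= 0))
  expect_true(all(ds$pbv >= 0 & ds$pbv <= 100))
  for (st in ds$sterimol) expect_lte(st["B1"], st["B5"] + 1e-9)
  expect_error(descriptor_set(rec, rx[[1]]$key_atoms, dispersion = 1:3),
               "per atom")
})
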