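# IO: XYZ, the native qclog dialect, the Gaussian-style parser, and
# reaction manifests.

test_that("read_xyz parses minimal and fixture files and round-trips", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "", "C 0 0 0"), f)
  s <- read_xyz(f)
  expect_equal(n_atoms(s), 1L)
  expect_equal(s$elements, "C")
  expect_equal(unname(s$coords[1, ]), c(0, 0, 0))

  w <- water_structure()
  f2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(w, f2)
  s2 <- read_xyz(f2)
  expect_equal(n_atoms(s2), 3L)
  expect_equal(s2$elements[1], "O")
  expect_equal(s2$coords, w$coords, tolerance = 1e-7)
  expect_equal(s2$label, w$label)
  # a second round trip is byte-identical (float formatting is fixed)
  f3 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(s2, f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("read_xyz errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "bad", "C 0 0 0", "H 0 0 x"), f)
  expect_error(read_xyz(f), "line 4")
  writeLines(c("zzz", "", "C 0 0 0"), f)
  expect_error(read_xyz(f), "line 1")
})

test_that("qclog parser handles energies, modes, and role invariants", {
  f <- withr::local_tempfile(fileext = ".qclog")
  writeLines(c("energy -0.5", "begin geometry", "He 0 0 0",
               "end geometry"), f)
  rec <- read_qm_log(f, level = "DFT")
  expect_equal(rec$e_elec, -0.5)
  expect_length(rec$frequencies, 0)

  # TS log with one imaginary mode
  ts <- qm_record(water_structure(), "AM1", e_elec = -76.0,
                  frequencies = c(-512.3, 1600, 3700))
  ts$structure$role <- "TS"
  f2 <- withr::local_tempfile(fileext = ".qclog")
  write_qm_log(ts, f2)
  rec2 <- read_qm_log(f2, level = "AM1")
  expect_equal(sum(rec2$frequencies < 0), 1L)
  expect_silent(check_role_frequencies(rec2, role = "TS"))
  expect_error(check_role_frequencies(rec2, role = "MA"), "imaginary")

  # minimum with a full positive mode set passes the role invariant
  minrec <- qm_record(water_structure(), "AM1", e_elec = -76.0,
                      frequencies = c(1595, 3657, 3756), mulliken = c(-0.6, 0.3, 0.3))
  f3 <- withr::local_tempfile(fileext = ".qclog")
  write_qm_log(minrec, f3)
  rec3 <- read_qm_log(f3, level = "AM1")
  expect_silent(check_role_frequencies(rec3, role = "MA"))
  expect_equal(rec3$mulliken, c(-0.6, 0.3, 0.3), tolerance = 1e-6)
})

test_that("qclog parser keeps the LAST geometry and energy block", {
  f <- withr::local_tempfile(fileext = ".qclog")
  writeLines(c("energy -1.0",
               "begin geometry", "C 0 0 0", "end geometry",
               "energy -2.0",
               "begin geometry", "C 1 1 1", "end geometry"), f)
  rec <- read_qm_log(f, level = "DFT")
  expect_equal(rec$e_elec, -2.0)
  expect_equal(unname(rec$structure$coords[1, ]), c(1, 1, 1))
})

test_that("qclog parser error and warning paths", {
  f <- withr::local_tempfile(fileext = ".qclog")
  writeLines(c("begin geometry", "C 0 0 0", "end geometry"), f)
  expect_error(read_qm_log(f, "DFT"), "no electronic energy")
  writeLines(c("energy -1", "begin geometry", "O 0 0 0.12",
               "H 0 0.76 -0.47", "H 0 -0.76 -0.47", "end geometry",
               "begin frequencies", "100 200", "end frequencies"), f)
  expect_warning(read_qm_log(f, "DFT"), "expected 3N-6")
})

test_that("gaussian-style logs parse through the registry", {
  f <- withr::local_tempfile(fileext = ".log")
  writeLines(c(
    " Charge =  0 Multiplicity = 1",
    " SCF Done:  E(RwB97XD) =  -76.123456     A.U. after 9 cycles",
    "                         Standard orientation:",
    " ---------------------------------------------------------------------",
    " Center     Atomic      Atomic             Coordinates (Angstroms)",
    " Number     Number       Type             X           Y           Z",
    " ---------------------------------------------------------------------",
    "      1          8           0        0.000000    0.000000    0.117300",
    "      2          1           0        0.000000    0.757200   -0.469200",
    "      3          1           0        0.000000   -0.757200   -0.469200",
    " ---------------------------------------------------------------------",
    " Frequencies --   1595.0000              3657.0000              3756.0000",
    " Mulliken charges:",
    "               1",
    "     1  O   -0.600000",
    "     2  H    0.300000",
    "     3  H    0.300000"), f)
  rec <- read_qm_log(f, level = "DFT", format = "gaussian")
  expect_equal(rec$e_elec, -76.123456)
  expect_equal(rec$structure$elements, c("O", "H", "H"))
  expect_equal(rec$frequencies, c(1595, 3657, 3756))
  expect_equal(rec$mulliken, c(-0.6, 0.3, 0.3))
})

test_that("merge_spe attaches the solvent energy and guards species", {
  opt <- qm_record(water_structure(), "AM1", e_elec = -1.0)
  spe <- qm_record(water_structure(), "AM1", e_elec = -1.1)
  merged <- merge_spe(opt, spe)
  expect_equal(merged$e_spe, -1.1)
  expect_equal(merged$e_elec, -1.0)
  expect_equal(composite_energy(merged), -1.1)
  # no-op SPE: composite equals gas phase
  same <- merge_spe(opt, qm_record(water_structure(), "AM1", e_elec = -1.0))
  expect_equal(composite_energy(same), opt$e_elec)
  # mismatched species
  other <- qm_record(qc_structure("He", matrix(0, 1, 3)), "AM1", -2.9)
  expect_error(merge_spe(opt, other), "mismatch")
})

test_that("manifests load, preserve tags, and report broken reactions", {
  gen <- generate_reactions(2, out_dir = withr::local_tempdir(), seed = 3,
                            noise_sd = 0.02)
  m <- gen$manifest
  m$split_tag[m$reaction_id == "rxn0001"] <- "train"
  m$split_tag[m$reaction_id == "rxn0002"] <- "test"
  save_manifest(m, gen$manifest_path)
  rx <- load_manifest(gen$manifest_path)
  expect_length(rx, 2L)
  expect_equal(rx[["rxn0001"]]$split_tag, "train")
  expect_equal(rx[["rxn0002"]]$split_tag, "test")
  expect_s3_class(get_record(rx[[1]], "SQM", "TS"), "qm_record")
  expect_equal(nrow(attr(rx, "errors")), 0L)

  # break one TS path: that reaction is reported, the other still loads
  m2 <- gen$manifest
  m2$path[m2$reaction_id == "rxn0002" & m2$role == "TS" &
            m2$level == "DFT"] <- "missing.qclog"
  p2 <- file.path(dirname(gen$manifest_path), "broken.csv")
  save_manifest(m2, p2)
  expect_warning(rx2 <- load_manifest(p2), "failed to load")
  expect_length(rx2, 1L)
  expect_equal(attr(rx2, "errors")$reaction_id, "rxn0002")
  expect_match(attr(rx2, "errors")$message, "missing")

  # duplicate rows are a hard error
  m3 <- rbind(gen$manifest, gen$manifest[1, ])
  p3 <- file.path(dirname(gen$manifest_path), "dup.csv")
  save_manifest(m3, p3)
  expect_error(load_manifest(p3), "duplicate")
})

test_that("key-atom indices out of range are rejected", {
  w <- water_structure()
  ts <- qm_record(w, "AM1", -76, frequencies = c(-500, 1600, 3700))
  ts$structure$role <- "TS"
  expect_error(
    reaction_record("bad", list(AM1 = list(TS = ts)),
                    key_atoms = list(nu_c = 9L, beta_c = 1L,
                                     carbonyl_o = 2L, core = c(1L, 2L),
                                     attach = integer(0))),
    "out of range")
})
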