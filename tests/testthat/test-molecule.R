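test_that("SD files round-trip: counts, ids, elements, coordinates", {
  mols <- lapply(1:10, function(k)
    random_molecule(fixture_spec(), seed = k, id = paste0("mol", k)))
  txt <- write_sd(mols)
  back <- read_sd(txt)
  expect_length(back, 10)
  expect_identical(attr(back, "errors"), character(0))
  for (k in 1:10) {
    expect_identical(back[[k]]$id, mols[[k]]$id)
    expect_identical(back[[k]]$atoms$element, mols[[k]]$atoms$element)
    expect_lt(max(abs(atom_coords(back[[k]]) - atom_coords(mols[[k]]))), 5e-5)
    expect_equal(back[[k]]$bonds, mols[[k]]$bonds)
  }
})

test_that("empty input yields an empty molecule list without error", {
  out <- read_sd(character(0))
  expect_length(out, 0)
  expect_identical(attr(out, "errors"), character(0))
  expect_length(write_sd(list()), 0)
})

test_that("a corrupt atom line fails only its own record", {
  mols <- lapply(1:3, function(k)
    random_molecule(fixture_spec(c(5L, 8L)), seed = k, id = paste0("m", k)))
  lines <- write_sd(mols)
  # truncate the first atom line of record 2 (line 5 after its header)
  rec2_start <- which(lines == "m2")
  lines[rec2_start + 4] <- substr(lines[rec2_start + 4], 1, 12)
  out <- suppressWarnings(read_sd(lines))
  expect_length(out, 2)
  expect_identical(vapply(out, `[[`, character(1), "id"), c("m1", "m3"))
  expect_length(attr(out, "errors"), 1)
  expect_match(attr(out, "errors"), "corrupt atom line")
})

test_that("V3000 records are rejected with a clear per-record error", {
  lines <- c("v3k", "", "", "  0  0  0  0  0  0  0  0  0  0999 V3000",
             "M  END", "$$$$")
  out <- suppressWarnings(read_sd(lines))
  expect_length(out, 0)
  expect_match(attr(out, "errors"), "V3000")
})

test_that("2D records (2D flag, all z = 0) are returned but flagged", {
  m <- random_molecule(fixture_spec(c(5L, 5L)), seed = 7, id = "flat")
  m$atoms$z <- 0
  m$flag2d <- TRUE
  expect_warning(out <- read_sd(write_sd(list(m))), "no 3D information")
  expect_true(out[[1]]$flag2d)
})

test_that("duplicate molecule names are disambiguated by record ordinal", {
  m1 <- random_molecule(fixture_spec(c(4L, 4L)), seed = 1, id = "same")
  m2 <- random_molecule(fixture_spec(c(4L, 4L)), seed = 2, id = "same")
  out <- read_sd(write_sd(list(m1, m2)))
  expect_identical(vapply(out, `[[`, character(1), "id"),
                   c("same_1", "same_2"))
})

test_that("formal charges survive an M CHG round trip", {
  m <- molecule3d("ion", c("N", "C", "O"), diag(3),
                  data.frame(i = c(1, 2), j = c(2, 3), order = 1L),
                  charge = c(1L, 0L, -1L))
  back <- read_sd(write_sd(list(m)))[[1]]
  expect_identical(back$atoms$charge, c(1L, 0L, -1L))
})

test_that("strip_hydrogens folds explicit H into heavy-atom counts", {
  w <- strip_hydrogens(water_mol())
  expect_identical(w$atoms$element, "O")
  expect_identical(w$atoms$hcount, 2L)
  # idempotent
  expect_identical(strip_hydrogens(w), w)
  # benzene with 6 explicit H: 6 C each with one attached hydrogen
  b <- benzene_mol()
  coords <- rbind(atom_coords(b), 2 * atom_coords(b))
  bonds <- rbind(b$bonds, data.frame(i = 1:6, j = 7:12, order = 1L))
  bz <- molecule3d("benzene_h", c(rep("C", 6), rep("H", 6)), coords, bonds)
  s <- strip_hydrogens(bz)
  expect_identical(s$atoms$element, rep("C", 6))
  expect_identical(s$atoms$hcount, rep(1L, 6))
  expect_equal(nrow(s$bonds), 6)
})

test_that("an all-hydrogen molecule cannot be stripped", {
  h2 <- molecule3d("h2", c("H", "H"), rbind(c(0, 0, 0), c(0.7, 0, 0)),
                   data.frame(i = 1L, j = 2L, order = 1L))
  expect_error(strip_hydrogens(h2), "no heavy atoms")
})

test_that("implicit hydrogens follow the valence model on read", {
  # methane written as a lone carbon: 4 implicit H
  ch4 <- molecule3d("methane", "C", matrix(c(0, 0, 0), 1))
  back <- read_sd(write_sd(list(ch4)))[[1]]
  expect_identical(back$atoms$hcount, 4L)
  # lone oxygen (water without explicit H): 2 implicit H
  o <- read_sd(write_sd(list(molecule3d("w", "O", matrix(0, 1, 3)))))[[1]]
  expect_identical(o$atoms$hcount, 2L)
})

test_that("lipinski filter applies the <=1-violation rule of five", {
  mk <- function(id, mw, hbd, hba, logp = NA) list(
    molecular_weight = mw, hbd_count = hbd, hba_count = hba, logp = logp)
  mols <- lapply(c("ok", "heavy", "awful"), function(id)
    random_molecule(fixture_spec(c(3L, 3L)), seed = nchar(id), id = id))
  props <- list(mk("ok", 400, 2, 5, 3),       # passes all rules
                mk("heavy", 600, 2, 5, 3),    # one violation: retained
                mk("awful", 600, 9, 12, 7))   # violates all four: removed
  kept <- lipinski_filter(mols, props)
  expect_identical(vapply(kept, `[[`, character(1), "id"), c("ok", "heavy"))
  # strict policy removes the single-violation molecule too
  strict <- lipinski_filter(mols, props, max_violations = 0L)
  expect_identical(vapply(strict, `[[`, character(1), "id"), "ok")
  # output is always a subsequence of the input
  ids_in <- vapply(mols, `[[`, character(1), "id")
  expect_true(all(diff(match(vapply(kept, `[[`, character(1), "id"),
                             ids_in)) > 0))
  expect_error(lipinski_filter(mols, props[1:2]), "align")
})

test_that("lipinski properties count NH/OH donors and N+O acceptors", {
  p <- lipinski_properties(phenol_mol())
  expect_identical(p$hbd_count, 1L)   # the hydroxyl hydrogen
  expect_identical(p$hba_count, 1L)   # the oxygen
  expect_equal(p$molecular_weight, 6 * 12.011 + 15.999 + 6 * 1.008,
               tolerance = 1e-6)
})

test_that("score annotations appear as UFSRAT_SCORE fields in rank order", {
  mols <- lapply(1:2, function(k)
    random_molecule(fixture_spec(c(4L, 4L)), seed = k, id = c("a", "b")[k]))
  txt <- write_sd(mols, annotations = c(a = 1.0, b = 0.5))
  tags <- grep("^> <UFSRAT_SCORE>$", txt)
  expect_length(tags, 2)
  expect_identical(trimws(txt[tags + 1]), c("1", "0.5"))
  back <- read_sd(txt)
  expect_identical(back[[1]]$data$UFSRAT_SCORE, "1")
  expect_error(write_sd(mols, annotations = c(zzz = 1)), "not present")
})

test_that("written SD files agree with an independent SDF reader", {
  skip_if_not_installed("ChemmineR")
  mols <- lapply(1:5, function(k)
    random_molecule(fixture_spec(), seed = k, id = paste0("x", k)))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sd(mols, path = path)
  sdf <- ChemmineR::read.SDFset(path)
  expect_length(sdf, 5)
  for (k in 1:5) {
    ab <- ChemmineR::atomblock(sdf[[k]])
    expect_equal(nrow(ab), n_atoms(mols[[k]]))
    expect_equal(unname(ab[, 1:3]), atom_coords(mols[[k]]), tolerance = 5e-5)
  }
})
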