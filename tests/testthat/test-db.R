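test_that("a packed record is exactly 200 bytes with the stated layout", {
  r <- pack_record(0, rep(0, 48))
  expect_identical(length(r), 200L)
  expect_true(all(r == as.raw(0)))
  r2 <- pack_record(7, runif(48))
  expect_identical(length(r2), 200L)
  expect_error(pack_record(1, rep(0, 47)), "48 values")
  expect_error(pack_record(-1, rep(0, 48)), "non-negative")
})

test_that("1000 random records round-trip exactly at single precision", {
  set.seed(18)
  ids <- floor(runif(1000, 0, 2^31)) +
    sample(0:10, 1000, replace = TRUE) * 2^32
  for (k in seq_len(1000)) {
    vals <- runif(48, -100, 100)
    back <- unpack_record(pack_record(ids[k], vals))
    expect_identical(back$id, ids[k])
    # values reproduce the single-precision representation bit-exactly
    expect_identical(back$values,
                     unpack_record(pack_record(ids[k], back$values))$values)
    expect_equal(back$values, vals, tolerance = 1e-6)
  }
})

make_lib <- function(n, seed0 = 0, path = tempfile(fileext = ".sdf")) {
  mols <- lapply(seq_len(n), function(k)
    random_molecule(fixture_spec(), seed = seed0 + k, id = paste0("lib", k)))
  write_sd(mols, path = path)
  list(path = path, mols = mols)
}

test_that("database files have header + 200 bytes per molecule", {
  lib <- make_lib(100)
  db <- tempfile(fileext = ".ufsrat")
  res <- build_db(lib$path, db)
  expect_identical(res$count, 100)
  hdr <- read_db_header(db)
  expect_identical(hdr$count, 100)
  expect_identical(hdr$mode, "ufsrat")
  expect_identical(file.size(db), 32 + 200 * 100)
  man <- read_manifest(res$manifest_path)
  expect_identical(nrow(man), 100L)
  expect_identical(man$name, paste0("lib", 1:100))
})

test_that("building twice from the same input is byte-identical", {
  lib <- make_lib(20)
  db1 <- tempfile(); db2 <- tempfile()
  build_db(lib$path, db1)
  build_db(lib$path, db2)
  expect_identical(readBin(db1, "raw", file.size(db1)),
                   readBin(db2, "raw", file.size(db2)))
})

test_that("corrupt records are skipped without renumbering survivors", {
  lib <- make_lib(10)
  lines <- readLines(lib$path)
  for (bad in c("lib3", "lib7")) {
    at <- which(lines == bad)
    lines[at + 4] <- substr(lines[at + 4], 1, 9)
  }
  path2 <- tempfile(fileext = ".sdf")
  writeLines(lines, path2)
  db <- tempfile()
  res <- build_db(path2, db)
  expect_identical(res$count, 8)
  expect_length(res$skipped, 2)
  man <- read_manifest(res$manifest_path)
  expect_identical(man$id, as.numeric(1:8))
  expect_false(any(c("lib3", "lib7") %in% man$name))
})

test_that("an input with no usable records refuses to build", {
  expect_error(suppressWarnings(
    build_db(c("junk", "", "", "garbage", "$$$$"), tempfile())),
    "nothing to write")
})

test_that("scan equals in-memory ranking and finds the query at rank 1", {
  lib <- make_lib(200)
  db <- tempfile()
  build_db(lib$path, db)
  man <- read_manifest(paste0(db, ".manifest.tsv"))
  # candidates and queries re-read from the SD source, exactly as the
  # database builder saw them (the file stores coordinates at 4 dp)
  disk_mols <- read_sd(lib$path)
  # candidate vectors as stored: single-precision quantised
  cand <- lapply(disk_mols, function(m) {
    s <- strip_hydrogens(m)
    v <- ufsrat_descriptors(s, assign_types(s))
    structure(ufsrat:::.float32(as.numeric(v)), class = "DescriptorVector",
              mode = "ufsrat", skew = "standardized",
              per_channel_refpoints = FALSE)
  })
  names(cand) <- as.character(man$id)
  for (qi in c(1, 57, 200)) {
    qm <- strip_hydrogens(disk_mols[[qi]])
    q <- ufsrat_descriptors(qm, assign_types(qm))
    got <- scan_db(q, db, n = 20)
    qq <- q
    qq[] <- ufsrat:::.float32(as.numeric(q))
    want <- rank_hits(qq, cand, n = 20)
    expect_identical(as.character(got$id), want$id)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    # the query's own record is rank 1 with score exactly 1
    expect_identical(got$id[1], as.numeric(qi))
    expect_identical(got$score[1], 1)
  }
})

test_that("scans refuse queries built under different conventions", {
  lib <- make_lib(5)
  db <- tempfile()
  build_db(lib$path, db, config = descriptor_config(skew = "standardized"))
  m <- strip_hydrogens(lib$mols[[1]])
  q_cbrt <- ufsrat_descriptors(m, assign_types(m),
                               descriptor_config(skew = "cbrt-central"))
  expect_error(scan_db(q_cbrt, db), "skew: db 'standardized'")
  q_pc <- ufsrat_descriptors(m, assign_types(m),
                             descriptor_config(per_channel_refpoints = TRUE))
  expect_error(scan_db(q_pc, db), "refpoints")
  q_usr <- usr_descriptors(m)
  expect_error(scan_db(q_usr, db), "mode")
})

test_that("fetch_hits retrieves source molecules in hit order", {
  lib <- make_lib(30)
  db <- tempfile()
  res <- build_db(lib$path, db)
  m5 <- strip_hydrogens(read_sd(lib$path)[[5]])
  hits <- scan_db(ufsrat_descriptors(m5, assign_types(m5)), db, n = 3)
  mols <- fetch_hits(hits, res$manifest_path, lib$path)
  expect_length(mols, 3)
  man <- read_manifest(res$manifest_path)
  for (k in 1:3) {
    src_name <- man$name[match(hits$id[k], man$id)]
    src <- lib$mols[[which(vapply(lib$mols, `[[`, character(1), "id")
                           == src_name)]]
    expect_lt(max(abs(atom_coords(mols[[k]]) - atom_coords(src))), 5e-5)
  }
  expect_identical(fetch_hits(hits[0, ], res$manifest_path, lib$path), list())
  bad <- hits
  bad$id[1] <- 99999
  expect_error(fetch_hits(bad, res$manifest_path, lib$path),
               "missing from manifest")
})

test_that("screening-coverage arithmetic reproduces the protocol numbers", {
  expect_equal(screening_coverage(3, 500, 3.8e6), 100 * 1500 / 3.8e6)
  expect_equal(round(screening_coverage(3, 500, 3.8e6), 2), 0.04)
})
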