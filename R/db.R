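#' @title One-file binary descriptor database
#' @name descriptor-db
#' @description
#' Pre-calculated descriptors live in a single binary file so that
#' screening only ever computes descriptors for the query. Each record is
#' exactly 200 bytes: an 8-byte little-endian unsigned identifier followed
#' by 48 little-endian IEEE-754 single-precision values (192 bytes) — 3.8
#' million compounds fit in about 730 MB. A 32-byte self-describing header
#' (magic, format version, mode, skew convention, reference-point scope,
#' record count) records every build convention so a scan can refuse a
#' query built differently. A sidecar TSV manifest maps each id to its
#' molecule name and byte offset in the source SD file for hit retrieval.
NULL

.DB_MAGIC <- "UFSRATDB"
.DB_HEADER_BYTES <- 32L
.DB_RECORD_BYTES <- 200L
.SKEW_CODES <- c(standardized = 1L, `cbrt-central` = 2L)

# 64-bit unsigned integer <-> 8 little-endian raw bytes, exact below 2^53
.uint64_to_raw <- function(x) {
  out <- raw(8)
  for (k in 1:8) {
    b <- x %% 256
    out[k] <- as.raw(b)
    x <- (x - b) / 256
  }
  out
}

.raw_to_uint64 <- function(r) sum(as.numeric(r) * 256^(0:7))

# round doubles to the nearest representable single-precision value; the
# query is quantised like the stored records so that a molecule compared
# with its own database record scores exactly 1
.float32 <- function(x) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
  readBin(rawConnectionValue(con), "numeric", n = length(x), size = 4L,
          endian = "little")
}

#' Pack one database record
#'
#' @param id non-negative integer identifier (stored as 64-bit unsigned;
#'   exact up to 2^53).
#' @param values numeric vector of exactly 48 descriptor values (stored at
#'   single precision).
#' @return a raw vector of exactly 200 bytes.
#' @export
pack_record <- function(id, values) {
  if (length(values) != 48)
    stop("a database record holds exactly 48 values, got ", length(values))
  if (id < 0) stop("record id must be non-negative")
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(.uint64_to_raw(id), con)
  writeBin(as.numeric(values), con, size = 4L, endian = "little")
  rawConnectionValue(con)
}

#' Unpack one database record
#'
#' @param bytes a raw vector of exactly 200 bytes.
#' @return list with `id` and `values` (length 48, single-precision
#'   values promoted to double).
#' @export
unpack_record <- function(bytes) {
  if (length(bytes) != .DB_RECORD_BYTES)
    stop("a packed record is exactly 200 bytes, got ", length(bytes))
  list(id = .raw_to_uint64(bytes[1:8]),
       values = readBin(bytes[9:200], "numeric", n = 48, size = 4L,
                        endian = "little"))
}

.write_db_header <- function(con, config, count) {
  writeBin(charToRaw(.DB_MAGIC), con)
  meta <- as.integer(c(
    1L,                                              # format version
    if (config$mode == "ufsrat") 48L else 12L,       # values per molecule
    .SKEW_CODES[[config$skew]],
    if (isTRUE(config$per_channel_refpoints)) 1L else 0L
  ))
  writeBin(meta, con, size = 4L, endian = "little")
  writeBin(.uint64_to_raw(count), con)
}

#' Read a descriptor database header
#'
#' @param path database file path.
#' @return list with `version`, `mode`, `skew`, `per_channel_refpoints`
#'   and `count`.
#' @export
read_db_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, .DB_MAGIC))
    stop("not a descriptor database: bad magic in ", path)
  meta <- readBin(con, "integer", n = 4L, size = 4L, endian = "little")
  count <- .raw_to_uint64(readBin(con, "raw", 8L))
  list(version = meta[1],
       mode = if (meta[2] == 48L) "ufsrat" else "usr",
       skew = names(.SKEW_CODES)[match(meta[3], .SKEW_CODES)],
       per_channel_refpoints = meta[4] == 1L,
       count = count)
}

#' Build a descriptor database from an SD file
#'
#' One pass over the library: parse each record (fail-soft — unparseable
#' records are skipped with a logged reason and never renumber the ids
#' already assigned), strip hydrogens, type atoms, compute descriptors,
#' append a 200-byte record. Ids are assigned sequentially from 1 in
#' record order, so the build is fully deterministic: identical input and
#' configuration give byte-identical files. The sidecar manifest
#' `<out_path>.manifest.tsv` maps id to molecule name and byte offset in
#' the source SD file.
#'
#' @param input SD file path or text (as for [read_sd()]).
#' @param out_path output database path.
#' @param rules a `TypingRules` object.
#' @param config a [descriptor_config()]. USR mode stores the 12 values
#'   padded with 36 zeros so the record layout is unchanged.
#' @return invisibly, a list with `path`, `manifest_path`, `count`, and
#'   `skipped` (named character vector of skip reasons).
#' @export
build_db <- function(input, out_path, rules = default_typing_rules(),
                     config = descriptor_config()) {
  mols <- suppressWarnings(read_sd(input))
  offsets <- attr(mols, "offsets")
  skipped <- attr(mols, "errors")
  con <- file(out_path, "wb")
  on.exit(close(con), add = TRUE)
  manifest <- character(0)
  count <- 0
  for (k in seq_along(mols)) {
    rec <- tryCatch({
      m <- strip_hydrogens(mols[[k]])
      v <- if (config$mode == "ufsrat")
        ufsrat_descriptors(m, assign_types(m, rules), config)
      else ufsrat_descriptors(m, config = config)
      as.numeric(v)
    }, error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      skipped <- c(skipped, paste0("record ", k, " (", mols[[k]]$id, "): ", rec))
      next
    }
    count <- count + 1
    if (count == 1) .write_db_header(con, config, 0)   # count patched below
    if (length(rec) == 12) rec <- c(rec, numeric(36))
    writeBin(pack_record(count, rec), con)
    manifest <- c(manifest,
                  paste(count, mols[[k]]$id, offsets[k], sep = "\t"))
  }
  if (count == 0) stop("no molecule could be processed; nothing to write")
  close(con)
  on.exit(NULL)
  # patch the record count into the header
  con2 <- file(out_path, "r+b")
  seek(con2, 24L, rw = "write")
  writeBin(.uint64_to_raw(count), con2)
  close(con2)
  manifest_path <- paste0(out_path, ".manifest.tsv")
  writeLines(c("id\tname\toffset", manifest), manifest_path)
  invisible(list(path = out_path, manifest_path = manifest_path,
                 count = count, skipped = skipped))
}

#' Read a database manifest
#'
#' @param path manifest TSV path (`id`, `name`, `offset`).
#' @return a data frame.
#' @export
read_manifest <- function(path) {
  utils::read.delim(path, colClasses = c("numeric", "character", "numeric"))
}

#' Linear-scan a descriptor database for the top N hits
#'
#' Streams the pre-computed records in chunks, scores each against the
#' query in double precision (single-precision stored values are promoted
#' on read; the query is quantised to the stored precision first, so a
#' molecule scanned against its own record scores exactly 1) and keeps a
#' bounded top-N buffer; candidate descriptors are never recomputed. The
#' scan refuses a query whose build conventions differ from the database
#' header, reporting the exact mismatch.
#'
#' @param query the query `DescriptorVector` (computed at query time with
#'   the same configuration the database was built with).
#' @param db_path database file path.
#' @param n number of hits to keep (default 500, the usual screening
#'   protocol depth).
#' @param w a [channel_weights()] object.
#' @param chunk_size records read per chunk.
#' @return a `RankedHits` data frame (`id`, `score`), descending score,
#'   ties broken by ascending id.
#' @export
scan_db <- function(query, db_path, n = 500L, w = channel_weights(),
                    chunk_size = 8192L) {
  hdr <- read_db_header(db_path)
  qmode <- attr(query, "mode")
  mismatches <- character(0)
  if (!is.null(qmode) && !identical(qmode, hdr$mode))
    mismatches <- c(mismatches, sprintf("mode: db '%s' vs query '%s'",
                                        hdr$mode, qmode))
  qskew <- attr(query, "skew")
  if (!is.null(qskew) && !identical(qskew, hdr$skew))
    mismatches <- c(mismatches, sprintf("skew: db '%s' vs query '%s'",
                                        hdr$skew, qskew))
  qpc <- attr(query, "per_channel_refpoints")
  if (!is.null(qpc) && !identical(isTRUE(qpc), hdr$per_channel_refpoints))
    mismatches <- c(mismatches,
                    sprintf("refpoints: db '%s' vs query '%s'",
                            if (hdr$per_channel_refpoints) "per-channel"
                            else "shared",
                            if (isTRUE(qpc)) "per-channel" else "shared"))
  if (length(mismatches) > 0)
    stop("query/database convention mismatch:\n  ",
         paste(mismatches, collapse = "\n  "))
  expected_len <- if (hdr$mode == "ufsrat") 48L else 12L
  if (length(query) != expected_len)
    stop("query has ", length(query), " values; database stores ",
         expected_len)
  qv <- .float32(as.numeric(query))
  con <- file(db_path, "rb")
  on.exit(close(con))
  readBin(con, "raw", .DB_HEADER_BYTES)
  buf <- list(id = numeric(0), score = numeric(0))
  remaining <- hdr$count
  while (remaining > 0) {
    take <- min(chunk_size, remaining)
    bytes <- readBin(con, "raw", take * .DB_RECORD_BYTES)
    k <- length(bytes) %/% .DB_RECORD_BYTES
    if (k == 0) break
    block <- matrix(bytes[seq_len(k * .DB_RECORD_BYTES)],
                    nrow = .DB_RECORD_BYTES)
    ids <- apply(block[1:8, , drop = FALSE], 2, .raw_to_uint64)
    vals <- matrix(readBin(as.raw(block[9:200, ]), "numeric",
                           n = 48L * k, size = 4L, endian = "little"),
                   nrow = 48L)
    if (expected_len == 12L) vals <- vals[1:12, , drop = FALSE]
    sc <- .score_matrix(qv, vals, w)
    buf <- .topn_merge(buf, ids, sc, as.integer(n))
    remaining <- remaining - k
  }
  structure(data.frame(id = as.numeric(buf$id), score = buf$score),
            class = c("RankedHits", "data.frame"))
}

#' Retrieve hit molecules from the source SD file
#'
#' Uses the manifest's byte offsets to seek directly to each hit's source
#' record, returning molecules in hit order ready for [write_sd()] with
#' scores.
#'
#' @param hits a `RankedHits` data frame with numeric database ids.
#' @param manifest manifest data frame (or path) from [build_db()].
#' @param source_sd path of the SD file the database was built from.
#' @return list of [Molecule3D] in hit order.
#' @export
fetch_hits <- function(hits, manifest, source_sd) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (nrow(hits) == 0) return(list())
  pos <- match(as.numeric(hits$id), manifest$id)
  if (anyNA(pos))
    stop("ids missing from manifest: ",
         paste(hits$id[is.na(pos)], collapse = ", "))
  con <- file(source_sd, "rb")
  on.exit(close(con))
  lapply(seq_len(nrow(hits)), function(k) {
    seek(con, manifest$offset[pos[k]])
    lines <- character(0)
    repeat {
      ln <- readLines(con, n = 1L, warn = FALSE)
      if (length(ln) == 0 || grepl("^\\$\\$\\$\\$", ln)) break
      lines <- c(lines, ln)
    }
    parse_sd_record(lines, manifest$id[pos[k]])
  })
}

#' Screening coverage arithmetic
#'
#' The fraction of a library examined when `n_queries` ranked lists of
#' `top_n` hits each are drawn from a database of `db_size` molecules —
#' e.g. three top-500 lists against 3.8 million compounds touch 1500
#' molecules, 0.04% of the database.
#'
#' @param n_queries number of queries.
#' @param top_n hits kept per query.
#' @param db_size database size.
#' @return percentage of the database selected.
#' @export
screening_coverage <- function(n_queries, top_n, db_size) {
  100 * n_queries * top_n / db_size
}
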