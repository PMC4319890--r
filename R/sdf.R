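#' @title MDL SD/SDF V2000 reading and writing
#' @name sdf-io
#' @description
#' Multi-record V2000 SD files are the exchange format for screening
#' libraries: each record is a header (name, program/dimension line,
#' comment), a counts line, fixed-width atom and bond blocks, property
#' lines up to `M  END`, optional tagged data fields, and a `$$$$`
#' terminator. Reading is fail-soft: a corrupt record is skipped with a
#' collected error message and parsing continues, because a multi-million
#' compound library build must not die on one bad entry. V3000 records are
#' rejected explicitly.
NULL

# Split SD text into records at "$$$$" lines, tracking the byte offset of
# each record start (LF line endings assumed, as written by write_sd).
split_sd_records <- function(lines) {
  nb <- nchar(lines, type = "bytes") + 1L
  starts_at <- cumsum(c(0L, nb[-length(nb)]))
  term <- which(grepl("^\\$\\$\\$\\$\\s*$", lines))
  ends <- c(term - 1L, if (length(term) == 0 || term[length(term)] < length(lines))
                         length(lines))
  begs <- c(1L, term + 1L)[seq_along(ends)]
  recs <- list()
  offs <- integer(0)
  for (k in seq_along(ends)) {
    if (ends[k] < begs[k]) next
    body <- lines[begs[k]:ends[k]]
    if (!any(nzchar(trimws(body)))) next
    recs[[length(recs) + 1L]] <- body
    offs <- c(offs, starts_at[begs[k]])
  }
  list(records = recs, offsets = offs)
}

.sdf_num <- function(s) suppressWarnings(as.numeric(s))

parse_sd_record <- function(lines, ordinal) {
  if (length(lines) < 4) stop("record ", ordinal, ": too short")
  name <- trimws(lines[1])
  flag2d_hdr <- grepl("2D", substr(lines[2], 21, 22), fixed = TRUE)
  counts <- lines[4]
  if (grepl("V3000", counts, fixed = TRUE))
    stop("record ", ordinal, ": V3000 records are not supported")
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1)
    stop("record ", ordinal, ": malformed counts line")
  if (length(lines) < 4 + natoms + nbonds)
    stop("record ", ordinal, ": truncated atom/bond block")

  al <- lines[5:(4 + natoms)]
  x <- .sdf_num(substr(al, 1, 10))
  y <- .sdf_num(substr(al, 11, 20))
  z <- .sdf_num(substr(al, 21, 30))
  el <- trimws(substr(al, 32, 34))
  if (any(is.na(x) | is.na(y) | is.na(z)) || any(!nzchar(el)))
    stop("record ", ordinal, ": corrupt atom line")
  # legacy charge column: 1..7 codes +3,+2,+1,radical,-1,-2,-3
  ccode <- suppressWarnings(as.integer(substr(al, 37, 39)))
  ccode[is.na(ccode)] <- 0L
  charge <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)[ccode + 1L]

  bonds <- NULL
  if (nbonds > 0) {
    bl <- lines[(5 + natoms):(4 + natoms + nbonds)]
    bi <- suppressWarnings(as.integer(substr(bl, 1, 3)))
    bj <- suppressWarnings(as.integer(substr(bl, 4, 6)))
    bo <- suppressWarnings(as.integer(substr(bl, 7, 9)))
    if (any(is.na(bi) | is.na(bj)) ||
        any(bi < 1 | bi > natoms | bj < 1 | bj > natoms))
      stop("record ", ordinal, ": corrupt bond line")
    bo[is.na(bo)] <- 1L
    bonds <- data.frame(i = bi, j = bj, order = bo)
  }

  # property block: M  CHG supersedes the legacy atom-block charges
  rest <- if (length(lines) > 4 + natoms + nbonds)
    lines[(5 + natoms + nbonds):length(lines)] else character(0)
  chg_lines <- grep("^M  CHG", rest, value = TRUE)
  if (length(chg_lines) > 0) {
    charge <- rep(0L, natoms)
    for (cl in chg_lines) {
      f <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))), "\\s+")[[1]])
      npair <- f[1]
      for (p in seq_len(npair)) {
        idx <- f[2 * p]
        if (idx >= 1 && idx <= natoms) charge[idx] <- f[2 * p + 1]
      }
    }
  }

  # tagged data fields after M  END
  data <- list()
  mend <- grep("^M  END", rest)
  if (length(mend) > 0 && mend[1] < length(rest)) {
    dl <- rest[(mend[1] + 1):length(rest)]
    tag_at <- grep("^>", dl)
    for (t in tag_at) {
      tag <- sub("^>\\s*<([^>]*)>.*$", "\\1", dl[t])
      vend <- t
      while (vend < length(dl) && nzchar(trimws(dl[vend + 1L]))) vend <- vend + 1L
      if (vend > t) data[[tag]] <- paste(dl[(t + 1):vend], collapse = "\n")
    }
  }

  bond_sums <- .bond_order_sums(natoms, if (is.null(bonds))
    data.frame(i = integer(0), j = integer(0), order = integer(0)) else bonds)
  himp <- .implicit_hydrogens(el, charge, bond_sums)
  himp[el == "H"] <- 0L

  mol <- molecule3d(
    id = if (nzchar(name)) name else as.character(ordinal),
    elements = el, coords = cbind(x, y, z), bonds = bonds,
    hcount = himp, charge = charge,
    flag2d = flag2d_hdr && all(z == 0)
  )
  if (length(data) > 0) mol$data <- data
  mol
}

#' Read a multi-molecule SD/SDF file
#'
#' @param input path to an SD file, or a character vector of its lines, or
#'   a single string containing the whole text.
#' @return a list of [Molecule3D] objects, in record order. Attributes:
#'   `errors` — character vector of per-record parse failures (empty when
#'   clean); `offsets` — byte offset of each successfully parsed record in
#'   the source, usable as a manifest for later random access. Records
#'   flagged 2D (all z = 0 plus a 2D header flag) are returned with
#'   `flag2d = TRUE` and a warning.
#' @export
read_sd <- function(input) {
  lines <- if (length(input) == 1 && !grepl("\n", input) &&
               file.exists(input)) readLines(input, warn = FALSE)
           else if (length(input) == 1) strsplit(input, "\n", fixed = TRUE)[[1]]
           else input
  if (length(lines) == 0 || !any(nzchar(trimws(lines)))) {
    out <- list()
    attr(out, "errors") <- character(0)
    attr(out, "offsets") <- integer(0)
    return(out)
  }
  sp <- split_sd_records(lines)
  mols <- list()
  offs <- integer(0)
  errs <- character(0)
  for (k in seq_along(sp$records)) {
    m <- tryCatch(parse_sd_record(sp$records[[k]], k),
                  error = function(e) conditionMessage(e))
    if (inherits(m, "Molecule3D")) {
      mols[[length(mols) + 1L]] <- m
      offs <- c(offs, sp$offsets[k])
    } else {
      errs <- c(errs, m)
    }
  }
  # disambiguate id collisions by appending the record ordinal
  ids <- vapply(mols, `[[`, character(1), "id")
  dup <- ids %in% ids[duplicated(ids)]
  if (any(dup)) {
    for (k in which(dup)) mols[[k]]$id <- paste0(ids[k], "_", k)
  }
  if (length(errs) > 0)
    warning(length(errs), " of ", length(sp$records),
            " SD records failed to parse", call. = FALSE)
  if (any(vapply(mols, function(m) isTRUE(m$flag2d), logical(1))))
    warning("some records carry no 3D information (2D flag, all z = 0)",
            call. = FALSE)
  attr(mols, "errors") <- errs
  attr(mols, "offsets") <- offs
  mols
}

format_sd_record <- function(mol, score = NULL) {
  a <- mol$atoms
  n <- nrow(a)
  lines <- c(
    mol$id,
    sprintf("%-20s%s", "  ufsrat", if (isTRUE(mol$flag2d)) "2D" else "3D"),
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(mol$bonds)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            a$x, a$y, a$z, a$element)
  )
  if (nrow(mol$bonds) > 0)
    lines <- c(lines, sprintf("%3d%3d%3d  0", mol$bonds$i, mol$bonds$j,
                              mol$bonds$order))
  chg <- which(a$charge != 0L)
  if (length(chg) > 0) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0(
        sprintf("M  CHG%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, a$charge[grp]), collapse = "")))
    }
  }
  lines <- c(lines, "M  END")
  if (!is.null(score))
    lines <- c(lines, "> <UFSRAT_SCORE>", format(signif(score, 6)), "")
  c(lines, "$$$$")
}

#' Write molecules as a multi-record SD file
#'
#' @param mols list of [Molecule3D] objects, written in the given order.
#' @param annotations optional named numeric vector of similarity scores,
#'   keyed by molecule id; each annotated molecule gets a
#'   `<UFSRAT_SCORE>` data field (6 significant digits).
#' @param path output file path, or `NULL` to return the text.
#' @return invisibly, the SD text as a character vector of lines.
#' @export
write_sd <- function(mols, annotations = NULL, path = NULL) {
  if (!is.null(annotations)) {
    ids <- vapply(mols, `[[`, character(1), "id")
    missing_ids <- setdiff(names(annotations), ids)
    if (length(missing_ids) > 0)
      stop("annotated ids not present: ", paste(missing_ids, collapse = ", "))
  }
  lines <- unlist(lapply(mols, function(m) {
    s <- if (!is.null(annotations) && m$id %in% names(annotations))
      annotations[[m$id]] else NULL
    format_sd_record(m, s)
  }))
  if (is.null(lines)) lines <- character(0)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
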