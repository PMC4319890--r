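#' @title Deterministic synthetic molecule fixtures
#' @name synthetic-fixtures
#' @description
#' Every module is testable without any external download: a seeded
#' generator produces 3D "molecules" — physically naive point clouds with
#' chain connectivity, element palettes chosen so the typing rules have
#' something to act on, and per-element default hydrogen counts. Labelled
#' benchmark sets emulate actives as coordinate-jittered conformers of a
#' seed molecule versus independent random decoys. These fixtures are not
#' chemically valid structures; they are sufficient because every in-scope
#' computation consumes only coordinates, elements, hydrogen counts and
#' the bond graph. Generation uses R's Mersenne-Twister stream under an
#' explicit integer seed, so the same specification always reproduces the
#' same molecules.
NULL

#' Fixture generation specification
#'
#' @param n_atoms integer range `c(min, max)` of heavy atoms per molecule.
#' @param elements named numeric vector of element sampling weights. The
#'   defaults give a carbon-rich palette with enough N/O for the donor and
#'   acceptor channels to be populated in most molecules.
#' @param scale edge length (Angstrom) of the cubic box coordinates are
#'   drawn in; 10 A spans typical drug-like molecule diameters.
#' @return a `FixtureSpec` list.
#' @export
fixture_spec <- function(n_atoms = c(10L, 30L),
                         elements = c(C = 0.7, N = 0.1, O = 0.15, S = 0.05),
                         scale = 10) {
  if (any(n_atoms < 1)) stop("n_atoms must be >= 1")
  structure(list(n_atoms = as.integer(rep_len(n_atoms, 2)),
                 elements = elements, scale = scale),
            class = "FixtureSpec")
}

# run fn under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Generate one random molecule
#'
#' Atoms are drawn uniformly in the box, elements from the palette, and
#' atom i is bonded to atom i-1 (single bonds) so the typing rules see a
#' connected graph. Hydrogen counts come from the same valence model the
#' SD reader applies (a mid-chain N carries one hydrogen and types as a
#' donor, a mid-chain O carries none and is acceptor-only, terminal N/O
#' carry more), so generated molecules round-trip through SD files with
#' their typing intact.
#'
#' @param spec a [fixture_spec()].
#' @param seed integer seed.
#' @param id molecule id.
#' @return a [Molecule3D].
#' @export
random_molecule <- function(spec = fixture_spec(), seed = 1L, id = "mol") {
  stopifnot(inherits(spec, "FixtureSpec"))
  .with_seed(seed, function() {
    n <- if (spec$n_atoms[1] == spec$n_atoms[2]) spec$n_atoms[1]
         else sample(spec$n_atoms[1]:spec$n_atoms[2], 1)
    el <- sample(names(spec$elements), n, replace = TRUE,
                 prob = spec$elements)
    coords <- matrix(stats::runif(3 * n, 0, spec$scale), ncol = 3)
    bonds <- if (n > 1)
      data.frame(i = 1:(n - 1), j = 2:n, order = 1L) else NULL
    bs <- .bond_order_sums(n, if (is.null(bonds))
      data.frame(i = integer(0), j = integer(0), order = integer(0))
      else bonds)
    hc <- .implicit_hydrogens(el, rep(0L, n), bs)
    molecule3d(id, el, coords, bonds, hcount = hc)
  })
}

#' Jittered conformers of a seed molecule
#'
#' Independent Gaussian noise (standard deviation `sigma` per axis) is
#' added to every coordinate of `n` copies; `sigma = 0` gives exact
#' copies. Stands in for "molecules capable of making similar
#' interactions" in benchmark sets.
#'
#' @param seed_mol a [Molecule3D].
#' @param n number of conformers.
#' @param sigma coordinate noise, Angstrom (>= 0).
#' @param seed integer seed.
#' @param id_prefix prefix for conformer ids (`<prefix>1`..`<prefix>n`).
#' @return list of `n` [Molecule3D].
#' @export
jittered_conformers <- function(seed_mol, n, sigma, seed = 1L,
                                id_prefix = paste0(seed_mol$id, "_conf")) {
  stopifnot(sigma >= 0)
  .with_seed(seed, function() {
    lapply(seq_len(n), function(k) {
      m <- seed_mol
      na <- n_atoms(m)
      noise <- matrix(stats::rnorm(3 * na, 0, sigma), ncol = 3)
      m$atoms$x <- m$atoms$x + noise[, 1]
      m$atoms$y <- m$atoms$y + noise[, 2]
      m$atoms$z <- m$atoms$z + noise[, 3]
      m$id <- paste0(id_prefix, k)
      m
    })
  })
}

#' Build a labelled synthetic benchmark library
#'
#' Per target: one random seed molecule is the query, its jittered
#' conformers are the actives, and independent random molecules are the
#' decoys. Id spaces are disjoint across targets; the query itself is not
#' part of the ranked library.
#'
#' @param n_targets,n_actives,n_decoys counts (all >= 1).
#' @param sigma active-conformer jitter, Angstrom.
#' @param seed integer master seed; per-target seeds are derived from it.
#' @param spec a [fixture_spec()] for seed and decoy molecules.
#' @return a labelled library as consumed by [benchmark()]: list with
#'   `molecules` and `targets`.
#' @export
benchmark_set <- function(n_targets = 10L, n_actives = 10L,
                          n_decoys = 490L, sigma = 0.05, seed = 1L,
                          spec = fixture_spec()) {
  stopifnot(n_targets >= 1, n_actives >= 1, n_decoys >= 1)
  molecules <- list()
  targets <- list()
  for (t in seq_len(n_targets)) {
    base <- (seed * 1000L + t * 131L) %% .Machine$integer.max
    tname <- sprintf("t%02d", t)
    query <- random_molecule(spec, seed = base, id = paste0(tname, "_query"))
    actives <- jittered_conformers(query, n_actives, sigma, seed = base + 1L,
                                   id_prefix = paste0(tname, "_act"))
    decoys <- lapply(seq_len(n_decoys), function(d)
      random_molecule(spec, seed = base + 1L + d,
                      id = sprintf("%s_dec%d", tname, d)))
    for (m in c(list(query), actives, decoys)) molecules[[m$id]] <- m
    targets[[tname]] <- list(
      query = query$id,
      actives = vapply(actives, `[[`, character(1), "id"),
      decoys = vapply(decoys, `[[`, character(1), "id"))
  }
  list(molecules = molecules, targets = targets)
}

#' Write a labelled library in the on-disk benchmark layout
#'
#' One shared `library.sdf` plus, per target, a directory holding
#' `query.sdf`, `actives.ids` and `decoys.ids` (plain-text id lists).
#'
#' @param library a labelled library from [benchmark_set()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_benchmark_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib_ids <- unlist(lapply(library$targets, function(t)
    c(t$actives, t$decoys)), use.names = FALSE)
  write_sd(library$molecules[unique(lib_ids)],
           path = file.path(dir, "library.sdf"))
  for (tn in names(library$targets)) {
    tgt <- library$targets[[tn]]
    td <- file.path(dir, tn)
    dir.create(td, showWarnings = FALSE)
    write_sd(library$molecules[tgt$query], path = file.path(td, "query.sdf"))
    writeLines(tgt$actives, file.path(td, "actives.ids"))
    writeLines(tgt$decoys, file.path(td, "decoys.ids"))
  }
  invisible(dir)
}

#' Read a labelled library from the on-disk benchmark layout
#'
#' @param dir directory written by [write_benchmark_library()].
#' @return a labelled library list (`molecules`, `targets`).
#' @export
read_benchmark_library <- function(dir) {
  lib <- read_sd(file.path(dir, "library.sdf"))
  molecules <- stats::setNames(lib, vapply(lib, `[[`, character(1), "id"))
  targets <- list()
  for (td in list.dirs(dir, recursive = FALSE)) {
    q <- read_sd(file.path(td, "query.sdf"))
    molecules[[q[[1]]$id]] <- q[[1]]
    targets[[basename(td)]] <- list(
      query = q[[1]]$id,
      actives = readLines(file.path(td, "actives.ids")),
      decoys = readLines(file.path(td, "decoys.ids")))
  }
  list(molecules = molecules, targets = targets)
}
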