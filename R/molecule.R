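#' @title Molecule containers
#' @name Molecule3D
#' @description
#' A `Molecule3D` is a light-weight container for a named molecule with 3D
#' coordinates: an atom table (element, x/y/z in Angstrom, attached hydrogen
#' count, formal charge), a bond table (1-based atom indices plus bond
#' order), and an id. Atom order is always preserved from the input file
#' because reference-point tie-breaking depends on it.
NULL

.ELEMENT_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

.DEFAULT_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

.HALOGENS <- c("F", "Cl", "Br", "I")

#' Construct a Molecule3D
#'
#' @param id molecule identifier (coerced to character).
#' @param elements character vector of element symbols.
#' @param coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param bonds data frame with columns `i`, `j` (1-based atom indices) and
#'   `order`, or `NULL` for no bonds.
#' @param hcount integer vector of attached hydrogens per atom (recycled).
#' @param charge integer vector of formal charges per atom (recycled).
#' @param flag2d logical; `TRUE` marks a record that carried no 3D
#'   information (all z = 0 and a 2D header flag).
#' @return an object of class `Molecule3D`.
#' @export
molecule3d <- function(id, elements, coords, bonds = NULL,
                       hcount = 0L, charge = 0L, flag2d = FALSE) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3)
    stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (n < 1) stop("a molecule needs at least one atom")
  if (length(elements) != n) stop("elements and coords disagree in length")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    bonds <- as.data.frame(bonds)
    if (nrow(bonds) > 0) {
      bad <- bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n
      if (any(bad)) stop("bond endpoints out of range")
      if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
    }
  }
  structure(
    list(
      id = as.character(id),
      atoms = data.frame(
        element = as.character(elements),
        x = coords[, 1], y = coords[, 2], z = coords[, 3],
        hcount = as.integer(rep_len(hcount, n)),
        charge = as.integer(rep_len(charge, n)),
        stringsAsFactors = FALSE
      ),
      bonds = bonds[, c("i", "j", "order")],
      flag2d = isTRUE(flag2d)
    ),
    class = "Molecule3D"
  )
}

#' @export
print.Molecule3D <- function(x, ...) {
  cat(sprintf("<Molecule3D '%s': %d atoms, %d bonds%s>\n",
              x$id, nrow(x$atoms), nrow(x$bonds),
              if (isTRUE(x$flag2d)) ", flagged 2D" else ""))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `Molecule3D`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Atom coordinates as a matrix
#' @param mol a `Molecule3D`.
#' @return numeric n x 3 matrix of coordinates (Angstrom).
#' @export
atom_coords <- function(mol) {
  unname(as.matrix(mol$atoms[, c("x", "y", "z")]))
}

# Bond-order sum per atom (explicit hydrogens included).
.bond_order_sums <- function(n, bonds) {
  s <- numeric(n)
  if (nrow(bonds) > 0) {
    ord <- ifelse(bonds$order %in% 1:3, bonds$order, 1)
    for (k in seq_len(nrow(bonds))) {
      s[bonds$i[k]] <- s[bonds$i[k]] + ord[k]
      s[bonds$j[k]] <- s[bonds$j[k]] + ord[k]
    }
  }
  s
}

# Implicit hydrogen count from standard valences; charge shifts the
# effective valence for N/P (ammonium-type) and O/S (oxyanion-type).
.implicit_hydrogens <- function(elements, charges, bond_sums) {
  val <- .DEFAULT_VALENCE[elements]
  val[is.na(val)] <- 0
  adj <- ifelse(elements %in% c("N", "P", "O", "S"), charges, 0L)
  pmax(0, as.integer(val) + adj - as.integer(round(bond_sums)))
}

#' Remove hydrogens, keeping per-atom hydrogen counts
#'
#' Hydrogens carry no information for distance-distribution descriptors and
#' are excluded from every channel, but donor typing needs to know how many
#' hydrogens sit on each heavy atom. `strip_hydrogens()` removes explicit H
#' atoms, folds them into the bonded heavy atom's `hcount`, and preserves
#' heavy-atom order. The operation is idempotent.
#'
#' @param mol a `Molecule3D` (with explicit and/or implicit hydrogens).
#' @return a `Molecule3D` containing heavy atoms only.
#' @export
strip_hydrogens <- function(mol) {
  stopifnot(inherits(mol, "Molecule3D"))
  is_h <- mol$atoms$element == "H"
  if (!any(is_h)) return(mol)
  if (all(is_h)) stop("molecule '", mol$id, "' has no heavy atoms")
  keep <- which(!is_h)
  hcount <- mol$atoms$hcount
  b <- mol$bonds
  if (nrow(b) > 0) {
    for (k in seq_len(nrow(b))) {
      if (is_h[b$i[k]] && !is_h[b$j[k]])
        hcount[b$j[k]] <- hcount[b$j[k]] + 1L
      else if (is_h[b$j[k]] && !is_h[b$i[k]])
        hcount[b$i[k]] <- hcount[b$i[k]] + 1L
    }
    keep_bond <- !is_h[b$i] & !is_h[b$j]
    b <- b[keep_bond, , drop = FALSE]
    remap <- integer(length(is_h))
    remap[keep] <- seq_along(keep)
    b$i <- remap[b$i]
    b$j <- remap[b$j]
  }
  out <- mol
  out$atoms <- mol$atoms[keep, , drop = FALSE]
  out$atoms$hcount <- hcount[keep]
  rownames(out$atoms) <- NULL
  out$bonds <- b
  out
}

#' Drug-likeness properties for the rule-of-five filter
#'
#' Molecular weight includes attached hydrogens. Hydrogen-bond donors are
#' counted as the number of hydrogens on nitrogen or oxygen; acceptors as
#' the number of nitrogen plus oxygen atoms (the classic rule-of-five
#' counting scheme). logP is not computed from structure: it is taken from
#' `logp` when supplied (mirroring property tables pre-computed in compound
#' databases) and otherwise left `NA`, in which case the logP rule is not
#' evaluated.
#'
#' @param mol a `Molecule3D` (hydrogen-stripped or not).
#' @param logp optional externally supplied logP estimate.
#' @return a list with `molecular_weight` (Da), `hbd_count`, `hba_count`
#'   and `logp`.
#' @export
lipinski_properties <- function(mol, logp = NA_real_) {
  m <- strip_hydrogens(mol)
  el <- m$atoms$element
  mass <- .ELEMENT_MASS[el]
  mass[is.na(mass)] <- 0
  mw <- sum(mass) + sum(m$atoms$hcount) * .ELEMENT_MASS[["H"]]
  hbd <- sum(m$atoms$hcount[el %in% c("N", "O")])
  hba <- sum(el %in% c("N", "O"))
  list(molecular_weight = mw, hbd_count = as.integer(hbd),
       hba_count = as.integer(hba), logp = as.numeric(logp))
}

#' Lipinski rule-of-five filter
#'
#' Retains molecules satisfying the rule of five: molecular weight <= 500
#' Da, H-bond donors <= 5, H-bond acceptors <= 10, logP <= 5. By the usual
#' convention one violation is tolerated (`max_violations = 1`); set
#' `max_violations = 0` for the strict reading. Input order is preserved
#' and the output is always a subsequence of the input.
#'
#' @param mols list of `Molecule3D`.
#' @param props optional list of property lists as returned by
#'   [lipinski_properties()], aligned with `mols`; computed internally when
#'   `NULL`.
#' @param max_violations number of rule violations tolerated (default 1).
#' @return the retained subset of `mols`.
#' @export
lipinski_filter <- function(mols, props = NULL, max_violations = 1L) {
  if (is.null(props)) props <- lapply(mols, lipinski_properties)
  if (length(props) != length(mols))
    stop("props must align with mols (", length(mols), " molecules, ",
         length(props), " property sets)")
  keep <- vapply(props, function(p) {
    v <- sum(p$molecular_weight > 500,
             p$hbd_count > 5,
             p$hba_count > 10,
             isTRUE(p$logp > 5))
    v <= max_violations
  }, logical(1))
  mols[keep]
}
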