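#' @title Shape + pharmacophore distance-distribution descriptors
#' @name descriptors
#' @description
#' A molecule's 3D shape is summarised, without any alignment, by the
#' moments of Euclidean distance distributions from four reference points:
#'
#' * P1 — geometric centre (unweighted centroid of heavy-atom positions);
#' * P2 — the atom closest to P1;
#' * P3 — the atom furthest from P2;
#' * P4 — the atom furthest from P3.
#'
#' For each point, the mean, variance and skew of the distances from a set
#' of atoms to that point give three values; four points give twelve. The
#' all-atom twelve are the classic USR shape descriptor. The typed
#' extension repeats the twelve moments for the hydrophobic, H-bond
#' acceptor and H-bond donor channels, yielding 48 values per molecule in
#' channel-major order `[all, hydrophobic, acceptor, donor] x [P1..P4] x
#' [mean, variance, skew]`. Because only interatomic distances enter, the
#' descriptor is invariant under rigid motions (and, inherently, under
#' reflection — the one blind spot of the distance-distribution family).
NULL

#' Descriptor build configuration
#'
#' @param mode `"ufsrat"` (48 values, four channels) or `"usr"` (12
#'   values, all-atom only).
#' @param skew `"standardized"` (third central moment over variance^1.5,
#'   zero when variance < 1e-12) or `"cbrt-central"` (signed cube root of
#'   the third central moment, the alternative normalisation used by some
#'   distance-moment implementations).
#' @param per_channel_refpoints if `TRUE`, P1-P4 are recomputed from each
#'   channel's own atoms; the default uses one shared set from all heavy
#'   atoms, preserving spatial registration between channels.
#' @return a `DescriptorConfig` list.
#' @export
descriptor_config <- function(mode = c("ufsrat", "usr"),
                              skew = c("standardized", "cbrt-central"),
                              per_channel_refpoints = FALSE) {
  structure(list(mode = match.arg(mode), skew = match.arg(skew),
                 per_channel_refpoints = isTRUE(per_channel_refpoints)),
            class = "DescriptorConfig")
}

#' Reference points of a point set
#'
#' Ties in the closest/furthest selections are broken by lowest atom
#' index, with exact floating-point comparison, so the choice is
#' deterministic for identical input coordinates.
#'
#' @param coords numeric n x 3 matrix (n >= 1).
#' @return list with `p1`..`p4` (3-vectors) and `p2_index`, `p3_index`,
#'   `p4_index` (1-based ordinals of the chosen atoms; P1 is not an atom).
#' @export
reference_points <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop("reference_points: empty coordinate set")
  p1 <- colMeans(coords)
  d1 <- sqrt(rowSums(sweep(coords, 2, p1)^2))
  i2 <- which.min(d1)                    # which.min takes the first minimum
  d2 <- sqrt(rowSums(sweep(coords, 2, coords[i2, ])^2))
  i3 <- which.max(d2)
  d3 <- sqrt(rowSums(sweep(coords, 2, coords[i3, ])^2))
  i4 <- which.max(d3)
  list(p1 = unname(p1), p2 = unname(coords[i2, ]), p3 = unname(coords[i3, ]),
       p4 = unname(coords[i4, ]),
       p2_index = i2, p3_index = i3, p4_index = i4)
}

#' Mean, variance and skew of a distance distribution
#'
#' Population moments: variance is the 1/N second central moment (N may be
#' 1), skew is the standardized third central moment with a zero-variance
#' guard so degenerate distributions (single atom, coincident points) give
#' skew 0 rather than NaN.
#'
#' @param distances numeric vector, length >= 1, all non-negative.
#' @param skew skew convention, as in [descriptor_config()].
#' @return numeric vector `c(mean, variance, skew)`.
#' @export
moments <- function(distances, skew = c("standardized", "cbrt-central")) {
  skew <- match.arg(skew)
  if (length(distances) < 1) stop("moments: empty distance list")
  m <- mean(distances)
  dev <- distances - m
  v <- mean(dev^2)
  mu3 <- mean(dev^3)
  s <- if (skew == "standardized") {
    if (v < 1e-12) 0 else mu3 / v^1.5
  } else {
    sign(mu3) * abs(mu3)^(1 / 3)
  }
  c(mean = m, variance = v, skew = s)
}

.point_dists <- function(coords, p) sqrt(colSums((t(coords) - p)^2))

.channel_block <- function(coords, rp, skew) {
  out <- numeric(12)
  k <- 0L
  for (p in list(rp$p1, rp$p2, rp$p3, rp$p4)) {
    out[k + 1:3] <- moments(.point_dists(coords, p), skew)
    k <- k + 3L
  }
  out
}

.descriptor_names <- function(mode) {
  ch <- if (mode == "ufsrat") c("all", "hydrophobic", "acceptor", "donor")
        else "all"
  unlist(lapply(ch, function(cn)
    unlist(lapply(paste0("p", 1:4), function(pn)
      paste(cn, pn, c("mean", "var", "skew"), sep = "_")))))
}

#' Compute the 48-value typed descriptor vector
#'
#' Each channel's atoms contribute Euclidean distances to P1-P4; by
#' default the reference points are shared across channels, computed from
#' all heavy atoms. A channel with no atoms yields twelve zeros — the
#' database must hold every molecule, and zeros make "no donors" maximally
#' similar to "no donors".
#'
#' @param mol a hydrogen-stripped [Molecule3D].
#' @param types an `AtomTypeAssignment` for `mol` (from [assign_types()]);
#'   ignored in USR mode.
#' @param config a [descriptor_config()].
#' @return a named `DescriptorVector` of length 48 (or 12 in USR mode)
#'   carrying the build conventions as attributes.
#' @export
ufsrat_descriptors <- function(mol, types = NULL,
                               config = descriptor_config()) {
  stopifnot(inherits(mol, "Molecule3D"))
  if (any(mol$atoms$element == "H"))
    stop("descriptors require a hydrogen-stripped molecule")
  coords <- atom_coords(mol)
  if (nrow(coords) < 1) stop("molecule has no heavy atoms")
  if (config$mode == "usr") {
    rp <- reference_points(coords)
    vals <- .channel_block(coords, rp, config$skew)
  } else {
    if (is.null(types)) types <- assign_types(mol)
    shared_rp <- if (config$per_channel_refpoints) NULL
                 else reference_points(coords)
    vals <- numeric(48)
    channels <- c("all", "hydrophobic", "acceptor", "donor")
    for (c_i in seq_along(channels)) {
      idx <- channel_atoms(mol, types, channels[c_i])
      block <- if (length(idx) == 0) numeric(12)
      else {
        sub <- coords[idx, , drop = FALSE]
        rp <- if (config$per_channel_refpoints) reference_points(sub)
              else shared_rp
        .channel_block(sub, rp, config$skew)
      }
      vals[(c_i - 1L) * 12L + 1:12] <- block
    }
  }
  names(vals) <- .descriptor_names(config$mode)
  structure(vals, class = "DescriptorVector",
            mode = config$mode, skew = config$skew,
            per_channel_refpoints = config$per_channel_refpoints)
}

#' Compute the 12-value all-atom (USR) descriptor
#'
#' Equals the first twelve entries of the typed vector built with shared
#' reference points.
#'
#' @inheritParams ufsrat_descriptors
#' @param skew skew convention.
#' @return a `DescriptorVector` of length 12.
#' @export
usr_descriptors <- function(mol, skew = c("standardized", "cbrt-central")) {
  skew <- match.arg(skew)
  ufsrat_descriptors(mol, config = descriptor_config("usr", skew))
}

#' @export
print.DescriptorVector <- function(x, ...) {
  cat(sprintf("<DescriptorVector %s (%d values, skew=%s, %s refpoints)>\n",
              attr(x, "mode"), length(x), attr(x, "skew"),
              if (isTRUE(attr(x, "per_channel_refpoints"))) "per-channel"
              else "shared"))
  print(unclass(x), ...)
  invisible(x)
}
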