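#' @title Enrichment-factor benchmark harness
#' @name enrichment
#' @description
#' Ranking power on a labelled library is measured by the enrichment
#' factor: the recall of known actives within the top fraction f of a
#' ranked list, divided by f. EF = 1 is what random picking would achieve;
#' EF = 2 doubles the expected recall, and EF can never exceed 1/f. The
#' harness ranks each target's actives-plus-decoys library with each
#' scoring method, reports per-target EF at the requested fractions
#' (defaults 0.5%, 1%, 2%, 5%), cross-target means, and pairwise win
#' counts between methods (ties are not wins).
NULL

#' Enrichment factor at a top fraction
#'
#' The top set is the first `ceiling(f * N)` entries of the ranking —
#' ceiling guarantees a non-empty selection at small fractions, at the
#' cost of slight inflation for tiny libraries (documented because EF at
#' small N is sensitive to this rounding choice).
#'
#' @param ranking character or numeric vector of candidate ids, best
#'   first.
#' @param actives ids of the known actives (must all appear in `ranking`).
#' @param fraction top fraction f in (0, 1].
#' @return EF = (recall of actives in the top set) / f, in \[0, 1/f\].
#' @export
enrichment_factor <- function(ranking, actives, fraction) {
  if (length(actives) == 0) stop("actives set is empty")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (!all(actives %in% ranking))
    stop("some actives are absent from the ranking")
  top <- ranking[seq_len(ceiling(fraction * length(ranking)))]
  (sum(actives %in% top) / length(actives)) / fraction
}

#' Rank one labelled target library with a scoring method
#' @noRd
.rank_target <- function(score_fn, target, molecules) {
  cand_ids <- c(target$actives, target$decoys)
  scores <- score_fn(molecules[[target$query]], molecules[cand_ids])
  if (!is.numeric(scores) || length(scores) != length(cand_ids))
    stop("scoring method returned ", length(scores), " scores for ",
         length(cand_ids), " candidates")
  cand_ids[order(-scores, .id_order_key(cand_ids))]
}

#' Benchmark scoring methods on a labelled library
#'
#' @param methods named list of scoring functions. Each is called as
#'   `fn(query_mol, candidate_mols)` (a [Molecule3D] and a named list of
#'   them) and must return one numeric score per candidate, higher =
#'   more similar. See [method_ufsrat()] / [method_usr()].
#' @param library a labelled library: list with `molecules` (named list
#'   of [Molecule3D]) and `targets` (named list; each has `query` — a
#'   molecule id — plus disjoint id vectors `actives` and `decoys`).
#' @param fractions top fractions at which to evaluate EF.
#' @return an `EnrichmentReport`: list with `per_target` (data frame of
#'   target, method, fraction, EF), `means` (method x fraction matrix),
#'   `wins` (named list of pairwise win-count matrices per fraction) and
#'   `failed` (named character vector of per-target method failures,
#'   excluded from the means).
#' @export
benchmark <- function(methods, library,
                      fractions = c(0.005, 0.01, 0.02, 0.05)) {
  stopifnot(length(methods) >= 1, !is.null(names(methods)))
  rows <- list()
  failed <- character(0)
  for (tn in names(library$targets)) {
    tgt <- library$targets[[tn]]
    if (length(intersect(tgt$actives, tgt$decoys)) > 0)
      stop("target ", tn, ": actives and decoys overlap")
    for (mn in names(methods)) {
      res <- tryCatch(
        list(ok = TRUE,
             ranking = .rank_target(methods[[mn]], tgt, library$molecules)),
        error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
      if (!res$ok) {
        failed[paste(tn, mn, sep = "/")] <- res$msg
        next
      }
      ranking <- res$ranking
      for (f in fractions) {
        rows[[length(rows) + 1L]] <- data.frame(
          target = tn, method = mn, fraction = f,
          ef = enrichment_factor(ranking, tgt$actives, f))
      }
    }
  }
  per_target <- do.call(rbind, rows)
  means <- tapply(per_target$ef,
                  list(per_target$method, per_target$fraction), mean)
  wins <- lapply(stats::setNames(fractions, paste0("f", fractions)),
                 function(f) {
    sub <- per_target[per_target$fraction == f, ]
    mns <- names(methods)
    w <- matrix(0L, length(mns), length(mns), dimnames = list(mns, mns))
    for (a in mns) for (b in mns) {
      if (a == b) next
      ea <- sub$ef[sub$method == a][match(unique(sub$target),
                                          sub$target[sub$method == a])]
      eb <- sub$ef[sub$method == b][match(unique(sub$target),
                                          sub$target[sub$method == b])]
      ok <- !is.na(ea) & !is.na(eb)
      w[a, b] <- sum(ea[ok] > eb[ok])
    }
    w
  })
  structure(list(per_target = per_target, means = means, wins = wins,
                 fractions = fractions, failed = failed),
            class = "EnrichmentReport")
}

#' @export
print.EnrichmentReport <- function(x, ...) {
  cat("Enrichment-factor report\n")
  cat("Mean EF across targets (rows: method, cols: top fraction):\n")
  print(round(x$means, 2))
  for (fn in names(x$wins)) {
    cat("\nWin counts at", fn, "(row method beats column method):\n")
    print(x$wins[[fn]])
  }
  if (length(x$failed) > 0) {
    cat("\nFailed target/method pairs (excluded from means):\n")
    for (nm in names(x$failed)) cat(" ", nm, ":", x$failed[[nm]], "\n")
  }
  invisible(x)
}

#' Write an enrichment report as TSV
#'
#' @param report an `EnrichmentReport`.
#' @param path output TSV path (per-target long table).
#' @return invisibly, `path`.
#' @export
write_enrichment_report <- function(report, path) {
  utils::write.table(report$per_target, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Built-in scoring methods for the harness
#'
#' `method_ufsrat()` scores candidates with the 48-value typed descriptor
#' and weighted similarity; `method_usr()` with the 12-value all-atom
#' descriptor. Both compute descriptors on the fly from hydrogen-stripped
#' molecules.
#'
#' @param w a [channel_weights()] object.
#' @param rules a `TypingRules` object.
#' @param config a [descriptor_config()].
#' @return a scoring function `fn(query_mol, candidate_mols)`.
#' @export
method_ufsrat <- function(w = channel_weights(),
                          rules = default_typing_rules(),
                          config = descriptor_config()) {
  desc <- function(m) {
    m <- strip_hydrogens(m)
    ufsrat_descriptors(m, assign_types(m, rules), config)
  }
  function(query_mol, candidate_mols) {
    qv <- desc(query_mol)
    vapply(candidate_mols, function(cm) score(qv, desc(cm), w), numeric(1))
  }
}

#' @rdname method_ufsrat
#' @param skew skew convention.
#' @export
method_usr <- function(skew = "standardized") {
  function(query_mol, candidate_mols) {
    qv <- usr_descriptors(strip_hydrogens(query_mol), skew)
    vapply(candidate_mols, function(cm)
      score(qv, usr_descriptors(strip_hydrogens(cm), skew)), numeric(1))
  }
}

#' Permutation test for enrichment above random
#'
#' Shuffles the active/decoy labels over the ranked ids `n_perm` times and
#' compares the observed EF with the null distribution.
#'
#' @param ranking ranked candidate ids, best first.
#' @param actives active ids.
#' @param fraction top fraction.
#' @param n_perm number of label permutations.
#' @return list with `ef` (observed), `p_value` (one-sided, add-one
#'   estimator) and `null_mean`.
#' @export
permutation_test_ef <- function(ranking, actives, fraction,
                                n_perm = 1000L) {
  ef_obs <- enrichment_factor(ranking, actives, fraction)
  n_act <- length(actives)
  null_ef <- vapply(seq_len(n_perm), function(i) {
    fake <- sample(ranking, n_act)
    enrichment_factor(ranking, fake, fraction)
  }, numeric(1))
  list(ef = ef_obs,
       p_value = (1 + sum(null_ef >= ef_obs)) / (n_perm + 1),
       null_mean = mean(null_ef))
}
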