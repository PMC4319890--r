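#' @title Pharmacophoric atom typing
#' @name atom-typing
#' @description
#' Each heavy atom is assigned to up to three pharmacophore channels —
#' hydrophobic, hydrogen-bond acceptor, hydrogen-bond donor — by an ordered
#' rule table (a user-definable atomic mask). Channels are not mutually
#' exclusive: a hydroxyl oxygen is both donor and acceptor. Typing depends
#' only on the bond graph, element identities, hydrogen counts and formal
#' charges, never on coordinates, so it is invariant under any rigid
#' transformation and equivariant under atom relabelling.
#'
#' Rules use a compact atom-environment pattern language, one predicate per
#' rule, matched against every heavy atom:
#'
#' * element list: `N,O` (or `*` for any atom, `X` for any halogen);
#' * optional conditions after `;`, comma-separated:
#'   `h>=1` / `h=0` (attached hydrogens), `q<=0` / `q=0` (formal charge),
#'   `nbr:C,S,X` (all bonded neighbours drawn from the listed elements),
#'   `adj=C=O` (bonded to an atom of the first element that itself has a
#'   double bond to the second — e.g. an amide nitrogen via its carbonyl
#'   carbon).
#'
#' Later rules override earlier ones: each rule sets (`+`) or clears (`-`)
#' one channel for all atoms it matches.
NULL

#' Parse typing rules
#'
#' @param lines character vector of rules, one per line, in the form
#'   `pattern<TAB>channel<TAB>+|-` (blank lines and `#` comments ignored),
#'   or the path of a rules file.
#' @return a `TypingRules` object (ordered list of parsed rules).
#' @export
typing_rules <- function(lines) {
  if (length(lines) == 1 && !grepl("\t", lines) && file.exists(lines))
    lines <- readLines(lines, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  rules <- lapply(seq_along(lines), function(k) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3)
      stop("rule ", k, ": expected pattern<TAB>channel<TAB>+|-")
    channel <- trimws(f[2])
    if (!channel %in% c("hydrophobic", "acceptor", "donor"))
      stop("rule ", k, ": unknown channel '", channel, "'")
    flag <- trimws(f[3])
    if (!flag %in% c("+", "-"))
      stop("rule ", k, ": flag must be + or -")
    pat <- parse_atom_pattern(trimws(f[1]), k)
    list(pattern = pat, channel = channel, set = flag == "+")
  })
  structure(rules, class = "TypingRules")
}

.expand_elements <- function(s) {
  e <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  out <- character(0)
  for (x in e) out <- c(out, if (x == "X") .HALOGENS else x)
  out
}

parse_atom_pattern <- function(s, k) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  pat <- list(elements = .expand_elements(parts[1]), conds = list())
  if (length(parts) > 1) {
    # '&' separates conditions because nbr:... element lists contain commas
    conds <- trimws(strsplit(parts[2], "&", fixed = TRUE)[[1]])
    parsed <- lapply(conds, function(cs) {
      if (grepl("^nbr:", cs))
        return(list(kind = "nbr", elements = .expand_elements(sub("^nbr:", "", cs))))
      if (grepl("^adj=", cs)) {
        ab <- strsplit(sub("^adj=", "", cs), "=", fixed = TRUE)[[1]]
        if (length(ab) != 2)
          stop("rule ", k, ": adj condition must be adj=A=B")
        return(list(kind = "adj_double", a = ab[1], b = ab[2]))
      }
      m <- regmatches(cs, regexec("^([hq])(>=|<=|=)(-?\\d+)$", cs))[[1]]
      if (length(m) == 0)
        stop("rule ", k, ": cannot parse condition '", cs, "'")
      list(kind = m[2], op = m[3], value = as.integer(m[4]))
    })
    pat$conds <- parsed
  }
  pat
}

.match_pattern <- function(pat, mol, nbrs) {
  el <- mol$atoms$element
  hit <- if (identical(pat$elements, "*")) rep(TRUE, length(el))
         else el %in% pat$elements
  for (cond in pat$conds) {
    m <- switch(cond$kind,
      h = .cmp(mol$atoms$hcount, cond$op, cond$value),
      q = .cmp(mol$atoms$charge, cond$op, cond$value),
      nbr = vapply(seq_along(el), function(i)
        all(el[nbrs[[i]]] %in% cond$elements), logical(1)),
      adj_double = .adj_double(mol, nbrs, cond$a, cond$b),
      stop("unknown condition kind"))
    hit <- hit & m
  }
  hit
}

.cmp <- function(x, op, v) switch(op, ">=" = x >= v, "<=" = x <= v, "=" = x == v)

# atom i matches when a neighbour of element `a` has a double bond to an
# atom of element `b` (e.g. amide N: neighbour C with C=O)
.adj_double <- function(mol, nbrs, a, b) {
  el <- mol$atoms$element
  bnd <- mol$bonds
  dbl_to_b <- rep(FALSE, length(el))
  if (nrow(bnd) > 0) {
    two <- bnd[bnd$order == 2L, , drop = FALSE]
    for (k in seq_len(nrow(two))) {
      if (el[two$j[k]] == b) dbl_to_b[two$i[k]] <- TRUE
      if (el[two$i[k]] == b) dbl_to_b[two$j[k]] <- TRUE
    }
  }
  vapply(seq_along(el), function(i)
    any(el[nbrs[[i]]] == a & dbl_to_b[nbrs[[i]]]), logical(1))
}

#' Default typing rule table
#'
#' Donors: N or O carrying at least one hydrogen, plus S-H. Acceptors: N or
#' O without positive formal charge and F, except amide-type N (bonded to a
#' carbonyl carbon). Hydrophobic: C or S whose neighbours are all C, S or
#' halogen, plus the halogens themselves. The table ships as a plain-text
#' file (`system.file("extdata", "typing_rules.tsv", package = "ufsrat")`)
#' and can be replaced wholesale.
#'
#' @return a `TypingRules` object.
#' @export
default_typing_rules <- function() {
  path <- system.file("extdata", "typing_rules.tsv", package = "ufsrat")
  if (nzchar(path)) return(typing_rules(path))
  # fall back for uninstalled use (e.g. pkgload)
  typing_rules(c(
    "N,O;h>=1\tdonor\t+",
    "S;h>=1\tdonor\t+",
    "N,O;q<=0\tacceptor\t+",
    "F\tacceptor\t+",
    "N;adj=C=O\tacceptor\t-",
    "C,S;nbr:C,S,X\thydrophobic\t+",
    "X\thydrophobic\t+"
  ))
}

#' Assign pharmacophore channels to every heavy atom
#'
#' @param mol a hydrogen-stripped [Molecule3D] with `hcount` populated.
#' @param rules a `TypingRules` object; defaults to
#'   [default_typing_rules()].
#' @return an `AtomTypeAssignment`: list of three logical vectors
#'   (`hydrophobic`, `acceptor`, `donor`), each of length `n_atoms(mol)`.
#' @export
assign_types <- function(mol, rules = default_typing_rules()) {
  stopifnot(inherits(mol, "Molecule3D"), inherits(rules, "TypingRules"))
  n <- n_atoms(mol)
  nbrs <- vector("list", n)
  b <- mol$bonds
  if (nrow(b) > 0) {
    for (k in seq_len(nrow(b))) {
      nbrs[[b$i[k]]] <- c(nbrs[[b$i[k]]], b$j[k])
      nbrs[[b$j[k]]] <- c(nbrs[[b$j[k]]], b$i[k])
    }
  }
  out <- list(hydrophobic = rep(FALSE, n),
              acceptor = rep(FALSE, n),
              donor = rep(FALSE, n))
  for (r in rules) {
    hit <- .match_pattern(r$pattern, mol, nbrs)
    out[[r$channel]][hit] <- r$set
  }
  structure(out, class = "AtomTypeAssignment")
}

#' Atom indices belonging to a channel
#'
#' @param mol a [Molecule3D].
#' @param types an `AtomTypeAssignment` for `mol`.
#' @param channel one of `"all"`, `"hydrophobic"`, `"acceptor"`, `"donor"`.
#' @return integer vector of 1-based atom indices, ascending.
#' @export
channel_atoms <- function(mol, types, channel) {
  channel <- match.arg(channel, c("all", "hydrophobic", "acceptor", "donor"))
  if (channel == "all") return(seq_len(n_atoms(mol)))
  which(types[[channel]])
}
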