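---
title: "Typed distance-distribution descriptors for ligand-based screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typed distance-distribution descriptors for ligand-based screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ufsrat)
```

## The method

Ligand-based virtual screening asks: given one molecule known to bind a
target, which members of a multi-million-compound library could make
similar interactions? Alignment-based 3D comparison is far too slow at
that scale. The distance-distribution family of descriptors (ultrafast
shape recognition) sidesteps alignment entirely: a conformer is summarised
by the statistical moments of its interatomic distance distributions, and
two molecules are compared by the distance between their moment vectors.

This package implements the typed-atom extension of that idea. Four
reference points are derived from the heavy-atom coordinates:

* **P1** — the geometric centre (unweighted centroid);
* **P2** — the atom closest to P1;
* **P3** — the atom furthest from P2;
* **P4** — the atom furthest from P3.

P2–P4 are actual atoms; P1 usually is not. For a set of atoms and one
reference point, the Euclidean distances from each atom to the point form
a distribution whose **mean** (Å), **variance** (Å²) and **skew**
(dimensionless) are recorded. Four points × three moments = 12 values —
the classic all-atom shape descriptor. The typed extension repeats those
12 values for three pharmacophore subsets of the atoms — **hydrophobic**,
**hydrogen-bond acceptor** and **hydrogen-bond donor** — giving a
48-value vector in channel-major order
`[all, hydrophobic, acceptor, donor] × [P1..P4] × [mean, var, skew]`.
Shape alone cannot distinguish an oxygen from a methyl group; the typed
channels encode where the polar and apolar regions sit, which is what
binding actually depends on, while remaining agnostic about the scaffold
that holds them in place. That is what permits scaffold hopping.

Because only distances enter, the descriptor is invariant under rotation
and translation — and also under reflection: a molecule and its mirror
image are indistinguishable. That blindness to chirality is inherited
from the whole descriptor family and is a known limitation, not a bug.
The descriptor is also conformer-dependent: it describes the supplied 3D
geometry, so the practical workflow stores one database record per
low-energy conformer rather than trying to canonicalise.

Two vectors $M^q$ (query) and $M^c$ (candidate) are scored as

$$
S_{qc} \;=\; \frac{1}{\,1 + \sum_{k} w_k \,\tfrac{1}{12}\sum_{i \in k}
  \lvert M^q_i - M^c_i \rvert\,}
$$

with one weight $w_k$ per channel (defaults ¼ each, normalised to sum 1
at load). The score lies in $(0, 1]$, equals 1 exactly when the vectors
are identical, is symmetric, and strictly decreases when any single
entry's difference grows. Restricted to the single all-atom channel with
unit weight it reduces to the published all-atom form
$1/(1 + \tfrac{1}{12}\sum|M^q_i - M^c_i|)$, which is the property that
pins the functional form: the typed score is a per-channel weighted
generalisation of it, scaled to the same interval.

## Atom typing

Typing is a *user-definable atomic mask*: an ordered rule table applied
to every heavy atom, later rules overriding earlier ones. The default
table (shipped as `inst/extdata/typing_rules.tsv`, editable wholesale):

| pattern | channel | effect |
|---|---|---|
| `N,O;h>=1` | donor | set |
| `S;h>=1` | donor | set |
| `N,O;q<=0` | acceptor | set |
| `F` | acceptor | set |
| `N;adj=C=O` | acceptor | clear (amide N) |
| `C,S;nbr:C,S,X` | hydrophobic | set |
| `X` (halogens) | hydrophobic | set |

Channels are not exclusive — a hydroxyl oxygen is donor *and* acceptor —
and an atom matched by no rule (a noble gas, say) simply belongs to no
typed channel. Typing reads only the bond graph, element symbols,
per-atom hydrogen counts and formal charges, never coordinates, so it is
rigid-invariant and permutation-equivariant by construction.

The patterns are deliberately small atom-environment predicates rather
than a full substructure-query language: element list, hydrogen-count and
charge comparisons, a neighbour-element constraint, and an
adjacent-double-bond test (enough to express amide-nitrogen exclusion).
Protonation states are taken from the input file's formal charges and
never recomputed — descriptor pre-calculation must be deterministic per
input record. Aromaticity is not perceived: a pyrrole-type nitrogen is
excluded from the acceptor channel only through its written hydrogen
count, and users who need finer distinctions should override the rule
file.

## Numerical choices

* **Moments are population moments**: variance is the $1/N$ second
  central moment ($N$ may be 1), skew is $\mu_3 / \sigma^3$ with a guard
  — skew is defined as 0 whenever variance $< 10^{-12}$ — so degenerate
  inputs (single atoms, coincident points) produce finite descriptors. An
  alternative skew convention, the signed cube root of $\mu_3$ (in Å,
  used by some implementations of the original all-atom method), is
  available as `descriptor_config(skew = "cbrt-central")`; the database
  header records which convention built it, and scans refuse mismatched
  queries rather than silently comparing incompatible vectors.
* **Tie-breaking**: the closest/furthest selections for P2–P4 use exact
  floating-point comparison, first minimum / first maximum (lowest atom
  index). Determinism across platforms matters more than any notion of
  fairness among ties, and the input file's atom order is preserved for
  exactly this reason.
* **Shared reference points**: P1–P4 are computed once from *all* heavy
  atoms and reused by every channel. This preserves spatial registration
  between channels — a donor's distance to the all-atom centre is
  meaningful relative to other channels' distances. Per-channel reference
  points (each channel's own P1–P4) are available via
  `descriptor_config(per_channel_refpoints = TRUE)` for sensitivity
  studies; the two conventions produce incompatible databases and are
  flagged in the header.
* **Empty channels yield twelve zeros** rather than an error or a
  sentinel. The database must hold every molecule, and under the
  Manhattan-difference score two donor-free molecules then contribute
  zero difference in the donor block — "no donors" is maximally similar
  to "no donors", which is the chemically sensible reading.
* **Storage precision**: records store 48 single-precision values (a
  200-byte record: 8-byte unsigned id + 192 bytes of values). Scores are
  computed in double precision with stored values promoted on read; the
  query vector is quantised to single precision before comparison so that
  a molecule scanned against its own record scores exactly 1 rather than
  0.99998.
* **Ranked lists break score ties by ascending candidate id**, making
  top-N lists reproducible across runs, platforms and scan chunkings.

## The screening pipeline

`build_db()` makes one pass over an SD file: parse (fail-soft — a corrupt
record is skipped with a logged reason and never renumbers the ids
already assigned), strip hydrogens (folding explicit hydrogens into
per-atom counts, since donor typing needs them), type, compute, append.
Identical input and configuration give byte-identical databases. The
sidecar manifest (TSV: id, name, byte offset) supports direct retrieval
of hit records from the source file, and `scan_db()` is a single
sequential pass holding only a bounded top-N buffer, so memory does not
grow with library size. A 3.8-million-compound library occupies
$200 \times 3.8\times10^6$ bytes ≈ 725 MB.

The drug-likeness step uses the rule of five: molecular weight ≤ 500 Da,
H-bond donors ≤ 5 (counted as N–H plus O–H hydrogens), acceptors ≤ 10
(N plus O atoms), logP ≤ 5. The classic convention tolerating one
violation is the default, with the strict all-rules reading selectable
(`max_violations = 0`). logP is never computed from structure — it is
accepted from an external property table when available and otherwise
left unevaluated, mirroring the pre-computed-database setting the filter
comes from.

## Enrichment evaluation

Ranking power on a labelled actives/decoys library is summarised by the
enrichment factor at top fraction $f$:

$$
\mathrm{EF}(f) = \frac{\text{fraction of actives in the top }
\lceil f N \rceil}{f},
$$

so EF = 1 matches random picking and EF ≤ $1/f$ always. Ceiling rounding
guarantees a non-empty top set at small $f$; at tiny $N$ this slightly
inflates EF, which is why the tests that probe EF's extremes use
libraries where $fN$ is integral. The harness ranks each target's library
with each method, reports per-target EF at 0.5%, 1%, 2% and 5% (the
standard reporting fractions), cross-target arithmetic means, and
pairwise win counts (method A strictly beats method B; ties are not
wins). A method that throws on a target is excluded from that target's
means with a logged reason rather than aborting the run. Two conventions
are fixed and documented rather than configurable per run: the query
molecule is *not* a member of the ranked library, and recall is counted
over all labelled actives whether or not they are retrievable at the
fraction cutoff.

A label-permutation test (`permutation_test_ef()`) guards against
reading noise as enrichment: it re-draws the active set uniformly from
the ranked ids and reports the one-sided add-one p-value.

## What the synthetic fixtures do and do not show

The generator produces point clouds, not molecules: atoms uniform in a
10 Å box (a typical drug-like diameter), elements drawn from a
C-rich/N/O/S palette, chain connectivity (atom $i$ bonded to atom
$i{-}1$), and hydrogen counts from the same valence model the SD reader
applies — so generated molecules round-trip through SD files with their
typing intact, and mid-chain nitrogens type as donors while mid-chain
oxygens are acceptor-only. "Actives" for a benchmark target are
coordinate-jittered copies of a seed molecule (Gaussian noise, default
σ = 0.05 Å, a tight conformer family); decoys are independent random
molecules. Everything is deterministic given an integer seed
(Mersenne-Twister, caller's RNG state restored afterwards).

Passing tests on these fixtures demonstrate the *machinery*: descriptor
arithmetic, invariances, storage, retrieval order, and that the score
separates near-copies from unrelated geometry. They do not demonstrate
chemical enrichment on real targets — real actives share pharmacophores,
not coordinates, and real decoys are property-matched rather than random.
Benchmarks on real labelled collections (the harness accepts any
user-supplied library in the same directory layout, and any external
scoring function for comparison) are the only evidence that transfers.

Default problem sizes were chosen to exercise every code path at
laptop-interactive cost: the benchmark preset uses 10 targets × (10
actives + 490 decoys), retrieval checks use 500-record databases with
top-50 scans across 10 seeds, and the invariance suite covers 100
fixtures × 100 random rigid transforms.

## A worked example

```{r example, eval = FALSE}
library(ufsrat)

# a small library and a query, via the deterministic generator
dir <- tempfile(); dir.create(dir)
mols <- lapply(1:100, function(k)
  random_molecule(fixture_spec(), seed = k, id = paste0("mol", k)))
write_sd(mols, path = file.path(dir, "library.sdf"))

# pre-calculate descriptors once
build_db(file.path(dir, "library.sdf"), file.path(dir, "library.ufsrat"))

# screen: only the query's descriptors are computed at query time
q <- strip_hydrogens(read_sd(file.path(dir, "library.sdf"))[[7]])
hits <- scan_db(ufsrat_descriptors(q, assign_types(q)),
                file.path(dir, "library.ufsrat"), n = 5)
hits
```

## Known limitations

* Reflection invariance: enantiomers are indistinguishable.
* Conformer dependence: similarity is between supplied geometries, and a
  biologically irrelevant conformer yields biologically irrelevant hits.
* The default typing table is a reasonable pharmacophore convention, not
  a calibrated one; ionisation and tautomers are taken as written in the
  input.
* V2000 SD files only; V3000 records are rejected with a clear error.
* Moment descriptors are a lossy shape summary: molecules with different
  geometry can collide in descriptor space, which is the price of
  constant-size records and linear-scan speed.
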