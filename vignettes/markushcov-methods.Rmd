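---
title: "Coverage analysis of Markush combinatorial libraries: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage analysis of Markush combinatorial libraries: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

A Markush structure in a product patent — a scaffold with $P$ variable
positions, each allowing a list of substituent fragments — implicitly claims
a combinatorial library (MCL) of up to $\prod_p |R_p|$ molecules. Only a
small set of those compounds is ever reported as synthesized (the
bibliographical database, BD), and hit-to-lead practice under Free–Wilson
assumptions keeps that set close to the original hit. `markushcov`
quantifies how much of the claimed chemical space such a subset actually
represents, and contrasts it with random sampling and with a rational
one-per-partition selection.

The pipeline is: enumerate the library, compute a descriptor matrix, reduce
it by PCA, partition the reduced space, then score selections with two
statistics:

* **space coverage** $\mathrm{SC} = 100\, k_{oc} / K$ — the percentage of
  the $K$ partitions containing at least one selected compound
  ($k_{oc}$ occupied);
* **population coverage** $\mathrm{PC} = 100\, n_{oc} / N$ — the
  percentage of all $N$ library compounds that live in the occupied
  partitions ($n_{oc}$ their total population).

A rational selection (one representative per partition) attains
SC = PC = 100 by construction; a focused analog series typically scores far
below an equally sized random sample. A third library, the BCL, is the
cross product of only those fragments that occur in BD — the combinatorial
space already proven synthetically accessible — and always satisfies
BD ⊆ BCL ⊆ MCL as structure sets.

## Enumeration

Fragments and scaffold use the standard R-group dummy-atom convention:
`[*:p]` marks position $p$ on the scaffold (written directly after its
neighbour atom, as a branch or terminally), and each fragment starts with
its attachment dummy. Products are formed by splicing the fragment body
onto the scaffold position with a single bond; fragment ring-closure labels
are remapped into a reserved `%40`–`%99` range per position so cyclic
fragments can be spliced inside open scaffold rings. Every product is
canonicalized (Open Babel) and duplicates — distinct fragment tuples
yielding the same molecule, as happens on symmetric scaffolds — are removed
keeping the first-encountered provenance tuple, so a library is a set of
molecules, each knowing which fragment choice produced it.

Positional isomerism ("all positional substitutions of the aryl ring") is
modelled by listing each isomer as its own fragment, which keeps the
enumerator a pure cross product. A cap (default $10^6$) refuses
accidentally astronomical spaces; practice for such patents is to reduce to
the explicitly listed substituents first.

## Chemical space

The descriptor stage substitutes an open set of 1D/2D descriptors (Open
Babel physicochemistry: MW, logP, TPSA, molar refractivity, H-bond
donors/acceptors, rotatable bonds; bond-order counts; cyclomatic ring
count; aromatic-bond fraction; per-element counts; heteroatom fraction) for
proprietary descriptor packages. The method is descriptor-set agnostic: it
needs a dense 2D property space, not one vendor's list, and a precomputed
matrix can be supplied as CSV instead.

Descriptors have incommensurate units, so columns are z-scored before PCA
(unscaled PCA would be dominated by molecular-weight-like columns);
zero-variance columns are dropped first. The space keeps the smallest
number $m$ of leading components whose cumulative explained variance
reaches the target (default 95%). Component signs are fixed by making each
component's largest-magnitude loading positive, so scores are reproducible
across platforms. Projection of new compounds applies the stored
centering/scaling and loadings; in the intended workflow BD and BCL are
subsets of the MCL, so their coordinates are row lookups.

## Partitioning

Ten methods divide the space into $K$ partitions:

* **Hierarchical agglomerative clustering** (Euclidean) with single,
  complete, average, median, centroid and Ward linkage, via
  `stats::hclust` cut at $K$. Following `hclust`'s contract, median and
  centroid linkage receive squared distances and may produce inversions;
  the tree is still simply cut at $K$. Tie-breaking is `hclust`'s own
  deterministic rule.
* **k-means** with 10 restarts keeping the best inertia (seeded), and
  **k-medoids** (PAM, `cluster::pam`). PAM's deterministic BUILD
  initialization is used rather than a randomized seeding: it needs no
  seed, is the textbook algorithm, and makes results order-reproducible.
  The limits $K = 1$ and $K = N$ are handled explicitly.
* **Equal-width binning** and **optimum-variance binning** on the first
  $d = \min(m, 5)$ components with $b$ bins per axis, where $b$ is the
  smallest integer with $b^d \ge K_{\mathrm{nominal}}$. The dimension cap
  keeps grids non-degenerate. $K$ is the number of *occupied* cells, so
  for binning methods $K$ can fall below the nominal grid size and the
  mean population rises correspondingly. Optimum-variance binning places
  each axis's bin edges to minimize the within-bin sum of squares by
  dynamic programming over contiguous segments (Fisher-style); axes with
  more than 800 points are first compressed into 800 weighted quantile
  groups, and edges fall midway between adjacent group extremes. This is
  a documented reconstruction of cell-based optimal binning, not a
  replica of any particular prior code.

**Choosing K.** The average-silhouette criterion (k-means over a k grid)
is provided, and the full curve is always returned: on combinatorial
libraries the strong inter-descriptor correlation typically yields a
concave or monotone curve whose largest values sit at useless extremes
(many tight clumps score near 1 at fine k), so no interior optimum exists.
The package therefore defaults to the square-root family of rules:
$K = \lceil\sqrt N\rceil$ (default), half of it, or ten times it. The
ceiling convention is adopted because it reproduces the reference counts
for all library sizes studied (e.g. 160 for $N = 25{,}472$, and the
80/160/1600 triple). Population diagnostics — mean and SD of partition
populations and the singleton percentage — expose unbalanced methods:
single, median and centroid linkage chain into one hyper-populated cluster
plus singletons, which is why comparative tables default to the compact
methods (average, complete, Ward, k-means, k-medoids, OV binning).

## Coverage statistics and baselines

`coverage()` reports exact SC/PC with their integer ingredients. Printed
percentages are rounded to one decimal **half-up** (36.25 prints as 36.3),
matching conventional table reporting; R's default round-half-to-even
would print 36.2.

The random baseline draws size-matched selections uniformly *without*
replacement (with replacement would distort the size matching) and averages
coverage over repetitions (default 5000, seeded). Its analytic counterpart
is exact: a partition with population $n_c$ is missed by a sample of size
$s$ with probability $\binom{N-n_c}{s}/\binom{N}{s}$, so

$$E[\mathrm{SC}] = \frac{100}{K}\sum_c \left[1 - \frac{\binom{N-n_c}{s}}{\binom{N}{s}}\right],
\qquad
E[\mathrm{PC}] = \frac{100}{N}\sum_c n_c\left[1 - \frac{\binom{N-n_c}{s}}{\binom{N}{s}}\right],$$

computed with log-binomials for stability. The Monte-Carlo and analytic
routes are kept separate deliberately; the test suite checks they agree
within four Monte-Carlo standard errors across randomized partition
compositions (with a one-repetition resolution floor for the saturated
case where every sample covers everything and the empirical SE collapses
to zero).

**Rational selection** picks, per partition, the member nearest to the
partition centroid in PC coordinates (the stored medoid for PAM), ties to
the lowest index. How the one representative is chosen does not affect
SC/PC of the full rational selection — any one-per-partition rule scores
100/100 — so nearest-to-centroid was chosen as the natural, deterministic
representative.

## The synthetic scenario generator

No public accessions exist for patent-derived libraries of this kind, so
the generator creates the three-library situation synthetically. Defaults
(3 positions × 8 fragments = 512 compounds, BD of 25 ≈ 5% of the library,
focus 0.8) give a desk-scale analogue of the studied patents, where BD is
0.2–5% of the MCL; tests that need finer coverage resolution state larger
sizes (e.g. 10×10×10 with BD 40).

*Abstract mode* draws, for every fragment, a latent contribution vector in
a 10-dimensional descriptor space, and a compound's descriptors are the sum
of its fragments' contributions plus Gaussian noise (SD 0.5 against
unit-variance contributions) — the additive Free–Wilson structure that
makes combinatorial descriptor matrices strongly correlated. A
parameter-recovery test regresses descriptors on fragment indicators and
sees $R^2 \to 1$ as noise vanishes. Within each position the contributions
form an AR(1) series (correlation 0.7 between neighbours): substituent
lists in real patents are homologous series, and neighbouring fragments
(methyl/ethyl, F/Cl) are chemically similar.

*SMILES mode* draws fragments from curated substituent pools (halide/polar,
alkyl, aryl, heteroaryl — each ordered as a rough chemical series) on a
benzamide-like scaffold, enumerates real molecules and computes real
descriptors; it exists to keep the cheminformatics path honest end-to-end.

The *focus* model generates BD around a hit tuple: each position reuses the
hit's fragment with probability $\varphi$; otherwise the fragment is
redrawn with probability decaying geometrically in series distance from the
hit's fragment, with effective decay $\gamma^\varphi$ (base $\gamma=0.5$).
One knob therefore controls both how often positions are modified and how
locally: at $\varphi = 0$ the decay vanishes and BD is a uniform draw; at
$\varphi = 1$ every draw is the hit and the duplicate-resolution step (a
single-position mutation of the fresh draw) makes BD the hit plus
single-point modifications. A fixed-decay variant was tried first and
rejected because it violated both limiting behaviours: with uniform
replacement over independent fragment contributions, a one-fragment swap is
a full-scale move in descriptor space and the "focused" subset covered as
much as random; with a fixed proximal decay, the $\varphi = 0$ draw stayed
hit-local instead of uniform.

What the generator does *not* emulate: synthetic feasibility, activity
cliffs, descriptor distributions of real molecules (abstract mode is
Gaussian by construction), multi-scaffold patents, or vague Markush
indeterminations. Passing tests therefore show the *statistics* behave as
designed under additive combinatorial structure, not that any particular
real patent would score identically.

## Numerical choices and edge cases

* Degenerate clustering (more clusters than distinct points) raises an
  error for the relocation methods; the silhouette scan records such k as
  missing instead of failing.
* All-identical data bins into a single occupied cell; $K = 1$ gives
  SD 0 and PC 100 for any non-empty selection; $K = N$ gives 100%
  singletons.
* Empty selections are rejected (coverage undefined) rather than scored 0.
* Enumeration products that fail to parse are dropped with a warning;
  malformed SDF records are skipped with a count report.
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; scenario generation is bit-reproducible from
  spec + seed.

## Problem sizes used by the test and acceptance suites

Deterministic worked examples run at their natural sizes (50- and
25,472-compound partition configurations; a 19 × 15 × 58 = 16,530-compound
enumeration). Statistical properties are tested at desk scale chosen for
stable inference: 20 randomized partition compositions with $N \le 2000$
and 5000-repetition baselines for the Monte-Carlo/analytic agreement, and
40 seeded 512-compound scenarios for the focused-vs-random comparison
across Ward, k-means and OV binning.

## Known limitations

* Visualization covers PC-plane scatter/contour and per-component density
  panels; no t-SNE embedding is provided.
* The optimum-variance binning procedure is an independent reconstruction
  of axis-wise optimal variance partitioning; other implementations may
  place ties differently.
* Generic Markush language (variable ring sizes, "optionally substituted"
  clauses) is out of scope: fragment lists must be explicit, with
  positional isomers enumerated as separate fragments.
* Descriptor values depend on the installed Open Babel version; spaces
  built with one version should not be mixed with projections from
  another.
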