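---
title: "Branch-site screening for adaptive evolution: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch-site screening for adaptive evolution: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hearsel)
```

This vignette is the package's own account of its science: the models it
fits, the numerical machinery behind them, the choices made where the
design was genuinely open, and what the synthetic-data tests do and do not
establish about real data.

## The substitution model

All likelihoods are built on the Goldman–Yang codon model over the 61
sense codons of the standard genetic code (lexicographic order, A < C <
G < T; the three stops are excluded from the state space, which is why an
internal stop codon in an alignment is a hard error).  For codons *i*, *j*
differing at exactly one nucleotide,

    q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous],

zero for multi-nucleotide changes, diagonal by row sums.  `kappa` is the
transition/transversion rate ratio, `omega` the dN/dS ratio, and `pi` the
equilibrium codon frequencies — the empirical codon-table (F61)
frequencies of each alignment, with a pseudocount (default 1e-6) so short
genes with unobserved codons still yield an irreducible chain.  The matrix
is scaled so branch lengths are expected substitutions per codon.
Transition matrices come from one symmetric eigendecomposition of
`D^{1/2} Q D^{-1/2}` (valid because the chain is reversible), so a single
decomposition serves every branch; tests assert detailed balance,
Chapman–Kolmogorov, stochasticity, and the stationary limit.

Ambiguous codons (IUPAC letters, partial gaps) enter the likelihood as
partial indicator vectors over their compatible sense codons; full gaps
are entirely missing data (all-ones vectors).  This is the standard
missing-data treatment; an all-gap column therefore has likelihood 1.

## The branch-site test and its two-step fit

Branch-site Model A assigns each site to one of four classes
(see `?branch_site_params`): purifying everywhere (`omega0`, proportion
`p0`), neutral everywhere (`p1`), and two classes that switch to
`omega2 >= 1` on the *foreground* branches while keeping `omega0` or 1 on
the background.  The test compares the alternative (`omega2` free) to the
null (`omega2 = 1`, the four-class structure retained) by a
likelihood-ratio statistic referred to chi-square with one degree of
freedom.  The Methods prose of some descriptions of this test describe the
null as estimating only `omega0`; the cited "test 2" fixes `omega2 = 1`
instead, and that is what this package implements.  A 50:50 point-mass /
chi-square boundary mixture is available behind `lrt(..., mixture = TRUE)`
but is off by default; the plain chi-square reference is conservative at
the boundary, which the calibration test demonstrates empirically.

**Common rate scale.** The class rate matrices share one scale factor:
with `r(omega)` the raw mean rate of the matrix at a given `omega`, every
class matrix is divided by `R = (p0 + p2a) r(omega0) + (p1 + p2b) r(1)`,
the mixture-averaged rate on the background.  Branch lengths are therefore
substitutions per codon averaged over site classes, and a class-2 site
genuinely evolves faster on the foreground under `omega2 > 1` rather than
merely shifting its synonymous/nonsynonymous composition.  This coupling
is where most of the test's detection signal comes from, and the simulator
uses the identical convention (an early version of this package scaled
each class to unit rate separately; the test loses nearly all its power
under that convention, which is worth knowing when comparing
implementations).

**Two-step optimisation.**  Joint optimisation of branch lengths with the
mixture parameters is prone to local minima, so the pipeline first fits
the one-ratio M0 model (single `omega`, all branch lengths free), freezes
the estimated lengths, and then fits the branch-site null and alternative
on the fixed tree:

* `fit_m0()` alternates a bounded quasi-Newton step on
  `(log kappa, log omega)` with exact coordinate-ascent sweeps over branch
  lengths.  Each sweep optimises one branch at a time by Brent's method
  against cached inside (subtree) and outside (root-side) partial
  likelihoods, recomputed before every branch so each one-dimensional step
  is an exact profile of the full likelihood; the alternation stops when
  the log-likelihood changes by less than 1e-7.  Bounds:
  `kappa` in [0.01, 100], `omega` in [1e-4, 20], lengths in [1e-6, 20].
* `fit_branch_site()` profiles the class proportions out of the outer
  optimisation entirely.  Because the proportions factorise as a product
  of two binary mixtures, the inner maximisation has a closed-form EM
  M-step; each outer evaluation (over `log kappa`, `log omega0`, and
  `log(omega2 - 1)` when free) runs that EM from fixed deterministic
  starts plus a quasi-Newton polish.  The scale factor `R` couples the
  proportions to the expensive pruning step, so each outer run holds the
  proportions inside `R` fixed and a second warm-started round updates
  them to self-consistency.  Three fixed multi-starts guard against local
  optima (`n_starts`); `branch_site_test()` additionally seeds the
  alternative fit from the null optimum, which guarantees the nesting
  `lnL_alt >= lnL_null` by construction.

Felsenstein pruning runs in C++ (RcppArmadillo) with per-node log scaling
and site-pattern compression; classes 2a/2b reuse the class-0/1 up-passes
and only recompute the foreground-to-root path.  Pruning is checked
against an explicit enumeration over internal-node states on trees of up
to five taxa.

## BEB site posteriors

`beb_posteriors()` integrates the site-class posteriors over a uniform
grid on `(p0, p1, omega0, omega2)` — by default 10 points per parameter,
cells with `p0 + p1 > 1` dropped, equal prior mass per retained cell —
holding `kappa`, the branch lengths, and the rate scale `R` at their
maximum-likelihood values.  The `omega2` grid spans [1, 11] by default
(midpoints), a range that brackets the `omega2` values the screening's
alternative fits produce; the grid is configurable, and collapsing it to
the MLE point reproduces naive empirical Bayes exactly (a unit test).
Because the prior factorises over the proportion grid and the omega grid,
the posterior is a product of a prior-averaged class proportion and a
grid-averaged class likelihood; this equals the full sum over the product
grid exactly and is checked against an exhaustive-summation oracle.  Sites
with posterior above 0.95 (configurable) are reported as positively
selected, with optional 1-based positions on a named reference taxon
(gaps in the reference are skipped).  Which grid dimensionality the
classic implementations use varies between versions; the four-parameter
grid here is a documented choice.

## The gene catalogue and its filters

`merge_gene_lists()` unions source panels after canonicalising through an
explicit synonym map (a static table, not a live lookup — determinism, no
network).  `filter_orthology()` reproduces the screening's exclusions: a
gene is dropped when it lacks reference-genome coordinates, when more
than `max_missing` (default 1) roster species have no ortholog after
same-taxon substitution, or when any species shows a one-to-many or
many-to-many relationship.  Substitution (`substitute_species()`) runs
first: a missing roster species is replaced by an alphabetically-first
same-taxon pool species with a one-to-one ortholog, recorded in the
provenance column.  Whether the original screening applied the missing
and multi-orthology criteria before or after substitution is not
documented; applying substitution first is this package's documented
reading.

## Regulatory-domain and TAD assignment

All coordinates are 0-based half-open (BED convention) everywhere
internally; overlap means at least one shared base (configurable minimum).
Regulatory domains follow the GREAT basal-plus-extension rule: a basal
window `basal_up` upstream / `basal_down` downstream of the strand-aware
TSS (defaults 5,000/1,000 bp — the GREAT defaults, since the rule is named
but its distances are not restated in the screening), extended on each
side to the nearest other gene's basal boundary, capped at
`max_extension` (default 1 Mb) from the TSS, never shrinking below the
basal window, clipped at chromosome bounds.  TAD assignment is permissive
by design: a region reaches every gene whose TSS shares a TAD with *any*
base of the region, consistent with treating TADs as compartments whose
elements could potentially contact any promoter within them.  Region
strand is ignored (accelerated elements are genomic, not transcribed,
features).  Every interval operation is tested against a per-base
brute-force oracle.

## What the simulators emulate — and what they do not

`simulate_alignment()` draws each site's class, draws the root codon from
`pi`, and applies the exact transition matrix of the class- and
branch-appropriate rate matrix along each branch (matrix exponential, not
an event-level simulation), under the same common-scale convention as the
fits.  The default study tree is a 14-leaf caricature of the screening
roster (two primates, two rodents, three laurasiatherians, a marsupial,
three birds, two reptiles, an amphibian) with branch lengths in
[0.01, 0.5] and the therian stem as foreground.  The generators do *not*
simulate indels, alignment error, GC-biased gene conversion, or
recombination; passing tests therefore validate the inference machinery
under the model, not robustness to misalignment — which the screening
addresses operationally instead, by intersecting results from two
alignment methods (`consensus()`).

`simulate_ortholog_table()` and `simulate_annotation()` plant exact counts
of filter failures and of coding/intronic/domain-only/TAD-only/outside
regions in a geometry (3 Mb gene spacing, 20 kb bodies, 3 Mb TADs) chosen
so the planted categories are unambiguous; they error on infeasible specs.

## Study scales used by the tests

The test-suite conditions are fixed study designs, chosen once:

* *M0 recovery*: 20 alignments, 14 taxa, 500 codons, `kappa = 2`,
  `omega = 0.3`; median recovery within 20%/15%.
* *Null calibration*: 200 alignments under the Model A null
  (`omega2 = 1`), 8 taxa, 200 codons; the rejection rate at 0.05 must not
  exceed the binomial upper bound — the chi-square reference is
  conservative at the boundary, so observed rates sit well below 0.05.
* *Power*: `omega2 = 4` on ~10% of sites over a 0.5-substitution
  foreground stem, strongly conserved background (`omega0 = 0.05`,
  typical of hearing-loss genes under purifying selection), 500 codons;
  the test must reject in a clear majority of replicates and BEB must
  rank planted sites above background.  Calibration and power runs use
  single deterministic starts with the alternative seeded at the null
  optimum (the production default remains three multi-starts); this choice
  can only lose likelihood on the alternative side, i.e. it is
  conservative for the type-I bound being asserted.

## Known limitations

* The foreground is whatever the input tree labels; the package does not
  decide whether an unrooted representation should flag one or both
  branches flanking the root.
* `omega2` is bounded at 50; saturated genes hit the bound and should be
  interpreted as "large" rather than point estimates.
* The common-scale factor uses the background mixture average; classic
  implementations do not document their exact convention, and small
  likelihood differences against them are expected even at identical
  parameters.
* Power at realistic mammalian-stem lengths (~0.15 substitutions per
  codon) is modest for single genes; the screening's strength is the
  panel-level FDR ranking, not any single gene's p-value.
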