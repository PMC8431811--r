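---
title: "Methods: conservation profiling, primer thermodynamics and gel-fingerprint clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation profiling, primer thermodynamics and gel-fingerprint clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sscpkit)
```

`sscpkit` implements the computational side of an SSCP screening
workflow: locating conserved primer windows on a marker-gene alignment,
screening candidate universal primer pairs thermodynamically, extracting
and grouping amplicons in silico, and turning digitized gel band tables
into normalized fingerprints, similarities and dendrograms. This
vignette records the models, the tunable parameters and the design
decisions, in the package's own words.

## Conservation profile

For each alignment column the package computes Shannon entropy over the
five states A, T, C, G and `-`,
$S_i = -\sum_m P(x_m)\,\log P(x_m)$ with $0\log 0 \equiv 0$, and a
similarity score: the percentage of the most frequent *nucleotide* in
the column. Three conventions are deliberate and configurable:

* **Log base.** The entropy base is not fixed by the five-state model;
  the default is the natural log (so $0 \le S_i \le \ln 5 \approx
  1.609$), with `"2"` and `"10"` available via `log_base`.
* **Gaps.** A gap is a *bona fide* fifth state for entropy. For
  similarity, gap rows stay in the denominator but can never be the
  modal symbol — the score asks "what fraction of rows carry the
  majority nucleotide", so an indel-riddled column scores low even if
  the residues that remain agree.
* **Ambiguity codes** (N, R, Y, ...). The five-state model has no slot
  for them, so they are excluded from both statistics and tracked by the
  `coverage` column (the fraction of rows that are unambiguous residues
  or gaps). A column consisting entirely of ambiguity codes is reported
  as `NA` with `defined = FALSE` rather than aborting the profile.

Sequences are normalized on ingest (uppercase, U→T, `.`→`-`), and all
column indices in reports are 1-based.

## Nearest-neighbor thermodynamics

Primer-quality screening re-implements the standard two-state
nearest-neighbor model rather than calling an external web tool, so the
whole pipeline runs offline and deterministically.

**Melting temperature.** Unified NN parameters (SantaLucia 1998) give
duplex $\Delta H$ and $\Delta S$ including the terminal-pair initiation
terms; the monovalent-salt correction is entropic,
$\Delta S' = \Delta S + 0.368\,(N-1)\ln[\mathrm{Na^+}]$, and
$T_m = \Delta H / (\Delta S' + R \ln C_T/4) - 273.15$
with $C_T/4$ for non-self-complementary duplexes at equal strand
concentrations (self-complementary oligos use $C_T$ and the symmetry
entropy correction). Defaults are 50 mM monovalent salt and 0.25 µM
total oligo — the documented defaults of common primer-QC calculators —
and divalent ions fold in as the usual $120\sqrt{[\mathrm{Mg^{2+}}]}$
monovalent equivalent. For the two published SSCP primers this engine
reproduces the printed 53.3/51.7 °C within the documented ±1.5 °C
(52.9/50.6 °C).

**Dimers.** `duplex_delta_g()` reports the minimum free energy over
*all* anti-parallel pairings of the two oligos, not just rigid
offset alignments: matched Watson-Crick pairs score by NN stacking
evaluated at the reporting temperature (default 25 °C, the convention
of primer-QC dimer reports), gaps between helices cost a
length-dependent entropic bulge/interior-loop penalty, and unpaired
neighbors of the two terminal pairs contribute dangling-end
stabilization. A rigid single-offset scan systematically underestimates
dimer stability — bulged structures dominate for the published pair —
which is why the looped model is the default and only model. Structures
must contain at least one helix of three consecutive pairs
(`min_helix`); otherwise the function returns the 0 sentinel ("no
dimer"). No duplex-initiation term is added, matching how dimer ΔG
values are conventionally reported. The implementation is a dynamic
program over last-paired positions with the helix-length requirement
tracked in the state; tests compare it against an independent recursive
enumeration of the full structure space on short oligos.

**Hairpins.** `hairpin_delta_g()` scans simple stem-loops: contiguous
Watson-Crick stems of ≥ 2 pairs scored by stacking, closed by a hairpin
loop of ≥ `min_loop` (default 3) bases with a tabulated entropic cost.
Positive minima are reported as such (an unstable best hairpin is
information); with no possible stem the 0 sentinel is returned. The
model deliberately excludes non-canonical G·T stems and bulged stems —
adequate for primer QC, where the question is "is there a stable
hairpin", not "what is the exact fold".

## Primer-pair search

Conserved windows are maximal runs of columns with entropy ≤
`max_entropy` and similarity ≥ `min_similarity`, at least as long as the
shortest primer; candidates are all primer-length sub-windows (15-30 nt
bounds, default 18-24), with the oligo taken as the column-majority
consensus (no degenerate bases; gap-majority columns drop out and such
candidates are discarded). Reverse candidates are the reverse complement
of the consensus slice. A candidate's *universality* is the fraction of
alignment sequences whose ungapped slice under the window matches with
at most `max_mismatch` mismatches (default 0) and none in the 3′
terminal `anchor_3prime` bases (default 3) — polymerase extension is
most sensitive there.

Pairs are kept when the median ungapped span across the alignment falls
in `len_window` (default 150-260 nt around the 200 nt target — short
enough for conformation-sensitive separation, long enough to span a
hypervariable core) and, by default, when they enclose at least one
column above the 90th entropy percentile (`require_variable_core`): a
universal pair around an invariant core would fingerprint nothing.
Ranking is lexicographic — universality (desc), enclosed maximum entropy
(desc), distance from the length target, thermodynamic penalty
($|\Delta T_m|$ plus any dimer stability beyond −8 kcal/mol), leftmost
forward coordinate as the deterministic tie-break.

## In-silico PCR

Binding-site search slides the primer (and, on the minus strand, its
reverse complement) along the template with a mismatch budget (default
2 — templates may deviate from consensus primers) and the same
mismatch-free 3′ anchor (default 3). Every forward/reverse site
combination is enumerated, then size-filtered to `size_window`
(default 150-300 nt) — the computational counterpart of cutting a gel
slice. Per template the status is explicit: `ok`, `no_amplification`,
or `ambiguous` with all in-window products listed; ambiguity is a
reported condition, never an exception or a silent drop. Amplicons span
primer site to primer site inclusive, matching how amplicon lengths are
conventionally reported.

Grouping is exact string identity after normalization; groups are
labelled `set1, set2, ...` by decreasing size (representative sequence
as tie-break), so labels are order-invariant. Substitution summaries
require equal-length representatives (the no-indel case); anything else
must be aligned externally first, and the error says so.

## Gel fingerprints

**Migration curves.** Each gel carries ladder lanes (first and last).
The standard curve is fit by least squares as migration distance versus
$s = \log_{10}(\text{size})$, by default the Gaussian form
$d(s) = A\,e^{-(s-\mu)^2/(2\sigma^2)} + c$ fitted with
Levenberg-Marquardt (`minpack.lm`), with a log-linear fall-back. On a
monotone flank of a Gaussian the individual parameters are only weakly
identified — $A$, $\mu$, $\sigma$ trade off — so quality is judged by
$R^2$ and by the fitted curve, not by parameter recovery; fits must be
monotone over the ladder range, and callers (including
`normalize_gel()`) reject curves with $R^2 < 0.95$. A minimum of four
rungs is enforced (`InsufficientLadder` otherwise).

**Normalization.** A band maps through its own gel's curve to a
fragment size and through the reference gel's curve back to a position.
Inversion is numeric (monotone root-finding) over the ladder range plus
a 0.3 margin in $s$; bands beyond that are flagged `extrapolated` with
`NA` positions rather than dropped, and bands inside the margin but
outside the fitted range are mapped *and* flagged.

**Similarity.** The band-difference similarity is a Dice coefficient
over tolerance-matched bands: with $m$ one-to-one matches at
$|\Delta\text{position}| \le$ `tolerance` (default 4, in reference-gel
units), similarity $= 100 \cdot 2m/(n_A+n_B)$; a Jaccard variant is one
argument away. The matcher is a greedy sweep over sorted positions,
which attains the maximum matching for threshold matching on a line
(verified against an exhaustive assignment oracle in the tests). Two
empty patterns score 100 — identical absence; this keeps the similarity
total — and empty-versus-nonempty scores 0.

**Clustering.** UPGMA on distance $= 100 -$ similarity, with the merge
between the two clusters of smallest average inter-point distance,
ultrametric node heights at half the merge distance, and ties broken by
the lexicographically smallest pair of cluster labels, making the tree
invariant to input order. Trees export as Newick and `ape::phylo`.
`cut_dendrogram()` groups everything merged below a similarity cut;
`compare_partitions()` cross-tabulates two assignments and reports the
Hubert-Arabie adjusted Rand index (1 for identity, ≈ 0 at chance; the
degenerate all-singleton versus all-one comparison is ≤ 0).

## Simulators and what they do (not) show

The three generators are pure functions of their arguments and seed.

* `simulate_msa()` mutates an ancestral sequence block-wise; the default
  blueprint is a 21/160/21 conserved-variable-conserved architecture
  (per-column substitution probabilities 0.005/0.35/0.005 across 24
  sequences), mirroring short conserved primer landing sites flanking a
  hypervariable core in an SSU rDNA fragment.
* `simulate_templates()` wraps planted primer sites and insert variants
  in random flanks, so amplification and grouping have exact truth.
* `simulate_gel()` defaults mirror the screen the package targets: 73
  sample lanes in seven fingerprint groups of 17/15/7/20/8/5/1, three
  bands per lane, spread over eight gels with a 100-1000 bp ladder first
  and last on each gel, per-gel affine warps (slope 0.9-1.1, offset ±5)
  and 0.5-unit Gaussian band noise — chosen once as a realistic
  digitization noise level on a ~150-unit migration range. The reference
  migration model is the Gaussian flank `reference_migration()`.

These fixtures validate the *computational* contract: that planted
structure is recovered exactly under known distortions. Real gels add
effects the generators do not model — band-intensity variation, smiling
beyond affine warp, co-migrating conformers, partial denaturation — so
passing tests certify the analysis chain, not wet-lab robustness. The
simulated warps are affine; the normalization path itself is exercised
on the nonlinear Gaussian scale because warps apply to ladder and
samples alike.

Problem sizes used in the test suite (1000 random columns, 200
oracle-checked oligo pairs at length ≤ 10, 500 round-trip templates, 500
band-pattern pairs, 200 five-leaf trees, one 73-lane end-to-end
recovery) were chosen to exercise each property across its input space
at desk scale.

## Known limitations

* Thermodynamic agreement with proprietary calculators is tolerance-
  based (±1.5 °C for $T_m$; sign and ±2 kcal/mol for dimer ΔG): their
  exact parameter sets, dangling-end treatments and salt models are not
  published in full.
* The similarity coefficient behind published banding-similarity
  percentages is not printed in the upstream tool's description; the
  Dice form implemented here matches the "matching/non-matching bands"
  phrasing, and Jaccard is provided for sensitivity analysis.
* Band calling from gel images, external-database primer specificity
  screening (BLAST), degenerate-primer design, and folding-based
  prediction of SSCP band mobility are out of scope.
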