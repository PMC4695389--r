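---
title: "Methods: amine-recognition motifs, their census, and their evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amine-recognition motifs, their census, and their evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amrec)
```

## The problem

Class-A GPCRs that detect amines anchor the ligand's protonated amino
group through an acidic side chain. The classical site is an aspartate at
Ballesteros–Weinstein position 3.32 on transmembrane helix III; a
non-classical alternative is an aspartate on helix V at 5.42, with some
mammalian receptors placing the acid one helical turn later at 5.43.
Receptors carrying both acids can bind diamines, which bridge the two
carboxylates. `amrec` asks three quantitative questions about a receptor
repertoire: *where* are the generic positions in each sequence, *how many*
receptors carry each motif configuration, and *in what order* were the two
sites gained and lost on the family's phylogeny. A fourth module fits the
dose–response curves that connect motifs to measured pharmacology.

## Generic numbering

Numbering is inherited by pairwise global alignment (Needleman–Wunsch,
affine gaps) of the query to an annotated reference. The defaults —
BLOSUM62 substitution scores, gap opening 10, gap extension 0.5 — are the
standard protein-alignment regime; they are configuration
(`align_params()`), not constants, because full-length class-A receptors
differ mainly by loop length and the exact penalties matter little as long
as opening ≫ extension. The alignment engine (Biostrings) is deterministic
for fixed parameters.

Assumptions and safeguards:

* **Class-A convention only.** Within each helix, generic numbers advance
  by exactly one per residue; no structure-aware bulge or constriction
  corrections are applied. The reference fixes one convention for the
  helix-V region; queries that genuinely bulge there would need a
  structure-based scheme, which is out of scope.
* **Landmark verification.** Every annotation carries a landmark report
  for N1.50, D2.50, DRY/DRH (3.49–3.51), W4.50, P5.50, P6.50 and NPxxY
  (7.49–7.53). A helix whose x.50 anchor is mismatched or gapped, or whose
  annotated span contains an internal indel, is flagged *low-confidence*;
  motif states are never read from flagged helices (they report
  `"unknown"`). Rationale: a census must not count hallucinated positions.
  If two or more x.50 anchors fail, the sequence is rejected as not
  numberable; the set-level wrapper converts this into an exclusion record.
* **No extrapolation.** Numbering is inherited only through aligned
  columns. Residues opposite gaps report `"absent"`.

The shipped reference is a *synthetic* class-A profile (7 TM helices, 205
annotated residues, an aminergic-style pocket with D3.32 and serines at
5.42/5.43/5.46). It is constructed by `synthetic_reference_profile()` and
shipped as a versioned text table; `build_reference()` accepts any
user-supplied annotated template, e.g. one derived from a solved
agonist-bound aminergic receptor structure, after validating the same
invariants (injective map, consecutive numbering, landmarks present).

Percent identity (`pairwise_identity`) uses identical columns over all
alignment columns excluding dual-gap columns. Conventions differ between
programs (shortest-sequence and compared-columns denominators are also
common); the choice is recorded in the result so printed identities are
interpretable. Published identity figures computed with unstated methods
should be treated as approximate anchors when comparing.

## Motif census

`classify_receptor()` maps the residues at 3.32 and 5.42 (optionally 5.43)
to the four categories X_only / Y_only / both / neither. Two deliberate
switches exist because the field mixes conventions:

* `acid_mode`: `"asp_only"` counts only aspartate; `"anion_DE"` also
  counts glutamate (some rodent receptors carry a conservative Glu3.32).
  The default is `asp_only`, matching how family surveys colour their
  trees; `anion_DE` can only increase counts (a tested monotonicity
  invariant).
* `y_positions`: `"5.42_or_5.43"` lets an aspartate at 5.43 satisfy the
  helix-V criterion, needed for the handful of mammalian receptors whose
  acid sits one turn later; enabling it never decreases the Y count.

Receptors whose deciding positions are `"unknown"` (flagged helix or
ambiguity letter X) are excluded with a reason, never silently binned —
census integrity is preferred over coverage. The four counts plus
exclusions always partition the input, and rows sum to their totals by
construction.

## Phylogenetics and the two-step model

The tree layer is deliberately desk-scale. Distances are p-distances over
pairwise global alignments (compared columns = both residues present and
unambiguous), optionally Poisson-corrected (−ln(1−p)); neighbor joining is
implemented with two reproducibility contracts: Q-criterion ties are
broken toward the lexicographically smallest tip labels, and negative
branch-length estimates are clamped to zero with a warning. On additive
matrices NJ provably recovers the generating tree, and the test suite
checks this exactly against path-metric oracles. Externally computed
maximum-likelihood trees are first-class citizens via Newick import
(internal node labels are kept as support strings); likelihood inference
itself is intentionally not reimplemented.

Ancestral states of the two binary characters (X = anion at 3.32,
Y = anion at 5.42/5.43) are reconstructed by unit-cost parsimony. The
implementation is an inside/outside (Sankoff-style) dynamic program rather
than the plain two-pass Fitch algorithm because the downstream claim needs
more than one arbitrary resolution: it reports, per node, the *set* of
states occurring in at least one most-parsimonious reconstruction, and,
per branch, whether a state change occurs in *every* minimal
reconstruction (`firm`) or only in *some* (`possible`). Change counts
equal the Fitch minimum (verified against exhaustive enumeration).
Missing states (`?`) contribute both states at no cost. Multifurcations
are resolved deterministically to binary before the DP; rooting is by
user-designated outgroup, for amine-receptor analyses conventionally a set
of biogenic amine receptor sequences.

`infer_transition_order()` walks the branches from a designated ancestor
to the ancestor of a focal clade and issues a verdict:
`two_step_gain_then_loss` only when a firm Y gain strictly precedes a firm
X loss on that path; orderings that hold under only some minimal
reconstructions — including both events forced onto the same branch — are
reported as `simultaneous_ambiguous`, never silently resolved. This is the
conservative reading: the two-step claim is only made when parsimony
leaves no alternative. When imported trees carry support values, users may
collapse weak nodes (e.g. support < 50) before reconstruction; the verdict
is computed on the tree as given, and the full tree is the default because
collapsing discards ordering information that the support values may still
weakly favour.

## Dose–response model

Responses follow the four-parameter logistic

$$r(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + (\mathrm{EC_{50}}/c)^{h}},$$

with concentrations in molar internally (the CLI converts nM/µM/mM). The
4PL is the standard sigmoid reported in receptor de-orphanization work;
the Hill slope defaults free within (0, 10] and may be fixed to 1.
Fitting is least squares by Levenberg–Marquardt on the log10-EC50 scale
with a fixed deterministic initialization: asymptotes from the extremes of
the concentration-averaged responses, EC50 from log-linear interpolation
at the half-range crossing, slope 1. Identical inputs give identical fits.

Diagnostics are explicit rather than silent: non-convergence is flagged;
fits whose EC50 leaves `[min(c)/100, max(c)·100]` are flagged
`extrapolated` (the data cannot localize them); near-flat or inverted fits
(dynamic range below twice the residual scatter, or top < bottom, which is
how a monotone-decreasing series ends up under the positive-slope
constraint) are flagged `degenerate`. Confidence intervals are Wald
intervals on log10 EC50; relative potencies propagate the two log-scale
standard errors. Normalization against no-receptor controls divides by the
per-concentration control mean and propagates control variability by the
delta method; non-positive control means are an error, and points without
a matching control are dropped with a warning.

Mixture screening follows the pooled design shipped with the package
(11 pools of 5–6 amines at 83.3 µM each): a hit on a pool nominates all
members, follow-up singles partition candidates into confirmed, rejected
and untested, and adding a hit pool never removes candidates. The hit
threshold (fold over control, default 2) is configuration because screens
state no universal cutoff.

## What the generator emulates — and what it does not

The synthetic-data module exists so every stage can be validated against
recorded truth with no downloads:

* `simulate_tree()`: pure-birth trees conditioned on the tip count.
* `evolve_repertoire()`: sites outside the protected landmark/motif
  positions substitute independently (uniform replacement over the other
  19 residues), scaled so the root-to-tip substitution probability equals
  the requested divergence; planted events rewrite the focal residue on
  their branch (gains write D; losses write N by default — a
  charge-neutralizing change — with A also supported). Landmark windows
  are fully protected by default so annotation failures isolate
  algorithmic faults.
* `simulate_two_step()`: an outgroup, a basal X_only clade, a planted Y
  gain creating a "both" grade, and a nested X loss creating a large
  Y_only clade — the qualitative layout expected if non-classical
  recognition arose by gain-then-loss.
* `make_census_fixture()`: exact per-category counts per group, including
  Glu3.32 variants and 5.43-positioned acids. The survey-shaped fixture
  used by the acceptance checks plants 112 fish receptors
  (20/84/7/1 across the four categories, with clade labels making an
  87-member derived clade of which 85 lack the helix-III acid), 15 mouse
  and 6 human receptors.
* `simulate_assay()`: 4PL means plus additive Gaussian noise (sd = 5% of
  top by default), 8 half-log concentrations × 3 replicates, no-receptor
  controls at the bottom level — the shape of a 96-well reporter assay.

Deliberate simplifications: no indel evolution (annotation gap handling is
tested with hand-built indel fixtures instead), no rate heterogeneity
beyond protected/free sites, no codon-level process, uniform replacement
rather than an empirical amino-acid matrix, and noise that is additive
Gaussian rather than heteroscedastic plate noise. Passing tests therefore
demonstrate correctness of the algorithms under these controlled
conditions, not robustness to every artefact of real repertoires (real
TAARs contain indels near helix termini and compositional biases that can
degrade alignment-based numbering; the landmark flags are the guard rail
there). A single integer seed drives all stages through a fixed splitting
scheme, so every fixture is byte-reproducible.

Real public sequence sets are used as plain FASTA + metadata inputs when
available; the package deliberately performs no downloading. The worked
example (`synthetic_taar13c_like()`) is a constructed stand-in whose
residue layout reproduces the canonical diamine-receptor indices (D112 at
3.32, D202 at 5.42, T203 at 5.43, S199 at 5.39, S276 at 6.55), so the
annotation contract can be demonstrated end to end offline.

## Problem sizes used by the validation suite

The acceptance checks run: the 133-receptor census fixture described
above; 200 random trees (4–7 tips) for the parsimony-vs-enumeration
property; 50 random additive matrices (4–12 tips) for NJ recovery; 100
four-tip repertoires at 30% divergence for planted-motif recovery; 100
noise-free two-step histories (4 + 3 + 8 tips plus outgroup) for the
verdict rate; and 200 simulated plates (8 × 3 design, 5% noise) for EC50
recovery. These sizes were chosen as the smallest that exercise each
property across its combinatorial range; all are fixed in
`scripts/acceptance.R` and seeded from its `--seed` argument.

## Known limitations

* Numbering is alignment-based; receptors with large insertions inside TM
  spans are flagged and excluded rather than renumbered.
* Parsimony ignores branch lengths; on trees where rates differ wildly
  between lineages, likelihood-based ancestral inference (on an imported
  ML tree) would be the stronger instrument, and the package's verdicts
  should then be read as the parsimony view.
* EC50 intervals are Wald intervals on the log scale; profile-likelihood
  intervals would be more accurate for poorly determined slopes.
* The two acid modes and the 5.43 fallback cover the conventions seen in
  amine-receptor surveys, but other families may need different position
  sets; `extract_motif_profile()` accepts arbitrary generic positions.
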