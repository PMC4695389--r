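# amrec — amine-recognition motif evolution in GPCR repertoires

Olfactory trace amine-associated receptors (TAARs) are class-A GPCRs that
detect amines. Classical biogenic amine receptors anchor the ligand's amino
group through an aspartate on transmembrane helix III (Ballesteros–Weinstein
position 3.32). Teleost fish evolved a second, non-classical solution: a
helix-V aspartate at position 5.42 (with some mammalian receptors carrying
the acid one helical turn later, at 5.43). Diamine receptors carry both
acids, and the large teleost clade III TAARs appear to have arisen in two
steps — an ancestral receptor first *gained* Asp5.42 (diamine sensitivity),
then a descendant *lost* Asp3.32, leaving the non-classical site alone.

`amrec` is an R package for quantifying this picture on any receptor
repertoire:

- **Generic numbering** (`assign_bw`): Ballesteros–Weinstein numbers
  (`h.pp`, x.50 anchors) assigned by global alignment to an annotated
  reference, verified against the class-A landmarks (DRY 3.49–3.51,
  NPxxY 7.49–7.53, prolines 5.50/6.50). Helices with failed anchors or
  internal indels are flagged rather than guessed.
- **Motif census** (`census`): every receptor classified as X_only
  (anion at 3.32), Y_only (anion at 5.42/5.43), both, or neither, with
  two acid modes (`asp_only` / `anion_DE`) and an optional 5.43 fallback;
  counts tabulated per receptor group.
- **Phylogenetics** (`neighbor_joining`, `fitch_parsimony`,
  `infer_transition_order`): distance trees from pairwise alignments
  (p or Poisson-corrected distances), import of externally computed
  maximum-likelihood trees (Newick), ancestral presence/absence of the two
  motifs by unit-cost parsimony with full minimal state sets, and a
  gain-before-loss verdict that is only called firm when it holds under
  *every* most-parsimonious reconstruction.
- **Pharmacology** (`fit_dose_response`, `deconvolve_mixture_hits`):
  four-parameter logistic (Hill) fits

  `response(c) = bottom + (top − bottom) / (1 + (EC50 / c)^h)`

  with deterministic initialization, EC50 confidence intervals, relative
  potencies, normalization against no-receptor controls, and pooled-mixture
  screen deconvolution (the shipped 11-pool amine panel is in
  `inst/extdata/mixture_design.tsv`).
- **Synthetic data** (`evolve_repertoire`, `simulate_two_step`,
  `make_census_fixture`, `simulate_assay`): seeded generators that emit
  repertoires evolved on known trees with planted motif gain/loss events,
  and Hill-shaped assay plates with Gaussian noise, each with recorded
  ground truth — so the whole pipeline is testable offline. The shipped
  numbering template is a *synthetic* class-A reference profile
  (`inst/extdata/reference_synthetic_class_a.tsv`); any annotated template
  (e.g. one derived from a solved aminergic receptor structure) can be
  supplied via `build_reference()`.

## Worked example

Annotate the synthetic diamine-receptor worked example (a constructed
stand-in whose layout mirrors a cloned zebrafish diamine receptor) and fit
a simulated cadaverine dose–response curve:

```r
library(amrec)

ref <- default_reference()
tl  <- synthetic_taar13c_like()
ann <- assign_bw(tl$sequence, ref, id = tl$id)
ann
#> BW annotation for 'synthetic_taar13c_like': 205 numbered residues
#>   all landmarks found

residue_at(ann, "3.32")   # index 112, residue "D"
residue_at(ann, "5.42")   # index 202, residue "D"
classify_receptor(extract_motif_profile(ann))$category
#> [1] "both"              # a diamine receptor: both anchor aspartates

truth <- data.frame(receptor = "TAAR13c_like", ligand = "cadaverine",
                    bottom = 0, top = 100, ec50 = 1e-5, hill = 1)
sa  <- simulate_assay(truth, noise_frac = 0.05, seed = 42)
fit <- fit_dose_response(sa$curves[[1]])
fit
#> 4PL dose-response fit: TAAR13c_like / cadaverine
#>   EC50 = 8.981e-06 M (95% CI 7.24e-06-1.11e-05), hill = 0.935
#>   bottom = -3.291, top = 103, residual sd = 4.33
```

The fitted EC50 (~9 µM) recovers the planted 10 µM within its confidence
interval. The annotation places the two aspartates at residues 112 (3.32)
and 202 (5.42) — the indices a census and a structure-activity analysis
would report for this receptor.

A thin command-line front end with subcommands `annotate`, `census`,
`phylo`, `fit` and `simulate` is installed at
`system.file("cli", "amrec.R", package = "amrec")`; every run writes a
run log (options, input digests, package version) to its output directory.

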