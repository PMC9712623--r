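---
title: "Models and methods in tepra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tepra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tepra` analyses how the enhancer activity of a transposable-element (TE)
subfamily, measured by massively parallel reporter assay (MPRA), relates
to the sequence evolution of its copies. This vignette documents the
statistical models, the tunable parameters, the synthetic data generator,
and the numerical and design choices, in that order.

## Enrichment scoring

Barcode-level counts are summed per tested fragment. A fragment is kept
only when its DNA total and every RNA-replicate total reach `min_total`
(default 5); this guarantees strictly positive denominators, so no
pseudocounts are used anywhere downstream. Counts of retained fragments
are scaled to counts per million (CPM) per column, expression per
replicate is RNA CPM / DNA CPM, and expression is divided by the mean
expression of basal promoter-only constructs pooled across replicates, so
that basal defines zero on the log2 scale:

$$E = \frac{1}{R}\sum_{r=1}^{R} \log_2
\frac{\mathrm{RNA\,CPM}_r/\mathrm{DNA\,CPM}}{\overline{\mathrm{basal}}}.$$

The per-fragment score is the mean of per-replicate log scores
(mean-of-logs rather than log-of-means: symmetric in the replicates and
robust to a single outlying replicate). Activity calls use a strict
threshold, `E > 1` by default — more than twofold over basal — with
`E > 0.5` supported as the conventional relaxed cutoff for low-activity
cellular contexts. Mutagenesis effects are differences of scores of a
mutant fragment and its native counterpart, i.e. log2 fold-changes;
group summaries report `2^mean(effect)` and two-group comparisons use
two-tailed Mann–Whitney U tests.

The count filter is applied at the level of the tested element
(summing its barcodes) rather than per barcode; the barcode-level
alternative would couple retention to barcode multiplicity, and the
element-level rule matches how the scores are subsequently used.

## Sequence primitives

All coordinates are 0-based half-open internally (BED-native); 1-based
coordinates appear only in human-readable output.

**Alignment.** Pairwise global alignment uses affine gap costs: a gap of
length $L$ costs `gap_open + (L-1) * gap_ext`, defaults +1/−1/−2/−0.5
for match/mismatch/open/extend. These defaults are a declared package
choice (config-overridable), and traceback ties resolve deterministically
(aligned pair, then gap in the query row, then gap in the reference
row), so alignments are reproducible byte for byte. Copies are projected
onto the reference coordinate system: one matrix column per reference
position, query insertions dropped, and columns carrying bases in less
than 20% of copies masked from downstream scans.

**PWM scanning.** Motif models carry probability matrices; log-odds are
computed against the background (uniform 0.25 by default) after adding a
pseudocount of 1e-3 and renormalising, avoiding infinite scores at zero
cells. Scores are discretised to integer thousandths, and the score
threshold for a scan p-value is derived by exact dynamic programming
over the full score distribution under the background — the same
construction FIMO-class scanners use. Windows containing N are
disqualified; both strands are scanned by default; the default scan
p-value is 1e-4. Note the granularity floor: a k-mer window cannot have
a p-value below $4^{-k}$, so very short motifs need a correspondingly
larger threshold. The matching k-mer set of a motif (used by the
conservation model) is enumerated by branch-and-bound over the same
integer scores, guaranteeing consistency with the scanner.

**Substitution model.** Transition (A↔G, C↔T) and transversion
probabilities per site are estimated by pooling mismatch counts over all
copies of a species against the reference, counting only columns where
both carry an unambiguous base. The per-site model is single-step: stay
with probability $1-s_{ti}-s_{tv}$, transition with $s_{ti}$, each
specific transversion with $s_{tv}/2$. No rate heterogeneity across
sites and no multiple-hit correction — the model matches the
probability calculation it feeds (below), not a general phylogenetic
likelihood.

## Position association (TE-WAS)

At each retained alignment column the major allele is the modal
unambiguous base (ties broken alphabetically and flagged); copies are
carriers or non-carriers, with gaps and N excluded as missing, and
monomorphic columns skipped. Association with the activity call uses a
two-sided Fisher's exact test on the 2×2 table, significant at
p < 5×10⁻⁵. Fisher's exact test is used in place of a 1-df allelic
chi-square: both address the same table, and the exact test is
preferable at subfamily sample sizes (tens to hundreds of copies). The
Fisher p is computed natively (hypergeometric summation with the
conventional 1+1e-7 relative tolerance) and is vectorised with
dedup­lication so that permutation studies over hundreds of labelings
remain cheap.

Motif overrepresentation among significant positions sums the
per-position information content $IC_i = 2 + \sum_b p_{ib}\log_2 p_{ib}$
(uniform background) over significant positions inside the motif span
and compares it with a null of uniformly re-drawn position sets of the
same size (1000 draws), by a one-sided t-test; motifs are reported when
p < 0.05 and at least `min_sig_in_motif` (default 2) significant
positions fall in the span. The minimum-positions rule guards against a
single high-IC base carrying the call.

An important behaviour to expect on tree-structured data: because motif
loss happens on branches, every substitution private to the losing
lineage is genuinely associated with activity. Lineage-marker positions
can therefore rank alongside or above the causal motif positions. This
is linkage, not a defect of the scan; with many independent loss events
(large subfamilies, star-like genealogies) the causal positions
dominate, and that is the regime in which the package's power checks
operate.

## Activity-track deconvolution

A tiled design measures each 160-bp tile's enrichment score; tiles step
by 10 bp, with the final tile right-anchored so the element end is
covered (elements shorter than one tile become a single flagged tile).
The latent per-10-bp step activities $x$ are modelled through the
averaging matrix $W$ ($W_{ij} = 1/k_i$ when tile $i$ fully covers step
$j$), and estimated by the ridge solution

$$\hat x_\lambda = (W^\top W + \lambda I)^{-1} W^\top M,$$

the MAP estimate under unit observation noise and a zero-mean Gaussian
prior with variance $1/\lambda$. The two conventional prior settings
λ = 1 and λ = 50 are both fitted and combined by their unweighted mean —
the combine rule is declared here as this package's definition. The
combined step profile is normalised by subtracting the mean inferred
step value of shuffled-control elements (subtraction, because scores are
log-scale and basal then stays at zero), linearly interpolated between
step centers ($js + s/2$) with constant extrapolation at the ends,
summed per element, and thresholded at 3 shuffled-control standard
deviations (computed over control step values) for peak calls.

Because $W$ averages 16 steps per tile, its eigenvalues are of order
1/16 and λ = 1 already shrinks substantially and non-uniformly: fitted
tile scores track the inputs but are not near-interpolants (on random
noiseless profiles the fitted-vs-input correlation is ≈ 0.7 at λ = 1,
> 0.99 only as λ → 0). This is intentional prior behaviour, and the test
suite checks the estimator's exact closed forms (single-tile and
one-step-per-tile designs), its shrinkage monotonicity, and its
light-penalty reconstruction limit.

## Conservation and neutral motif retention

Sliding 10-bp windows (step 1) on the consensus score each copy by the
fraction of compared positions matching the consensus; positions with a
gap or degenerate base on either side are excluded, and a copy is
dropped from a window when 5 or more of its 10 positions are excluded.
Each window's values are compared against the values pooled over all
windows by a one-sided Welch t-test (elevated conservation only —
depletion is not the question asked), Bonferroni-corrected across
windows at α = 0.05. Degenerate windows (fewer than two copies, or zero
variance everywhere, as when all copies equal the consensus) report
p = 1 rather than NaN. Windows conserved in every species are
intersected, and motifs fully contained in the merged shared intervals
are reported.

The neutral retention expectation asks: if the ancestral motif sequence
evolved one step under the estimated ti/tv model with no selection, what
is the probability it still matches the motif? With matching set
$\mathcal{M}$ (all k-mers reaching the scan threshold, either strand):

$$P_{\mathrm{exp}} = \sum_{m \in \mathcal{M}} \prod_{i=1}^{k}
P(a_i \to m_i).$$

The ancestral state is the consensus k-mer when measuring conservation
from the subfamily consensus; for the speciation-phase comparison the
reference copy's own bases are the starting state per element and
expectations are averaged over elements. Monte-Carlo simulations mutate
each copy's motif region per site under the same model and score
retention with the same scanner, so the simulated fractions are an
unbiased estimate of the same quantity; the observed fraction is the
share of copies (excluding those gapped in the span) whose projected
span still contains a hit. Observed vs expected is tested by a
one-sample two-sided z-test of proportions,
$z = (\hat p - P_{\mathrm{exp}})/\sqrt{P_{\mathrm{exp}}(1-P_{\mathrm{exp}})/n}$.

## Annotation overlap

Annotation intervals are merged on construction; strand is ignored. An
element overlaps when its covered bases reach 50% of its length, so
results are invariant to interval order and splitting, and enlarging an
interval can only add flags. Genome-level enrichment builds the 2×2
table in the interval-Fisher style: flagged elements, unflagged
elements, annotation intervals hit by no element, and remaining genomic
"slots" estimated as genome size divided by the mean annotation interval
length (floored at zero after subtracting the other cells). The exact
construction varies between versions of the common command-line tool, so
this package's table is fixed, documented, and reported alongside the
sample and Haldane-corrected odds ratios. Elements on chromosomes absent
from the annotation count as non-overlapping.

## The synthetic study

The generator emulates the two-phase history of a TE subfamily:

1. **Transposition.** A Yule birth process grows from the root sequence
   to `n_transposition_leaves` copies; each branch applies per-site
   substitutions (defaults $s_{ti} = 0.015$, $s_{tv} = 0.0075$) and rare
   indels (0.001/site per branch, geometric lengths capped at 9),
   giving root-to-leaf divergences around the 15–20% typical of an old
   LTR subfamily.
2. **Speciation.** Every transposition leaf acquires one present-day
   copy per species, at species branch lengths of 0.007–0.045
   substitutions/site with a 2:1 ti:tv ratio — the range spanning close
   to distant primate relatives.

Defaults produce 200 present-day elements (40 ancestors × 5 species),
the package's standard study size. Two motifs are planted in the root:
a JUN-like AP-1 site (`GCTGAGTCATG`, effect log2 1.68) and a DBP-like
CEBP site (`ATTATGTAACC`, effect log2 2.36) — consensus strings and
effect magnitudes on the scale reported for such motifs in MPRA
mutagenesis. Activity is linear in motif dosage:
`baseline (0.2) + Σ effect × presence + N(0, 0.25)`, where presence is
determined by scanning the generated sequence itself, so the truth is
always recomputable from sequence. Shuffled copies of the root serve as
control elements for the basal track background. Barcode counts are
negative binomial (size 25, mean DNA depth 100) with 10 barcodes per
fragment, 300 for the basal construct, and 3 RNA replicates whose means
scale as $2^{\mathrm{activity}}$.

What the generator does **not** emulate: cell-type-specific trans
environments, chromatin or epigenetic silencing, barcode-specific
biases, PCR jackpotting, alignment uncertainty from low-complexity
sequence, or selection (retention in synthetic data is neutral by
construction, so observed ≈ expected there). Passing tests therefore
demonstrate correctness of the estimators under a faithful generative
null, not robustness to every artefact of real MPRA libraries.

## Numerical choices and problem sizes

- PWM scores are integers (thousandths of a bit) end to end, making the
  scanner, the threshold DP, the branch-and-bound matching set, and the
  retention simulations exactly consistent with each other; thresholds
  are memoized per (matrix, background, p).
- Fisher tests, the window t statistics, and retention simulations are
  vectorised; permutation studies (500 relabelings of a 200 × 360
  matrix) and 1000-draw simulations run in seconds.
- The test suite uses 200-element studies for end-to-end recovery and
  calibration, 20 seeds for localisation power (on star genealogies, for
  the linkage reason above), 100 seeds of 60-copy neutral matrices for
  window-test specificity, and exhaustive enumeration up to k = 6 and
  table totals of 40 for the exact oracles — sizes chosen to exercise
  the statistics at study scale while keeping the default run fast.
- Degenerate cases are defined, not accidental: empty queries align to
  all-gap rows; zero-variance windows report p = 1; saturated overlap
  tables report an infinite sample odds ratio alongside the Haldane
  correction; monomorphic association columns are excluded.

## Known limitations

- The aligner is a plain affine-gap global aligner; highly diverged or
  rearranged copies should be pre-aligned with a dedicated MSA tool and
  supplied as gapped input via `ref_alignment()`.
- The substitution model is single-step per branch without multiple-hit
  correction; retention expectations over long branches are therefore
  conservative.
- The ridge deconvolution implements the two-prior MAP / combine /
  interpolate path only, not fully Bayesian tiling-inference variants.
- TE-WAS offers no covariates or lineage-structure correction; on deeply
  tree-structured subfamilies, linked lineage markers will share the
  association signal of causal positions.
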