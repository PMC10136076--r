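---
title: "Methods: cross-species conservation analysis of lens differentiation states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species conservation analysis of lens differentiation states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model, the parameter choices, the
synthetic-data generator and the numerical decisions behind `conservomics`.
It states no empirical result that the test suite does not itself compute.

## The analysis model

The pipeline integrates two species' lens differentiation contrasts
(fiber vs epithelial cells) at four levels.

**Expression classes.** Each gene carries a log2 fold change
(fiber/epithelial) and an FDR-adjusted q-value from an upstream differential
test (how those were produced is out of scope here). A gene is classified
`EPITHELIAL` iff `log2fc < 0 & q < alpha`, `FIBER` iff `log2fc > 0 &
q < alpha`, else `NS`. The inequalities are deliberately strict, exactly as
such criteria are conventionally printed; a gene with `log2fc == 0` is `NS`
regardless of q. This makes the three labels an exact partition.

**Conservation.** A one-to-one ortholog map links the species. Ambiguous
pairs (either member appearing more than once) are *dropped*, not resolved:
gene-level intersection presumes unique correspondence, and any imputation
rule would be arbitrary. An ortholog pair is *conserved epithelial* (resp.
*fiber*) iff both members carry that label. Association between the species'
classifications is tested with the upper-tail hypergeometric probability

$$P(X \ge k), \quad X \sim \mathrm{Hypergeometric}(N, K, n),$$

with `K` = pairs in the species-A class, `n` = pairs in the species-B class,
`k` = pairs in both, and `N` = the universe. The universe is the set of
one-to-one orthologs labelled in both species. This is a design choice — the
convention in published analyses is frequently left unstated — and it is the
smallest defensible universe: any larger one (all genes, all orthologs
including unmeasured ones) only deflates p-values. It is overridable via
`universe_size`.

**Promoter chromatin states.** Promoter windows span 7.5 kb upstream to
2.5 kb downstream of the TSS, oriented by strand. For a minus-strand gene
the window mirrors the plus-strand one about the TSS base
(`[pos - 2499, pos + 7501)` in 0-based half-open coordinates), so the TSS
itself is always inside the window; upstream/downstream conventions for
minus-strand genes are rarely written down, and mirroring about the TSS base
is the one choice that keeps both strands exactly symmetric. Differential
peaks are classified with the same strict sign/q rule as genes. A promoter
is `EPI_PREFERRED` iff ≥ 1 epithelial-specific peak and 0 fiber-specific
peaks overlap the window by ≥ 1 bp (the simplest testable overlap
criterion), `FIBER_PREFERRED` for the reverse, `BOTH` when mixed. We add a
`NONE` category for promoters containing no significant differential peak;
published three-category totals simply exclude such genes, but an explicit
label keeps the classification a partition and makes specificity testable.

**Motif enrichment.** Peaks are assigned to the gene with the nearest TSS,
measured from the peak midpoint `floor((start + end - 1)/2)` — midpoint
rather than edge distance is stable under peak-width variation — with
distance ties broken by lexicographically smallest gene id (deterministic,
order-independent). Peaks nearest to conserved epithelial or fiber genes
form the two foreground sequence sets. Published analyses delegate the
enrichment step to external motif tools whose scoring internals are not
reproducible from their descriptions; we replace that stage with an
explicitly specified equivalent:

1. PFMs become log-odds PWMs with a background-weighted pseudocount
   (default 1.0, uniform background):
   `p = (count + pc·bg) / (colsum + pc)`, `PWM = log2(p/bg)`.
2. A sequence's score is the best ungapped placement on either strand;
   placements covering non-ACGT bases score `-Inf`.
3. A sequence is a *hit* iff its best score reaches 0.75 of the motif's
   maximum achievable score. A fixed fraction is reproducible and can be
   checked against a brute-force placement oracle, unlike tool-internal
   threshold optimization.
4. Each foreground is compared to a dinucleotide-preserving
   (Altschul–Erickson) shuffle of itself — the standard control that
   preserves composition and CpG content — by a one-sided Fisher exact test
   on per-sequence hit indicators; BH correction is applied within each test
   family separately, mirroring the per-submission correction of a motif
   tool run.

Four families are run per species: epithelial vs shuffled (`E`), fiber vs
shuffled (`F`), epithelial foreground vs fiber background (`D_E`) and the
reverse (`D_F`), each significant iff `q ≤ alpha`. The four-way partition
is: `EPI_ONLY = E ∧ ¬F`; `FIBER_ONLY = F ∧ ¬E`;
`EPI_PREFERRED = E ∧ F ∧ D_E`; `FIBER_PREFERRED = E ∧ F ∧ D_F ∧ ¬D_E`;
`SHARED = E ∧ F ∧ ¬D_E ∧ ¬D_F`; otherwise `NONE`. "Preferred" is thus
operationalized as significance in the cross-class test — the natural
reading of "more significantly enriched in one class than the other", which
is otherwise undefined. When both cross-tests pass (a case a real contrast
cannot produce, but a partition must handle), `EPI_PREFERRED` wins and a
message is logged: any tie rule works as long as it is deterministic and
announced. A motif is reported only if it earns a compatible label in *both*
species (per-species runs intersected, the stricter of the two plausible
readings of a cross-species claim) and only if its TF's gene is detected in
both species' expression tables.

**Database overlap.** Overlap of a conserved gene list with a curated set is
reported as `k` of `n` (`100k/n`, rounded to 2 decimals) with the
hypergeometric tail p. Symbols are matched case-insensitively after
whitespace stripping, because cross-species symbol conventions differ in
case only (all-caps vs title-case). The percentage is invariant to the
universe; the p-value is not — both facts are asserted in the tests. Generic
GMT-based over-representation analysis uses the same report per set with BH
correction across sets; combined-score rankings of web ORA tools are
intentionally not reimplemented.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `alpha` | 0.05 | — | the conventional FDR threshold the classification criteria print |
| `upstream_bp` / `downstream_bp` | 7500 / 2500 | bp | the promoter window the promoter-state rule is defined on |
| `pseudocount` | 1.0 | counts | standard Laplace-style regularization of PFM columns |
| `background` | uniform | — | matches the uniform-composition generator; override for real genomes |
| `threshold_fraction` | 0.75 | fraction of max score | admits ~2 low-information mismatches in a sharp 24-position motif while keeping random 400 bp hits rare |
| `seed` | — | — | controls only the shuffled controls (and the generator) |

## The synthetic world

The generator emulates the statistical structure the cross-species analysis
assumes: two species with shared differential classes and class-specific
accessible chromatin carrying TF motifs. Defaults (all in `sim_config()`):
150 genes per species, 120 one-to-one orthologs (orthologous genes share a
symbol, as real cross-species symbol sets largely do), 25 conserved
epithelial + 25 conserved fiber pairs, planted `|log2FC| ~ |N(2.0, 0.5)|`
with `q ~ U(1e-8, 1e-3)`, null genes `log2FC ~ N(0, 0.3)` with
`q ~ U(0.05, 1)` — so at `alpha = 0.05` recovery of the planted classes is
guaranteed by construction, not by statistical luck. Each planted gene gets
one 400 bp class-specific differential peak centred 1 kb upstream of its
TSS (inside its promoter window on either strand); fiber peaks carry two
instances of the planted motif sampled column-wise from its PFM (sampling,
not consensus-writing, exercises the hit threshold); epithelial peaks carry
none by default so the fiber/epi asymmetry is the detectable signal
(`epi_motif_ids` enables symmetric planting). Fifty non-significant decoy
peaks per species are placed outside all promoter windows.

One stated default was internally inconsistent: 150 genes at the ≥ 20 kb
spacing that the nearest-TSS recovery argument requires (peak offset 1 kb ≪
spacing) cannot fit on a 1 Mb chromosome, so the default `chrom_length` is
3.2 Mb. TSSs are uniformly spaced with ±5 kb jitter (post-jitter spacing
≥ 10 kb) and alternating strands.

The shipped motif library (`inst/extdata/synthetic_motifs.jaspar`) is
synthetic — one high-information 24-position planted motif plus five
decoys of widths 16–24 with distinct consensus sequences; it stands in for a
real motif database and is labelled as such. With 98/2 count columns and
pseudocount 1, a sampled instance tolerates two minority bases at the 0.75
threshold; the probability of three or more is ~1% per instance, ~1.5e-4 per
two-copy peak.

What the generator does **not** emulate: realistic GC content or repeat
structure (uniform composition isolates motif enrichment from compositional
confounds), many-to-many orthology, correlated q-values, peak-width
variation, overlapping promoter windows, or biological pathway structure in
the gene sets. A green fixture test therefore establishes the pipeline's
correctness on its stated contract — not power or calibration on real
genomes.

## Numerical choices and degenerate inputs

* The hypergeometric tail is summed in log space (`lchoose` +
  log-sum-exp); it agrees with exhaustive subset enumeration to < 1e-12 for
  every valid configuration with N ≤ 12 (acceptance test), and `k = 0`
  returns exactly 1.
* The PWM scanner accumulates column scores in ascending position order in
  double precision; the brute-force oracle does the same, so equality is
  exact, not approximate. Sequences shorter than the motif score `-Inf`
  with a warning; all-N sequences can never be hits.
* BH adjustment is the step-up rule with explicit monotonicity enforcement,
  validated against `stats::p.adjust(, "BH")` as an independent oracle.
* The Altschul–Erickson shuffle draws a uniformly random last-edge
  arborescence (rejection sampling) and permutes remaining out-edges; single
  -symbol and length-≤2 sequences are fixed points. Determinism comes from
  seeding R's RNG once per call.
* Promoter windows are clamped to `[0, chromosome length)`; a window that
  clamps to zero length is an error rather than a silent empty window.
* Write/read round trips are byte-identical for the peak BED dialect and
  value-identical for all other formats; fixture writing records MD5
  checksums in the manifest and same-seed runs reproduce every byte.

## Known limitations

* Promoter-state counting is O(genes × peaks) with plain interval
  arithmetic — ample for tens of thousands of features, but an interval
  tree would be preferable at millions.
* The motif stage models hits as per-sequence indicators; it ignores hit
  multiplicity within a sequence and positional preference.
* The expressed-TF filter equates "detected" with "present in the DE
  table"; expression-level thresholds are upstream concerns.
* The BED6+2 peak dialect is fixed (log2FC and q in columns 7–8);
  narrowPeak files must be converted, since narrowPeak has no slot for a
  differential q-value.
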