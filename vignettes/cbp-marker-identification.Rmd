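---
title: "Identifying tortoiseshell species from corneous beta-protein markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying tortoiseshell species from corneous beta-protein markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbpid)
```

## The problem

Tortoiseshell objects are made from the cornified scutes of sea turtles,
predominantly the hawksbill *Eretmochelys imbricata*. The scute proteome is
dominated by corneous beta-proteins (CBPs, historically "beta-keratins"):
short proteins with a conserved central beta-sheet region and glycine-rich
termini. Because almost no marine turtle genomes are sequenced, species
identification relies on a curated panel of tryptic peptide *markers*
validated across the five scute-growing species (*Chelonia mydas*,
*Caretta caretta*, *E. imbricata*, *Lepidochelys olivacea*,
*L. kempii*). `cbpid` implements the full downstream workflow from a
peptide-spectrum match (PSM) table to a species call, plus the
classification of unknown (e.g. archaeological) samples against a modern
reference system, and a synthetic-data generator used to validate every
statistical component.

## The marker model

Markers are grouped into sequence classes along the CBP:

* **A-D** cover the conserved N-terminal half; **D** spans the beta-sheet
  core, has no usable tryptic boundary at its C-side and is excluded from
  species assignment by default.
* **E1-E4** tile the variable glycine-repeat region; **E4a** occurs as a
  25- and a 28-residue form and is the most species-informative class.
* **F** is the short conserved C-terminus.

Each class has a wildcard template over the amino-acid alphabet plus `X`
(variable position). `match_template()` compares a peptide to a template
position by position; leucine and isoleucine are treated as equivalent
(`il_equivalent`), as the isomers are indistinguishable by mass.
`classify_peptide()` assigns the minimal-mismatch class among
length-compatible templates with a default budget of two substitutions —
the largest substitution count observed among validated markers (C-2
carries two). Curated class labels on database markers are authoritative:
inference exists for novel peptides, and at least one published marker
(E2c-4) deliberately does not minimize mismatches against its own class
template.

## Score filtering

Searches report a `-10lgP` score per PSM. For each marker, a cut-off is
computed from the pooled eligible PSMs of the cohort — those carrying no
modification beyond carbamidomethylation — as

$$\mathrm{cutoff} = \mathrm{median}(s) - \mathrm{MAD}(s), \qquad
\mathrm{MAD}(s) = \mathrm{median}\left(|s - \mathrm{median}(s)|\right),$$

deliberately **unscaled** (no 1.4826 normal-consistency factor). PSMs of
the marker scoring below the cut-off are removed; markers with no eligible
PSM are flagged and left unfiltered. Cut-offs pool the whole cohort by
default (`per_sample = TRUE` is available).

## Degradation metrics

A PSM's cleavage status compares its termini with the canonical boundaries
of its marker: `determined` (both ends tryptic or at a marked boundary),
`semi`, or `undetermined` (neither end — the proxy for hydrolytic damage).
Classes whose template marks only one tryptic side (D and F at the N-side;
E1, E2b, E2d, E4a at the C-side) can only reach `determined` with flanking
residue evidence on the other side. Peptides not assignable to a marker
are judged from flanks alone and are `undetermined` when no flanks exist.
`undetermined_fraction()` reports the percentage overall, per class or per
sample; in modern hawksbill scutes it sits near 30% and roughly doubles in
archaeological material.

## PTM statistics

Oxidation (+15.995 Da) and dioxidation (+31.990 Da) are counted on
P/Y/H/W residues only. The denominator is *potential sites x PSM count*
summed over (marker, sample) pairs; the numerator counts site-level
observations (a PSM with two oxidized residues contributes two). Oxidation
on other residues (e.g. methionine, allowed by common search settings) is
excluded from both sides and reported separately. Phosphoserine counts are
bucketed by following residue and by the SAHR/SCHR suffix context.

## Species assignment

For each species, the fraction of its validated markers present in the
filtered detection set is computed (class D excluded by default). The call
rule is deliberately evidence-ranked rather than a bare argmax:

1. among species with at least one detected *unique* marker, call the one
   with the highest fraction (confidence `unique_markers`);
2. if no species has unique support, call the unique argmax-fraction
   species with confidence `fraction_only`;
3. ties, or empty detection sets, are `inconclusive`.

The design addresses repertoire nesting: *L. kempii*'s small validated set
is almost entirely contained in *E. imbricata*'s, so its fraction can top
the ranking for hawksbill samples by noise alone; conversely *L. kempii*
itself has only two unique markers (both in fast-degrading E4b), so a rule
that requires unique support unconditionally refuses many genuine
*L. kempii* samples. Ranking unique evidence first and falling back to the
fraction only when no unique evidence exists resolves both failure modes
without introducing numeric thresholds.

## Multivariate classification

The feature matrix holds the highest retained score per (sample, marker),
zero when undetected. PCA is column-centred without variance scaling. The
self-organizing map is the standard online algorithm on the centred
features: a 4 x 4 square grid, 10 000 training presentations, learning
rate decaying linearly 0.05 to 0.01, Gaussian neighbourhood with radius
decaying from half the grid diagonal to 1, deterministic under a seed.
Node codebooks are clustered by k-means for k = 1..8 and k is chosen at
the knee of the WCSS curve, located as the maximal second difference of
log(WCSS). The log scale matters: the raw second difference is dominated
by the first large drop of the curve and systematically answers k = 2 on
clearly four-cluster data, whereas the relative (log) drop peaks at the
true cluster count. Archaeological/query samples never influence training;
they are mapped to their best-matching unit and inherit its cluster.

The SOM is trained on the centred feature matrix directly rather than on
PCA scores: the two analyses are parallel views of the same features, and
the map does not benefit from discarding low-variance directions at these
sample sizes.

## The synthetic generator

`generator_config()` + `generate_cohort()` emulate the study conditions:

* per-marker detection probability `base_detect_p` (0.85 at `d = 0`),
  reduced multiplicatively under degradation `d` by class weights that
  degrade E4a/E4b fastest (weight 1), then A (0.8), then the rest —
  matching the observed preferential loss of the matrix-forming termini;
* `-10lgP` scores from a normal (mean 45, sd 8) truncated at the usual
  export floor of 25, with the mean depressed by `5 d` (an invented
  nuisance dimension that exercises the MAD filter);
* PSM counts per detected marker of `1 + Poisson(mean - 1)` (a detected
  marker must yield at least one PSM);
* undetermined-cleavage probability `u(d) = u0 + u_slope * d`
  (defaults 0.30 + 0.30 d: about 30% in modern scutes, doubling at full
  degradation), realized by trimming both termini to non-tryptic
  positions; the same probability applies to the alpha-keratin background
  decoys so the cohort-wide percentage stays interpretable;
* per-site oxidation/dioxidation draws on P/Y/H/W (defaults 0.05 and
  0.025; doubled for *C. mydas* cohorts when emulating its elevated
  oxidation), phosphorylation of SAHR serines (0.5) and never of SCHR
  serines;
* an alpha-keratin background of invented non-CBP tryptic decoy peptides
  whose count scales with `1 - d` (these proteins vanish from
  archaeological samples). Decoy lengths avoid every template length so
  they never classify into a CBP class.

What the generator does *not* model: real spectra and search-engine score
behaviour, chimeric PSMs, inter-marker detection correlation, sequence
variation beyond the validated panel, deamidation chemistry, and any
kinetics of hydrolysis. Passing recovery tests therefore demonstrates the
correctness of the statistical pipeline under the stated generative model,
not instrument-level performance on real material.

## The synthetic reference panel

The full validated marker inventory is published only as supplementary
material, so the package constructs `synthetic_reference_panel()`: a
deterministic stand-in whose class sizes and species-sharing structure
satisfy every published inventory count (187 markers; A/B/E4a = 34/53/47;
33 in all five species; 56 across the four genera; unique counts 20/19/17/
15/2; 21 shared exclusively by *E. imbricata* + *C. caretta* +
*Lepidochelys*; 124 in *E. imbricata*), with the five individually
published sequences included verbatim. Sequences are derived from the
class templates; substitutions avoid K/R (no spurious tryptic sites) and I
(I/L mass equivalence). The panel exercises the set algebra, the species
caller and the generator at realistic scale, but its unpublished sequences
are synthetic.

## Numerical and design choices

* Trypsin cleaves after K/R including before proline by default (search
  engines differ; a flag restores the no-cleavage-before-P rule).
* Coordinates are 1-based inclusive throughout.
* Peptide-to-marker alignment tries exact substring first, then a unique
  best offset with at most two substitutions; ambiguity yields
  `undetermined`.
* Peptide masses are monoisotopic (residue table + water + named deltas).
* The worked match fraction for a sample detecting 93 of the 124
  *E. imbricata* markers (75.0%) is computed over the full repertoire
  (`exclude_classes = character(0)`), since the published 124 denominator
  is the complete validated set.
* Problem sizes in the test-suite simulations (cohorts of 1-5 specimens,
  2 000-10 000 PSMs, 20-seed clustering replicates, 100-replicate
  recovery runs) were chosen as the smallest scales at which the binomial
  tolerances of the checks are meaningful.

## Limitations

The marker panel outside the five published sequences is synthetic; real
supplementary inventories can be ingested with
`import_supplementary_markers()` and all analyses apply unchanged. The
species caller assumes detections are genuine (no decoy-FDR modelling).
SOM cluster identities are arbitrary labels; interpreting clusters as
species requires the reference metadata, and sparsely represented species
(one specimen, few unique markers) may not separate from the species whose
repertoire contains theirs.
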