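# cbpid

Species identification of tortoiseshell from corneous beta-protein (CBP)
peptide markers.

Tortoiseshell artefacts are made from sea turtle scutes, overwhelmingly
from the critically endangered hawksbill *Eretmochelys imbricata*. The
scute proteome is dominated by CBPs ("beta-keratins"), for which almost no
marine turtle reference sequences exist, so identification rests on a
curated panel of validated tryptic peptide markers classified into
sequence regions A-F along the protein (A-D conserved N-terminal half and
beta-sheet core, E1-E4 glycine-repeat region, F C-terminus). `cbpid` takes
a table of peptide-spectrum matches (PSMs) exported from a search engine
and answers: *which species made this sample, and how degraded is it?*

The core statistics:

* **Wildcard template matching** — each class has a template over the
  amino-acid alphabet plus `X`; a peptide belongs to the minimal-mismatch,
  length-compatible class (<= 2 substitutions, I/L equivalent).
* **Per-marker MAD score cut-off** — for each marker, PSMs scoring below
  `median(s) − median(|s − median(s)|)` (unscaled MAD, computed from
  carbamidomethyl-only/unmodified PSMs pooled across the cohort) are
  discarded.
* **Species call** — per species, the fraction of its validated markers
  detected; the call is the highest-fraction species among those with at
  least one detected species-unique marker.
* **Degradation metrics** — percentage of PSMs whose termini match neither
  tryptic boundary of their marker ("undetermined cleavages", ~30% in
  modern hawksbill scute, doubling in archaeological material), and
  oxidation/dioxidation site occupancy on P/Y/H/W residues
  (sites x PSM count denominator).
* **Sample classification** — PCA (centred, unscaled), a 4 x 4
  self-organizing map (10 000 iterations), and elbow k-means over the SOM
  codebooks; unknown samples are projected onto the modern reference
  system without influencing it.
* **Synthetic cohorts** — a seeded generator emulating modern and degraded
  specimens (class-biased marker loss, score depression, non-tryptic
  termini, PTM draws, alpha-keratin background) with a ground-truth
  sidecar, used to validate every estimator.

## Worked example

```r
library(cbpid)

db <- synthetic_panel_db()          # 187-marker panel (synthetic stand-in)
cfg <- generator_config("Eretmochelys imbricata", n_specimens = 1,
                        d = 0.7, seed = 808)   # a degraded "comb"
comb <- generate_cohort(cfg, db)
res <- run_identify(comb, db)
res$calls[[1]]
```

```
<species_call> Eretmochelys imbricata (unique_markers)
  Eretmochelys imbricata    48.3% (58/120), unique hits: 6
  Lepidochelys kempii       47.5% (19/40), unique hits: 0
  Lepidochelys olivacea     42.9% (45/105), unique hits: 0
  Chelonia mydas            41.2% (35/85), unique hits: 0
  Caretta caretta           40.9% (45/110), unique hits: 0
```

Despite 70% degradation the sample is called hawksbill: 58 of its 120
class-D-excluded markers survive (48.3%), including 6 markers unique to
*E. imbricata* — the same logic that identifies archaeological combs. The
run also reports per-marker score cut-offs, detection matrices,
undetermined-cleavage percentages (`res$undetermined$overall` shows 47.7%
here, against ~30% for modern scute) and oxidation site occupancy
(`res$ptm`).

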