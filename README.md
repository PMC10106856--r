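# centroscape

Centromere and pericentromere repeat-landscape analysis for plant
genome assemblies, validated end-to-end on synthetic chromosomes with
planted ground truth.

Plant centromeres are megabase-scale satellite arrays massively invaded
by LTR retrotransposons; the flanking pericentromeres carry their own
satellites and an older transposon population. `centroscape`
implements the computational steps used to characterise such regions:

* **Satellite probe tracks** — map centromere-/pericentromere-/telomere-
  specific repeat monomers (e.g. *CentBr1*-like Cent-SRs, *PCRBr*-like
  Peri-SRs, the *BrSTR* telomere motif) onto chromosomes with a
  seed-and-extend local aligner and summarise them as sliding-window
  covered-fraction tracks (500 kb window, 100 kb step).
* **Compartment calling** — turn the tracks into explicit centromere and
  pericentromere intervals (threshold / minimum run / merge gap, with
  boundaries snapped to the outermost probe hits), with the criterion
  stamped into every output.
* **LTR chronology** — date full-length LTR retrotransposons from the
  divergence of their two terminal repeats, `T = K / (2 mu)` with
  JC69- or K2P-corrected `K` and `mu = 1.5e-8` substitutions/site/year;
  classify elements young (`T <= 0.5` MYA) or old; detect nested
  insertions by span containment; tabulate family / superfamily
  composition per compartment and contrast compartment ages with
  Welch's two-sided t-test.
* **Identity landscape** — pairwise sequence identity between all
  non-overlapping 10 kb bins of a region (the centromere "heatmap"),
  plus change-point segmentation of its block structure.
* **Novel repeat discovery** — the occurrence filter that surfaces a
  previously unannotated pericentromeric repeat from element sequences:
  all-vs-all self-alignment, keep units found in ≥ 50 elements, keep
  units with > 1000 merged hits on the pericentromere, discard units
  resembling known satellites.
* **A synthetic-genome simulator** — chromosomes with telomeres,
  satellite arrays, aged (optionally nested) LTR insertions and a hidden
  pericentromeric repeat, all with recorded truth, so every stage above
  is tested by parameter recovery.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
simulated 3 Mb chromosome; each step writes its tables under
`results/`:

```sh
Rscript analysis/01_simulate.R        # genome + planted truth
Rscript analysis/02_probe_density.R   # probe hits, tracks, telomeres
Rscript analysis/03_call_compartments.R
Rscript analysis/04_date_ltrs.R
Rscript analysis/05_identity_heatmap.R
Rscript analysis/06_discover_repeats.R
```

`01` plants 106 elements (36 Copia + 14 Gypsy in the centromere, 40
Gypsy in the pericentromeres, 19 nested pairs) and a 630 bp hidden
repeat with 300 pericentromeric copies. `03` then recovers the planted
500 kb centromere almost exactly:

```
  chrom   start     end           role  evidence
1  chr1  950000 1250000 pericentromere 0.1543437
2  chr1 1250000 1749916     centromere 0.3502712
3  chr1 1749916 2050001 pericentromere 0.1543437
centromere boundary error: start +0 bp, end -84 bp
```

`04` dates every element from its LTR pair and reproduces the
young-centromere / old-pericentromere contrast the pipeline is built to
measure (planted means 0.14 vs 0.51 MYA):

```
centromere 0.151 MYA (n=50) vs pericentromere 0.486 MYA (n=40): Welch t = -7.49, two-sided p = 3.33e-10
young fraction: centromere 0.96, pericentromere 0.45
```

and `06` rediscovers the hidden repeat through the 50 / 1000 filter with
full length coverage:

```
  unit_id length self_occurrences peri_hits known_overlap
1 unit001    632               62      1263         FALSE
planted unit: 630 bp; recovered unit covers 100.0% of it
```

Interactively, the same pipeline is one call:

```r
library(centroscape)
sim <- simulate_chromosome(sim_config(seed = 1))
res <- run_pipeline(sim$seq, sim$truth$probes, "out/",
                    ltr_gff3 = NULL)   # engages the structural LTR finder
res$regions
```

See `vignettes/centroscape-methods.Rmd` for the model, the boundary
criterion, the precision limits of divergence dating, and what the
simulator does and does not emulate.

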