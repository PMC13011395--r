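# viromeAP

Gut virome profiling and cross-kingdom association analysis for
case/control metagenome cohorts with ordered disease-severity strata —
built for acute pancreatitis (AP) versus healthy controls (HC), usable
for any two-group virome study.

## Who this is for

Microbiome researchers who have (a) read alignments of fecal shotgun
metagenomes against a viral genome catalog, (b) the catalog's metadata
(genome lengths, family, lifestyle, predicted host, KO annotations),
(c) a bacterial relative-abundance table, and (d) per-sample clinical
metadata — and who want the standard virome analysis battery as tested,
reusable functions rather than one-off scripts. A fully ground-truthed
synthetic-cohort generator makes every stage verifiable offline, with no
access to raw sequencing data.

## The model at the core

- **Presence** of a vOTU *v* in a sample requires coverage breadth
  ≥ 10%: |∪ read intervals| / genome length.
- **Abundance** is length-adjusted: RPK_v = reads_v / (L_v/1000),
  scaled per sample and renormalized so each sample sums to 1.
- **Beta diversity**: Bray–Curtis d = Σ|x−y| / Σ(x+y) and presence
  Jaccard; PCoA by Gower double-centering of −d²/2; PERMANOVA pseudo-F
  with permutation p = (#{F\* ≥ F} + 1)/(B + 1).
- **Differential features**: Wilcoxon rank-sum + Benjamini–Hochberg,
  selected at q < 0.05, fold change > 1.2, mean abundance > 0.01%;
  validated by covariate-adjusted OLS on arcsine-√ abundances.
- **Severity trajectories**: strictly ordered group means along
  MAP → MSAP → SAP plus a BH-significant Spearman trend.
- **Diagnostics**: random forest (in-package C++ implementation),
  stratified 5-fold × 5-repeat CV, rank-statistic AUC, leak-free
  feature-count curves.
- **Networks**: all-pairs Spearman across virus/bacterium/clinical
  blocks, edges at |ρ| > 0.4 and q < 0.05, topology (average degree,
  BFS mean path length, components), hubs, group comparison.

## Worked example

```r
library(viromeAP)

cfg <- synthetic_config(seed = 42, n_ap = 50, n_hc = 60, n_votus = 200)
cat_ <- generate_catalog(cfg)
coh  <- generate_cohort(cfg, cat_)
grp  <- coh$metadata$group

ad <- alpha_diversity(coh$viral)
d  <- distance_matrix(coh$viral, "bray_curtis")
permanova(d, grp, n_perm = 999, seed = 1)
#> PERMANOVA: pseudo-F = 14.2154, R2 = 0.1163, p = 0.001 (999 permutations)

ord <- pcoa(d)                      # PCoA1/PCoA2 explain 14.71% / 5.51%

dt <- select_differential(coh$viral, coh$metadata)
sum(dt$direction != "ns")           # 44 (21 AP-enriched, 23 HC-enriched)
dt <- covariate_validate(coh$viral, coh$metadata, dt)
mean(dt$validated[dt$direction != "ns"])   # 0.95

tm <- detect_monotone(coh$viral, coh$metadata)
sum(tm$monotone_direction != "none")       # 17 (12 planted)

spec <- cv_spec(seed = 7, n_trees = 300)
cross_validated_auc(coh$viral$values, as.integer(grp == "AP"), spec)
#> classifier_report: mean CV AUC = 1.000 (5 x 5 CV, 300 trees)
```

What the numbers mean: the cohort was generated with 40 planted
differential vOTUs at 4-fold change and 12 planted monotone severity
trajectories; the pipeline recovers essentially all of them (44 selected,
95% surviving covariate adjustment, 17 trajectories), separates the
groups in ordination space (R² = 0.12 of Bray–Curtis variance,
p = 0.001), and classifies cases perfectly — because the planted effects
are large by design. `coh$truth` holds the full ground truth for
checking any of this.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/virome-ap.R", package = "viromeAP"))')
Rscript "$CLI" simulate --outdir demo --seed 3 --n-ap 20 --n-hc 20
Rscript "$CLI" profile  --catalog demo/catalog.tsv --aln demo/alignments \
                        --min-breadth 0.10 --out demo/votu_abund.tsv
Rscript "$CLI" ecology  --abund demo/votu_abund.tsv --meta demo/metadata.tsv \
                        --metric bray_curtis --permutations 999 --seed 7
Rscript "$CLI" diff     --abund demo/viral_abundance.tsv --meta demo/metadata.tsv
```

Subcommands: `simulate`, `profile`, `ecology`, `diff`, `trajectory`,
`classify`, `network`.

## Layout

- `R/` — synthetic generator, profiling, ecology, differential,
  trajectory, classifier, network, I/O, CLI
- `src/rf.cpp` — the random forest
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/virome-ap-methods.Rmd` — the methods vignette (model,
  assumptions, calibration of the synthetic world, limitations)
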