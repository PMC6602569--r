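# sitedriver

Prioritization of cancer driver mutations and driver proteins from the
positions they hit on protein structures.

## What it does, and for whom

Tumor genomes carry a handful of driver mutations among many passengers.
Drivers concentrate in functional protein regions: orthosteric
(substrate/catalytic) sites and allosteric sites — regions distinct from the
orthosteric site whose perturbation propagates to it. `sitedriver` is for
cancer genomics and structural bioinformatics researchers who have
per-sample missense mutation calls (MAF, ANNOVAR output, or a plain
`sample;gene;V600E` list) and want, per sample, a ranked table of candidate
driver proteins justified by scored site mutations.

The pipeline:

1. **Map** each missense mutation, in 1-based UniProt protein coordinates,
   onto a site database (experimentally verified allosteric, predicted
   allosteric, orthosteric residue sets), giving each mutation exactly one
   of four areas (the fourth being "other"). Overlaps resolve by the
   precedence ORTHO > ALLO_EXP > ALLO_PRED.
2. **Featurize** site-mapped mutations: one-hot site flags, relative
   solvent accessibility, a flexibility proxy, and substitution deltas
   (Kyte–Doolittle hydropathy, residue volume, formal charge, BLOSUM62,
   proline/glycine backbone flags) — 11 features in the v1 schema.
3. **Score** with a class-rebalanced ensemble. Training data is ~0.12
   driver:passenger, so SMOTE (k = 5, target ratio 1.0) synthesizes
   minority points `x + u (x_nn − x)` first. A probability random forest
   (depth 4, 130 trees, 0.4 feature fraction) on raw features and a
   20–15 ReLU / sigmoid-output perceptron (SGD, learning rate 0.1,
   momentum 0.8) on standardized features are combined as

   `score = (P_RF(driver) + P_MLP(driver)) / 2`,

   and a mutation is called a driver iff `score > 0.5` (strictly).
4. **Rank** driver proteins per sample by their best driver-mutation score,
   with profiles (area frequencies, score table), pan-cancer site-mutation
   matrices and PFAM-style domain overlays as side outputs.

Evaluation uses a trapezoidal ROC/AUC equal to the Mann–Whitney U statistic
with half-credit ties, plus sensitivity counts at the 0.5 threshold. Every
input has a seeded synthetic generator, so the whole package is testable
offline; see `vignettes/methods.Rmd` for the model, its assumptions, and
what the synthetic validation does and does not show.

## Worked example

```r
library(sitedriver)

# A synthetic "site world" (site DB + residue annotations + gene map +
# FASTA) and a 2-sample cohort over it:
spec  <- fixture_spec(n_proteins = 5, n_samples = 2, muts_per_sample = 8,
                      frac_on_sites = 0.75, seed = 42)
world <- gen_site_world(spec, "world")
gen_cohort_maf(spec, world, "world/cohort.maf")

# Train the ensemble on a labeled dataset with planted separation d' = 2.5
# at the published benchmark shape (73 drivers / 582 passengers):
ds <- gen_labeled_dataset(separation_spec(n_pos = 73, n_neg = 582,
                                          dprime = 2.5, seed = 42))
cv <- cv_ensemble(ds, ensemble_config(seed = 42), smote_config(seed = 42),
                  folds = 10, seed = 42)
sprintf("pooled CV AUC %.3f, sensitivity %d/%d",
        cv$auc_pooled, cv$detected, cv$n_positive)
#> "pooled CV AUC 0.943, sensitivity 57/73"
model <- train_driver_model(ds, ensemble_config(seed = 42),
                            smote_config(seed = 42))

# Map, profile, score, rank:
db   <- load_site_db(world$sites, world$residues, world$genemap, "functional")
seqs <- load_fasta(world$fasta)
mc   <- map_cohort(parse_maf("world/cohort.maf"), db, seqs)
area_profile(mc$mapped, "sample_1")
#> <area_profile> sample sample_1: ALLO_EXP=3 ALLO_PRED=3 ORTHO=0 OTHER=2
preds  <- score_cohort(mc$mapped, db, model)
ranked <- rank_targets(preds, 0.5)
head(ranked)
#>   sample_id gene_symbol uniprot_id ref_aa position alt_aa      area     score
#> 1  sample_1       GENE2     P00002      A       63      F ALLO_PRED 0.7111148
#> 2  sample_1       GENE5     P00005      G       37      V  ALLO_EXP 0.6490583
#> 3  sample_1       GENE5     P00005      C       17      Q  ALLO_EXP 0.5714734
#> 4  sample_2       GENE1     P00001      S      110      E  ALLO_EXP 0.6770211
```

The pooled cross-validated AUC (0.943) is the ranking quality of the
ensemble under 10-fold CV with SMOTE re-run inside each training fold;
57/73 is how many planted drivers score strictly above 0.5. In the ranked
table, each row is one predicted driver mutation; within a sample, the
top-ranked protein is the one carrying the highest-scoring driver mutation
(here GENE2 via A63F at a predicted allosteric site, score 0.711).

`write_target_table(ranked, "target_table.tsv")` emits the summary table
with columns Sample, Gene/Protein, UniProt ID, Driver mutation, Location,
Area, Score.

## Command line

A thin Rscript front end mirrors the workflow stages:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "sitedriver.R", package = "sitedriver"))')
Rscript $CLI fixtures  --out world --seed 42
Rscript $CLI train     --data labeled.tsv --out model.rds --seed 42
Rscript $CLI run       --input world/cohort.maf --format maf \
                       --mode functional --sites world --model model.rds \
                       --out results --seed 42
Rscript $CLI benchmark --labels labels.tsv --sites world --model model.rds \
                       --name functional_synthetic --out bench
```

Exit codes: 0 success, 2 usage error, 3 data error, 4 model error. `run`
writes `target_table.tsv`, `area_profile.tsv`,
`area_profile_by_protein.tsv`, `score_profile.tsv`, `mapping_report.tsv`
and `validation_report.tsv`; two runs with the same inputs and seed are
byte-identical.

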