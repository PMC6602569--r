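# Shared fixtures, built in code. World/model construction is memoized per
# test run to keep the suite fast.

.fixture_env <- new.env(parent = emptyenv())

# A small deterministic site world on disk (6 proteins x 3 sites).
test_world <- function() {
  if (is.null(.fixture_env$world)) {
    dir <- file.path(tempdir(), "sitedriver-world")
    .fixture_env$spec <- fixture_spec(n_proteins = 6, sites_per_protein = 3,
                                      seq_length = 120, n_samples = 3,
                                      muts_per_sample = 10,
                                      frac_on_sites = 0.5, seed = 11)
    .fixture_env$world <- gen_site_world(.fixture_env$spec, dir)
  }
  .fixture_env$world
}

test_world_spec <- function() {
  test_world()
  .fixture_env$spec
}

test_db <- function(mode = "functional") {
  w <- test_world()
  load_site_db(w$sites, w$residues, w$genemap, mode)
}

test_seqs <- function() load_fasta(test_world()$fasta)

# A quick ensemble trained on an easy synthetic dataset; reused across tests
# that only need *a* model, not a particular one.
test_model <- function() {
  if (is.null(.fixture_env$model)) {
    ds <- gen_labeled_dataset(separation_spec(n_pos = 30, n_neg = 120,
                                              dprime = 3, seed = 4))
    .fixture_env$model <- train_driver_model(
      ds, ensemble_config(rf_n_trees = 50, mlp_epochs = 50, seed = 4),
      smote_config(seed = 4))
  }
  .fixture_env$model
}

# A hand-built three-site database with overlapping residue sets, written to
# temp files so it exercises the real loaders.
overlap_db <- function(mode = "functional") {
  dir <- tempfile("overlap-db")
  dir.create(dir)
  writeLines(c(
    "uniprot_id\tgene_symbol\tpdb_id\tsite_id\tsite_type\tresidues",
    "P1\tG1\t1ABC\tSA\tALLO_EXP\t10,11,12,76",
    "P1\tG1\t1ABC\tSB\tALLO_PRED\t12,13,76",
    "P1\tG1\t1ABC\tSC\tORTHO\t30,31,76"),
    file.path(dir, "sites.tsv"))
  seq_aa <- paste(rep("A", 100), collapse = "")
  res <- data.frame(uniprot_id = "P1", position = 1:100, wt_aa = "A",
                    rsa = 0.5, flex = 0.0)
  writeLines(c("uniprot_id\tposition\twt_aa\trsa\tflex",
               sprintf("P1\t%d\tA\t0.5000\t0.0000", 1:100)),
             file.path(dir, "residues.tsv"))
  writeLines(c("gene_symbol\tuniprot_id", "G1\tP1"),
             file.path(dir, "genemap.tsv"))
  writeLines(c(">sp|P1|G1_TEST test protein", seq_aa),
             file.path(dir, "proteins.fasta"))
  load_site_db(file.path(dir, "sites.tsv"), file.path(dir, "residues.tsv"),
               file.path(dir, "genemap.tsv"), mode)
}

# Cohort data.frame -> cohort object, for tests that build mutations directly.
make_cohort <- function(df, format = "LIST") {
  if (is.null(df$uniprot_id)) df$uniprot_id <- NA_character_
  df <- df[, c("sample_id", "gene_symbol", "uniprot_id", "ref_aa",
               "position", "alt_aa")]
  sitedriver:::new_cohort(df, format)
}

# Brute-force pairwise AUC oracle: probability that a random positive
# outscores a random negative, half credit for ties.
auc_pairwise_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) for (q in sn) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(sp) * length(sn))
}
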