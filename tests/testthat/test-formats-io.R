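test_that("mutation-list grammar decomposes sample;gene;RefPosAlt records", {
  recs <- parse_mutation_list("sample_1;BRAF;V600E\n\nsample_2;TP53;p.R175H")
  expect_equal(nrow(recs), 2)
  expect_equal(recs$sample_id, c("sample_1", "sample_2"))
  expect_equal(recs$gene_symbol[1], "BRAF")
  expect_equal(recs$ref_aa, c("V", "R"))
  expect_equal(recs$position, c(600L, 175L))
  expect_equal(recs$alt_aa, c("E", "H"))
})

test_that("blank input yields an empty record list", {
  recs <- parse_mutation_list("\n\n  \n")
  expect_equal(nrow(recs), 0)
})

test_that("malformed lines raise parse errors naming the line", {
  expect_error(parse_mutation_list("s1;BRAF;600E"), "line 1")
  expect_error(parse_mutation_list("s1;BRAF;V600E\nnot-a-line"), "line 2")
  expect_error(parse_mutation_list("s1;BRAF"), "line 1")
})

test_that("synonymous changes are rejected records, not errors", {
  recs <- parse_mutation_list("s1;BRAF;V600V\ns1;BRAF;V600E")
  expect_equal(nrow(recs), 1)
  rej <- attr(recs, "rejected")
  expect_equal(rej$line, 1L)
  expect_match(rej$reason, "synonymous")
})

test_that("three-letter protein changes normalize to one-letter codes", {
  pc <- parse_protein_change(c("p.Val600Glu", "V600E", "p.V600E", "garbage"))
  expect_equal(pc$ref_aa, c("V", "V", "V", NA))
  expect_equal(pc$position, c(600L, 600L, 600L, NA))
  expect_equal(pc$alt_aa, c("E", "E", "E", NA))
})

write_maf <- function(rows, path = tempfile(fileext = ".maf")) {
  writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification\tHGVSp_Short",
               rows), path)
  path
}

test_that("MAF parsing keeps exactly the missense rows", {
  path <- write_maf(c("BRAF\ts1\tMissense_Mutation\tp.V600E",
                      "PTPN11\ts1\tMissense_Mutation\tp.E76K",
                      "TP53\ts1\tSilent\tp.L35L"))
  co <- parse_maf(path)
  expect_s3_class(co, "cohort")
  expect_equal(nrow(co$mutations), 2)
  expect_equal(co$mutations$gene_symbol, c("BRAF", "PTPN11"))
  # the E76K decomposition
  expect_equal(co$mutations$ref_aa[2], "E")
  expect_equal(co$mutations$position[2], 76L)
  expect_equal(co$mutations$alt_aa[2], "K")
})

test_that("MAF with a missing required column errors naming it", {
  path <- tempfile(fileext = ".maf")
  writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode\tHGVSp_Short",
               "BRAF\ts1\tp.V600E"), path)
  expect_error(parse_maf(path), "Variant_Classification")
})

test_that("unparseable MAF protein changes are skipped with a warning", {
  path <- write_maf(c("BRAF\ts1\tMissense_Mutation\tp.V600E",
                      "GENEX\ts1\tMissense_Mutation\tp.?"))
  expect_warning(co <- parse_maf(path), "skipped")
  expect_equal(nrow(co$mutations), 1)
})

test_that("ANNOVAR output parses as a single sample named by the file stem", {
  path <- file.path(tempdir(), "caseA.txt")
  writeLines(c(
    "line1\tnonsynonymous SNV\tBRAF:NM_004333:exon15:c.1799T>A:p.V600E\tchr7",
    "line2\tsynonymous SNV\tTP53:NM_000546:exon4:c.300C>T:p.P100P\tchr17",
    "line3\tnonsynonymous SNV\tPTPN11:NM_002834:exon3:c.226G>A:p.E76K\tchr12"),
    path)
  co <- parse_annovar(path)
  expect_equal(unique(co$mutations$sample_id), "caseA")
  expect_equal(nrow(co$mutations), 2)
  # colon-grammar decomposition
  expect_equal(co$mutations$gene_symbol[1], "BRAF")
  expect_equal(co$mutations$ref_aa[1], "V")
  expect_equal(co$mutations$position[1], 600L)
  expect_equal(co$mutations$alt_aa[1], "E")
})

test_that("ANNOVAR input with no parseable missense row errors", {
  path <- file.path(tempdir(), "caseB.txt")
  writeLines("line1\tsynonymous SNV\tTP53:NM_000546:exon4:c.300C>T:p.P100P\tchr17",
             path)
  expect_error(parse_annovar(path), "no missense mutations")
})

test_that("cohort validation applies the strict per-sample mutation cap", {
  mk <- function(n, id) data.frame(
    sample_id = id, gene_symbol = "G", ref_aa = "A",
    position = seq_len(n), alt_aa = "V", stringsAsFactors = FALSE)
  co <- make_cohort(rbind(mk(2000, "at_cap"), mk(2001, "over_cap")))
  val <- validate_cohort(co)
  expect_equal(val$report$status[val$report$sample_id == "at_cap"], "accepted")
  expect_equal(val$report$status[val$report$sample_id == "over_cap"], "rejected")
  expect_setequal(unique(val$cohort$mutations$sample_id), "at_cap")
  # accepted mutations pass through unchanged
  co_small <- make_cohort(mk(5, "s"))
  expect_identical(validate_cohort(co_small)$cohort$mutations,
                   co_small$mutations)
})

test_that("validation of an all-rejected cohort errors", {
  df <- data.frame(sample_id = "s", gene_symbol = "G", ref_aa = "A",
                   position = 1:3, alt_aa = "V", stringsAsFactors = FALSE)
  co <- make_cohort(df)
  expect_error(validate_cohort(co, validation_config(max_mutations_per_sample = 2)),
               "empty cohort")
})

test_that("FASTA loading keys records by UniProt accession", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">sp|Q06124|PTN11_HUMAN desc", "MTSRRWFHPN",
               ">P99999", "ACDEFGHIKL"), path)
  seqs <- load_fasta(path)
  expect_setequal(names(seqs), c("Q06124", "P99999"))
  expect_equal(unname(seqs["Q06124"]), "MTSRRWFHPN")
})

test_that("FASTA loading rejects duplicates and non-amino-acid characters", {
  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|A", "ACDE", ">sp|P1|B", "ACDE"), dup)
  expect_error(load_fasta(dup), "duplicate")
  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">sp|P2|A", "ACDEX"), bad)
  expect_error(load_fasta(bad), "P2")
})

test_that("target table round-trips through write and read", {
  ranked <- data.frame(
    sample_id = c("s1", "s1"), gene_symbol = c("PTPN11", "BRAF"),
    uniprot_id = c("Q06124", "P15056"), ref_aa = c("E", "V"),
    position = c(76L, 600L), alt_aa = c("K", "E"),
    area = c("ALLO_EXP", "ORTHO"), score = c(0.647, 0.6012345678901),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_target_table(ranked, path)
  back <- read_target_table(path)
  expect_equal(names(back), c("Sample", "Gene/Protein", "UniProt ID",
                              "Driver mutation", "Location", "Area", "Score"))
  expect_equal(back$`Driver mutation`, c("E76K", "V600E"))
  expect_equal(back$Location, c(76L, 600L))
  expect_equal(back$Score, ranked$score)
  # empty ranking -> header-only file
  write_target_table(ranked[0, ], path)
  expect_equal(length(readLines(path)), 1)
  expect_equal(nrow(read_target_table(path)), 0)
})

test_that("label tables reject conflicting duplicate labels", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("uniprot_id\tgene_symbol\tref_aa\tposition\talt_aa\tlabel\tsource",
               "P1\tG1\tA\t10\tV\tdriver\tOncoKB",
               "P1\tG1\tA\t10\tV\tpassenger\tTCGA"), path)
  expect_error(read_label_table(path), "conflicting")
})
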