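test_that("area assignment follows set membership with ORTHO precedence", {
  db <- overlap_db("functional")
  m <- function(pos) list(sample_id = "s", gene_symbol = "G1",
                          uniprot_id = NA_character_, ref_aa = "A",
                          position = pos, alt_aa = "V")
  expect_equal(map_mutation(m(10), db)$area, "ALLO_EXP")
  expect_equal(map_mutation(m(13), db)$area, "ALLO_PRED")
  expect_equal(map_mutation(m(30), db)$area, "ORTHO")
  expect_equal(map_mutation(m(50), db)$area, "OTHER")
  # position 76 belongs to all three sites: ORTHO wins
  expect_equal(map_mutation(m(76), db)$area, "ORTHO")
  # precedence is configurable
  expect_equal(map_mutation(m(76), db,
                            precedence = c("ALLO_EXP", "ORTHO", "ALLO_PRED"))$area,
               "ALLO_EXP")
})

test_that("allosteric mode maps orthosteric-only positions to OTHER", {
  db <- overlap_db("allosteric")
  m <- list(sample_id = "s", gene_symbol = "G1", uniprot_id = NA_character_,
            ref_aa = "A", position = 30, alt_aa = "V")
  expect_equal(map_mutation(m, db)$area, "OTHER")
  # 76 still allosteric via the ALLO_EXP site
  m$position <- 76
  expect_equal(map_mutation(m, db)$area, "ALLO_EXP")
})

test_that("reference mismatches and beyond-length positions are caught", {
  db <- overlap_db()
  seqs <- c(P1 = paste(rep("A", 100), collapse = ""))
  m <- list(sample_id = "s", gene_symbol = "G1", uniprot_id = NA_character_,
            ref_aa = "R", position = 10, alt_aa = "K")
  expect_equal(map_mutation(m, db, seqs)$ref_check, "mismatch")
  m$ref_aa <- "A"
  expect_equal(map_mutation(m, db, seqs)$ref_check, "match")
  m$position <- 500
  mm <- map_mutation(m, db, seqs)
  expect_equal(mm$ref_check, "mismatch")
  expect_equal(mm$area, "OTHER")
})

test_that("cohort mapping excludes mismatches from scoring but keeps them in profiles", {
  db <- overlap_db()
  seqs <- c(P1 = paste(rep("A", 100), collapse = ""))
  df <- data.frame(sample_id = "s1", gene_symbol = "G1",
                   ref_aa = c("A", "R", "A"), position = c(10, 11, 50),
                   alt_aa = c("V", "K", "E"), stringsAsFactors = FALSE)
  expect_warning(mc <- map_cohort(make_cohort(df), db, seqs), "issues")
  expect_equal(mc$mapped$scoreable, c(TRUE, FALSE, FALSE))
  expect_equal(mc$mapped$area[2], "OTHER")  # mismatch forced off-site
  expect_equal(mc$report$issue, "reference residue mismatch")
  # profile still counts all three mutations
  ap <- area_profile(mc$mapped, "s1")
  expect_equal(sum(ap$counts), 3)
  # error mode aborts
  expect_error(map_cohort(make_cohort(df), db, seqs,
                          validation_config(on_ref_mismatch = "error")),
               "mismatch")
})

test_that("unknown genes map to OTHER and are reported", {
  db <- overlap_db()
  df <- data.frame(sample_id = "s1", gene_symbol = c("NOGENE", "G1"),
                   ref_aa = "A", position = c(10, 10), alt_aa = "V",
                   stringsAsFactors = FALSE)
  expect_warning(mc <- map_cohort(make_cohort(df), db), "issues")
  expect_equal(mc$mapped$area, c("OTHER", "ALLO_EXP"))
  expect_equal(mc$report$issue[1], "unknown gene")
})

test_that("area counts partition the sample and per-protein tallies conserve", {
  spec <- test_world_spec()
  db <- test_db()
  maf <- tempfile(fileext = ".maf")
  gen_cohort_maf(spec, test_world(), maf)
  co <- parse_maf(maf)
  mc <- map_cohort(co, db, test_seqs())
  for (s in unique(co$mutations$sample_id)) {
    ap <- area_profile(mc$mapped, s)
    n_s <- sum(mc$mapped$sample_id == s)
    expect_equal(sum(ap$counts), n_s)
    expect_equal(sum(ap$per_protein), sum(ap$counts))
    expect_equal(colSums(ap$per_protein), ap$counts[colnames(ap$per_protein)])
  }
  # empty sample -> zero profile
  ap0 <- area_profile(mc$mapped, "no_such_sample")
  expect_equal(sum(ap0$counts), 0)
})

test_that("map_mutation is pure and order-invariant under site shuffling", {
  db <- overlap_db()
  m <- list(sample_id = "s", gene_symbol = "G1", uniprot_id = NA_character_,
            ref_aa = "A", position = 76, alt_aa = "V")
  base <- map_mutation(m, db)
  for (perm in list(c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
    db2 <- db
    db2$sites <- db$sites[perm, , drop = FALSE]
    expect_equal(map_mutation(m, db2)[c("area", "site_id")],
                 base[c("area", "site_id")])
  }
})
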