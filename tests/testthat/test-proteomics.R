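test_that("reference normalization divides by the within-plex reference", {
  tab <- toy_plex()
  out <- normalize_to_reference(list(tab))
  expect_equal(unname(out$abundance["P1", "plex1:114"]), 2.0)  # 200 / 100
  expect_true(all(out$abundance["P2", ] == 1))  # all channels equal reference
  ref_cols <- out$columns$column[out$columns$role == "reference"]
  expect_true(all(out$abundance[, ref_cols] == 1))
})

test_that("plex-level scaling cancels: 3x intensities give identical profiles", {
  base <- rbind(P1 = c(100, 200, 100, 150, 120),
                P2 = c(50, 55, 50, 52, 50),
                P3 = c(10, 40, 20, 30, 10))
  a <- toy_plex("plexA", base)
  b <- toy_plex("plexB", base * 3)
  out <- normalize_to_reference(list(a, b))
  pa <- out$abundance[, out$columns$plex == "plexA"]
  pb <- out$abundance[, out$columns$plex == "plexB"]
  expect_equal(unname(pa), unname(pb))
})

test_that("normalization is idempotent and drops zero-reference proteins", {
  tab <- toy_plex()
  once <- normalize_to_reference(list(tab))
  renorm_tab <- protein_quant_table(
    "plex1",
    structure(once$abundance, dimnames = list(rownames(once$abundance),
                                              tab$sample_map$channel)),
    tab$sample_map)
  twice <- normalize_to_reference(list(renorm_tab))
  expect_equal(unname(twice$abundance), unname(once$abundance))

  zr <- rbind(P1 = c(0, 200, 100, 150, 120),  # zero in the reference channel
              P2 = c(50, 50, 50, 50, 50),
              P3 = c(10, 40, 20, 30, 10))
  out <- normalize_to_reference(list(toy_plex("plex1", zr)))
  expect_false("P1" %in% rownames(out$abundance))
  expect_true("P1" %in% out$dropped$protein)
  expect_match(out$dropped$reason[out$dropped$protein == "P1"], "zero reference")
})

test_that("a missing reference channel is rejected", {
  m <- rbind(P1 = c(1, 2), P2 = c(3, 4))
  colnames(m) <- c("113", "114")
  expect_error(
    protein_quant_table("p", m, data.frame(
      channel = c("113", "114"), donor = c("a", "b"),
      age_group = c("young", "old"), role = c("biological", "biological"))),
    class = "immunoflux_input_error")
})

test_that("group ratios and p-values match the Student t oracle", {
  set.seed(7)
  mat <- matrix(rlnorm(40, 0, 0.2), nrow = 5,
                dimnames = list(paste0("P", 1:5), NULL))
  norm <- toy_normalized(mat, donors = paste0("d", 1:8),
                         ages = rep(c("young", "old"), each = 4))
  rec <- group_ratio_test(norm)
  for (p in rec$protein) {
    y <- mat[p, 1:4]; o <- mat[p, 5:8]
    expect_equal(rec$ratio[rec$protein == p], mean(o) / mean(y))
    expect_equal(rec$p_value[rec$protein == p], student_ttest(o, y)$p_value)
  }
  expect_equal(rec$avg_old, rec$ratio * rec$avg_young, tolerance = 1e-14)
})

test_that("identical groups give ratio 1 and p 1", {
  mat <- matrix(rep(c(1.3, 0.8), each = 6), nrow = 2, byrow = TRUE,
                dimnames = list(c("P1", "P2"), NULL))
  norm <- toy_normalized(mat, donors = paste0("d", 1:6),
                         ages = rep(c("young", "old"), 3))
  rec <- group_ratio_test(norm)
  expect_equal(rec$ratio, c(1, 1))
  expect_equal(rec$p_value, c(1, 1))
})

test_that("swapping age labels inverts the ratio and preserves p", {
  set.seed(11)
  mat <- matrix(rlnorm(24, 0, 0.3), nrow = 3,
                dimnames = list(paste0("P", 1:3), NULL))
  ages <- rep(c("young", "old"), each = 4)
  a <- group_ratio_test(toy_normalized(mat, paste0("d", 1:8), ages))
  b <- group_ratio_test(toy_normalized(mat, paste0("d", 1:8),
                                       ifelse(ages == "young", "old", "young")))
  expect_equal(b$ratio, 1 / a$ratio)
  expect_equal(b$p_value, a$p_value)
})

test_that("technical duplicates are collapsed to their donor mean", {
  mat <- matrix(c(1, 3, 2, 2, 4, 4, 2, 2), nrow = 1,
                dimnames = list("P1", NULL))
  norm <- toy_normalized(mat, donors = c("y1", "y1", "y2", "y2",
                                         "o1", "o2", "o3", "o4"),
                         ages = c(rep("young", 4), rep("old", 4)),
                         roles = c("biological", "technical_duplicate",
                                   "biological", "technical_duplicate",
                                   rep("biological", 4)))
  rec <- group_ratio_test(norm)
  expect_equal(rec$n_young, 2)  # y1 and y2, not 4 channels
  expect_equal(rec$avg_young, mean(c(mean(c(1, 3)), mean(c(2, 2)))))
  expect_equal(rec$avg_old, 3)
})

test_that("filter cascade stages reject and count as hand-enumerated", {
  # six constructed records: exactly 2 survive all three stages
  # stage 1 drops P1 (1.2) and P2 (1.1, both inside [0.7, 1.3]); stage 2
  # drops P3 (p 0.2); stage 3 drops P4 (no evidence record); P5 and P6 remain
  records <- data.frame(
    protein = paste0("P", 1:6),
    avg_young = 1, avg_old = 1,
    ratio = c(1.2,   1.1,  1.6,  1.8,   2.0,  0.6),
    p_value = c(0.01, 0.01, 0.20, 0.001, 0.03, 0.04),
    n_young = 4, n_old = 4)
  evidence <- data.frame(
    protein = c("P3", "P5", "P6"),
    unique_peptides = c(3, 2, 5),
    confidence = c("high", "high", "high"),
    max_ion_score = c(50, 31, 90))
  rep <- filter_cascade(records, evidence)
  expect_equal(rep$n_input, 6)
  expect_equal(rep$n_pass_ratio, 4)
  expect_equal(rep$n_pass_pvalue, 3)
  expect_equal(rep$n_pass_evidence, 2)
  expect_setequal(rep$selected, c("P5", "P6"))
  expect_equal(rep$up, "P5")
  expect_equal(rep$down, "P6")
  expect_equal(rep$rejections$reason[rep$rejections$protein == "P4"],
               "no evidence record")
  expect_true(rep$n_input >= rep$n_pass_ratio &&
                rep$n_pass_ratio >= rep$n_pass_pvalue &&
                rep$n_pass_pvalue >= rep$n_pass_evidence)
})

test_that("a well-evidenced 1.6-fold protein is retained; empty input is empty", {
  records <- data.frame(protein = "GPDM", avg_young = 0.9734,
                        avg_old = 1.5531, ratio = 1.5956, p_value = 4e-4,
                        n_young = 4, n_old = 18)
  evidence <- data.frame(protein = "GPDM", unique_peptides = 4,
                         confidence = "high", max_ion_score = 60)
  expect_equal(filter_cascade(records, evidence)$selected, "GPDM")
  empty <- filter_cascade(records[0, ], evidence)
  expect_equal(empty$n_input, 0L)
  expect_equal(empty$selected, character(0))
})

test_that("plex and evidence TSV readers round-trip", {
  td <- withr::local_tempdir()
  plex_df <- data.frame(protein_id = c("P1", "P2"),
                        `plex1:113` = c(100, 50), `plex1:114` = c(200, 50),
                        `plex1:115` = c(150, 50), check.names = FALSE)
  write.table(plex_df, file.path(td, "plex1.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  design <- data.frame(plex = "plex1", tag = c("113", "114", "115"),
                       donor = c("reference", "y1", "o1"),
                       age_group = c("young", "young", "old"),
                       role = c("reference", "biological", "biological"))
  tab <- read_plex_tsv(file.path(td, "plex1.tsv"), "plex1", design)
  expect_s3_class(tab, "protein_quant_table")
  expect_equal(unname(tab$intensities["P1", "114"]), 200)

  ev_df <- data.frame(protein_id = "P1", unique_peptides = 3,
                      confidence = "high", max_ion_score = 45)
  write.table(ev_df, file.path(td, "ev.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ev <- read_evidence_tsv(file.path(td, "ev.tsv"))
  expect_equal(ev$protein, "P1")
  expect_equal(ev$max_ion_score, 45)
})

test_that("planted 1.5-fold proteins are recovered by the full cascade", {
  surv <- ratios <- numeric(0)
  for (s in 1:5) {
    cfg <- study_config(seed = s)
    sim <- simulate_proteomics(cfg)
    rec <- group_ratio_test(normalize_to_reference(sim$tables))
    rep <- filter_cascade(rec, sim$evidence)
    planted <- sim$truth$planted_up
    surv <- c(surv, mean(planted %in% rep$selected))
    ratios <- c(ratios, median(rec$ratio[rec$protein %in% planted]))
    # no null protein should sneak through at this effect/noise setting
    expect_lte(sum(!rep$selected %in% planted), 1)
  }
  expect_gte(mean(surv), 0.8)
  expect_true(all(ratios > 1.4 & ratios < 1.6))
})
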