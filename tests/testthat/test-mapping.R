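# Peptide-to-position mapping, replicate filtering, classification,
# validation against reference topologies.

test_that("exact substring matches place the modified residue correctly", {
  db <- protein_set("P1", "MKTAYIAKQR")
  obs <- observation_table("TAYIAK", mod_offset = 6, replicate_id = "r1")
  pos <- map_peptides(obs, db)
  expect_identical(nrow(pos), 1L)
  expect_identical(pos$protein_id, "P1")
  expect_identical(pos$position, 8L)   # match starts at 3; 3 + 6 - 1
  expect_identical(pos$residue, "K")
  expect_false(pos$ambiguous)
})

test_that("observations merge by (protein, position) with replicate sets", {
  db <- protein_set("P1", "MKTAYIAKQR")
  obs <- observation_table(rep("TAYIAK", 3), mod_offset = 6,
                           replicate_id = c("r1", "r2", "r1"),
                           cell_line = c("HL60", "K562", "HL60"))
  pos <- map_peptides(obs, db)
  expect_identical(nrow(pos), 1L)
  expect_identical(pos$observation_count, 3L)
  expect_identical(pos$replicates[[1]], c("r1", "r2"))
  expect_identical(pos$cell_lines[[1]], c("HL60", "K562"))
  expect_identical(pos$n_replicates, 2L)
})

test_that("the identity threshold admits one mismatch in 25 but not two", {
  base <- paste(rep(c("A", "D", "E", "G", "H"), 5), collapse = "")
  seq <- paste0("MKW", base, "KWM")
  db <- protein_set("P1", seq)
  pep1 <- base; substr(pep1, 3, 3) <- "Y"                  # 24/25 = 96%
  pep2 <- pep1; substr(pep2, 10, 10) <- "Y"                # 23/25 = 92%
  p1 <- suppressMessages(map_peptides(
    observation_table(pep1, mod_offset = 1, replicate_id = "r1"), db))
  p2 <- suppressMessages(map_peptides(
    observation_table(pep2, mod_offset = 1, replicate_id = "r1"), db))
  expect_identical(nrow(p1), 1L)
  expect_identical(p1$position, 4L)    # best window starts after MKW
  expect_identical(nrow(p2), 0L)
})

test_that("multi-protein peptides map everywhere and are flagged ambiguous", {
  db <- protein_set(c("P1", "P2"), c("MKTAYIAKQR", "GGTAYIAKWW"))
  obs <- observation_table("TAYIAK", mod_offset = 6, replicate_id = "r1")
  pos <- map_peptides(obs, db)
  expect_identical(nrow(pos), 2L)
  expect_setequal(pos$protein_id, c("P1", "P2"))
  expect_true(all(pos$ambiguous))
  # merge consistency: one observation, matched in two proteins
  expect_identical(sum(pos$observation_count), 2L)
})

test_that("illegal peptides and non-lysine offsets are rejected with a log record", {
  db <- protein_set("P1", "MKTAYIAKQR")
  obs <- observation_table(c("TAYIAK", "TAZIAK", "TAYIAK"),
                           mod_offset = c(6, 6, 3),
                           replicate_id = "r1")
  expect_message(pos <- map_peptides(obs, db), "rejected 2")
  expect_identical(nrow(attr(pos, "rejected")), 2L)
  expect_identical(pos$observation_count, 1L)
  # N-terminal labeling at offset 1 is chemistry-legal on any residue
  obs_nt <- observation_table("MKTAYIAK", mod_offset = 1, replicate_id = "r1")
  expect_identical(map_peptides(obs_nt, db)$position, 1L)
})

test_that("total observation counts equal successfully mapped observation events", {
  cfg <- synthetic_config(n_proteins = 10L, detection_prob = 0.7, seed = 404L)
  gen <- generate_proteins(cfg)
  lab <- simulate_labeling(gen$proteins, gen$annotations, cfg)
  pos <- map_peptides(lab$observations, gen$proteins)
  expect_identical(sum(pos$observation_count),
                   attr(pos, "n_mapped_events"))
  expect_true(all(pos$residue == "K" | pos$position == 1L))
})

test_that("replicate filtering is exact, order-preserving and idempotent", {
  expect_identical(nrow(filter_by_replicates(
    map_peptides(observation_table(character(0), mod_offset = integer(0),
                                   replicate_id = character(0)),
                 protein_set("P1", "MKTAYIAKQR")), 3)), 0L)
  db <- protein_set("P1", "MKTAYIAKQRMKTAYIAGQR")
  obs <- observation_table(
    rep(c("TAYIAK", "MKTAYIAGQR"), c(3, 2)),
    mod_offset = c(6, 6, 6, 2, 2),
    replicate_id = c("r1", "r2", "r3", "r1", "r2"))
  pos <- map_peptides(obs, db)
  flt <- filter_by_replicates(pos, 3)
  expect_identical(flt$position, 8L)            # {r1, r2, r3} survives
  expect_identical(filter_by_replicates(flt, 3), flt)   # idempotent
  # subset of the input
  expect_true(all(paste(flt$protein_id, flt$position) %in%
                  paste(pos$protein_id, pos$position)))
  expect_identical(nrow(filter_by_replicates(pos, 1)), nrow(pos))
})

test_that("proteins classify as TMP iff the prediction contains a membrane segment", {
  model <- synth_model()
  tmp_seq <- paste0("KKKRKKDEK", strrep("L", 21), "SSTSNSTQS")
  sol_seq <- paste(rep(c("S", "T", "E", "K", "D", "Q", "N", "G", "P", "A"), 5),
                   collapse = "")
  cls <- classify_proteins(protein_set(c("TMP1", "SOL1"), c(tmp_seq, sol_seq)),
                           model)
  expect_identical(unname(cls["TMP1"]), "TMP")
  expect_identical(unname(cls["SOL1"]), "soluble")
  expect_identical(length(classify_proteins(
    protein_set(character(0), character(0)), model)), 0L)
})

test_that("validation against references counts comparable and confirmed positions", {
  refs <- list(topology_from_labels("P1", paste0(strrep("I", 10),
                                                 strrep("M", 20),
                                                 strrep("O", 10))))
  pos <- data.frame(protein_id = c("P1", "P1", "P1", "P1", "P9"),
                    position = c(35L, 36L, 37L, 5L, 3L))
  rep <- validate_against_reference(pos, refs)
  expect_identical(rep$n_positions_total, 5L)
  expect_identical(rep$n_positions_comparable, 4L)
  expect_identical(rep$n_confirmed_extracellular, 3L)
  expect_equal(rep$percent_confirmed, 75.0)
  # all-extracellular set
  rep100 <- validate_against_reference(
    data.frame(protein_id = "P1", position = c(31L, 40L)), refs)
  expect_equal(rep100$percent_confirmed, 100.0)
  # no references: percent reported as absent, not zero
  rep0 <- validate_against_reference(pos, list())
  expect_identical(rep0$n_positions_comparable, 0L)
  expect_null(rep0$percent_confirmed)
  # beyond-length positions are logged and not comparable
  expect_message(
    repb <- validate_against_reference(
      data.frame(protein_id = "P1", position = 99L), refs),
    "beyond reference")
  expect_identical(repb$n_positions_comparable, 0L)
})

test_that("mapped positions and constraint exports round-trip through TSV", {
  db <- protein_set("P1", "MKTAYIAKQR")
  obs <- observation_table(rep("TAYIAK", 2), mod_offset = 6,
                           replicate_id = c("r1", "r2"), cell_line = "HL60")
  pos <- map_peptides(obs, db)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mapped_positions(pos, path)
  back <- read_mapped_positions(path)
  expect_identical(back$protein_id, pos$protein_id)
  expect_identical(back$position, pos$position)
  expect_identical(back$replicates, unname(pos$replicates))
  cons <- positions_to_constraints(pos)
  expect_identical(cons$label, "O")
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_constraints(cons, cpath)
  expect_identical(read_constraints(cpath), cons)
})
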