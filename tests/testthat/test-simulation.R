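# Constraint sampling, corruption and the benchmark simulation.

test_that("constraint sampling draws the right number from the right pool", {
  e <- synth_benchmark()$entries[[1]]
  n_ext <- length(e$extracellular_lysines)
  expect_identical(nrow(sample_constraints(e, 0)), 0L)
  all_c <- sample_constraints(e, 1)
  expect_identical(sort(all_c$position), e$extracellular_lysines)
  expect_true(all(all_c$label == "O"))
  set.seed(4)
  half <- sample_constraints(e, 0.5)
  expect_identical(nrow(half), as.integer(floor(0.5 * n_ext + 0.5)))
  expect_true(all(half$position %in% e$extracellular_lysines))
  # sampled positions are lysines in the sequence
  aa <- strsplit(e$protein$sequence, "")[[1]]
  expect_true(all(aa[half$position] == "K"))
})

test_that("corruption replaces the right count with intracellular decoys", {
  bench <- synth_benchmark()$entries
  e <- bench[[which(vapply(bench, function(x)
    length(x$intracellular_lysines), integer(1)) >= 4)[1]]]
  set.seed(8)
  cons <- sample_constraints(e, 1)
  expect_identical(corrupt_constraints(cons, e, 0), cons)
  c1 <- corrupt_constraints(cons, e, 1)
  expect_true(all(c1$position %in% e$intracellular_lysines) ||
                nrow(c1) < nrow(cons))  # pool exhaustion shrinks, logged
  expect_true(all(c1$label == "O"))
  cons4 <- cons[1:4, ]
  ch <- corrupt_constraints(cons4, e, 0.5)
  expect_identical(nrow(ch), 4L)
  expect_identical(sum(ch$position %in% e$intracellular_lysines), 2L)
  expect_identical(sum(ch$position %in% cons4$position), 2L)
})

test_that("reliability-coverage curves end at the overall accuracy", {
  rec <- data.frame(protein_id = c("a", "b"), reliability = c(0.9, 0.5),
                    correct = c(TRUE, FALSE))
  curve <- reliability_coverage(rec)
  expect_equal(curve$coverage, c(50, 100))
  expect_equal(curve$accuracy, c(100, 50))
  all_ok <- data.frame(protein_id = letters[1:4],
                       reliability = c(0.9, 0.8, 0.7, 0.6),
                       correct = TRUE)
  expect_true(all(reliability_coverage(all_ok)$accuracy == 100))
  expect_identical(nrow(reliability_coverage(rec[0, ])), 0L)
})

test_that("a small simulation has the expected deterministic structure", {
  model <- synth_model()
  bench <- synth_benchmark()$entries[1:10]
  cfg <- simulation_config(fractions = c(0, 1),
                           corruption_fractions = 0,
                           n_randomizations = 3L, seed = 42L)
  res <- suppressMessages(run_simulation(bench, model, cfg))
  # p = 0: every randomization is the identical unconstrained run
  p0 <- res$summary[res$summary$p == 0, ]
  expect_identical(p0$accuracy_sd, 0)
  uncon_acc <- 100 * mean(vapply(bench, function(e) {
    compare_topology(predict_topology(model, e$protein)$topology, e$reference)
  }, logical(1)))
  expect_equal(p0$accuracy_mean, uncon_acc)
  # p = 1 without corruption is deterministic too (the full pool is used)
  expect_identical(res$summary$accuracy_sd[res$summary$p == 1], 0)
  # curve endpoint equals the cell accuracy
  for (pp in c(0, 1)) {
    cur <- res$curves[res$curves$p == pp, ]
    expect_equal(cur$accuracy_mean[which.max(cur$coverage)],
                 res$summary$accuracy_mean[res$summary$p == pp])
  }
  # every record's constraints came from the right pools
  expect_true(all(res$records$correct %in% c(TRUE, FALSE)))
  expect_identical(nrow(res$records), 2L * 1L * 3L * 10L)
})

test_that("identical seeds reproduce the simulation bit for bit", {
  model <- synth_model()
  bench <- synth_benchmark()$entries[1:6]
  cfg <- simulation_config(fractions = c(0.5), corruption_fractions = c(0.1),
                           n_randomizations = 2L, seed = 77L)
  a <- suppressMessages(run_simulation(bench, model, cfg))
  b <- suppressMessages(run_simulation(bench, model, cfg))
  expect_identical(a$records, b$records)
  expect_identical(a$summary, b$summary)
  cfg2 <- simulation_config(fractions = c(0.5), corruption_fractions = c(0.1),
                            n_randomizations = 2L, seed = 78L)
  c_ <- suppressMessages(run_simulation(bench, model, cfg2))
  expect_false(identical(a$records$reliability, c_$records$reliability))
})

test_that("simulation results write as tidy TSV files", {
  model <- synth_model()
  bench <- synth_benchmark()$entries[1:4]
  cfg <- simulation_config(fractions = 1, corruption_fractions = 0,
                           n_randomizations = 1L, seed = 5L)
  res <- suppressMessages(run_simulation(bench, model, cfg))
  dir <- withr::local_tempdir()
  write_simulation_result(res, dir)
  expect_true(all(file.exists(file.path(dir,
    c("records.tsv", "summary.tsv", "curves.tsv")))))
  back <- read_tsv(file.path(dir, "summary.tsv"))
  expect_equal(back$accuracy_mean, res$summary$accuracy_mean)
})
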