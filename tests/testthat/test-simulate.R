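test_that("identical seeds give identical datasets", {
  cfg <- sim_config(n_genes = 40, seed = 1)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$matrix$signals, b$matrix$signals)
  expect_identical(a$matrix$detection_p, b$matrix$detection_p)
  expect_identical(a$truth$de_genes, b$truth$de_genes)
  expect_identical(a$truth$as_events, b$truth$as_events)
  c_ <- simulate_dataset(sim_config(n_genes = 40, seed = 2))
  expect_false(identical(a$matrix$signals, c_$matrix$signals))
})

test_that("planted fractions are exact and zero fractions give empty truth", {
  s0 <- simulate_dataset(sim_config(n_genes = 50, de_fraction = 0,
                                    as_fraction = 0, seed = 3))
  expect_equal(nrow(s0$truth$de_genes), 0)
  expect_equal(nrow(s0$truth$as_events), 0)

  s1 <- simulate_dataset(sim_config(n_genes = 100, as_fraction = 0.1,
                                    de_fraction = 0.2, seed = 3))
  expect_equal(nrow(s1$truth$as_events), 10)
  expect_equal(nrow(s1$truth$de_genes), 20)
  expect_length(intersect(s1$truth$as_events$gene_id,
                          s1$truth$de_genes$gene_id), 0)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(probesets_per_gene = c(3, 8)), ">= 4")
  expect_error(sim_config(noise_sd = 0), "positive")
  expect_error(sim_config(de_fraction = 1.2), "\\[0, 1\\]")
})

test_that("plant_as_event modifies exactly the event span of one group", {
  prof <- matrix(8, 6, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  out <- plant_as_event(prof, "cassette", c(3, 4), -2, "g1")
  expect_equal(out[, "g1"] - prof[, "g1"], c(0, 0, -2, -2, 0, 0))
  expect_equal(out[, c("g2", "g3")], prof[, c("g2", "g3")])

  out2 <- plant_as_event(prof, "alt_first", c(1, 3), -4, "g2")
  expect_equal(out2[, "g2"] - prof[, "g2"], c(-4, -4, -4, 0, 0, 0))

  expect_identical(plant_as_event(prof, "cassette", c(3, 4), 0, "g1"), prof)
  expect_error(plant_as_event(prof, "cassette", c(5, 7), 1, "g1"),
               "outside")
})

test_that("event spans lie inside genes and obey their type geometry", {
  sim <- simulate_dataset(sim_config(n_genes = 200, as_fraction = 0.3,
                                     seed = 11))
  ev <- sim$truth$as_events
  len <- table(sim$annotation$transcript_cluster_id)
  for (i in seq_len(nrow(ev))) {
    L <- as.integer(len[ev$gene_id[i]])
    expect_gte(ev$span_first[i], 1)
    expect_lte(ev$span_last[i], L)
    if (ev$event_type[i] == "alt_first") expect_equal(ev$span_first[i], 1)
    if (ev$event_type[i] == "alt_last") expect_equal(ev$span_last[i], L)
    if (ev$event_type[i] == "exon_extension")
      expect_equal(ev$span_first[i], ev$span_last[i])
  }
  expect_true(all(ev$event_type %in%
    c("cassette", "intron_retention", "alt_first", "alt_last",
      "exon_extension")))
  expect_true(all(ev$affected_group %in% c("blood", "cd34")))
})

test_that("analytic DABG mapping has the expected tails", {
  expect_equal(simulate_dabg(matrix(3, 1, 1,
                                    dimnames = list("p", "s")),
                             noise_floor = 3)[1, 1], 0.5)
  expect_lt(simulate_dabg(matrix(13, 1, 1, dimnames = list("p", "s")),
                          noise_floor = 3)[1, 1], 1e-6)
  x <- matrix(seq(2, 12, by = 0.5), ncol = 1,
              dimnames = list(NULL, "s"))
  p <- simulate_dabg(x, noise_floor = 4)
  expect_true(all(diff(p[, 1]) < 0))   # monotone decreasing in excess
  expect_true(all(p > 0 & p <= 1))
})

test_that("background genes escape detection, expressed genes do not", {
  sim <- simulate_dataset(sim_config(n_genes = 120, seed = 5,
                                     de_fraction = 0, as_fraction = 0,
                                     background_fraction = 0.15))
  bg_ps <- sim$annotation$probeset_id[sim$annotation$evidence == "full"]
  p_bg <- sim$matrix$detection_p[bg_ps, , drop = FALSE]
  # per background probeset, nearly all samples stay above alpha
  frac_all_above <- mean(apply(p_bg > 0.05, 1, all))
  expect_gte(frac_all_above, 0.9)
  expr_ps <- setdiff(rownames(sim$matrix$signals), bg_ps)
  p_ex <- sim$matrix$detection_p[expr_ps, , drop = FALSE]
  expect_gte(mean(rowSums(p_ex <= 0.05) >= 3), 0.99)
})

test_that("without planted splicing, group differences are flat per gene", {
  sim <- simulate_dataset(sim_config(n_genes = 60, as_fraction = 0,
                                     de_fraction = 0.2, seed = 9,
                                     background_fraction = 0))
  deltas <- group_delta(sim$matrix, sim$annotation, sim$groups,
                        "blood", "liver")
  # noise of a mean difference: sd ~ noise_sd * sqrt(1/4 + 1/3)
  spread <- vapply(deltas, function(d) diff(range(d)), numeric(1))
  expect_lt(max(spread), 8 * 0.3 * sqrt(1 / 4 + 1 / 3))
})

test_that("truth tables and dataset files round-trip to disk", {
  sim <- simulate_dataset(sim_config(n_genes = 20, seed = 2))
  dir <- withr::local_tempdir()
  write_truth_tables(sim$truth, dir)
  de <- read.delim(file.path(dir, "truth_de_genes.tsv"))
  expect_equal(nrow(de), nrow(sim$truth$de_genes))
  expect_equal(sort(de$gene_id), sort(sim$truth$de_genes$gene_id))
})
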