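test_that("window contrasts match hand-computed values and kill constants", {
  # frozen from the brute-force contrast oracle
  expect_equal(unname(dsi_window(c(0, 0, -2, -2))), c(2, 0, 4 / 3))
  expect_equal(unname(dsi_window(c(0, 3, 0, 0))), c(3 / 2, 3 / 2, 3))
  for (c_ in c(-3, 0, 0.7, 12))
    expect_equal(unname(dsi_window(rep(c_, 4))), c(0, 0, 0))
  expect_error(dsi_window(c(1, 2, NA, 4)), "finite")
  expect_error(dsi_window(1:3), "4")
})

test_that("dsiT anchors a window per probeset and leaves the tail unscored", {
  delta <- c(0, 0, -2, -2, 0, 0)
  out <- dsiT_per_probeset(delta)
  expect_length(out, 6)
  expect_true(all(is.na(out[4:6])))
  expect_equal(out[1], 2 + 0 + 4 / 3)     # window (0,0,-2,-2)
  expect_equal(unname(out[1:3]), unname(oracle_dsiT(delta)[1:3]))
  expect_equal(unname(dsiT_per_probeset(rep(0, 8))[1:5]), rep(0, 5))
})

test_that("dsiT equals the brute-force window oracle on random genes", {
  set.seed(123)
  for (i in 1:1000) {
    L <- sample(4:8, 1)
    delta <- rnorm(L, sd = 2)
    expect_equal(dsiT_per_probeset(delta), oracle_dsiT(delta))
  }
})

test_that("dsi is shift-invariant and antisymmetric under group swap", {
  set.seed(99)
  for (i in 1:200) {
    w <- rnorm(4, sd = 2)
    shift <- rnorm(1, sd = 5)
    expect_equal(dsi_window(w + shift), dsi_window(w))
    expect_equal(unname(dsi_window(-w)), -unname(dsi_window(w)))
  }
  delta <- rnorm(10)
  expect_equal(dsiT_per_probeset(delta + 5), dsiT_per_probeset(delta))
  expect_equal(dsiT_per_probeset(-delta), dsiT_per_probeset(delta))
})

test_that("group_delta recovers planted difference profiles", {
  anno <- toy_annotation(2, 6)
  groups <- sample_groups(data.frame(
    sample_id = sprintf("s%02d", 1:6),
    group = rep(c("A", "B"), each = 3)))
  base <- matrix(8, 12, 6,
                 dimnames = list(anno$probeset_id, groups$sample_id))
  # gene 1: cassette at probesets 3-4, magnitude -2 in group A
  base[3:4, 1:3] <- 6
  # gene 2: whole-gene 2-fold shift in group A
  base[7:12, 1:3] <- 9
  x <- ps_matrix(base)
  d <- group_delta(x, anno, groups, "A", "B")
  expect_equal(unname(d$TC00001), c(0, 0, -2, -2, 0, 0))
  expect_equal(unname(d$TC00002), rep(1, 6))
  # identical groups give a zero profile
  d0 <- group_delta(x, anno, groups, "A", "A")
  expect_equal(unname(d0$TC00001), rep(0, 6))
  # whole-gene shifts never score
  expect_equal(unname(dsiT_per_probeset(d$TC00002)[1:3]), rep(0, 3))
})

test_that("clusters below 4 retained probesets are excluded from scoring", {
  anno <- toy_annotation(2, 4)
  groups <- sample_groups(data.frame(sample_id = sprintf("s%02d", 1:4),
                                     group = rep(c("A", "B"), each = 2)))
  x <- ps_matrix(matrix(8, 8, 4, dimnames = list(anno$probeset_id,
                                                 groups$sample_id)))
  mask <- setNames(rep(TRUE, 8), anno$probeset_id)
  mask[1] <- FALSE                     # gene 1 drops to 3 probesets
  d <- group_delta(x, anno, groups, "A", "B", mask = mask)
  expect_equal(names(d), "TC00002")
  expect_equal(attr(d, "excluded"), "TC00001")
})

test_that("the default hematopoietic plan has 21 comparisons", {
  sim <- simulate_dataset(sim_config(n_genes = 10, seed = 1))
  plan <- default_comparison_plan(sim$groups)
  expect_equal(nrow(plan), 21)
  expect_false(any(plan$group_a == "spleen" | plan$group_b == "spleen"))
  expect_equal(sum(plan$group_a == "blood" & plan$group_b == "cd34"), 1)
  expect_equal(sum(plan$group_a == "blood"), 11)
  expect_equal(sum(plan$group_a == "cd34"), 10)
})

test_that("top-K selection is deterministic, tie-broken by probeset id", {
  tab <- data.frame(
    probeset_id = sprintf("PS%03d", 1:6),
    transcript_cluster_id = "TC1",
    comparison = "A_vs_B",
    dsi1 = 0, dsi2 = 0, dsi3 = 0,
    dsiT = c(5, 3, 3, 1, NA, NA),
    stringsAsFactors = FALSE)
  out <- select_top_k(tab, "A_vs_B", k = 2)
  expect_equal(out$probeset_id[out$selected], c("PS001", "PS002"))
  expect_equal(out$rank[1:4], 1:4)
  expect_true(all(is.na(out$rank[5:6])))
  # quota clipping warns and selects everything scoreable
  expect_warning(out2 <- select_top_k(tab, "A_vs_B", k = 100),
                 "only 4 scoreable")
  expect_equal(sum(out2$selected), 4)
  # all-zero scores: first k by id, still deterministic
  tab$dsiT <- c(0, 0, 0, 0, 0, 0)
  out3 <- select_top_k(tab, "A_vs_B", k = 3)
  expect_equal(out3$probeset_id[out3$selected],
               c("PS001", "PS002", "PS003"))
})

test_that("a full 21-comparison scan flags exactly 21 x 100 selections", {
  sim <- simulate_dataset(sim_config(n_genes = 400, seed = 7))
  mask <- dabg_filter(sim$matrix)
  plan <- default_comparison_plan(sim$groups)
  dsi <- dsi_scan(sim$matrix, sim$annotation, sim$groups, plan,
                  k = 100, mask = mask)
  expect_equal(sum(dsi$selected), 2100)
  per_comp <- tapply(dsi$selected, dsi$comparison, sum)
  expect_true(all(per_comp == 100))
})

test_that("selected probesets aggregate to a deduplicated transcript list", {
  tab <- data.frame(
    probeset_id = c("PS1", "PS2", "PS3", "PS1"),
    transcript_cluster_id = c("TC1", "TC1", "TC2", "TC1"),
    comparison = c("c1", "c1", "c1", "c2"),
    dsiT = 1, selected = c(TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  agg <- aggregate_as_list(tab)
  expect_equal(nrow(agg), 2)
  tc1 <- agg[agg$transcript_cluster_id == "TC1", ]
  expect_equal(tc1$n_probesets_selected, 2)
  expect_equal(tc1$n_comparisons, 2)
  # empty selection -> empty list
  tab$selected <- FALSE
  expect_equal(nrow(aggregate_as_list(tab)), 0)
  # unannotated selections are an error
  tab$selected <- TRUE
  anno <- toy_annotation(1, 4)
  expect_error(aggregate_as_list(tab, anno), "without annotation")
})

test_that("planted splicing events are recovered from the AS list", {
  sim <- simulate_dataset(sim_config(n_genes = 300, as_fraction = 0.1,
                                     as_effect_log2 = 2, noise_sd = 0.3,
                                     seed = 21))
  mask <- dabg_filter(sim$matrix)
  plan <- default_comparison_plan(sim$groups)
  dsi <- dsi_scan(sim$matrix, sim$annotation, sim$groups, plan,
                  k = 100, mask = mask)
  as_list <- aggregate_as_list(dsi, sim$annotation)
  planted <- sim$truth$as_events$gene_id
  recovery <- mean(planted %in% as_list$transcript_cluster_id)
  expect_gte(recovery, 0.8)
})

test_that("overlap with DE lists reports exact set counts", {
  mk_sam <- function(up, down) {
    structure(data.frame(gene_id = c(up, down, "z1"),
                         d = 0, fold = 1, q = 1,
                         call = c(rep("up", length(up)),
                                  rep("down", length(down)), "ns"),
                         stringsAsFactors = FALSE),
              class = c("sam_result", "data.frame"),
              s0 = 0, n_perm_used = 0, groups = c("a", "b"),
              fold_cutoff = 2, fdr_cutoff = 0.05)
  }
  sam_a <- mk_sam(c("g1", "g2"), "g5")
  sam_b <- mk_sam(c("g2", "g3"), "g6")
  ov <- overlap_with_de(c("g2", "g6", "g9"), sam_a, sam_b)
  expect_equal(ov$n_up_union, 3)
  expect_equal(ov$n_down_union, 2)
  expect_equal(ov$n_as_in_up, 1)
  expect_equal(ov$n_as_in_down, 1)
  # disjoint AS list
  ov0 <- overlap_with_de("g9", sam_a, sam_b)
  expect_equal(ov0$n_as_in_up + ov0$n_as_in_down, 0)
  # AS list inside the up union
  ov1 <- overlap_with_de(c("g1", "g3"), sam_a, sam_b)
  expect_equal(ov1$n_as_in_up, 2)
})
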