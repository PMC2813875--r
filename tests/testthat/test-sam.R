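# two-group expression matrix with optional planted fold changes
make_de_matrix <- function(n_genes, n1, n2, effect_log2 = 0, n_de = 0,
                           noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n1 + n2), 8, noise_sd), n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n1 + n2))))
  if (n_de > 0)
    m[seq_len(n_de), seq_len(n1)] <- m[seq_len(n_de), seq_len(n1)] +
      effect_log2
  labels <- rep(c("A", "B"), c(n1, n2))
  list(m = m, labels = labels)
}

test_that("a gene with identical group means gets d = 0 and call ns", {
  dat <- make_de_matrix(50, 4, 4, seed = 2)
  dat$m["g0001", ] <- rep(c(7, 8, 9, 8), 2)   # same values in both groups
  suppressWarnings(res <- sam_test(dat$m, dat$labels, "A", "B", seed = 1))
  row <- res[res$gene_id == "g0001", ]
  expect_equal(row$d, 0)
  expect_equal(row$fold, 1)
  expect_equal(row$call, "ns")
})

test_that("with s0 = 0 and shared variance, d matches the two-sample t form", {
  dat <- make_de_matrix(30, 4, 4, seed = 3)
  suppressWarnings(
    res <- sam_test(dat$m, dat$labels, "A", "B", seed = 1,
                    s0_percentile = 0))
  # s0 = min(se) > 0, so compare against the explicit formula per gene
  s0 <- attr(res, "s0")
  g <- "g0010"
  x1 <- dat$m[g, 1:4]; x2 <- dat$m[g, 5:8]
  se <- sqrt((1 / 4 + 1 / 4) * (sum((x1 - mean(x1))^2) +
                                  sum((x2 - mean(x2))^2)) / 6)
  expect_equal(res$d[res$gene_id == g],
               (mean(x1) - mean(x2)) / (se + s0))
  # the plain Welch-free pooled t statistic is recovered as s0 -> 0
  expect_equal(res$d[res$gene_id == g] * (se + s0) / se,
               unname(t.test(x1, x2, var.equal = TRUE)$statistic),
               tolerance = 1e-12)
})

test_that("small designs are enumerated exhaustively with a warning", {
  dat <- make_de_matrix(20, 3, 3, seed = 4)
  expect_warning(res <- sam_test(dat$m, dat$labels, "A", "B", n_perm = 100),
                 "exhaustively")
  expect_equal(attr(res, "n_perm_used"), choose(6, 3))
})

test_that("q-values are monotone in |d| and invariant to within-group relabeling", {
  dat <- make_de_matrix(40, 3, 3, n_de = 5, effect_log2 = 2, seed = 5)
  suppressWarnings(res <- sam_test(dat$m, dat$labels, "A", "B", seed = 1))
  expect_true(all(diff(res$q) >= 0))           # rows ordered by |d| desc
  # permute samples within each group: exhaustive null is unchanged
  perm <- c(2, 3, 1, 6, 4, 5)
  suppressWarnings(res2 <- sam_test(dat$m[, perm], dat$labels[perm],
                                    "A", "B", seed = 99))
  expect_equal(res2$q[match(res$gene_id, res2$gene_id)], res$q)
  expect_equal(res2$d[match(res$gene_id, res2$gene_id)], res$d)
})

test_that("pure-null data yields calls at or below the nominal FDR bound", {
  dat <- make_de_matrix(500, 4, 4, seed = 6)
  suppressWarnings(
    res <- sam_test(dat$m, dat$labels, "A", "B", n_perm = 100, seed = 1))
  expect_lte(sum(res$call != "ns"), 0.05 * 500)
})

test_that("planted 4-fold genes at n = 4 per group are recovered", {
  dat <- make_de_matrix(300, 4, 4, effect_log2 = 2, n_de = 30,
                        noise_sd = 0.3, seed = 7)
  suppressWarnings(
    res <- sam_test(dat$m, dat$labels, "A", "B", n_perm = 100, seed = 1))
  planted <- sprintf("g%04d", 1:30)
  recalled <- res$gene_id[res$call == "up"]
  expect_gte(length(intersect(planted, recalled)) / 30, 0.9)
  # and fold changes are computed on de-logged group means
  row <- res[res$gene_id == "g0001", ]
  m1 <- mean(dat$m["g0001", 1:4]); m2 <- mean(dat$m["g0001", 5:8])
  expect_equal(row$fold, 2^(m1 - m2))
})

test_that("degenerate group sizes are rejected", {
  dat <- make_de_matrix(10, 4, 4)
  expect_error(sam_test(dat$m, dat$labels, "A", "C"), "at least 2")
})

test_that("venn decomposition reproduces the printed signature arithmetic", {
  # cardinalities from the hematopoietic study: 1345 blood-up, 1723
  # CD34-up, 506 shared
  blood_up <- sprintf("g%04d", 1:1345)
  cd34_up <- sprintf("g%04d", c(1:506, 1346:2562))
  v <- venn_signatures(blood_up, cd34_up, labels = c("blood", "cd34"))
  expect_length(v$common, 506)
  expect_length(v$a_specific, 839)
  expect_length(v$b_specific, 1217)
  expect_equal(length(v$common) + length(v$a_specific) +
                 length(v$b_specific),
               length(union(blood_up, cd34_up)))
  expect_equal(length(union(blood_up, cd34_up)), 2562)
})

test_that("venn edge cases: identical and disjoint inputs", {
  v1 <- venn_signatures(c("a", "b"), c("a", "b"))
  expect_length(v1$a_specific, 0)
  expect_length(v1$b_specific, 0)
  expect_setequal(v1$common, c("a", "b"))
  v2 <- venn_signatures(c("a", "b"), c("c"))
  expect_length(v2$common, 0)
  expect_setequal(v2$a_specific, c("a", "b"))
  expect_setequal(v2$b_specific, "c")
})
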