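# Two-class SAM machinery: moderated d statistic with fudge factor s0,
# permutation-based q-values, fold-change + FDR calls.

# per-gene group means, pooled standard error and d = (m1-m2)/(se+s0)
sam_stats <- function(m, idx1, idx2, s0) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(m[, idx1, drop = FALSE])
  m2 <- rowMeans(m[, idx2, drop = FALSE])
  ss1 <- rowSums((m[, idx1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((m[, idx2, drop = FALSE] - m2)^2)
  se <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(diff = m1 - m2, se = se, d = (m1 - m2) / (se + s0))
}

# Tusher-style fudge factor: the percentile of the per-gene standard errors
# that minimizes the coefficient of variation of the d spread across bins
# of se. `s0_percentile` forces a fixed percentile instead.
choose_s0 <- function(diff, se, s0_percentile = NULL) {
  if (!is.null(s0_percentile))
    return(stats::quantile(se, s0_percentile / 100, names = FALSE))
  cands <- stats::quantile(se, seq(0, 1, by = 0.05), names = FALSE)
  n_bins <- min(10L, max(2L, floor(length(se) / 20)))
  breaks <- unique(stats::quantile(se, seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3) return(stats::median(se))
  bin <- cut(se, breaks, include.lowest = TRUE)
  cv <- vapply(cands, function(s0) {
    v <- vapply(split(diff / (se + s0), bin),
                function(z) stats::mad(z), numeric(1))
    v <- v[is.finite(v)]
    if (mean(v) == 0) Inf else stats::sd(v) / mean(v)
  }, numeric(1))
  cands[which.min(cv)]
}

# all (or n_perm random) two-class label assignments as index sets of group 1
perm_assignments <- function(n, n1, n_perm) {
  total <- choose(n, n1)
  if (total <= n_perm) {
    warning("requested ", n_perm, " permutations but only ", total,
            " distinct assignments exist; enumerating exhaustively")
    asplit(utils::combn(n, n1), 2)
  } else {
    lapply(seq_len(n_perm), function(i) sample.int(n, n1))
  }
}

#' SAM-style two-class differential expression test
#'
#' Computes, per gene, the moderated difference statistic
#' `d = (mean_A - mean_B) / (se + s0)` where `se` is the pooled standard
#' error and `s0` a fudge factor chosen to stabilize the variance of `d`
#' across the range of standard errors. The null distribution is obtained by
#' permuting group labels; each gene's q-value is the median number of
#' permuted `|d*|` values exceeding its observed `|d|`, divided by the
#' observed count at that threshold, made monotone in the `|d|` ranking.
#' A gene is called up (down) when its fold change on the de-logged group
#' means is at least `fold` (at most `1/fold`) and its q-value is at most
#' `fdr`.
#'
#' @param m numeric gene x sample matrix of log2 expression values.
#' @param groups a [sample_groups] table, or a character vector of group
#'   labels aligned with `colnames(m)`.
#' @param group_a,group_b the two group labels to compare (A vs B).
#' @param n_perm number of label permutations (default 100). When the number
#'   of distinct assignments is smaller, they are enumerated exhaustively
#'   with a warning.
#' @param fold fold-change cutoff on the raw scale (default 2).
#' @param fdr q-value cutoff (default 0.05).
#' @param seed integer seed for the permutation draw.
#' @param s0_percentile optional fixed percentile (0-100) of the standard
#'   errors to use as `s0`, bypassing the automatic search. `s0_percentile
#'   = 0` with equal group variances reduces `d` to the ordinary two-sample
#'   t form.
#' @return data.frame of class `sam_result` with columns `gene_id`, `d`,
#'   `fold`, `q`, `call` (`up`/`down`/`ns`), ordered by decreasing `|d|`;
#'   attributes `s0`, `n_perm_used`, `groups`.
#' @export
sam_test <- function(m, groups, group_a, group_b, n_perm = 100, fold = 2.0,
                     fdr = 0.05, seed = 1L, s0_percentile = NULL) {
  if (inherits(groups, "sample_groups")) {
    lab <- groups$group[match(colnames(m), groups$sample_id)]
  } else {
    lab <- as.character(groups)
    if (length(lab) != ncol(m))
      stop("`groups` must cover every column of `m`")
  }
  idx1 <- which(lab == group_a)
  idx2 <- which(lab == group_b)
  if (length(idx1) < 2 || length(idx2) < 2)
    stop("both groups need at least 2 samples (",
         group_a, ": ", length(idx1), ", ", group_b, ": ", length(idx2), ")")
  sub <- m[, c(idx1, idx2), drop = FALSE]
  n1 <- length(idx1); n <- ncol(sub)
  i1 <- seq_len(n1); i2 <- (n1 + 1):n

  base <- sam_stats(sub, i1, i2, 0)
  s0 <- choose_s0(base$diff, base$se, s0_percentile)
  obs <- sam_stats(sub, i1, i2, s0)

  set.seed(seed)
  perms <- perm_assignments(n, n1, n_perm)
  abs_obs <- abs(obs$d)
  ord <- order(abs_obs, decreasing = TRUE)
  # count of permuted |d*| >= each observed |d| (genes sorted by |d| desc)
  sorted_abs <- abs_obs[ord]
  fp <- vapply(perms, function(p) {
    dstar <- abs(sam_stats(sub, p, setdiff(seq_len(n), p), s0)$d)
    # for each threshold in sorted_abs, how many dstar >= threshold
    ds <- sort(dstar, decreasing = TRUE)
    findInterval(-sorted_abs, -ds)
  }, numeric(length(abs_obs)))
  med_fp <- apply(fp, 1, stats::median)
  q_sorted <- pmin(1, med_fp / seq_along(sorted_abs))
  q_sorted <- cummax(q_sorted)          # monotone non-decreasing down ranks
  q <- numeric(length(abs_obs))
  q[ord] <- q_sorted

  fold_change <- 2^(obs$diff)           # ratio of de-logged group means
  call <- rep("ns", length(q))
  call[fold_change >= fold & q <= fdr & obs$d > 0] <- "up"
  call[fold_change <= 1 / fold & q <= fdr & obs$d < 0] <- "down"

  res <- data.frame(gene_id = rownames(m), d = obs$d, fold = fold_change,
                    q = q, call = call, stringsAsFactors = FALSE)
  res <- res[ord, ]
  rownames(res) <- NULL
  structure(res, class = c("sam_result", "data.frame"),
            s0 = s0, n_perm_used = length(perms),
            groups = c(group_a, group_b),
            fold_cutoff = fold, fdr_cutoff = fdr)
}

#' @export
print.sam_result <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("SAM result: %s vs %s, %d genes, s0 = %.4g, %d permutations\n",
              g[1], g[2], nrow(x), attr(x, "s0"), attr(x, "n_perm_used")))
  cat(sprintf("  calls: %d up, %d down (fold >= %g, q <= %g)\n",
              sum(x$call == "up"), sum(x$call == "down"),
              attr(x, "fold_cutoff"), attr(x, "fdr_cutoff")))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' @export
summary.sam_result <- function(object, ...) {
  g <- attr(object, "groups")
  out <- list(comparison = paste(g, collapse = " vs "),
              n_genes = nrow(object),
              n_up = sum(object$call == "up"),
              n_down = sum(object$call == "down"),
              s0 = attr(object, "s0"),
              n_perm = attr(object, "n_perm_used"))
  class(out) <- "summary.sam_result"
  out
}

#' @export
print.summary.sam_result <- function(x, ...) {
  cat(sprintf("%s: %d genes, %d up / %d down, s0 %.4g, %d permutations\n",
              x$comparison, x$n_genes, x$n_up, x$n_down, x$s0, x$n_perm))
  invisible(x)
}

#' Up/down gene lists from a SAM result
#' @param x a `sam_result`
#' @return list with character vectors `up` and `down`
#' @export
sam_calls <- function(x) {
  stopifnot(inherits(x, "sam_result"))
  list(up = x$gene_id[x$call == "up"], down = x$gene_id[x$call == "down"])
}

#' Venn decomposition of two differential gene lists
#'
#' Splits two gene lists (e.g. genes up-regulated in whole blood vs solid
#' tissues, and in CD34+ progenitors vs solid tissues) into the shared
#' "common" signature and the two group-specific signatures, by exact set
#' algebra.
#'
#' @param up_a,up_b character vectors of gene ids.
#' @param labels length-2 labels for the two lists (used in printing).
#' @return list of class `signature_venn` with elements `common`,
#'   `a_specific`, `b_specific` (character vectors) and `labels`.
#' @examples
#' v <- venn_signatures(c("g1", "g2", "g3"), c("g2", "g4"))
#' lengths(v[1:3])
#' @export
venn_signatures <- function(up_a, up_b, labels = c("A", "B")) {
  up_a <- unique(as.character(up_a))
  up_b <- unique(as.character(up_b))
  common <- intersect(up_a, up_b)
  structure(list(common = common,
                 a_specific = setdiff(up_a, common),
                 b_specific = setdiff(up_b, common),
                 labels = labels),
            class = "signature_venn")
}

#' @export
print.signature_venn <- function(x, ...) {
  cat(sprintf("signature venn (%s / %s): %d common, %d %s-specific, %d %s-specific, union %d\n",
              x$labels[1], x$labels[2], length(x$common),
              length(x$a_specific), x$labels[1],
              length(x$b_specific), x$labels[2],
              length(x$common) + length(x$a_specific) +
                length(x$b_specific)))
  invisible(x)
}
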