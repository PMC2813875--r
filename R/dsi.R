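# Differential splicing index (dsi / dsiT): windowed zero-sum contrasts of
# per-probeset group differences, scored over four contiguous probesets.

# contrast coefficient rows for (step, bump, spike); zero-sum, so any
# whole-gene (constant) group difference scores 0 and the index is invariant
# to shifts of a group's overall expression level
dsi_coefficients <- function() {
  rbind(step  = c( 1/2,  1/2, -1/2, -1/2),
        bump  = c(-1/2,  1/2,  1/2, -1/2),
        spike = c(-1/3,  1,   -1/3, -1/3))
}

#' Per-cluster group-difference profiles
#'
#' For one comparison (group A vs group B), computes per transcript cluster
#' the ordered vector of per-probeset differences of group-mean log2
#' signals, `delta_i = mean_A(probeset i) - mean_B(probeset i)`, over the
#' retained (mask-passing) probesets in annotation ordinal order. Clusters
#' with fewer than 4 retained probesets cannot host a scoring window and are
#' excluded.
#'
#' @param x a [ps_matrix].
#' @param annotation a [ps_annotation].
#' @param groups a [sample_groups].
#' @param group_a,group_b group labels to contrast (A minus B).
#' @param mask optional logical mask from [dabg_filter]; scoring is defined
#'   on the detection-filtered probeset set.
#' @return named list (by transcript cluster) of named numeric delta
#'   vectors (names = probeset ids, ordinal order). Excluded clusters are
#'   reported in attribute `excluded`.
#' @export
group_delta <- function(x, annotation, groups, group_a, group_b,
                        mask = NULL) {
  stopifnot(inherits(x, "ps_matrix"), inherits(annotation, "ps_annotation"))
  check_groups(x, groups)
  sa <- group_samples(groups, group_a)
  sb <- group_samples(groups, group_b)
  sig <- x$signals
  keep <- rownames(sig)
  if (!is.null(mask))
    keep <- intersect(keep, if (is.logical(mask)) names(mask)[mask]
                      else as.character(mask))
  anno <- annotation[annotation$probeset_id %in% keep, , drop = FALSE]
  delta_all <- rowMeans(sig[anno$probeset_id, sa, drop = FALSE]) -
    rowMeans(sig[anno$probeset_id, sb, drop = FALSE])
  # annotation is already sorted by cluster + ordinal
  by_cluster <- split(delta_all, anno$transcript_cluster_id)
  lens <- lengths(by_cluster)
  excluded <- names(by_cluster)[lens < 4]
  out <- by_cluster[lens >= 4]
  attr(out, "excluded") <- excluded
  out
}

#' The three dsi contrasts of one 4-probeset window
#'
#' Given the group differences `(delta_n, delta_{n+1}, delta_{n+2},
#' delta_{n+3})` of four contiguous probesets, returns the three
#' differential splicing indexes: a step contrast (first half vs second
#' half), a bump contrast (inner pair vs outer pair) and a spike contrast
#' (second probeset vs the mean of the other three). All three are zero-sum,
#' hence exactly 0 on any constant window.
#'
#' @param window numeric vector of length 4, finite.
#' @return named numeric vector `c(dsi1, dsi2, dsi3)`.
#' @examples
#' dsi_window(c(0, 0, -2, -2))
#' @export
dsi_window <- function(window) {
  if (length(window) != 4 || !all(is.finite(window)))
    stop("`window` must be 4 finite values")
  co <- dsi_coefficients()
  stats::setNames(as.numeric(co %*% window), c("dsi1", "dsi2", "dsi3"))
}

#' Total splicing index dsiT per probeset
#'
#' Anchors a 4-probeset window at each probeset `n` of a cluster's
#' difference profile and scores `dsiT(n) = |dsi1| + |dsi2| + |dsi3|` of the
#' window `(n, n+1, n+2, n+3)`. The last three probesets of a cluster have
#' no complete window and receive `NA`.
#'
#' @param delta numeric difference vector of length >= 4 (one cluster,
#'   ordinal order), e.g. one element of [group_delta] output.
#' @return numeric vector of the same length and names as `delta`.
#' @export
dsiT_per_probeset <- function(delta) {
  L <- length(delta)
  if (L < 4) stop("dsiT needs at least 4 probesets")
  if (!all(is.finite(delta))) stop("non-finite delta")
  co <- dsi_coefficients()
  n_anchor <- L - 3L
  # windows matrix: 4 x n_anchor
  w <- vapply(seq_len(n_anchor), function(i) delta[i:(i + 3L)],
              numeric(4))
  scores <- colSums(abs(co %*% w))
  out <- rep(NA_real_, L)
  out[seq_len(n_anchor)] <- scores
  names(out) <- names(delta)
  out
}

#' Score every cluster for one group comparison
#'
#' Runs [group_delta] and [dsiT_per_probeset] for one (A, B) pair and
#' returns the per-probeset dsi table for that comparison.
#'
#' @inheritParams group_delta
#' @param comparison label stored in the output (default "A_vs_B").
#' @return data.frame with columns `probeset_id`, `transcript_cluster_id`,
#'   `comparison`, `dsi1`, `dsi2`, `dsi3`, `dsiT` (NA for the last three
#'   probesets of each cluster).
#' @export
score_comparison <- function(x, annotation, groups, group_a, group_b,
                             mask = NULL,
                             comparison = paste(group_a, "vs", group_b,
                                                sep = "_")) {
  deltas <- group_delta(x, annotation, groups, group_a, group_b, mask)
  co <- dsi_coefficients()
  rows <- lapply(names(deltas), function(cl) {
    d <- deltas[[cl]]
    L <- length(d)
    n_anchor <- L - 3L
    w <- vapply(seq_len(n_anchor), function(i) d[i:(i + 3L)], numeric(4))
    ds <- co %*% w
    data.frame(
      probeset_id = names(d),
      transcript_cluster_id = cl,
      comparison = comparison,
      dsi1 = c(ds[1, ], rep(NA_real_, 3)),
      dsi2 = c(ds[2, ], rep(NA_real_, 3)),
      dsi3 = c(ds[3, ], rep(NA_real_, 3)),
      dsiT = c(colSums(abs(ds)), rep(NA_real_, 3)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(probeset_id = character(),
                      transcript_cluster_id = character(),
                      comparison = character(), dsi1 = numeric(),
                      dsi2 = numeric(), dsi3 = numeric(), dsiT = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Default hematopoietic comparison plan
#'
#' Each hematopoietic group against each solid tissue, plus the two
#' hematopoietic groups against each other. Groups listed in `exclude`
#' (by default the mixed-composition spleen) take part in no comparison.
#' With 2 hematopoietic groups, 11 solid tissues and spleen excluded this
#' yields the 21-comparison design.
#'
#' @param groups a [sample_groups] or character vector of group labels.
#' @param hematopoietic labels of the hematopoietic groups (default the
#'   first two distinct labels).
#' @param exclude labels excluded from the plan (default `"spleen"` when
#'   present).
#' @return data.frame of class `comparison_plan` with columns `group_a`,
#'   `group_b`.
#' @export
default_comparison_plan <- function(groups,
                                    hematopoietic = NULL,
                                    exclude = "spleen") {
  labs <- if (inherits(groups, "sample_groups")) unique(groups$group)
          else unique(as.character(groups))
  if (is.null(hematopoietic)) hematopoietic <- labs[seq_len(2)]
  if (!all(hematopoietic %in% labs))
    stop("hematopoietic group(s) not found: ",
         paste(setdiff(hematopoietic, labs), collapse = ", "))
  solid <- setdiff(labs, c(hematopoietic, exclude))
  plan <- rbind(
    expand.grid(group_a = hematopoietic, group_b = solid,
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
    if (length(hematopoietic) >= 2)
      data.frame(group_a = hematopoietic[1], group_b = hematopoietic[2],
                 stringsAsFactors = FALSE))
  # stable, readable order: first hema group vs all solids, then second, ...
  plan <- plan[order(match(plan$group_a, hematopoietic),
                     match(plan$group_b, c(solid, hematopoietic))), ]
  rownames(plan) <- NULL
  class(plan) <- c("comparison_plan", "data.frame")
  plan
}

#' Flag the K highest-dsiT probesets of one comparison
#'
#' Orders the scoreable (non-NA dsiT) probesets of one comparison by
#' decreasing dsiT, breaking ties by ascending probeset id, and flags the
#' top `min(k, scoreable)`. Deterministic.
#'
#' @param dsi data.frame from [score_comparison] (possibly several
#'   comparisons stacked).
#' @param comparison comparison label to select within.
#' @param k selection quota (default 100).
#' @return the input rows for `comparison` with added columns `rank`
#'   (NA for unscoreable probesets) and `selected` (logical).
#' @export
select_top_k <- function(dsi, comparison, k = 100) {
  rows <- dsi[dsi$comparison == comparison, , drop = FALSE]
  if (!nrow(rows)) stop("comparison '", comparison, "' not found")
  scoreable <- which(!is.na(rows$dsiT))
  ord <- scoreable[order(-rows$dsiT[scoreable],
                         rows$probeset_id[scoreable])]
  rows$rank <- NA_integer_
  rows$rank[ord] <- seq_along(ord)
  n_sel <- min(k, length(scoreable))
  if (length(scoreable) < k)
    warning("comparison '", comparison, "': only ", length(scoreable),
            " scoreable probesets for quota ", k)
  rows$selected <- !is.na(rows$rank) & rows$rank <= n_sel
  rows
}

#' Score and select over a whole comparison plan
#'
#' Runs [score_comparison] and [select_top_k] for every pair of the plan and
#' stacks the results into one table.
#'
#' @inheritParams group_delta
#' @param plan a [default_comparison_plan]-style data.frame with columns
#'   `group_a`, `group_b`.
#' @param k per-comparison selection quota (default 100).
#' @return data.frame of class `dsi_table`: per (probeset, comparison) rows
#'   with dsi contrasts, `dsiT`, `rank`, `selected`.
#' @export
dsi_scan <- function(x, annotation, groups, plan, k = 100, mask = NULL) {
  stopifnot(all(c("group_a", "group_b") %in% names(plan)))
  parts <- lapply(seq_len(nrow(plan)), function(i) {
    sc <- score_comparison(x, annotation, groups,
                           plan$group_a[i], plan$group_b[i], mask)
    select_top_k(sc, unique(sc$comparison), k)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out, class = c("dsi_table", "data.frame"), k = k)
}

#' @export
print.dsi_table <- function(x, ...) {
  cat(sprintf("dsi table: %d probeset x comparison rows, %d comparisons, %d selected (quota %d)\n",
              nrow(x), length(unique(x$comparison)), sum(x$selected),
              attr(x, "k")))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Aggregate probeset selections to the candidate AS transcript list
#'
#' Deduplicates the selected probesets of all comparisons to their
#' transcript clusters and records which comparisons selected each cluster.
#'
#' @param dsi a [dsi_scan] result (or any table with `probeset_id`,
#'   `transcript_cluster_id`, `comparison`, `selected`).
#' @param annotation optional [ps_annotation] used to verify that every
#'   selected probeset is annotated.
#' @return data.frame with one row per transcript cluster: `transcript_
#'   cluster_id`, `n_probesets_selected`, `n_comparisons`, `comparisons`
#'   (comma-separated), ordered by decreasing support.
#' @export
aggregate_as_list <- function(dsi, annotation = NULL) {
  sel <- dsi[dsi$selected, , drop = FALSE]
  if (!is.null(annotation)) {
    un <- setdiff(sel$probeset_id, annotation$probeset_id)
    if (length(un))
      stop("selected probeset(s) without annotation: ",
           paste(utils::head(un, 5), collapse = ", "))
  }
  if (!nrow(sel))
    return(data.frame(transcript_cluster_id = character(),
                      n_probesets_selected = integer(),
                      n_comparisons = integer(), comparisons = character(),
                      stringsAsFactors = FALSE))
  by_tc <- split(sel, sel$transcript_cluster_id)
  out <- data.frame(
    transcript_cluster_id = names(by_tc),
    n_probesets_selected = vapply(by_tc, function(d)
      length(unique(d$probeset_id)), integer(1)),
    n_comparisons = vapply(by_tc, function(d)
      length(unique(d$comparison)), integer(1)),
    comparisons = vapply(by_tc, function(d)
      paste(sort(unique(d$comparison)), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_comparisons, -out$n_probesets_selected,
                   out$transcript_cluster_id), ]
  rownames(out) <- NULL
  out
}

#' Overlap of the AS transcript list with differential-expression calls
#'
#' Reports how many candidate alternatively-spliced transcripts fall in the
#' union of up-regulated genes and in the union of down-regulated genes of
#' two SAM comparisons (e.g. blood vs solid tissues and CD34+ vs solid
#' tissues).
#'
#' @param as_list character vector of transcript cluster ids (or an
#'   [aggregate_as_list] data.frame).
#' @param sam_a,sam_b two `sam_result` objects on the same gene-id
#'   namespace.
#' @return list with `n_up_union`, `n_down_union`, `n_as_in_up`,
#'   `n_as_in_down` and the underlying id vectors `as_in_up`, `as_in_down`.
#' @export
overlap_with_de <- function(as_list, sam_a, sam_b) {
  if (is.data.frame(as_list)) as_list <- as_list$transcript_cluster_id
  as_list <- unique(as.character(as_list))
  ca <- sam_calls(sam_a); cb <- sam_calls(sam_b)
  up_union <- union(ca$up, cb$up)
  down_union <- union(ca$down, cb$down)
  list(n_up_union = length(up_union),
       n_down_union = length(down_union),
       n_as_in_up = length(intersect(as_list, up_union)),
       n_as_in_down = length(intersect(as_list, down_union)),
       as_in_up = intersect(as_list, up_union),
       as_in_down = intersect(as_list, down_union))
}
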