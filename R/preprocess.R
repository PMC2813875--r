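#' Percentile (scale) normalization of log2 signals
#'
#' Shifts each sample additively on the log2 scale (a multiplicative
#' rescaling of raw intensities) so that its q-th percentile equals a common
#' target, the scaling convention of array-scanner software that "conserves"
#' a chosen percentile across samples. Rank order within each sample is
#' preserved exactly.
#'
#' @param x a [ps_matrix].
#' @param q percentile in (0, 100); default 75.
#' @param target common target value for the percentile: a number, or
#'   `"median-of-samples"` (default) to use the median of the per-sample
#'   percentiles.
#' @return a [ps_matrix] with shifted signals (detection p-values carried
#'   through unchanged).
#' @export
scale_percentile <- function(x, q = 75, target = "median-of-samples") {
  stopifnot(inherits(x, "ps_matrix"))
  if (q <= 0 || q >= 100) stop("`q` must lie in (0, 100)")
  sig <- x$signals
  rng <- apply(sig, 2, function(v) diff(range(v)))
  if (any(rng == 0))
    stop("constant-signal sample(s): ",
         paste(colnames(sig)[rng == 0], collapse = ", "),
         " — percentile scaling undefined")
  pct <- apply(sig, 2, stats::quantile, probs = q / 100, names = FALSE)
  if (identical(target, "median-of-samples")) target <- stats::median(pct)
  if (!is.numeric(target) || length(target) != 1)
    stop("`target` must be a single number or 'median-of-samples'")
  sig <- sweep(sig, 2, pct - target)
  ps_matrix(sig, x$detection_p)
}

#' Detection-above-background (DABG) probeset filter
#'
#' A probeset is retained when its detection p-value is at or below `alpha`
#' in at least `min_detected` samples, counted over all samples jointly.
#' Returns a logical mask over probesets; the matrix itself is untouched so
#' filtering stays reversible until explicitly materialized.
#'
#' @param x a [ps_matrix] with detection p-values.
#' @param alpha detection p-value cutoff (inclusive); default 0.05.
#' @param min_detected minimum number of detected samples; default 3.
#' @return named logical vector, `TRUE` for retained probesets.
#' @export
dabg_filter <- function(x, alpha = 0.05, min_detected = 3) {
  stopifnot(inherits(x, "ps_matrix"))
  if (is.null(x$detection_p))
    stop("`dabg_filter` needs detection p-values")
  mask <- rowSums(x$detection_p <= alpha) >= min_detected
  names(mask) <- rownames(x$signals)
  mask
}

#' Apply a probeset mask to a signal matrix
#'
#' @param x a [ps_matrix]
#' @param mask logical mask from [dabg_filter] (or a character vector of
#'   probeset ids to keep)
#' @return a [ps_matrix] restricted to the retained probesets.
#' @export
apply_mask <- function(x, mask) {
  stopifnot(inherits(x, "ps_matrix"))
  keep <- if (is.logical(mask)) names(mask)[mask] else as.character(mask)
  keep <- intersect(rownames(x$signals), keep)
  ps_matrix(x$signals[keep, , drop = FALSE],
            if (is.null(x$detection_p)) NULL
            else x$detection_p[keep, , drop = FALSE])
}

#' Summarize retained probesets to transcript-cluster (gene) level
#'
#' One row per transcript cluster; each sample's value is the `method`
#' (median by default) over the cluster's retained probesets. Clusters with
#' no retained probeset are dropped with a message.
#'
#' @param x a [ps_matrix].
#' @param annotation a [ps_annotation]; every retained probeset must be
#'   annotated.
#' @param method `"median"` (default) or `"mean"`.
#' @param mask optional logical mask from [dabg_filter]; if omitted every
#'   probeset is used.
#' @return numeric matrix, transcript clusters x samples.
#' @export
summarize_gene_level <- function(x, annotation, method = c("median", "mean"),
                                 mask = NULL) {
  stopifnot(inherits(x, "ps_matrix"), inherits(annotation, "ps_annotation"))
  method <- match.arg(method)
  fun <- if (method == "median") stats::median else mean
  sig <- x$signals
  if (!is.null(mask)) {
    keep <- if (is.logical(mask)) names(mask)[mask] else as.character(mask)
    sig <- sig[intersect(rownames(sig), keep), , drop = FALSE]
  }
  unannotated <- setdiff(rownames(sig), annotation$probeset_id)
  if (length(unannotated))
    stop("retained probeset(s) without annotation: ",
         paste(utils::head(unannotated, 5), collapse = ", "))
  cluster <- annotation$transcript_cluster_id[
    match(rownames(sig), annotation$probeset_id)]
  all_clusters <- unique(annotation$transcript_cluster_id)
  dropped <- setdiff(all_clusters, cluster)
  if (length(dropped))
    message(length(dropped),
            " transcript cluster(s) had no retained probeset and were dropped")
  idx <- split(seq_len(nrow(sig)), cluster)
  out <- t(vapply(idx, function(i)
    apply(sig[i, , drop = FALSE], 2, fun), numeric(ncol(sig))))
  colnames(out) <- colnames(sig)
  out[order(rownames(out)), , drop = FALSE]
}
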