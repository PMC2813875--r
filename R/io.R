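#' Probeset-level signal container
#'
#' Bundles a probesets x samples matrix of log2 signal values with an
#' optional, shape-matched matrix of detection-above-background (DABG)
#' p-values. This is the atomic input of the pipeline: one row per probeset
#' (the exon-level measurement unit of the array), one column per sample.
#'
#' @param signals numeric matrix of log2 signals with unique, non-empty
#'   rownames (probeset ids) and colnames (sample ids). All values must be
#'   finite.
#' @param detection_p optional numeric matrix of per-probeset, per-sample
#'   detection p-values in (0, 1], with the same dimnames as `signals`.
#' @return An object of class `ps_matrix`: a list with elements `signals`
#'   and `detection_p` (possibly `NULL`).
#' @examples
#' m <- matrix(rnorm(6, 8), 3, 2,
#'             dimnames = list(paste0("PS", 1:3), c("s1", "s2")))
#' ps_matrix(m)
#' @export
ps_matrix <- function(signals, detection_p = NULL) {
  if (!is.matrix(signals) || !is.numeric(signals))
    stop("`signals` must be a numeric matrix")
  if (is.null(rownames(signals)) || is.null(colnames(signals)))
    stop("`signals` must have probeset rownames and sample colnames")
  if (anyDuplicated(rownames(signals)))
    stop("duplicate probeset ids in signal matrix")
  if (anyDuplicated(colnames(signals)))
    stop("duplicate sample ids in signal matrix")
  if (!all(is.finite(signals)))
    stop("non-finite signal values")
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !is.numeric(detection_p))
      stop("`detection_p` must be a numeric matrix")
    if (!identical(dim(detection_p), dim(signals)))
      stop("`detection_p` must have the same shape as `signals`")
    if (!identical(dimnames(detection_p), dimnames(signals)))
      stop("`detection_p` dimnames must match `signals`")
    if (any(detection_p <= 0 | detection_p > 1, na.rm = TRUE))
      stop("detection p-values must lie in (0, 1]")
  }
  structure(list(signals = signals, detection_p = detection_p),
            class = "ps_matrix")
}

#' @export
print.ps_matrix <- function(x, ...) {
  cat(sprintf("ps_matrix: %d probesets x %d samples (%s detection p-values)\n",
              nrow(x$signals), ncol(x$signals),
              if (is.null(x$detection_p)) "without" else "with"))
  invisible(x)
}

#' @export
dim.ps_matrix <- function(x) dim(x$signals)

#' Probeset annotation table
#'
#' Maps each probeset to its transcript cluster (the array's gene-level
#' grouping) with an ordinal position along the transcription direction and
#' an evidence class. Ordinals are re-densified to 0, 1, 2, ... within each
#' cluster, preserving their original order; the dsi window statistics rely
#' on this contiguity convention (0-based, 5' to 3').
#'
#' @param df data.frame with columns `probeset_id`, `transcript_cluster_id`,
#'   `ordinal` (numeric, orderable) and `evidence` (`"core"` or `"full"`).
#' @return A data.frame of class `ps_annotation`, sorted by cluster and
#'   ordinal, with ordinals densified per cluster.
#' @export
ps_annotation <- function(df) {
  req <- c("probeset_id", "transcript_cluster_id", "ordinal", "evidence")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("annotation is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[req]
  df$probeset_id <- as.character(df$probeset_id)
  df$transcript_cluster_id <- as.character(df$transcript_cluster_id)
  df$ordinal <- as.numeric(df$ordinal)
  df$evidence <- as.character(df$evidence)
  if (anyDuplicated(df$probeset_id))
    stop("a probeset is assigned to more than one annotation row")
  if (!all(df$evidence %in% c("core", "full")))
    stop("`evidence` must be 'core' or 'full'")
  if (any(!is.finite(df$ordinal)))
    stop("non-finite ordinal")
  # stable sort by cluster then ordinal, then densify ordinals per cluster
  df <- df[order(df$transcript_cluster_id, df$ordinal, df$probeset_id), ]
  dup_ord <- vapply(split(df$ordinal, df$transcript_cluster_id),
                    anyDuplicated, integer(1))
  if (any(dup_ord > 0))
    stop("duplicate ordinals within transcript cluster(s): ",
         paste(names(dup_ord)[dup_ord > 0], collapse = ", "))
  df$ordinal <- unsplit(lapply(split(df$ordinal, df$transcript_cluster_id),
                               function(o) seq_along(o) - 1L),
                        df$transcript_cluster_id)
  rownames(df) <- NULL
  class(df) <- c("ps_annotation", "data.frame")
  df
}

#' Sample-to-group assignment
#'
#' @param df data.frame with columns `sample_id` and `group`, one row per
#'   sample.
#' @return data.frame of class `sample_groups`.
#' @export
sample_groups <- function(df) {
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("groups table needs columns `sample_id` and `group`")
  df <- df[c("sample_id", "group")]
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  if (anyDuplicated(df$sample_id))
    stop("a sample is assigned to more than one group")
  rownames(df) <- NULL
  class(df) <- c("sample_groups", "data.frame")
  df
}

#' Samples belonging to one group
#' @param groups a `sample_groups` table
#' @param group group label
#' @return character vector of sample ids, in table order
#' @export
group_samples <- function(groups, group) {
  s <- groups$sample_id[groups$group == group]
  if (!length(s)) stop("no samples in group '", group, "'")
  s
}

# Check that every matrix sample has exactly one group assignment.
check_groups <- function(mat, groups) {
  missing <- setdiff(colnames(mat$signals), groups$sample_id)
  if (length(missing))
    stop("samples without group assignment: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

# full-precision numeric formatting so write/read round-trips bit-exactly
fmt_num <- function(x) formatC(x, digits = 17, format = "g")

write_matrix_tsv <- function(m, path) {
  body <- matrix(fmt_num(m), nrow = nrow(m))
  out <- cbind(rownames(m), body)
  lines <- c(paste(c("probeset_id", colnames(m)), collapse = "\t"),
             apply(out, 1, paste, collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

read_matrix_tsv <- function(path, what) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "probeset_id")
    stop("first column of ", what, " must be 'probeset_id'")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate probeset id(s) in ", what, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- names(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id(s) in ", what)
  m <- matrix(NA_real_, length(ids), length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1]]) & df[[j + 1]] != "NA")
    if (length(bad))
      stop(sprintf("non-numeric value in %s at row %d, column '%s': '%s'",
                   what, bad[1], samples[j], df[[j + 1]][bad[1]]))
    m[, j] <- v
  }
  m
}

#' Read / write a probeset signal matrix
#'
#' Tab-delimited text: header row of sample ids, first column `probeset_id`,
#' "." decimal, no quoting. Finite values round-trip bit-exactly.
#'
#' @param path file path
#' @param detection_path optional path of a same-shaped detection p-value
#'   matrix to attach.
#' @return `read_signal_matrix`: a [ps_matrix]. `write_signal_matrix`:
#'   the path, invisibly.
#' @export
read_signal_matrix <- function(path, detection_path = NULL) {
  sig <- read_matrix_tsv(path, "signal matrix")
  dp <- NULL
  if (!is.null(detection_path)) {
    dp <- read_matrix_tsv(detection_path, "detection p-value matrix")
    dp <- dp[rownames(sig), colnames(sig), drop = FALSE]
  }
  ps_matrix(sig, dp)
}

#' @rdname read_signal_matrix
#' @param x a [ps_matrix]
#' @export
write_signal_matrix <- function(x, path, detection_path = NULL) {
  stopifnot(inherits(x, "ps_matrix"))
  write_matrix_tsv(x$signals, path)
  if (!is.null(detection_path)) {
    if (is.null(x$detection_p))
      stop("no detection p-values to write")
    write_matrix_tsv(x$detection_p, detection_path)
  }
  invisible(path)
}

#' Read / write the probeset annotation CSV
#'
#' RFC 4180 CSV with columns `probeset_id`, `transcript_cluster_id`,
#' `ordinal`, `evidence`.
#'
#' @param path file path
#' @return `read_annotation`: a [ps_annotation]. `write_annotation`: the
#'   path, invisibly.
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path, header = TRUE, colClasses = "character")
  ps_annotation(df)
}

#' @rdname read_annotation
#' @param anno a [ps_annotation]
#' @export
write_annotation <- function(anno, path) {
  utils::write.csv(as.data.frame(anno), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write the sample group table (two-column TSV)
#'
#' @param path file path
#' @return `read_groups`: a [sample_groups]. `write_groups`: the path,
#'   invisibly.
#' @export
read_groups <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character")
  sample_groups(df)
}

#' @rdname read_groups
#' @param groups a [sample_groups]
#' @export
write_groups <- function(groups, path) {
  utils::write.table(as.data.frame(groups), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# generic TSV writer used for result tables
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
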