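# Fisher exact over-representation of a gene list against an expressed
# background, across functional categories (e.g. GO biological process).

#' Read a category map from a two-column TSV
#'
#' @param path TSV with header columns `category_id`, `gene_id`.
#' @param names_path optional TSV with columns `category_id`, `name`.
#' @return named list of character vectors (gene sets); category names, if
#'   supplied, attached as attribute `category_names`.
#' @export
read_category_map <- function(path, names_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character")
  if (!all(c("category_id", "gene_id") %in% names(df)))
    stop("category map needs columns `category_id` and `gene_id`")
  cm <- lapply(split(df$gene_id, df$category_id), unique)
  if (!is.null(names_path)) {
    nm <- utils::read.delim(names_path, header = TRUE, sep = "\t",
                            quote = "", colClasses = "character")
    attr(cm, "category_names") <-
      stats::setNames(nm$name, nm$category_id)
  }
  cm
}

#' Read a category map in GMT format
#'
#' One tab-separated line per category: id, description, then gene ids.
#'
#' @param path GMT file path
#' @return named list of character gene-set vectors with attribute
#'   `category_names` (the description field).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("GMT line ", bad[1], " has fewer than 3 fields")
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids)) stop("duplicate category ids in GMT")
  cm <- stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids)
  attr(cm, "category_names") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2), ids)
  cm
}

#' Fisher exact over-representation test per category
#'
#' For each category, builds the 2x2 table of background genes
#' (query / non-query) x (in category / out of category) and computes the
#' two-sided Fisher exact p-value, the sample odds ratio, and
#' Benjamini-Hochberg adjusted p-values across categories. Categories are
#' intersected with the background first, so the test compares the query
#' against the rest of the analyzed (expressed) gene set.
#'
#' @param query character vector of gene ids; must be a subset of
#'   `background`.
#' @param background character vector of gene ids (the expressed universe).
#' @param categories named list of character gene-set vectors, e.g. from
#'   [read_category_map] or [read_gmt].
#' @param alpha raw-p significance flag threshold (default 0.01).
#' @return data.frame with one row per category: counts
#'   `query_in`, `query_out`, `bg_in`, `bg_out` (bg = background minus
#'   query), `odds_ratio`, `p`, `p_adj` (BH), `significant` (raw
#'   `p <= alpha`), ordered by `p`.
#' @export
fisher_enrichment <- function(query, background, categories, alpha = 0.01) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  extra <- setdiff(query, background)
  if (length(extra))
    stop("query gene(s) not in background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  rest <- setdiff(background, query)
  nq <- length(query); nr <- length(rest)
  rows <- lapply(names(categories), function(id) {
    cat_genes <- intersect(categories[[id]], background)
    a <- length(intersect(query, cat_genes))   # query, in category
    b <- nq - a                                # query, out
    c_ <- length(cat_genes) - a                # rest, in category
    d <- nr - c_                               # rest, out
    tab <- matrix(c(a, c_, b, d), 2)
    p <- stats::fisher.test(tab)$p.value
    or <- if (b * c_ == 0) {
      if (a * d == 0) NaN else Inf
    } else (a * d) / (b * c_)
    data.frame(category = id, query_in = a, query_out = b,
               bg_in = c_, bg_out = d, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(category = character(), query_in = integer(),
                      query_out = integer(), bg_in = integer(),
                      bg_out = integer(), odds_ratio = numeric(),
                      p = numeric(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p <= alpha
  nm <- attr(categories, "category_names")
  if (!is.null(nm)) out$name <- unname(nm[out$category])
  out <- out[order(out$p, out$category), ]
  rownames(out) <- NULL
  out
}
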