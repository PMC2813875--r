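# End-to-end orchestration: simulate/load -> normalize -> DABG filter ->
# gene-level SAM + Venn -> dsi scan -> DE overlap -> enrichment -> report.

#' PCA quality-control of a gene-level matrix
#'
#' Principal component analysis of the samples (genes as variables,
#' centered), with a simple separation summary: mean within-group pairwise
#' distance vs mean between-group centroid distance in the first two
#' components.
#'
#' @param m numeric genes x samples matrix.
#' @param groups a [sample_groups] covering the columns of `m`.
#' @param n_comp number of components to return (default 2).
#' @return list of class `pca_qc`: `coords` (samples x components, centered),
#'   `variance_explained`, `within_group_dist`, `between_group_dist`,
#'   `separation_ratio` (between / within; NA with a single group).
#' @export
pca_qc <- function(m, groups, n_comp = 2) {
  if (ncol(m) < 3) stop("PCA QC needs at least 3 samples")
  lab <- groups$group[match(colnames(m), groups$sample_id)]
  if (anyNA(lab)) stop("sample(s) without group assignment")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  n_comp <- min(n_comp, ncol(pc$x))
  coords <- pc$x[, seq_len(n_comp), drop = FALSE]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  within <- NA_real_; between <- NA_real_
  gl <- unique(lab)
  wd <- unlist(lapply(gl, function(g) {
    xs <- coords[lab == g, , drop = FALSE]
    if (nrow(xs) < 2) return(numeric())
    as.numeric(stats::dist(xs))
  }))
  if (length(wd)) within <- mean(wd)
  if (length(gl) >= 2) {
    cent <- t(vapply(gl, function(g)
      colMeans(coords[lab == g, , drop = FALSE]), numeric(n_comp)))
    between <- mean(stats::dist(cent))
  }
  structure(list(coords = coords,
                 variance_explained = ve[seq_len(n_comp)],
                 within_group_dist = within,
                 between_group_dist = between,
                 separation_ratio = between / within,
                 groups = lab),
            class = "pca_qc")
}

#' @export
print.pca_qc <- function(x, ...) {
  cat(sprintf(paste0("PCA QC: %d samples, %d groups; PC1 %.1f%%, PC2 %.1f%% ",
                     "variance\n  within-group dist %.3g, between-centroid ",
                     "dist %.3g (ratio %.3g)\n"),
              nrow(x$coords), length(unique(x$groups)),
              100 * x$variance_explained[1],
              if (length(x$variance_explained) > 1)
                100 * x$variance_explained[2] else 0,
              x$within_group_dist, x$between_group_dist,
              x$separation_ratio))
  invisible(x)
}

#' Default pipeline configuration
#'
#' Declarative settings covering every stage. `inputs` may name file paths
#' (`signals`, `detection_p`, `annotation`, `groups`), otherwise the
#' synthetic generator runs with `simulation` (a [sim_config] or argument
#' list).
#'
#' @param ... overrides of the default keys (`inputs`, `simulation`,
#'   `normalization`, `filter`, `de`, `plan`, `dsi`, `enrichment`, `seed`).
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    inputs = NULL,
    simulation = list(),
    normalization = list(percentile = 75, target = "median-of-samples"),
    filter = list(alpha = 0.05, min_detected = 3),
    de = list(n_perm = 100, fold = 2.0, fdr = 0.05,
              hematopoietic = NULL, exclude = "spleen",
              summarize = "median"),
    plan = list(exclude = "spleen"),
    dsi = list(k = 100),
    enrichment = list(alpha = 0.01, categories = NULL),
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Coerce a config object, list or YAML path into a [pipeline_config]
#' @param config a `pipeline_config`, a plain list of its keys, or a YAML
#'   file path.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("malformed config")
  do.call(pipeline_config, config)
}

# deterministic sub-seeds so stages stay reproducible independently
derive_seed <- function(seed, offset) (as.integer(seed) + offset) %% 2147483647L

# synthetic category map on the simulated gene namespace: random categories
# plus one concentrated in the planted AS genes, so the enrichment stage is
# exercised end-to-end with a known positive
synthetic_categories <- function(gene_ids, truth, seed, n_categories = 20,
                                 size = 25) {
  set.seed(seed)
  cm <- lapply(seq_len(n_categories), function(i)
    sample(gene_ids, min(size, length(gene_ids))))
  names(cm) <- sprintf("SYNCAT%02d", seq_len(n_categories))
  planted <- truth$as_events$gene_id
  if (length(planted) >= 3) {
    extra <- sample(setdiff(gene_ids, planted),
                    min(5, length(gene_ids) - length(planted)))
    cm$SYNCAT_AS <- unique(c(planted, extra))
  }
  cm
}

#' Run the whole analysis pipeline
#'
#' Stages: load or simulate probeset-level data; percentile normalization;
#' DABG filtering; gene-level summarization; SAM differential expression of
#' each hematopoietic group against the pooled solid tissues plus Venn
#' signature decomposition; dsiT scoring and top-K selection over the
#' comparison plan; aggregation to the candidate AS transcript list and
#' overlap with the DE calls; Fisher enrichment of the AS list; PCA QC.
#' Every result table is written to `outdir` as TSV and the run is
#' deterministic given the config seed.
#'
#' @param config a [pipeline_config], a list of its keys, or the path of a
#'   YAML file holding them.
#' @param outdir output directory (created; overwritten files).
#' @return invisible list with the in-memory results (`sim`, `mask`,
#'   `gene_matrix`, `sam`, `venn`, `dsi`, `as_list`, `overlap`,
#'   `enrichment`, `qc`, `paths`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  cfg <- load_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "log.txt")
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  say("pipeline start, seed %d", cfg$seed)

  # ---- inputs ----
  truth <- NULL
  if (!is.null(cfg$inputs)) {
    req <- c("signals", "annotation", "groups")
    miss <- setdiff(req, names(cfg$inputs))
    if (length(miss))
      stop("config `inputs` missing: ", paste(miss, collapse = ", "))
    for (p in unlist(cfg$inputs))
      if (!file.exists(p)) stop("input file not found: ", p)
    mat <- read_signal_matrix(cfg$inputs$signals, cfg$inputs$detection_p)
    anno <- read_annotation(cfg$inputs$annotation)
    groups <- read_groups(cfg$inputs$groups)
    say("loaded %d probesets x %d samples", nrow(mat$signals),
        ncol(mat$signals))
  } else {
    sim_args <- cfg$simulation
    if (inherits(sim_args, "sim_config")) sc <- sim_args
    else {
      if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
      sc <- do.call(sim_config, sim_args)
    }
    sim <- simulate_dataset(sc)
    mat <- sim$matrix; anno <- sim$annotation; groups <- sim$groups
    truth <- sim$truth
    write_truth_tables(truth, outdir)
    say("simulated %d probesets x %d samples (%d DE, %d AS planted)",
        nrow(mat$signals), ncol(mat$signals), nrow(truth$de_genes),
        nrow(truth$as_events))
  }
  check_groups(mat, groups)

  # ---- normalize + filter + summarize ----
  mat <- scale_percentile(mat, q = cfg$normalization$percentile,
                          target = cfg$normalization$target)
  mask <- dabg_filter(mat, alpha = cfg$filter$alpha,
                      min_detected = cfg$filter$min_detected)
  say("DABG filter: %d / %d probesets retained", sum(mask), length(mask))
  gene_m <- suppressMessages(
    summarize_gene_level(mat, anno, method = cfg$de$summarize, mask = mask))
  say("gene-level matrix: %d transcripts", nrow(gene_m))

  # ---- QC ----
  qc <- pca_qc(gene_m, groups)
  qc_df <- data.frame(sample_id = rownames(qc$coords),
                      group = qc$groups, qc$coords,
                      stringsAsFactors = FALSE)
  write_tsv(qc_df, file.path(outdir, "qc_pca.tsv"))
  writeLines(c(utils::capture.output(print(qc)),
               sprintf("retained probesets: %d / %d", sum(mask),
                       length(mask))),
             file.path(outdir, "qc.txt"))

  # ---- gene-level DE: each hematopoietic group vs pooled solids ----
  labs <- unique(groups$group)
  hema <- cfg$de$hematopoietic
  if (is.null(hema)) hema <- labs[seq_len(min(2, length(labs)))]
  solid <- setdiff(labs, c(hema, cfg$de$exclude))
  sams <- list(); de_rows <- list()
  if (length(solid)) {
    pooled <- ifelse(groups$group %in% solid, "solid", groups$group)
    pooled_groups <- sample_groups(data.frame(sample_id = groups$sample_id,
                                              group = pooled,
                                              stringsAsFactors = FALSE))
    for (i in seq_along(hema)) {
      g <- hema[i]
      sams[[g]] <- sam_test(gene_m, pooled_groups, g, "solid",
                            n_perm = cfg$de$n_perm, fold = cfg$de$fold,
                            fdr = cfg$de$fdr,
                            seed = derive_seed(cfg$seed, i))
      say("SAM %s vs solid: %d up, %d down (s0 %.3g)", g,
          sum(sams[[g]]$call == "up"), sum(sams[[g]]$call == "down"),
          attr(sams[[g]], "s0"))
      de_rows[[g]] <- cbind(comparison = paste0(g, "_vs_solid"),
                            as.data.frame(sams[[g]]))
    }
  }
  write_tsv(do.call(rbind, de_rows), file.path(outdir, "de.tsv"))

  venn <- NULL
  if (length(sams) >= 2) {
    venn <- venn_signatures(sam_calls(sams[[1]])$up,
                            sam_calls(sams[[2]])$up,
                            labels = names(sams)[1:2])
    venn_df <- data.frame(
      set = c("common", paste0(names(sams)[1], "_specific"),
              paste0(names(sams)[2], "_specific")),
      n = c(length(venn$common), length(venn$a_specific),
            length(venn$b_specific)),
      genes = c(paste(venn$common, collapse = ","),
                paste(venn$a_specific, collapse = ","),
                paste(venn$b_specific, collapse = ",")),
      stringsAsFactors = FALSE)
    write_tsv(venn_df, file.path(outdir, "venn.tsv"))
    say("venn: %d common, %d + %d specific", length(venn$common),
        length(venn$a_specific), length(venn$b_specific))
  }

  # ---- dsi scan over the comparison plan ----
  plan <- default_comparison_plan(groups, hematopoietic = hema,
                                  exclude = cfg$plan$exclude)
  dsi <- dsi_scan(mat, anno, groups, plan, k = cfg$dsi$k, mask = mask)
  write_tsv(as.data.frame(dsi), file.path(outdir, "dsi.tsv"))
  as_list <- aggregate_as_list(dsi, anno)
  write_tsv(as_list, file.path(outdir, "as_transcripts.tsv"))
  say("dsi: %d comparisons, %d selections, %d AS transcripts",
      nrow(plan), sum(dsi$selected), nrow(as_list))

  overlap <- NULL
  if (length(sams) >= 2) {
    overlap <- overlap_with_de(as_list, sams[[1]], sams[[2]])
    write_tsv(data.frame(metric = c("up_union", "down_union",
                                    "as_in_up", "as_in_down"),
                         n = c(overlap$n_up_union, overlap$n_down_union,
                               overlap$n_as_in_up, overlap$n_as_in_down)),
              file.path(outdir, "as_de_overlap.tsv"))
  }

  # ---- enrichment of the AS list against the expressed background ----
  background <- rownames(gene_m)
  if (!is.null(cfg$enrichment$categories)) {
    cm <- if (is.list(cfg$enrichment$categories)) cfg$enrichment$categories
          else read_category_map(cfg$enrichment$categories)
  } else if (!is.null(truth)) {
    cm <- synthetic_categories(background, truth,
                               derive_seed(cfg$seed, 99))
  } else cm <- NULL
  enr <- NULL
  if (!is.null(cm)) {
    enr <- fisher_enrichment(intersect(as_list$transcript_cluster_id,
                                       background),
                             background, cm, alpha = cfg$enrichment$alpha)
    write_tsv(enr, file.path(outdir, "enrichment.tsv"))
    say("enrichment: %d categories, %d significant at p <= %g",
        nrow(enr), sum(enr$significant), cfg$enrichment$alpha)
  }

  say("pipeline done")
  writeLines(log_lines, log_path)
  invisible(list(matrix = mat, annotation = anno, groups = groups,
                 truth = truth, mask = mask, gene_matrix = gene_m,
                 sam = sams, venn = venn, dsi = dsi, as_list = as_list,
                 overlap = overlap, enrichment = enr, qc = qc,
                 paths = list(outdir = outdir, log = log_path)))
}
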