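#' Simulation configuration for synthetic exon-array data
#'
#' Defines a multi-group probeset-level dataset with known (planted)
#' differential-expression and alternative-splicing structure. The default
#' design mirrors a hematopoietic-vs-solid-tissue study: 13 groups — whole
#' blood (4 samples), CD34+ stem/progenitor cells (3 samples) and 11 solid
#' tissues (3 samples each, one of them a mixed-composition "spleen" group
#' that the default comparison plan excludes).
#'
#' @param n_groups number of sample groups.
#' @param samples_per_group integer scalar or length-`n_groups` vector of
#'   samples per group. The default gives blood 4 samples and every other
#'   group 3.
#' @param group_names optional group labels; defaults to the hematopoietic
#'   design when `n_groups = 13`, otherwise `group01`, `group02`, ...
#' @param n_genes number of transcript clusters to simulate.
#' @param probesets_per_gene integer range (length-2) of probesets per gene;
#'   minimum must be >= 4 because the splicing-index window spans four
#'   contiguous probesets.
#' @param baseline_log2 grand mean expressed signal, log2 scale.
#' @param noise_sd additive Gaussian noise sd on the log2 scale
#'   (log-normal on the raw scale).
#' @param de_fraction fraction of genes carrying a whole-gene expression
#'   difference in one affected group.
#' @param de_effect_log2 magnitude of the planted expression difference
#'   (log2 units; direction is randomized per gene).
#' @param as_fraction fraction of genes carrying one localized splicing
#'   event.
#' @param as_effect_log2 magnitude of the planted splicing event (log2).
#' @param background_fraction fraction of probesets pinned at the noise
#'   floor (unexpressed exons / intronic probesets).
#' @param noise_floor_log2 log2 signal level of background; defaults to
#'   `baseline_log2 - 5`.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 13,
                       samples_per_group = NULL,
                       group_names = NULL,
                       n_genes = 300,
                       probesets_per_gene = c(4L, 12L),
                       baseline_log2 = 8,
                       noise_sd = 0.3,
                       de_fraction = 0.1,
                       de_effect_log2 = 2,
                       as_fraction = 0.1,
                       as_effect_log2 = 2,
                       background_fraction = 0.1,
                       noise_floor_log2 = baseline_log2 - 5,
                       seed = 1L) {
  if (is.null(group_names)) {
    group_names <- if (n_groups == 13) {
      c("blood", "cd34", "breast", "cerebellum", "heart", "kidney", "liver",
        "muscle", "pancreas", "prostate", "spleen", "testis", "thyroid")
    } else sprintf("group%02d", seq_len(n_groups))
  }
  if (length(group_names) != n_groups)
    stop("`group_names` must have length `n_groups`")
  if (is.null(samples_per_group))
    samples_per_group <- ifelse(group_names == "blood", 4L, 3L)
  samples_per_group <- as.integer(rep_len(samples_per_group, n_groups))
  if (any(samples_per_group < 2))
    stop("each group needs at least 2 samples")
  probesets_per_gene <- as.integer(probesets_per_gene)
  if (length(probesets_per_gene) == 1)
    probesets_per_gene <- rep(probesets_per_gene, 2)
  if (probesets_per_gene[1] < 4)
    stop("`probesets_per_gene` minimum must be >= 4: the dsi window needs ",
         "four contiguous probesets")
  if (probesets_per_gene[2] < probesets_per_gene[1])
    stop("`probesets_per_gene` range is reversed")
  for (f in c(de_fraction, as_fraction, background_fraction))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  if (n_genes < 1) stop("`n_genes` must be positive")
  structure(list(
    n_groups = as.integer(n_groups),
    samples_per_group = samples_per_group,
    group_names = group_names,
    n_genes = as.integer(n_genes),
    probesets_per_gene = probesets_per_gene,
    baseline_log2 = baseline_log2,
    noise_sd = noise_sd,
    de_fraction = de_fraction,
    de_effect_log2 = de_effect_log2,
    as_fraction = as_fraction,
    as_effect_log2 = as_effect_log2,
    background_fraction = background_fraction,
    noise_floor_log2 = noise_floor_log2,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: %d groups (%d samples), %d genes, %d-%d probesets/gene\n",
    "  baseline %.1f log2, noise sd %.2f, floor %.1f\n",
    "  DE: %.0f%% of genes at %.1f log2; AS: %.0f%% at %.1f log2; ",
    "background %.0f%% of probesets; seed %d\n"),
    x$n_groups, sum(x$samples_per_group), x$n_genes,
    x$probesets_per_gene[1], x$probesets_per_gene[2],
    x$baseline_log2, x$noise_sd, x$noise_floor_log2,
    100 * x$de_fraction, x$de_effect_log2,
    100 * x$as_fraction, x$as_effect_log2,
    100 * x$background_fraction, x$seed))
  invisible(x)
}

as_event_types <- c("cassette", "intron_retention", "alt_first", "alt_last",
                    "exon_extension")

#' Plant an alternative-splicing event into a per-group mean profile
#'
#' Modifies the probeset-mean profile of the affected group only, over a
#' contiguous span of probesets determined by the event type:
#' cassette exon and intron retention shift an internal span; alternative
#' first/last exon shift everything on one side of a breakpoint; exon
#' extension shifts a single probeset adjacent to the event boundary.
#' Probesets outside the span are untouched, so the between-group
#' difference profile is exactly `magnitude` inside the span and 0 outside.
#'
#' @param profile numeric matrix of per-group probeset means
#'   (probesets x groups).
#' @param type one of `"cassette"`, `"intron_retention"`, `"alt_first"`,
#'   `"alt_last"`, `"exon_extension"`.
#' @param span integer vector `c(first, last)` of affected probeset
#'   positions (1-based, inclusive).
#' @param magnitude log2 shift applied inside the span; 0 leaves the
#'   profile unchanged.
#' @param group affected group (column name or index).
#' @return the modified profile matrix.
#' @export
plant_as_event <- function(profile, type, span, magnitude, group) {
  type <- match.arg(type, as_event_types)
  span <- as.integer(span)
  if (length(span) == 1) span <- c(span, span)
  if (span[1] < 1 || span[2] > nrow(profile) || span[1] > span[2])
    stop("event span [", span[1], ", ", span[2],
         "] lies outside the gene's ", nrow(profile), " probesets")
  if (magnitude == 0) return(profile)
  if (type == "alt_first" && span[1] != 1)
    stop("alt_first span must start at the first probeset")
  if (type == "alt_last" && span[2] != nrow(profile))
    stop("alt_last span must end at the last probeset")
  if (type == "exon_extension" && span[1] != span[2])
    stop("exon_extension affects a single probeset")
  profile[span[1]:span[2], group] <- profile[span[1]:span[2], group] +
    magnitude
  profile
}

# Draw the span for one event type within a gene of `len` probesets.
# Spans leave at least one unaffected probeset on the exterior side where
# the type requires one (cassette/intron retention are internal).
draw_event_span <- function(type, len) {
  switch(type,
    cassette = ,
    intron_retention = {
      w <- sample.int(max(1L, len - 2L), 1L)          # internal span width
      a <- sample.int(len - w - 1L, 1L) + 1L          # start in 2..len-w
      c(a, a + w - 1L)
    },
    alt_first = c(1L, sample.int(len - 1L, 1L)),
    alt_last = c(sample.int(len - 1L, 1L) + 1L, len),
    exon_extension = {
      a <- sample.int(len, 1L)
      c(a, a)
    })
}

#' Analytic DABG p-values from signal above a noise floor
#'
#' Maps each log2 signal to a one-sided Gaussian upper-tail p-value of its
#' excess over the noise floor: `p = 1 - pnorm((signal - floor) / sd)`.
#' A signal at the floor receives p = 0.5; strongly expressed probesets
#' (>= 2 log2 above the floor) fall below 0.05 with high probability.
#'
#' @param signals numeric matrix of log2 signals (or a [ps_matrix]).
#' @param noise_floor background level on the log2 scale of `signals`.
#' @param sd width of the background tail in log2 units.
#' @return matrix of p-values in (0, 1], same shape as `signals`.
#' @export
simulate_dabg <- function(signals, noise_floor, sd = 1.0) {
  if (inherits(signals, "ps_matrix")) signals <- signals$signals
  p <- stats::pnorm(signals - noise_floor, sd = sd, lower.tail = FALSE)
  pmax(p, .Machine$double.xmin)
}

#' Simulate a probeset-level exon-array dataset with known truth
#'
#' Generates per-gene contiguous probeset series over a multi-group design,
#' plants whole-gene expression differences in a deterministic fraction of
#' genes and one localized splicing event in another (disjoint) fraction,
#' pins a fraction of probesets at the noise floor, adds Gaussian noise on
#' the log2 scale and derives DABG detection p-values analytically from the
#' noisy signals. Gene sets receiving DE and AS effects are the first
#' `round(fraction * n_genes)` entries of a seeded shuffle, so planted
#' counts are exact and the truth table is exactly recoverable.
#'
#' Splicing events are planted in one of the hematopoietic-like groups (the
#' first two groups of the design) against all others, emulating
#' lineage-specific splicing; expression differences affect one group drawn
#' from the whole design.
#'
#' @param config a [sim_config].
#' @return list of class `exon_sim` with elements `matrix` ([ps_matrix]
#'   with detection p-values), `annotation` ([ps_annotation]), `groups`
#'   ([sample_groups]) and `truth` (class `sim_truth`: data.frames
#'   `de_genes` and `as_events`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes

  gene_ids <- sprintf("TC%05d", seq_len(ng))
  n_ps_per_gene <- if (config$probesets_per_gene[1] ==
                       config$probesets_per_gene[2]) {
    rep(config$probesets_per_gene[1], ng)
  } else {
    sample(seq(config$probesets_per_gene[1], config$probesets_per_gene[2]),
           ng, replace = TRUE)
  }
  total_ps <- sum(n_ps_per_gene)
  ps_ids <- sprintf("PS%07d", seq_len(total_ps))
  gene_of_ps <- rep(gene_ids, n_ps_per_gene)

  groups_vec <- rep(config$group_names, config$samples_per_group)
  sample_ids <- unlist(lapply(seq_along(config$group_names), function(i)
    sprintf("%s_%02d", config$group_names[i],
            seq_len(config$samples_per_group[i]))))
  n_samples <- length(sample_ids)

  # deterministic planted-gene assignment: shuffle once, slice
  n_de <- round(config$de_fraction * ng)
  n_as <- round(config$as_fraction * ng)
  if (n_de + n_as > ng)
    stop("de_fraction + as_fraction exceed the gene count")
  shuffled <- sample(gene_ids)
  de_ids <- sort(shuffled[seq_len(n_de)])
  as_ids <- sort(shuffled[n_de + seq_len(n_as)])

  # per-gene baseline and per-probeset affinity (log2 scale)
  gene_base <- stats::rnorm(ng, config$baseline_log2, 1.0)
  names(gene_base) <- gene_ids
  ps_affinity <- stats::rnorm(total_ps, 0, 0.5)

  # background probesets: deterministic count, seeded positions
  n_bg <- round(config$background_fraction * total_ps)
  bg_idx <- sort(sample.int(total_ps, n_bg))
  is_bg <- rep(FALSE, total_ps)
  is_bg[bg_idx] <- TRUE

  # per-group mean profiles, probesets x groups
  mu <- matrix(gene_base[gene_of_ps] + ps_affinity,
               nrow = total_ps, ncol = config$n_groups,
               dimnames = list(ps_ids, config$group_names))
  mu[is_bg, ] <- config$noise_floor_log2

  # plant whole-gene DE: one affected group, random direction
  de_truth <- NULL
  if (n_de > 0) {
    de_group <- sample(config$group_names, n_de, replace = TRUE)
    de_dir <- sample(c(1, -1), n_de, replace = TRUE)
    for (i in seq_len(n_de)) {
      rows <- which(gene_of_ps == de_ids[i] & !is_bg)
      mu[rows, de_group[i]] <- mu[rows, de_group[i]] +
        de_dir[i] * config$de_effect_log2
    }
    de_truth <- data.frame(
      gene_id = de_ids,
      direction = ifelse(de_dir > 0, "up", "down"),
      affected_group = de_group,
      effect_log2 = de_dir * config$de_effect_log2,
      stringsAsFactors = FALSE)
  } else {
    de_truth <- data.frame(gene_id = character(), direction = character(),
                           affected_group = character(),
                           effect_log2 = numeric(),
                           stringsAsFactors = FALSE)
  }

  # plant AS events in a hematopoietic-like group (first two groups)
  hema <- config$group_names[seq_len(min(2L, config$n_groups))]
  if (n_as > 0) {
    as_type <- sample(as_event_types, n_as, replace = TRUE)
    as_group <- sample(hema, n_as, replace = TRUE)
    as_dir <- sample(c(1, -1), n_as, replace = TRUE)
    span_lo <- integer(n_as); span_hi <- integer(n_as)
    for (i in seq_len(n_as)) {
      rows <- which(gene_of_ps == as_ids[i])
      len <- length(rows)
      span <- draw_event_span(as_type[i], len)
      span_lo[i] <- span[1]; span_hi[i] <- span[2]
      mu[rows, , drop = FALSE] -> prof
      prof <- plant_as_event(prof, as_type[i], span,
                             as_dir[i] * config$as_effect_log2, as_group[i])
      mu[rows, ] <- prof
    }
    as_truth <- data.frame(
      gene_id = as_ids,
      event_type = as_type,
      span_first = span_lo,
      span_last = span_hi,
      affected_group = as_group,
      other_group = "all_others",
      magnitude_log2 = as_dir * config$as_effect_log2,
      stringsAsFactors = FALSE)
  } else {
    as_truth <- data.frame(gene_id = character(), event_type = character(),
                           span_first = integer(), span_last = integer(),
                           affected_group = character(),
                           other_group = character(),
                           magnitude_log2 = numeric(),
                           stringsAsFactors = FALSE)
  }

  # expand group means to samples, add log2 noise
  signals <- mu[, groups_vec, drop = FALSE] +
    matrix(stats::rnorm(total_ps * n_samples, 0, config$noise_sd),
           total_ps, n_samples)
  colnames(signals) <- sample_ids

  detection_p <- simulate_dabg(signals, config$noise_floor_log2)

  anno <- ps_annotation(data.frame(
    probeset_id = ps_ids,
    transcript_cluster_id = gene_of_ps,
    ordinal = unlist(lapply(n_ps_per_gene, seq_len)) - 1L,
    evidence = ifelse(is_bg, "full", "core"),
    stringsAsFactors = FALSE))

  grp <- sample_groups(data.frame(sample_id = sample_ids,
                                  group = groups_vec,
                                  stringsAsFactors = FALSE))

  truth <- structure(list(de_genes = de_truth, as_events = as_truth),
                     class = "sim_truth")

  structure(list(matrix = ps_matrix(signals, detection_p),
                 annotation = anno, groups = grp, truth = truth,
                 config = config),
            class = "exon_sim")
}

#' @export
print.exon_sim <- function(x, ...) {
  cat(sprintf(paste0("exon_sim: %d probesets x %d samples, %d genes\n",
                     "  planted: %d DE genes, %d AS events\n"),
              nrow(x$matrix$signals), ncol(x$matrix$signals),
              length(unique(x$annotation$transcript_cluster_id)),
              nrow(x$truth$de_genes), nrow(x$truth$as_events)))
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d DE genes, %d AS events\n",
              nrow(x$de_genes), nrow(x$as_events)))
  invisible(x)
}

#' Write the generator's ground-truth tables as TSV
#'
#' @param truth a `sim_truth` (element `truth` of [simulate_dataset] output)
#' @param dir output directory (created if needed)
#' @return the two file paths, invisibly.
#' @export
write_truth_tables <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "truth_de_genes.tsv")
  p2 <- file.path(dir, "truth_as_events.tsv")
  write_tsv(truth$de_genes, p1)
  write_tsv(truth$as_events, p2)
  invisible(c(p1, p2))
}
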