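#' Independent characteristics counted per condition
#'
#' Under the genomic fabric view each gene contributes one expression
#' level, one variability value (REV), and one correlation with every other
#' gene, so `n` genes yield `n + n + n(n-1)/2` independent characteristics
#' per condition.  The per-gene factor `(n + 3)/2` is how many times more
#' data this is than a level-only analysis.
#'
#' @param n_genes Number of quantified genes (>= 2).
#' @return One-row tibble: `n_genes`, `n_levels`, `n_rev`, `n_pairs`,
#'   `total`, `per_gene_factor`.
#' @export
#' @examples
#' gfp_value_count(17657)$total   # 155,911,310
gfp_value_count <- function(n_genes) {
  if (!is.finite(n_genes) || n_genes < 2)
    stop("`n_genes` must be >= 2", call. = FALSE)
  n <- as.double(n_genes)
  pairs <- n * (n - 1) / 2
  tibble::tibble(
    n_genes = n, n_levels = n, n_rev = n, n_pairs = pairs,
    total = 2 * n + pairs,
    per_gene_factor = (2 * n + pairs) / n
  )
}

#' Signed percent change and absolute difference
#'
#' `100 * (mean_new - mean_ref) / mean_ref` together with the raw
#' difference, e.g. for cell-density comparisons between conditions.
#'
#' @param mean_ref Reference mean (> 0).
#' @param mean_new Comparison mean.
#' @return One-row tibble: `mean_ref`, `mean_new`, `difference`,
#'   `percent_change`.
#' @export
#' @examples
#' percent_change(1780, 768)   # about a 57% reduction
percent_change <- function(mean_ref, mean_new) {
  if (!is.finite(mean_ref) || mean_ref <= 0)
    stop("`mean_ref` must be positive", call. = FALSE)
  tibble::tibble(
    mean_ref = mean_ref, mean_new = mean_new,
    difference = mean_new - mean_ref,
    percent_change = 100 * (mean_new - mean_ref) / mean_ref
  )
}

#' Run the full genomic fabric pipeline on spot-level data
#'
#' Orchestrates every stage: spot validity filtering, iterative median
#' normalization, redundancy-group aggregation, REV/GES, adaptive-cut-off
#' regulation calls, per-condition coordination matrices, optional pathway
#' fabric summaries and enrichment.  Deterministic given the seed.  When
#' `output_dir` is given, every table is written as TSV together with a
#' JSON manifest (config hash, stage row counts, exclusions, timings).
#'
#' @param spots Spot tibble covering both conditions (e.g. from
#'   [simulate_two_color()] or [read_spot_table()]).
#' @param genesets Optional named list of gene sets (see [read_gmt()]) for
#'   fabric remodeling and enrichment.
#' @param cond_a,cond_b Condition labels; default to the two present.
#' @param alpha Regulation significance level.
#' @param stability_rev REV threshold for the stable-gene count.
#' @param r2_min Profile-similarity R^2 threshold.
#' @param weights Spot-aggregation weighting scheme.
#' @param tol,max_iter Normalization settings.
#' @param n_perm Enrichment permutations.
#' @param seed Integer seed for the permutation stage.
#' @param output_dir Optional directory for TSV outputs and manifest.
#' @return Object of class `gfp_analysis`: list with `valid_spots`,
#'   `norm`, `groups`, `expr`, `rev`, `ges`, `stable`, `ges_shift`,
#'   `regulation`, `summary`, `coord` (list per condition), `fabric`
#'   (per gene set), `enrichment`, `manifest`.
#' @export
#' @examples
#' sim <- simulate_two_color(sim_config(n_genes = 40, seed = 11))
#' fit <- run_pipeline(sim$spots, seed = 11)
#' glance(fit)
run_pipeline <- function(spots, genesets = NULL, cond_a = NULL,
                         cond_b = NULL, alpha = 0.05, stability_rev = 10,
                         r2_min = 0.9, weights = "inverse_cv2", tol = 0.05,
                         max_iter = 50, n_perm = 2000, seed = 1L,
                         output_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  conds <- unique(spots$condition)
  if (is.null(cond_a)) cond_a <- conds[1]
  if (is.null(cond_b)) cond_b <- conds[2]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  valid <- filter_valid_spots(spots)
  tick("filter")
  norm <- normalize_iterative(spots, valid, tol = tol, max_iter = max_iter)
  tick("normalize")
  groups <- build_redundancy_groups(spots, valid)
  expr <- aggregate_redundancy(norm, groups, weights = weights)
  tick("aggregate")
  rev_tbl <- compute_rev(norm)
  ges_tbl <- compute_ges(rev_tbl)
  stable <- count_stable(rev_tbl, threshold = stability_rev)
  shift <- ges_shift(ges_tbl, cond_a, cond_b)
  tick("variability")
  reg <- call_regulation(expr, rev_tbl, cond_a, cond_b, alpha = alpha)
  reg_sum <- regulation_summary(reg)
  tick("regulation")
  coord <- list()
  coord[[cond_a]] <- coordination_matrix(expr, cond_a)
  coord[[cond_b]] <- coordination_matrix(expr, cond_b)
  tick("coordination")

  fabric <- NULL
  enr <- NULL
  if (!is.null(genesets) && length(genesets) > 0) {
    fabric <- purrr::imap(genesets, function(set, nm) {
      tryCatch(
        dplyr::mutate(
          fabric_remodeling(coord[[cond_a]], coord[[cond_b]], set,
                            r2_min = r2_min),
          pathway = nm, .before = 1),
        error = function(e) NULL)
    })
    fabric <- dplyr::bind_rows(fabric)
    set.seed(seed)
    up <- reg$gene_id[reg$call == "up"]
    enr <- rank_pathways(up, genesets, universe = reg$gene_id,
                         n_perm = n_perm)
    tick("fabric")
  }

  manifest <- list(
    package = "genofabric",
    version = as.character(utils::packageVersion("genofabric")),
    conditions = c(cond_a, cond_b),
    settings = list(alpha = alpha, stability_rev = stability_rev,
                    r2_min = r2_min, weights = weights, tol = tol,
                    max_iter = max_iter, n_perm = n_perm, seed = seed),
    counts = list(
      spots = nrow(spots), valid_spots = length(valid),
      genes = nrow(groups), genes_with_rev = length(unique(rev_tbl$gene_id)),
      regulated = reg_sum$n_altered, up = reg_sum$n_up,
      down = reg_sum$n_down
    ),
    exclusions = list(
      missing_spots = attr(valid, "missing"),
      floored_signals = norm$n_floored,
      rev_excluded = attr(rev_tbl, "excluded"),
      regulation_excluded = attr(reg, "excluded")
    ),
    timings_s = as.list(timings)
  )

  out <- structure(list(
    valid_spots = valid, norm = norm, groups = groups, expr = expr,
    rev = rev_tbl, ges = ges_tbl, stable = stable, ges_shift = shift,
    regulation = reg, summary = reg_sum, coord = coord, fabric = fabric,
    enrichment = enr, manifest = manifest
  ), class = "gfp_analysis")

  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

write_pipeline_outputs <- function(fit, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(output_dir, f)
  write_expression_matrix(fit$expr[c("gene_id", "condition", "replica_id",
                                     "value")], p("expression.tsv"))
  readr::write_tsv(fit$ges, p("rev_ges.tsv"), progress = FALSE)
  readr::write_tsv(fit$ges_shift, p("ges_shift.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(fit$regulation), p("regulation.tsv"),
                   progress = FALSE)
  for (cond in names(fit$coord))
    readr::write_tsv(coordination_edges(fit$coord[[cond]]),
                     p(paste0("edges_", cond, ".tsv")), progress = FALSE)
  if (!is.null(fit$fabric))
    readr::write_tsv(fit$fabric, p("fabric.tsv"), progress = FALSE)
  if (!is.null(fit$enrichment))
    readr::write_tsv(fit$enrichment, p("enrichment.tsv"), progress = FALSE)
  manifest <- fit$manifest
  manifest$outputs <- list.files(output_dir)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(output_dir)
}

#' @export
print.gfp_analysis <- function(x, ...) {
  s <- x$summary
  cat("<gfp_analysis> ", s$n_genes, " genes; ", s$n_altered,
      " regulated (", s$pct_altered, "%): ", s$n_up, " up / ", s$n_down,
      " down\n", sep = "")
  cat("  stable genes (REV < ",
      x$manifest$settings$stability_rev, "): ",
      paste(sprintf("%s=%d", x$stable$condition, x$stable$n_stable),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy and summary methods for pipeline results
#'
#' `tidy()` returns the per-gene regulation table (one row per gene with
#' fold change, adaptive cut-off, p-value and call); `glance()` returns the
#' one-row experiment summary (gene, DEG and stable-gene counts).
#'
#' @param x A `gfp_analysis` object from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.gfp_analysis <- function(x, ...) {
  tibble::as_tibble(x$regulation)
}

#' @rdname tidy.gfp_analysis
#' @exportS3Method generics::glance
glance.gfp_analysis <- function(x, ...) {
  stable <- tidyr::pivot_wider(x$stable, names_from = "condition",
                               values_from = "n_stable",
                               names_prefix = "n_stable_")
  dplyr::bind_cols(x$summary, stable)
}
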