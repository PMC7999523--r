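#' Pooled coefficient of variation across redundant spots
#'
#' For one gene in one condition, with replicate expression levels for each
#' of its `R` redundant spots, the pooled CV is the root of the mean squared
#' per-spot CV: `sqrt(mean_k((s_k / mu_k)^2))`, where `s_k` is the sample
#' (n - 1) standard deviation of spot `k` across biological replicas and
#' `mu_k` its mean.  Any non-positive spot mean makes the CV undefined
#' (`NA`).
#'
#' @param values Numeric matrix, spots in rows and replicas in columns (a
#'   vector is treated as one spot), or a list of per-spot replicate
#'   vectors.
#' @return Dimensionless pooled CV (scalar).
#' @export
#' @examples
#' pooled_cv(c(8, 10, 12, 10))            # one spot
#' pooled_cv(rbind(c(9, 10, 11, 10), c(18, 20, 22, 20)))
pooled_cv <- function(values) {
  if (is.list(values)) {
    cvs2 <- vapply(values, function(v) {
      m <- mean(v)
      if (!is.finite(m) || m <= 0 || length(v) < 2) return(NA_real_)
      (stats::sd(v) / m)^2
    }, numeric(1))
  } else {
    if (is.vector(values)) values <- matrix(values, nrow = 1)
    if (ncol(values) < 2)
      stop("each spot needs at least 2 replicas", call. = FALSE)
    m <- rowMeans(values)
    if (any(!is.finite(m)) || any(m <= 0)) return(NA_real_)
    cvs2 <- (apply(values, 1, stats::sd) / m)^2
  }
  if (anyNA(cvs2)) return(NA_real_)
  sqrt(mean(cvs2))
}

#' Chi-squared interval correction coefficient for a CV estimate
#'
#' Midpoint of the two confidence-bound factors of a standard-deviation
#' estimate with `r` degrees of freedom:
#' `0.5 * (sqrt(r / qchisq(0.975, r)) + sqrt(r / qchisq(0.025, r)))`.
#' It exceeds 1, widens the CV estimate most when few measurements are
#' available, decreases strictly with `r`, and tends to 1 as `r` grows.
#' With 4 replicas and `R` redundant spots, `r = 4R - 1`.
#'
#' @param r Degrees of freedom (>= 1), vectorized.
#' @return Correction coefficient(s) > 1.
#' @export
#' @examples
#' chi2_correction(3)   # single spot, 4 replicas
#' chi2_correction(7)   # two spots, 4 replicas
chi2_correction <- function(r) {
  if (any(!is.finite(r)) || any(r < 1))
    stop("`r` must be >= 1", call. = FALSE)
  0.5 * (sqrt(r / stats::qchisq(0.975, df = r)) +
           sqrt(r / stats::qchisq(0.025, df = r)))
}

#' Relative expression variability (REV) per gene and condition
#'
#' REV is the chi-squared interval-corrected pooled CV, in percent:
#' `REV = chi2_correction(r) * pooled_cv * 100` with `r = n_replicas * R - 1`
#' degrees of freedom for a gene probed by `R` redundant spots.  Genes with
#' a non-positive spot mean are excluded and reported via the `excluded`
#' attribute.
#'
#' @param norm A `gfp_norm` object from [normalize_iterative()] (or its
#'   spot-level `values` tibble with columns `spot_id`, `gene_id`,
#'   `condition`, `replica_id`, `value`).
#' @return Tibble with one row per (gene, condition): `gene_id`,
#'   `condition`, `r_spots` (R), `df` (degrees of freedom), `pooled_cv`,
#'   `correction`, `rev` (percent).
#' @export
#' @examples
#' sim <- simulate_two_color(sim_config(n_genes = 40, seed = 4))
#' nm <- normalize_iterative(sim$spots, filter_valid_spots(sim$spots))
#' compute_rev(nm)
compute_rev <- function(norm) {
  values <- if (inherits(norm, "gfp_norm")) norm$values else norm
  out <- values |>
    dplyr::group_by(.data$gene_id, .data$condition) |>
    dplyr::summarise(
      r_spots = length(unique(.data$spot_id)),
      n_reps = length(unique(.data$replica_id)),
      pooled_cv = pooled_cv(split(.data$value, .data$spot_id)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      df = .data$n_reps * .data$r_spots - 1L,
      correction = chi2_correction(.data$df),
      rev = .data$correction * .data$pooled_cv * 100
    ) |>
    dplyr::select("gene_id", "condition", "r_spots", "df",
                  "pooled_cv", "correction", "rev")
  excluded <- unique(out$gene_id[!is.finite(out$rev)])
  out <- dplyr::filter(out, is.finite(.data$rev))
  attr(out, "excluded") <- excluded
  out
}

#' Gene expression stability (GES) percentiles
#'
#' Ranks genes within each condition by decreasing REV and converts the
#' rank to a midpoint percentile `GES = 100 * (rank - 0.5) / N`, so the most
#' variable gene lands in the first percentile (GES < 1 for N >= 50) and
#' the most stable gene in the last (GES > 99).  Ties receive their average
#' rank.  High GES therefore means stable expression.
#'
#' @param revs REV tibble from [compute_rev()].
#' @return The input with a `ges` column appended.
#' @export
compute_ges <- function(revs) {
  if (nrow(revs) == 0) stop("empty REV table", call. = FALSE)
  revs |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(
      ges = 100 * (rank(-.data$rev, ties.method = "average") - 0.5) /
        dplyr::n()
    ) |>
    dplyr::ungroup()
}

#' Count very stably expressed genes
#'
#' Number of genes with REV strictly below `threshold` (default 10%), per
#' condition.
#'
#' @param revs REV tibble from [compute_rev()].
#' @param threshold REV threshold in percent.
#' @return Tibble `condition`, `n_stable`.
#' @export
#' @examples
#' count_stable(tibble::tibble(gene_id = letters[1:4], condition = "CTR",
#'                             rev = c(5, 9.9, 10, 12)))
count_stable <- function(revs, threshold = 10) {
  if (nrow(revs) == 0)
    return(tibble::tibble(condition = character(), n_stable = integer()))
  revs |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_stable = sum(.data$rev < threshold), .groups = "drop")
}

#' Per-gene stability shift between two conditions
#'
#' Pairs each gene's GES in two conditions and flags outliers whose absolute
#' GES change exceeds `threshold` percentile points — genes whose expression
#' control changed drastically (e.g. from very stable to very unstable).
#'
#' @param ges GES tibble from [compute_ges()] covering both conditions.
#' @param cond_a,cond_b Condition labels (reference first).
#' @param threshold Absolute GES-change flag threshold, percentile points.
#' @return Tibble `gene_id`, `ges_a`, `ges_b`, `delta_ges`, `outlier`.
#' @export
ges_shift <- function(ges, cond_a, cond_b, threshold = 50) {
  a <- dplyr::filter(ges, .data$condition == cond_a)
  b <- dplyr::filter(ges, .data$condition == cond_b)
  common <- intersect(a$gene_id, b$gene_id)
  if (length(common) == 0)
    stop("conditions share no genes", call. = FALSE)
  tibble::tibble(
    gene_id = common,
    ges_a = a$ges[match(common, a$gene_id)],
    ges_b = b$ges[match(common, b$gene_id)]
  ) |>
    dplyr::mutate(
      delta_ges = .data$ges_b - .data$ges_a,
      outlier = abs(.data$delta_ges) > threshold
    )
}
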