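#' Signed fold change between two mean expression levels
#'
#' `x = mu_b / mu_a` when `mu_b >= mu_a` and `-mu_a / mu_b` otherwise, so
#' `|x| >= 1` always and equal means give `+1`.  Vectorized.
#'
#' @param mu_a,mu_b Positive mean levels in the reference and the contrast
#'   condition.
#' @return Signed fold change(s).
#' @export
#' @examples
#' fold_change(5, 10)   # +2
#' fold_change(10, 5)   # -2
fold_change <- function(mu_a, mu_b) {
  if (any(!is.finite(mu_a) | mu_a <= 0) || any(!is.finite(mu_b) | mu_b <= 0))
    stop("mean levels must be positive", call. = FALSE)
  ifelse(mu_b >= mu_a, mu_b / mu_a, -mu_a / mu_b)
}

#' Adaptive per-gene fold-change cut-off
#'
#' `CUT = 1 + sqrt(2 * (rev_a^2 + rev_b^2)) / 100`, combining the gene's
#' relative expression variability (percent) in both conditions into the
#' minimum absolute fold change it must exceed to be called regulated.
#' Replaces a uniform fold cut-off (e.g. 1.5x) with one that widens for
#' noisy genes.  Vectorized; CUT >= 1 with equality only when both REVs
#' are zero.
#'
#' @param rev_a,rev_b REV of the gene in each condition, percent (>= 0).
#' @return Cut-off value(s).
#' @export
#' @examples
#' compute_cut(10, 10)   # 1.2
compute_cut <- function(rev_a, rev_b) {
  if (any(rev_a < 0) || any(rev_b < 0))
    stop("REV values must be >= 0", call. = FALSE)
  1 + sqrt(2 * (rev_a^2 + rev_b^2)) / 100
}

#' Two-sided heteroscedastic (Welch) t-test p-value
#'
#' Unequal-variance t-test with Welch--Satterthwaite degrees of freedom on
#' two replicate vectors.  Both groups constant gives `NA` (the caller
#' reports and excludes such genes).
#'
#' @param x,y Numeric replicate vectors (>= 2 values each).
#' @return Two-sided p-value.
#' @export
welch_p <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 replicas", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) return(NA_real_)
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Call differentially expressed genes with the adaptive cut-off
#'
#' A gene is called `up` when its signed fold change exceeds its per-gene
#' cut-off (`x > CUT`) with `p < alpha`, `down` when `x < -CUT` with
#' `p < alpha`, and `unchanged` otherwise.  Fold changes compare the
#' gene-level replicate means of the two conditions; the heteroscedastic
#' t-test runs on the gene-level replicate values.  Genes lacking a REV in
#' either condition, or with an undefined p-value, are excluded and
#' reported.
#'
#' @param expr Gene-level expression tibble from [aggregate_redundancy()]
#'   (`gene_id`, `condition`, `replica_id`, `value`).
#' @param revs REV tibble from [compute_rev()] covering both conditions.
#' @param cond_a,cond_b Reference and contrast condition labels; defaults
#'   to the first two conditions present in `expr`.
#' @param alpha Significance level for the t-test.
#' @return Tibble of class `gfp_regulation`: `gene_id`, `mu_a`, `mu_b`,
#'   `x`, `cut`, `p`, `call`; attribute `excluded` lists dropped genes,
#'   attributes `cond_a`/`cond_b`/`alpha` record the contrast.
#' @export
#' @examples
#' sim <- simulate_two_color(sim_config(n_genes = 60, deg_fraction = 0.1,
#'                                      seed = 5))
#' nm <- normalize_iterative(sim$spots, filter_valid_spots(sim$spots))
#' expr <- aggregate_redundancy(nm, build_redundancy_groups(sim$spots))
#' call_regulation(expr, compute_rev(nm))
call_regulation <- function(expr, revs, cond_a = NULL, cond_b = NULL,
                            alpha = 0.05) {
  conds <- unique(expr$condition)
  if (is.null(cond_a)) cond_a <- conds[1]
  if (is.null(cond_b)) cond_b <- conds[2]
  stopifnot(cond_a %in% conds, cond_b %in% conds, cond_a != cond_b)

  rev_w <- revs |>
    dplyr::filter(.data$condition %in% c(cond_a, cond_b)) |>
    dplyr::select("gene_id", "condition", "rev") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "rev")

  wide <- expr |>
    dplyr::filter(.data$condition %in% c(cond_a, cond_b)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      mu_a = mean(.data$value[.data$condition == cond_a]),
      mu_b = mean(.data$value[.data$condition == cond_b]),
      p = tryCatch(
        welch_p(.data$value[.data$condition == cond_a],
                .data$value[.data$condition == cond_b]),
        error = function(e) NA_real_),
      .groups = "drop"
    ) |>
    dplyr::left_join(rev_w, by = "gene_id")

  bad <- !is.finite(wide$mu_a) | !is.finite(wide$mu_b) |
    wide$mu_a <= 0 | wide$mu_b <= 0 | !is.finite(wide$p) |
    !is.finite(wide[[cond_a]]) | !is.finite(wide[[cond_b]])
  excluded <- wide$gene_id[bad]
  wide <- wide[!bad, , drop = FALSE]

  out <- wide |>
    dplyr::mutate(
      x = fold_change(.data$mu_a, .data$mu_b),
      cut = compute_cut(.data[[cond_a]], .data[[cond_b]]),
      call = dplyr::case_when(
        .data$x > .data$cut & .data$p < alpha ~ "up",
        .data$x < -.data$cut & .data$p < alpha ~ "down",
        TRUE ~ "unchanged"
      )
    ) |>
    dplyr::select("gene_id", "mu_a", "mu_b", "x", "cut", "p", "call")
  attr(out, "excluded") <- excluded
  attr(out, "cond_a") <- cond_a
  attr(out, "cond_b") <- cond_b
  attr(out, "alpha") <- alpha
  class(out) <- c("gfp_regulation", class(out))
  out
}

#' Summarise a regulation table
#'
#' Counts and percentages of regulated genes, in the paper-style layout:
#' percent of the universe altered, and up/down percentages of the altered
#' set, all rounded half-away-from-zero to one decimal.
#'
#' @param records A `gfp_regulation` tibble from [call_regulation()].
#' @return One-row tibble: `n_genes`, `n_altered`, `n_up`, `n_down`,
#'   `pct_altered`, `pct_up`, `pct_down`.
#' @export
regulation_summary <- function(records) {
  n <- nrow(records)
  n_up <- sum(records$call == "up")
  n_down <- sum(records$call == "down")
  n_alt <- n_up + n_down
  tibble::tibble(
    n_genes = n, n_altered = n_alt, n_up = n_up, n_down = n_down,
    pct_altered = round_half_up(100 * n_alt / max(n, 1), 1),
    pct_up = round_half_up(100 * n_up / max(n_alt, 1), 1),
    pct_down = round_half_up(100 * n_down / max(n_alt, 1), 1)
  )
}

# round half away from zero (printed-style rounding, unlike round()'s
# round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
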