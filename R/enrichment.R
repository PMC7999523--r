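#' Standardized-difference (Z) score for gene-set enrichment
#'
#' Standardizes the number of positives observed in a gene set against the
#' hypergeometric expectation under random draws from the measured
#' universe:
#' `Z = (r - n R / N) / sqrt(n (R/N) (1 - R/N) (1 - (n-1)/(N-1)))`,
#' with `r` positives among the `n` measured set members, `R` positives
#' among the `N` measured genes overall.
#'
#' @param r Positives in the set.
#' @param n Measured genes in the set (>= 1).
#' @param R Total positives (0 < R < N).
#' @param N Total measured genes.
#' @return Z score (vectorized over `r`/`n`).
#' @export
#' @examples
#' enrichment_z(4, 4, 5, 10)   # 2.449
enrichment_z <- function(r, n, R, N) {
  if (any(n < 1) || R <= 0 || R >= N || any(r > n) || any(r > R) ||
      any(n > N))
    stop("invalid counts: need 0 <= r <= n <= N, 0 < R < N, r <= R",
         call. = FALSE)
  p <- R / N
  denom2 <- n * p * (1 - p) * (1 - (n - 1) / (N - 1))
  if (any(denom2 <= 0))
    stop("degenerate Z denominator", call. = FALSE)
  (r - n * p) / sqrt(denom2)
}

#' One-sided permutation p-value for set enrichment
#'
#' Draws `R` positives uniformly without replacement among `N` genes
#' `n_perm` times and reports the smoothed fraction of draws placing at
#' least `r` positives inside the `n`-gene set:
#' `(1 + #{draws >= r}) / (n_perm + 1)`.  Converges to the exact upper
#' hypergeometric tail.
#'
#' @param r,n,R,N Counts as in [enrichment_z()].
#' @param n_perm Number of permutations (>= 1000).
#' @param seed Optional integer seed.
#' @return Permutation p-value.
#' @export
permutation_p <- function(r, n, R, N, n_perm = 10000, seed = NULL) {
  if (n_perm < 1000) stop("`n_perm` must be >= 1000", call. = FALSE)
  if (r > n || n > N || R > N || r > R || any(c(r, n, R, N) < 0))
    stop("invalid counts", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  hits <- stats::rhyper(n_perm, m = R, n = N - R, k = n)
  (1 + sum(hits >= r)) / (n_perm + 1)
}

#' Rank gene sets by enrichment among regulated genes
#'
#' Computes, for each gene set, the number of positives it contains, its Z
#' score and its permutation p-value, and flags sets significant at
#' `Z > z_min` and `p < alpha`.  Gene identifiers are matched
#' case-insensitively; sets reduce to their measured members.
#'
#' @param positives Character vector of positive genes (e.g. upregulated
#'   DEGs), a subset of `universe`.
#' @param genesets Named list of gene-id vectors (see [read_gmt()]).
#' @param universe Character vector of all measured genes.
#' @param n_perm Permutations per set.
#' @param z_min,alpha Significance thresholds.
#' @param seed Optional integer seed for the permutation draws.
#' @return Tibble sorted by decreasing Z: `pathway`, `r`, `n`, `R`, `N`,
#'   `percent`, `z`, `p_perm`, `significant`.
#' @export
rank_pathways <- function(positives, genesets, universe, n_perm = 10000,
                          z_min = 2, alpha = 0.05, seed = NULL) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  uni <- unique(toupper(universe))
  pos <- intersect(unique(toupper(positives)), uni)
  N <- length(uni)
  R <- length(pos)
  rows <- purrr::imap(genesets, function(members, nm) {
    set <- intersect(unique(toupper(members)), uni)
    n <- length(set)
    if (n == 0) return(NULL)
    r <- length(intersect(set, pos))
    z <- if (R > 0 && R < N) enrichment_z(r, n, R, N) else NA_real_
    p <- if (R > 0) permutation_p(r, n, R, N, n_perm = n_perm) else 1
    tibble::tibble(pathway = nm, r = r, n = n, R = R, N = N,
                   percent = round_half_up(100 * r / n, 1),
                   z = z, p_perm = p)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(significant = is.finite(.data$z) & .data$z > z_min &
                    .data$p_perm < alpha) |>
    dplyr::arrange(dplyr::desc(.data$z))
}
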