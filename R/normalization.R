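#' Iterative intra-/inter-array median normalization
#'
#' Background-subtracts the valid spots and then alternates two scaling
#' steps until the values stabilize: (intra) each array-channel sample is
#' scaled so that its median over valid spots matches the global median of
#' all valid spots; (inter) each array (both channels together) is scaled so
#' that its median matches the global median.  Iteration stops when the
#' maximum relative change of any normalized value between successive
#' iterations drops below `tol` (default 5%).
#'
#' Non-positive background-subtracted signals are floored at the smallest
#' positive observed net signal times `1e-3`; their count is reported.
#'
#' @param spots Spot tibble covering all samples.
#' @param valid Character vector of valid spot ids from
#'   [filter_valid_spots()].
#' @param tol Convergence tolerance on the maximum relative change.
#' @param max_iter Iteration cap; non-convergence is an error carrying the
#'   trace so far.
#' @return Object of class `gfp_norm`: list with `values` (tibble `spot_id`,
#'   `gene_id`, `condition`, `replica_id`, `value`), `trace` (tibble
#'   `iteration`, `max_rel_change`), `n_floored`, `converged`.
#' @export
#' @examples
#' sim <- simulate_two_color(sim_config(n_genes = 50, seed = 3))
#' nm <- normalize_iterative(sim$spots, filter_valid_spots(sim$spots))
#' nm$trace
normalize_iterative <- function(spots, valid, tol = 0.05, max_iter = 50) {
  validate_spot_table(spots)
  if (length(valid) == 0) stop("no valid spots to normalize", call. = FALSE)
  tbl <- dplyr::filter(spots, .data$spot_id %in% valid)
  sample_id <- paste(tbl$array_id, tbl$channel, sep = "|")
  all_samples <- unique(paste(spots$array_id, spots$channel, sep = "|"))
  empty <- setdiff(all_samples, unique(sample_id))
  if (length(empty) > 0)
    stop("array-channel(s) without valid spots: ",
         paste(empty, collapse = ", "), call. = FALSE)

  net <- tbl$fg - tbl$bg
  floor_at <- if (any(net > 0)) min(net[net > 0]) * 1e-3 else
    stop("no positive background-subtracted signal", call. = FALSE)
  n_floored <- sum(net <= 0)
  net[net <= 0] <- floor_at

  x <- net
  trace <- tibble::tibble(iteration = integer(), max_rel_change = numeric())
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    prev <- x
    gmed <- stats::median(x)
    med_s <- tapply(x, sample_id, stats::median)
    x <- x * (gmed / med_s[sample_id])
    gmed <- stats::median(x)
    med_a <- tapply(x, tbl$array_id, stats::median)
    x <- x * (gmed / med_a[tbl$array_id])
    delta <- max(abs(x - prev) / prev)
    trace <- dplyr::bind_rows(trace,
      tibble::tibble(iteration = it, max_rel_change = delta))
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("normalization did not converge in ", max_iter,
            " iterations (last max relative change ",
            signif(trace$max_rel_change[nrow(trace)], 3), ")", call. = FALSE)
  }
  structure(list(
    values = tibble::tibble(
      spot_id = tbl$spot_id, gene_id = tbl$gene_id,
      condition = tbl$condition, replica_id = tbl$replica_id,
      value = as.numeric(x)
    ),
    trace = trace, n_floored = n_floored, converged = converged
  ), class = "gfp_norm")
}

#' @export
print.gfp_norm <- function(x, ...) {
  cat("<gfp_norm> ", nrow(x$values), " spot values; ",
      nrow(x$trace), " iteration(s), ",
      if (x$converged) "converged" else "NOT converged",
      "; ", x$n_floored, " floored signal(s)\n", sep = "")
  invisible(x)
}

#' Aggregate redundant spots to gene-level expression
#'
#' Each gene's expression in a replica is the weighted average of its valid
#' member spots.  With `weights = "inverse_cv2"` (default) each spot is
#' weighted by the inverse squared across-replica coefficient of variation
#' of that spot within the condition, renormalized to sum to 1; when any
#' member spot has a zero or undefined CV the gene falls back to equal
#' weights.  `weights = "equal"` always uses equal weights.  Genes with no
#' valid spots are excluded and reported via the `excluded` attribute.
#'
#' @param norm A `gfp_norm` object (or its `values` tibble).
#' @param groups Redundancy groups from [build_redundancy_groups()].
#' @param weights `"inverse_cv2"` or `"equal"`.
#' @return Tibble with columns `gene_id`, `condition`, `replica_id`,
#'   `value`, `r` (spot redundancy), carrying attribute `excluded`.
#' @export
aggregate_redundancy <- function(norm, groups,
                                 weights = c("inverse_cv2", "equal")) {
  weights <- match.arg(weights)
  values <- if (inherits(norm, "gfp_norm")) norm$values else norm
  keep <- values$spot_id %in% unlist(groups$spot_ids)
  values <- values[keep, , drop = FALSE]
  excluded <- setdiff(groups$gene_id, unique(values$gene_id))

  spot_stats <- values |>
    dplyr::group_by(.data$gene_id, .data$condition, .data$spot_id) |>
    dplyr::mutate(
      spot_cv = stats::sd(.data$value) / mean(.data$value)
    ) |>
    dplyr::group_by(.data$gene_id, .data$condition) |>
    dplyr::mutate(
      w = if (weights == "equal" || any(!is.finite(.data$spot_cv)) ||
                any(.data$spot_cv == 0)) 1
          else 1 / .data$spot_cv^2
    ) |>
    dplyr::ungroup()

  out <- spot_stats |>
    dplyr::group_by(.data$gene_id, .data$condition, .data$replica_id) |>
    dplyr::summarise(
      value = sum(.data$w * .data$value) / sum(.data$w),
      r = dplyr::n(),
      .groups = "drop"
    )
  attr(out, "excluded") <- sort(excluded)
  out
}
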