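#' Replicate-wise gene-gene Pearson coordination matrix
#'
#' Pairwise Pearson correlations between the expression levels of all gene
#' pairs across the biological replicas of one condition, computed on the
#' normalized linear levels (set `log2 = TRUE` for log-scale correlation).
#' Genes with zero replicate variance carry no coordination information and
#' are excluded from the universe (reported via the `excluded` attribute).
#'
#' @param expr Gene-level expression tibble from [aggregate_redundancy()].
#' @param condition Condition label to use.
#' @param log2 Correlate log2 levels instead of linear levels.
#' @return Symmetric correlation matrix of class `gfp_coord` with gene ids
#'   as dimnames and attributes `condition`, `n_replicas`, `excluded`.
#' @export
#' @examples
#' sim <- simulate_two_color(sim_config(n_genes = 15, seed = 8))
#' nm <- normalize_iterative(sim$spots, filter_valid_spots(sim$spots))
#' expr <- aggregate_redundancy(nm, build_redundancy_groups(sim$spots))
#' cm <- coordination_matrix(expr, "CTR")
#' cm[1:3, 1:3]
coordination_matrix <- function(expr, condition, log2 = FALSE) {
  mat <- expr_matrix(expr, condition)
  if (ncol(mat) < 3)
    stop("at least 3 replicas are required", call. = FALSE)
  if (log2) mat <- base::log2(mat)
  v <- apply(mat, 1, stats::var)
  excluded <- rownames(mat)[!is.finite(v) | v == 0]
  mat <- mat[is.finite(v) & v > 0, , drop = FALSE]
  rho <- stats::cor(t(mat))
  structure(rho, class = c("gfp_coord", class(rho)),
            condition = condition, n_replicas = ncol(mat),
            excluded = excluded)
}

# long expression tibble -> gene x replica matrix for one condition
expr_matrix <- function(expr, condition) {
  sub <- dplyr::filter(expr, .data$condition == !!condition)
  if (nrow(sub) == 0) stop("condition not found: ", condition, call. = FALSE)
  wide <- tidyr::pivot_wider(sub, id_cols = "gene_id",
                             names_from = "replica_id",
                             values_from = "value")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$gene_id
  mat
}

#' @export
print.gfp_coord <- function(x, ...) {
  cat("<gfp_coord> ", nrow(x), " genes, condition ",
      attr(x, "condition"), ", ", attr(x, "n_replicas"), " replicas\n",
      sep = "")
  invisible(x)
}

#' Classify a coordination coefficient
#'
#' Pairs are `synergistic` when `rho > syn` (default 0.90), `antagonistic`
#' when `rho < ant` (default -0.90), `independent` when `|rho| < ind`
#' (default 0.05) and `unclassified` otherwise; all inequalities are
#' strict, so the boundary values themselves are unclassified.  The default
#' thresholds are the one-sided p < 0.05 significant correlation for 4
#' biological replicas (see [critical_rho()]).
#'
#' @param rho Correlation value(s) in `[-1, 1]`.
#' @param syn,ant,ind Class thresholds.
#' @return Character vector in
#'   `{synergistic, antagonistic, independent, unclassified}`.
#' @export
#' @examples
#' classify_rho(c(0.95, 0.90, 0.03, 0.5, -0.95))
classify_rho <- function(rho, syn = 0.90, ant = -0.90, ind = 0.05) {
  if (any(abs(rho) > 1 + 1e-12, na.rm = TRUE))
    stop("|rho| must be <= 1", call. = FALSE)
  dplyr::case_when(
    rho > syn ~ "synergistic",
    rho < ant ~ "antagonistic",
    abs(rho) < ind ~ "independent",
    TRUE ~ "unclassified"
  )
}

#' Critical Pearson correlation for n replicas
#'
#' The smallest correlation significant at one-sided level `alpha` with `n`
#' paired observations, obtained by inverting the exact null relation
#' `t = rho * sqrt(n - 2) / sqrt(1 - rho^2)` against the critical t with
#' `n - 2` degrees of freedom.  With 4 replicas and `alpha = 0.05` this is
#' 0.90 (2 dp), the class threshold used throughout.
#'
#' @param n_replicas Number of paired observations (>= 3).
#' @param alpha One-sided significance level.
#' @return Critical correlation in (0, 1).
#' @export
#' @examples
#' critical_rho(4)        # 0.8999...
#' critical_rho(3)        # 0.9877...
critical_rho <- function(n_replicas, alpha = 0.05) {
  if (!is.finite(n_replicas) || n_replicas < 3)
    stop("`n_replicas` must be >= 3", call. = FALSE)
  df <- n_replicas - 2
  tcrit <- stats::qt(1 - alpha, df = df)
  tcrit / sqrt(df + tcrit^2)
}

#' Coordination profile of one gene
#'
#' The vector of a gene's correlations against every other gene in the
#' coordination universe.
#'
#' @param coord A `gfp_coord` matrix.
#' @param gene Gene id.
#' @return Named numeric vector of length `nrow(coord) - 1`.
#' @export
coordination_profile <- function(coord, gene) {
  if (!gene %in% rownames(coord))
    stop("gene not in coordination universe: ", gene, call. = FALSE)
  coord[gene, setdiff(colnames(coord), gene)]
}

#' Similarity of two genes' coordination profiles
#'
#' Fits one gene's coordination profile against the other's by least
#' squares (both profiles taken over the shared universe minus the two
#' genes themselves) and classifies the pair as `similar` (R^2 >= `r2_min`
#' with positive slope), `opposite` (R^2 >= `r2_min` with negative slope)
#' or `neutral`.  Partner-overlap counts — how many genes are synergistic,
#' antagonistic or independent partners of *both* — are reported alongside.
#' Universes overlapping in fewer than 10 genes are reported and classed
#' neutral.
#'
#' @param coord A `gfp_coord` matrix (or a second one via `coord_b` is not
#'   supported: profiles must come from the same condition matrix).
#' @param gene_a,gene_b Gene ids.
#' @param r2_min Coefficient-of-determination threshold (default 0.9).
#' @param ... Thresholds passed to [classify_rho()] for overlap counts.
#' @return One-row tibble: `gene_a`, `gene_b`, `r_squared`, `slope`,
#'   `class`, `n_shared_synergistic`, `n_shared_antagonistic`,
#'   `n_shared_independent`, `n_universe`.
#' @export
profile_similarity <- function(coord, gene_a, gene_b, r2_min = 0.9, ...) {
  universe <- setdiff(rownames(coord), c(gene_a, gene_b))
  pa <- coord[gene_a, universe]
  pb <- coord[gene_b, universe]
  ok <- is.finite(pa) & is.finite(pb)
  pa <- pa[ok]; pb <- pb[ok]
  n_uni <- length(pa)
  if (n_uni < 10) {
    warning("profile universe overlap below 10 genes; class set to neutral",
            call. = FALSE)
    r2 <- NA_real_; slope <- NA_real_; cls <- "neutral"
  } else {
    fit <- stats::lm.fit(cbind(1, pa), pb)
    slope <- unname(fit$coefficients[2])
    r2 <- 1 - sum(fit$residuals^2) / sum((pb - mean(pb))^2)
    cls <- if (is.finite(r2) && r2 >= r2_min) {
      if (slope > 0) "similar" else "opposite"
    } else "neutral"
  }
  ca <- classify_rho(pa, ...)
  cb <- classify_rho(pb, ...)
  tibble::tibble(
    gene_a = gene_a, gene_b = gene_b,
    r_squared = r2, slope = slope, class = cls,
    n_shared_synergistic = sum(ca == "synergistic" & cb == "synergistic"),
    n_shared_antagonistic = sum(ca == "antagonistic" & cb == "antagonistic"),
    n_shared_independent = sum(ca == "independent" & cb == "independent"),
    n_universe = n_uni
  )
}

#' Coordination class counts within a gene set
#'
#' Enumerates all unordered within-set gene pairs present in the
#' coordination universe, classifies each pair, and reports counts and
#' percentages.  Genes absent from the universe are skipped and reported.
#'
#' @param coord A `gfp_coord` matrix.
#' @param geneset Character vector of gene ids (case-insensitive match
#'   against the universe).
#' @param ... Thresholds passed to [classify_rho()].
#' @return One-row tibble: `n_genes`, `n_pairs`, `n_synergistic`,
#'   `n_antagonistic`, `n_independent`, `n_unclassified`,
#'   `pct_synergistic`; attribute `skipped` lists absent genes.
#' @export
count_pathway_coordination <- function(coord, geneset, ...) {
  hit <- match(toupper(geneset), toupper(rownames(coord)))
  skipped <- geneset[is.na(hit)]
  present <- rownames(coord)[hit[!is.na(hit)]]
  if (length(present) == 0)
    stop("gene set does not intersect the coordination universe",
         call. = FALSE)
  sub <- coord[present, present, drop = FALSE]
  rho <- sub[upper.tri(sub)]
  cls <- classify_rho(rho, ...)
  n_pairs <- length(rho)
  out <- tibble::tibble(
    n_genes = length(present), n_pairs = n_pairs,
    n_synergistic = sum(cls == "synergistic"),
    n_antagonistic = sum(cls == "antagonistic"),
    n_independent = sum(cls == "independent"),
    n_unclassified = sum(cls == "unclassified"),
    pct_synergistic = round_half_up(
      100 * sum(cls == "synergistic") / max(n_pairs, 1), 1)
  )
  attr(out, "skipped") <- skipped
  out
}

#' Pathway fabric remodeling between two conditions
#'
#' Compares a gene set's within-set coordination between two conditions:
#' pair-class counts, percent synergistic pairs, and the percent of
#' within-set pairs with similar coordination profiles, together with their
#' deltas.  Only genes present in both coordination universes enter.
#'
#' @param coord_a,coord_b `gfp_coord` matrices for the two conditions.
#' @param geneset Character vector of gene ids.
#' @param r2_min Profile-similarity R^2 threshold.
#' @param ... Thresholds passed to [classify_rho()].
#' @return Tibble with one row per condition plus a `delta` row, columns as
#'   in [count_pathway_coordination()] plus `pct_similar_profiles`.
#' @export
fabric_remodeling <- function(coord_a, coord_b, geneset, r2_min = 0.9, ...) {
  shared <- intersect(rownames(coord_a), rownames(coord_b))
  hit <- shared[toupper(shared) %in% toupper(geneset)]
  if (length(hit) < 2)
    stop("fewer than 2 set genes shared by both universes", call. = FALSE)

  one <- function(coord, label) {
    cnt <- count_pathway_coordination(coord, hit, ...)
    pairs <- utils::combn(hit, 2, simplify = FALSE)
    sim <- vapply(pairs, function(p)
      suppressWarnings(
        profile_similarity(coord, p[1], p[2], r2_min = r2_min, ...)$class),
      character(1))
    dplyr::mutate(cnt,
      condition = label,
      pct_similar_profiles = round_half_up(
        100 * sum(sim == "similar") / length(sim), 1),
      .before = 1)
  }
  ta <- one(coord_a, attr(coord_a, "condition") %||% "A")
  tb <- one(coord_b, attr(coord_b, "condition") %||% "B")
  delta <- tb
  delta$condition <- "delta"
  num <- vapply(ta, is.numeric, logical(1))
  delta[num] <- tb[num] - ta[num]
  dplyr::bind_rows(ta, tb, delta)
}

#' Stream coordination class counts over the whole transcriptome
#'
#' Counts synergistic/antagonistic/independent/unclassified pairs over all
#' unordered gene pairs of a condition without materializing the full
#' correlation matrix: the gene set is processed in tiles of
#' `tile_size` x `tile_size` correlations.  Results are identical to
#' classifying the full matrix.
#'
#' @param expr Gene-level expression tibble.
#' @param condition Condition label.
#' @param tile_size Number of genes per tile.
#' @param log2 Correlate log2 levels.
#' @param ... Thresholds passed to [classify_rho()].
#' @return One-row tibble: `n_genes`, `n_pairs`, `n_synergistic`,
#'   `n_antagonistic`, `n_independent`, `n_unclassified`.
#' @export
coordination_class_counts <- function(expr, condition, tile_size = 1000,
                                      log2 = FALSE, ...) {
  mat <- expr_matrix(expr, condition)
  if (log2) mat <- base::log2(mat)
  v <- apply(mat, 1, stats::var)
  mat <- mat[is.finite(v) & v > 0, , drop = FALSE]
  z <- mat - rowMeans(mat)
  z <- z / sqrt(rowSums(z^2))
  n <- nrow(z)
  counts <- c(synergistic = 0, antagonistic = 0, independent = 0,
              unclassified = 0)
  starts <- seq(1, n, by = tile_size)
  for (bi in starts) {
    ei <- min(bi + tile_size - 1, n)
    for (bj in starts[starts >= bi]) {
      ej <- min(bj + tile_size - 1, n)
      tile <- z[bi:ei, , drop = FALSE] %*% t(z[bj:ej, , drop = FALSE])
      rho <- if (bi == bj) tile[upper.tri(tile)] else as.vector(tile)
      cls <- classify_rho(pmin(pmax(rho, -1), 1), ...)
      tab <- table(factor(cls, levels = names(counts)))
      counts <- counts + as.numeric(tab)
    }
  }
  tibble::tibble(n_genes = n, n_pairs = n * (n - 1) / 2,
                 n_synergistic = counts[["synergistic"]],
                 n_antagonistic = counts[["antagonistic"]],
                 n_independent = counts[["independent"]],
                 n_unclassified = counts[["unclassified"]])
}

#' Export a coordination matrix as a classified edge list
#'
#' @param coord A `gfp_coord` matrix.
#' @param keep Classes to keep (default: drop `unclassified` edges).
#' @param ... Thresholds passed to [classify_rho()].
#' @return Tibble `gene_a`, `gene_b`, `rho`, `class` — a plain edge list
#'   consumable by graph tools.
#' @export
coordination_edges <- function(coord,
                               keep = c("synergistic", "antagonistic",
                                        "independent"), ...) {
  idx <- which(upper.tri(coord), arr.ind = TRUE)
  out <- tibble::tibble(
    gene_a = rownames(coord)[idx[, 1]],
    gene_b = colnames(coord)[idx[, 2]],
    rho = coord[idx],
    class = classify_rho(coord[idx], ...)
  )
  dplyr::filter(out, .data$class %in% keep)
}
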