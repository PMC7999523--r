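#' Configuration for the synthetic two-color microarray generator
#'
#' Bundles and validates every knob of [simulate_two_color()].  The defaults
#' emulate a two-condition, four-replicate rat retina study profiled on
#' Agilent-style 4x44k two-color arrays: each gene probed by a couple of
#' redundant spots, log-normally distributed baseline abundance, per-gene
#' biological coefficients of variation in the 5--35% range, about 1% of
#' genes differentially expressed, multiplicative array/dye scaling and an
#' additive fluorescence background.
#'
#' @param n_genes Number of genes on the array.
#' @param spots_per_gene Redundant spots probing each gene; a single count or
#'   a vector of length `n_genes` (all values >= 1).
#' @param n_replicas Biological replicas per condition (two samples are
#'   co-hybridized per array, one per channel).
#' @param baseline_log_mean,baseline_log_sd Mean and sd of the natural-log
#'   baseline expression level across genes.
#' @param cv_range Length-2 interval from which each gene's biological
#'   coefficient of variation is drawn uniformly.
#' @param deg_fraction Fraction of genes planted as differentially expressed
#'   between the two conditions, in `[0, 1]`.
#' @param deg_fold_range Length-2 interval of planted absolute fold changes
#'   (all values >= 1); each planted gene is up- or downregulated with equal
#'   probability, the fold applied to the second condition's mean.
#' @param module_specs List of coordination modules to plant, each a list (or
#'   length-2 numeric vector) of `(size, rho)`: number of member genes and
#'   target within-module replicate correlation in `[-1, 1]`.
#' @param corrupt_fraction Fraction of spots corrupted (flagged, or given a
#'   foreground below twice background, in one random sample), in `[0, 1]`.
#' @param array_scale_sd Log-scale sd of the multiplicative per (array,
#'   channel) scaling factor; 0 disables array/dye effects.
#' @param background_mean Additive background fluorescence level (a.u.).
#' @param conditions Character vector of the two condition labels.
#' @param seed Integer seed fixing all randomness of the generator.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_two_color()]
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 1)
#' cfg$n_replicas
sim_config <- function(n_genes = 1000,
                       spots_per_gene = 2,
                       n_replicas = 4,
                       baseline_log_mean = log(1000),
                       baseline_log_sd = 1,
                       cv_range = c(0.05, 0.35),
                       deg_fraction = 0.011,
                       deg_fold_range = c(1.5, 6),
                       module_specs = list(),
                       corrupt_fraction = 0.02,
                       array_scale_sd = 0.2,
                       background_mean = 50,
                       conditions = c("CTR", "ONC"),
                       seed = 1L) {
  stop_if <- function(bad, msg) if (bad) stop(msg, call. = FALSE)
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  stop_if(!num_ok(n_genes) || length(n_genes) != 1 || n_genes < 1,
          "`n_genes` must be a single positive count")
  n_genes <- as.integer(n_genes)
  stop_if(!num_ok(spots_per_gene) ||
            !(length(spots_per_gene) %in% c(1L, n_genes)) ||
            any(spots_per_gene < 1),
          "`spots_per_gene` must be >= 1, length 1 or n_genes")
  stop_if(!num_ok(n_replicas) || n_replicas < 2,
          "`n_replicas` must be >= 2")
  stop_if(!num_ok(baseline_log_mean) || !num_ok(baseline_log_sd) ||
            baseline_log_sd < 0, "invalid baseline log-normal parameters")
  stop_if(!num_ok(cv_range) || length(cv_range) != 2 || any(cv_range < 0) ||
            cv_range[1] > cv_range[2], "`cv_range` must be 0 <= lo <= hi")
  stop_if(!num_ok(deg_fraction) || deg_fraction < 0 || deg_fraction > 1,
          "`deg_fraction` must be in [0, 1]")
  stop_if(!num_ok(deg_fold_range) || length(deg_fold_range) != 2 ||
            any(deg_fold_range < 1) || deg_fold_range[1] > deg_fold_range[2],
          "`deg_fold_range` must be 1 <= lo <= hi")
  stop_if(!is.list(module_specs), "`module_specs` must be a list")
  module_specs <- lapply(module_specs, function(m) {
    m <- as.list(m)
    names(m) <- c("size", "rho")[seq_along(m)]
    stop_if(!num_ok(m$size) || m$size < 2, "module size must be >= 2")
    stop_if(!num_ok(m$rho) || abs(m$rho) > 1, "module rho must be in [-1, 1]")
    list(size = as.integer(m$size), rho = as.numeric(m$rho))
  })
  stop_if(sum(vapply(module_specs, `[[`, 1L, "size")) > n_genes,
          "modules cannot cover more genes than `n_genes`")
  stop_if(!num_ok(corrupt_fraction) || corrupt_fraction < 0 ||
            corrupt_fraction > 1, "`corrupt_fraction` must be in [0, 1]")
  stop_if(!num_ok(array_scale_sd) || array_scale_sd < 0,
          "`array_scale_sd` must be >= 0")
  stop_if(!num_ok(background_mean) || background_mean < 0,
          "`background_mean` must be >= 0")
  stop_if(length(conditions) != 2 || anyDuplicated(conditions) > 0,
          "`conditions` must be two distinct labels")
  stop_if(!num_ok(seed) || length(seed) != 1, "`seed` must be one integer")

  structure(list(
    n_genes = n_genes,
    spots_per_gene = as.integer(rep_len(spots_per_gene, n_genes)),
    n_replicas = as.integer(n_replicas),
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    cv_range = as.numeric(cv_range),
    deg_fraction = deg_fraction,
    deg_fold_range = as.numeric(deg_fold_range),
    module_specs = module_specs,
    corrupt_fraction = corrupt_fraction,
    array_scale_sd = array_scale_sd,
    background_mean = background_mean,
    conditions = as.character(conditions),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_genes, " genes x ",
      x$n_replicas, " replicas x 2 conditions; ",
      length(x$module_specs), " planted module(s); seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Read/write a generator configuration as YAML
#'
#' @param config A [sim_config()] object.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path, precision = 16L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' Impose a target pairwise correlation on a replicate matrix
#'
#' Mixes a common latent replicate factor into each row (gene) of `values`
#' so that the expected pairwise Pearson correlation between rows equals
#' `target_rho`, while each row keeps its original mean and standard
#' deviation.  With `exact = TRUE` the rows are rebuilt from an orthonormal
#' basis of the centered sample space (Gram-matrix square root), making every
#' pairwise *sample* correlation exactly `target_rho`; this needs
#' `nrow(values) <= ncol(values) - 1`.
#'
#' Negative targets are realized by flipping the factor loading sign for the
#' second half of the rows, so cross-half pairs attain `target_rho` while
#' within-half pairs attain `|target_rho|` (a module in which every pair is
#' negatively correlated does not exist below `-1/(size - 1)`).
#'
#' @param values Numeric matrix, genes in rows, replicas in columns (>= 2).
#' @param target_rho Target correlation in `[-1, 1]`.
#' @param exact If `TRUE`, make sample correlations exactly `target_rho`.
#' @return A matrix of the same shape, same rownames.
#' @export
#' @examples
#' m <- matrix(rnorm(40, 100, 10), nrow = 4)
#' cor(t(plant_correlation(m, 1)))   # all 1
plant_correlation <- function(values, target_rho, exact = FALSE) {
  values <- as.matrix(values)
  n <- ncol(values)
  k <- nrow(values)
  if (n < 2) stop("at least 2 replicas are required", call. = FALSE)
  if (!is.finite(target_rho) || abs(target_rho) > 1)
    stop("`target_rho` must be in [-1, 1]", call. = FALSE)
  mu <- rowMeans(values)
  sd0 <- apply(values, 1, stats::sd)
  sd0[!is.finite(sd0) | sd0 == 0] <- abs(mu[!is.finite(sd0) | sd0 == 0]) * 0.05 + 1e-8
  signs <- rep(1, k)
  if (target_rho < 0 && k > 1) signs[seq(ceiling(k / 2) + 1, k)] <- -1
  rho <- abs(target_rho)

  if (exact) {
    if (k > n - 1)
      stop("exact mode needs nrow(values) <= ncol(values) - 1", call. = FALSE)
    # orthonormal basis of the centered sample space, then a square root of
    # the target correlation matrix C = (1 - rho) I + rho s s'
    base <- matrix(stats::rnorm(n * k), nrow = n)
    base <- sweep(base, 2, colMeans(base))
    base <- qr.Q(qr(base))[, seq_len(k), drop = FALSE]   # n x k, orthonormal
    cmat <- (1 - rho) * diag(k) + rho * (signs %o% signs)
    ev <- eigen(cmat, symmetric = TRUE)
    root <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) %*% t(ev$vectors)
    z <- root %*% t(base)                                 # k x n, sample-corr C
    z <- z / apply(z, 1, stats::sd)
  } else {
    f <- stats::rnorm(n)
    f <- (f - mean(f)) / stats::sd(f)   # keeps row means exact
    z0 <- (values - mu) / sd0
    z <- sqrt(1 - rho) * z0 + (signs * sqrt(rho)) %o% f
  }
  out <- mu + sd0 * z
  dimnames(out) <- dimnames(values)
  out
}

#' Simulate a two-condition, two-color spot-level microarray experiment
#'
#' Generates spot-level fluorescence tables for two conditions with known
#' ground truth.  Per gene and condition the true replicate signal is
#' log-normal around the condition mean at the gene's planted coefficient of
#' variation; each redundant spot realizes its own independent replicate
#' noise (matching the degrees-of-freedom bookkeeping `r = n_replicas * R - 1`
#' used downstream), except genes inside planted coordination modules, whose
#' replicate factor is shared across their spots so that gene-level
#' correlations hit the module target.  Replicas are laid out pairwise on
#' arrays (two samples per array, channels Cy3/Cy5) with a multiplicative
#' per (array, channel) scale and an additive background:
#' `fg = bg + scale * true_signal`.
#'
#' Corrupted spots are, with equal probability, flagged or given a foreground
#' below twice background in one random sample, so the validity filter of
#' [filter_valid_spots()] catches them.
#'
#' @param config A [sim_config()].
#' @return A list with
#' \describe{
#'   \item{spots}{tibble with columns `array_id`, `channel` (Cy3/Cy5),
#'     `spot_id`, `gene_id`, `replica_id`, `condition`, `fg`, `bg`, `flag`
#'     covering both conditions.}
#'   \item{truth}{list with `gene_means` (tibble gene x condition mean and
#'     planted cv), `deg` (tibble of planted DEGs with signed folds),
#'     `modules` (tibble gene_id, module, target_rho), `corrupt_spots`
#'     (character), and the `config`.}
#' }
#' @export
#' @examples
#' sim <- simulate_two_color(sim_config(n_genes = 20, seed = 7))
#' dplyr::count(sim$spots, condition)
simulate_two_color <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  nr <- config$n_replicas
  conds <- config$conditions
  gene_id <- sprintf("g%05d", seq_len(ng))
  rsp <- config$spots_per_gene

  cv <- stats::runif(ng, config$cv_range[1], config$cv_range[2])
  base_mean <- stats::rlnorm(ng, config$baseline_log_mean,
                             config$baseline_log_sd)

  n_deg <- round(config$deg_fraction * ng)
  deg_idx <- if (n_deg > 0) sample.int(ng, n_deg) else integer()
  fold <- stats::runif(n_deg, config$deg_fold_range[1],
                       config$deg_fold_range[2])
  up <- sample(c(TRUE, FALSE), n_deg, replace = TRUE)
  signed_fold <- ifelse(up, fold, -fold)

  mean_a <- base_mean
  mean_b <- base_mean
  if (n_deg > 0)
    mean_b[deg_idx] <- ifelse(up, base_mean[deg_idx] * fold,
                              base_mean[deg_idx] / fold)

  # assign module membership to non-DEG genes (keeps planted folds clean)
  mod_tbl <- NULL
  free <- setdiff(seq_len(ng), deg_idx)
  if (length(config$module_specs) > 0) {
    rows <- list()
    for (m in seq_along(config$module_specs)) {
      spec <- config$module_specs[[m]]
      if (spec$size > length(free))
        stop("not enough non-DEG genes left for module ", m, call. = FALSE)
      pick <- sample(free, spec$size)
      free <- setdiff(free, pick)
      rows[[m]] <- tibble::tibble(gene_idx = pick,
                                  module = paste0("mod", m),
                                  target_rho = spec$rho)
    }
    mod_tbl <- dplyr::bind_rows(rows)
  }

  # true replicate signal per (gene, spot, replica, condition)
  sim_condition <- function(means) {
    sig <- sqrt(log(1 + cv^2))
    vals <- vector("list", ng)
    for (i in seq_len(ng)) {
      z <- matrix(stats::rnorm(rsp[i] * nr), nrow = rsp[i])
      vals[[i]] <- means[i] * exp(sig[i] * z - sig[i]^2 / 2)
    }
    # module genes: shared replicate factor across spots, planted correlation
    if (!is.null(mod_tbl)) {
      for (mod in split(mod_tbl, mod_tbl$module)) {
        idx <- mod$gene_idx
        gm <- matrix(NA_real_, length(idx), nr)
        for (j in seq_along(idx))
          gm[j, ] <- means[idx[j]] *
            exp(sig[idx[j]] * stats::rnorm(nr) - sig[idx[j]]^2 / 2)
        gm <- plant_correlation(gm, mod$target_rho[1])
        gm[gm <= 0] <- min(gm[gm > 0], means[idx] * 1e-3)
        for (j in seq_along(idx))
          vals[[idx[j]]] <- matrix(rep(gm[j, ], each = rsp[idx[j]]),
                                   nrow = rsp[idx[j]])
      }
    }
    vals
  }

  spot_gene <- rep(seq_len(ng), times = rsp)
  spot_id <- sprintf("s%06d", seq_along(spot_gene))
  spot_within <- sequence(rsp)

  build_condition <- function(cond_i) {
    means <- if (cond_i == 1) mean_a else mean_b
    vals <- sim_condition(means)
    n_arrays <- ceiling(nr / 2)
    array_of_rep <- rep(seq_len(n_arrays), each = 2)[seq_len(nr)]
    channel_of_rep <- rep(c("Cy3", "Cy5"), n_arrays)[seq_len(nr)]
    scale <- exp(stats::rnorm(nr, 0, config$array_scale_sd))
    reps <- lapply(seq_len(nr), function(r) {
      truev <- unlist(lapply(seq_len(ng), function(i) vals[[i]][, r]))
      tibble::tibble(
        array_id = sprintf("%s_arr%d", conds[cond_i], array_of_rep[r]),
        channel = channel_of_rep[r],
        spot_id = spot_id,
        gene_id = gene_id[spot_gene],
        replica_id = sprintf("%s%d", conds[cond_i], r),
        condition = conds[cond_i],
        fg = config$background_mean + scale[r] * truev,
        bg = config$background_mean,
        flag = 0L
      )
    })
    dplyr::bind_rows(reps)
  }

  spots <- dplyr::bind_rows(build_condition(1), build_condition(2))

  # corruption: per corrupted spot, one random sample is flagged or dimmed
  n_corrupt <- round(config$corrupt_fraction * length(spot_id))
  corrupt_spots <- character()
  if (n_corrupt > 0) {
    corrupt_spots <- sort(sample(spot_id, n_corrupt))
    all_reps <- unique(spots$replica_id)
    hit_rep <- sample(all_reps, n_corrupt, replace = TRUE)
    by_flag <- stats::runif(n_corrupt) < 0.5
    key <- paste(spots$spot_id, spots$replica_id)
    hit <- match(paste(corrupt_spots, hit_rep), key)
    spots$flag[hit[by_flag]] <- 1L
    dim_i <- hit[!by_flag]
    spots$fg[dim_i] <- pmax(spots$bg[dim_i], 1) * 1.5
  }

  truth <- list(
    gene_means = tibble::tibble(
      gene_id = gene_id,
      !!conds[1] := mean_a, !!conds[2] := mean_b,
      cv = cv, spots = rsp
    ),
    deg = tibble::tibble(
      gene_id = gene_id[deg_idx],
      fold = signed_fold
    ),
    modules = if (is.null(mod_tbl)) {
      tibble::tibble(gene_id = character(), module = character(),
                     target_rho = numeric())
    } else {
      tibble::tibble(gene_id = gene_id[mod_tbl$gene_idx],
                     module = mod_tbl$module,
                     target_rho = mod_tbl$target_rho)
    },
    corrupt_spots = corrupt_spots,
    config = config
  )
  list(spots = spots, truth = truth)
}
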