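#' Read and write spot-level two-color microarray tables
#'
#' The on-disk dialect is fixed: UTF-8 tab-separated text with a header row
#' `array_id channel spot_id gene_id replica_id condition fg bg flag`,
#' `"."` as decimal mark, channels `Cy3`/`Cy5`.  Malformed rows are rejected
#' with line-numbered errors.
#'
#' @param path File path.
#' @param spots A spot tibble as produced by [simulate_two_color()] or
#'   [read_spot_table()].
#' @return `read_spot_table()` returns a tibble; `write_spot_table()` returns
#'   `path` invisibly.
#' @export
read_spot_table <- function(path) {
  cols <- c("array_id", "channel", "spot_id", "gene_id", "replica_id",
            "condition", "fg", "bg", "flag")
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      array_id = readr::col_character(), channel = readr::col_character(),
      spot_id = readr::col_character(), gene_id = readr::col_character(),
      replica_id = readr::col_character(), condition = readr::col_character(),
      fg = readr::col_double(), bg = readr::col_double(),
      flag = readr::col_integer()
    ),
    progress = FALSE, locale = readr::locale(decimal_mark = ".")
  )
  if (!identical(names(tbl), cols))
    stop("spot table must have columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0)
    stop("malformed spot table rows at lines: ",
         paste(utils::head(probs$row, 10), collapse = ", "), call. = FALSE)
  validate_spot_table(tbl)
  tbl
}

#' @rdname read_spot_table
#' @export
write_spot_table <- function(spots, path) {
  validate_spot_table(spots)
  readr::write_tsv(spots, path, progress = FALSE)
  invisible(path)
}

validate_spot_table <- function(spots) {
  need <- c("array_id", "channel", "spot_id", "gene_id", "replica_id",
            "condition", "fg", "bg", "flag")
  miss <- setdiff(need, names(spots))
  if (length(miss) > 0)
    stop("spot table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(spots$fg < 0, na.rm = TRUE) || any(spots$bg < 0, na.rm = TRUE))
    stop("fluorescence values must be >= 0", call. = FALSE)
  dup <- duplicated(spots[c("spot_id", "replica_id")])
  if (any(dup))
    stop("duplicated (spot_id, replica_id) rows", call. = FALSE)
  g_per_spot <- tapply(spots$gene_id, spots$spot_id,
                       function(g) length(unique(g)))
  if (any(g_per_spot > 1))
    stop("a spot_id maps to more than one gene_id", call. = FALSE)
  invisible(spots)
}

#' Spot validity filter across all profiled samples
#'
#' A spot is valid only if, in *every* profiled sample of the experiment, it
#' is unflagged and its foreground fluorescence is at least twice its
#' background.  A single failing sample disqualifies the spot everywhere
#' (validity is a per-spot, not per-sample, decision).  A foreground exactly
#' equal to twice the background is kept.  Spots missing from some samples
#' are treated as invalid and reported in the `missing` attribute.
#'
#' @param spots Spot tibble (both conditions; every sample of the design).
#' @return Character vector of valid `spot_id`s, with attributes
#'   `n_samples` (samples expected per spot) and `missing` (spot ids absent
#'   from some samples).
#' @export
#' @examples
#' sim <- simulate_two_color(sim_config(n_genes = 10, seed = 2))
#' length(filter_valid_spots(sim$spots))
filter_valid_spots <- function(spots) {
  validate_spot_table(spots)
  samples <- unique(spots$replica_id)
  n_samples <- length(samples)
  per <- spots |>
    dplyr::group_by(.data$spot_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      ok = all(.data$flag == 0 & .data$fg >= 2 * .data$bg),
      .groups = "drop"
    )
  missing <- per$spot_id[per$n < n_samples]
  valid <- per$spot_id[per$ok & per$n == n_samples]
  structure(sort(valid), n_samples = n_samples, missing = sort(missing))
}

#' Group spots probing the same gene
#'
#' Organizes the (typically pre-filtered) spot universe into redundancy
#' groups, one per gene, recording the member spots and the redundancy
#' `r_i` used downstream for degrees-of-freedom bookkeeping.
#'
#' @param spots Spot tibble.
#' @param valid Optional character vector of valid spot ids (from
#'   [filter_valid_spots()]); when given, only those spots are grouped.
#' @return Tibble with columns `gene_id`, `spot_ids` (list column) and `r`
#'   (member count); groups partition the retained spot universe.
#' @export
build_redundancy_groups <- function(spots, valid = NULL) {
  tbl <- dplyr::distinct(spots, .data$gene_id, .data$spot_id)
  if (!is.null(valid)) tbl <- dplyr::filter(tbl, .data$spot_id %in% valid)
  tbl |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(spot_ids = list(sort(.data$spot_id)),
                     r = dplyr::n(), .groups = "drop")
}

#' Read and write GMT gene-set files
#'
#' One set per line: `name<TAB>description<TAB>member1<TAB>member2...`.
#' Members are case-normalized (upper-cased) and deduplicated; empty lines
#' are skipped; a line with fewer than three fields is an error reported
#' with its line number.
#'
#' @param path File path.
#' @param genesets Named list of character vectors (an optional
#'   `descriptions` attribute, named like the list, is written back).
#' @return `read_gmt()` returns a named list of character vectors with a
#'   `descriptions` attribute; `write_gmt()` returns `path` invisibly.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("P1\tcomplement\tC3\tC1s\tc3", tf)
#' read_gmt(tf)$P1
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)))
  sets <- list()
  desc <- character()
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    members <- unique(toupper(trimws(fields[-(1:2)])))
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop("GMT line ", i, " has an empty member list", call. = FALSE)
    sets[[fields[1]]] <- members
    desc[fields[1]] <- fields[2]
  }
  structure(sets, descriptions = desc)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(genesets, path) {
  desc <- attr(genesets, "descriptions")
  lines <- vapply(names(genesets), function(nm) {
    d <- if (!is.null(desc) && !is.na(desc[nm])) desc[[nm]] else ""
    paste(c(nm, d, genesets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Minimal gene-by-sample expression matrix importer
#'
#' Reads a tab-separated expression matrix with a two-row header (condition,
#' then replica label) and gene ids in the first column, the format written
#' by [write_expression_matrix()].  Intended for externally normalized
#' matrices (e.g. a repository download) entering the pipeline after the
#' normalization stage.
#'
#' @param path File path.
#' @return Long tibble with columns `gene_id`, `condition`, `replica_id`,
#'   `value`.
#' @export
read_expression_matrix <- function(path) {
  hdr <- readLines(path, n = 2)
  cond <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]][-1]
  repl <- strsplit(hdr[2], "\t", fixed = TRUE)[[1]][-1]
  if (length(cond) != length(repl) || length(cond) == 0)
    stop("expression matrix header rows disagree", call. = FALSE)
  body <- utils::read.delim(path, skip = 2, header = FALSE,
                            colClasses = c("character",
                                           rep("numeric", length(cond))))
  if (ncol(body) != length(cond) + 1)
    stop("expression matrix body does not match its header", call. = FALSE)
  names(body) <- c("gene_id", paste(cond, repl, sep = "\r"))
  tibble::as_tibble(body) |>
    tidyr::pivot_longer(-"gene_id", names_to = c("condition", "replica_id"),
                        names_sep = "\r", values_to = "value")
}

#' @rdname read_expression_matrix
#' @param expr Long expression tibble (`gene_id`, `condition`, `replica_id`,
#'   `value`) such as from [aggregate_redundancy()].
#' @export
write_expression_matrix <- function(expr, path) {
  wide <- expr |>
    dplyr::arrange(.data$condition, .data$replica_id) |>
    tidyr::pivot_wider(id_cols = "gene_id",
                       names_from = c("condition", "replica_id"),
                       names_sep = "\r", values_from = "value")
  keys <- strsplit(names(wide)[-1], "\r", fixed = TRUE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste(c("condition", vapply(keys, `[`, "", 1)), collapse = "\t"),
    paste(c("replica", vapply(keys, `[`, "", 2)), collapse = "\t")
  ), con)
  utils::write.table(wide, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
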