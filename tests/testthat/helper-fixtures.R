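# small in-code fixtures

# long expression tibble from a gene x replica matrix
expr_from_matrix <- function(mat, condition = "CTR") {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("r%d", seq_len(ncol(mat)))
  tibble::tibble(
    gene_id = rep(rownames(mat), ncol(mat)),
    condition = condition,
    replica_id = rep(colnames(mat), each = nrow(mat)),
    value = as.vector(mat)
  )
}

# minimal spot table: one gene/one spot per row spec, constant across samples
make_spot_table <- function(n_spots = 10, n_reps = 4,
                            conditions = c("CTR", "ONC"),
                            fg = 1000, bg = 50) {
  grid <- expand.grid(spot = seq_len(n_spots),
                      rep = seq_len(n_reps),
                      cond = conditions, stringsAsFactors = FALSE)
  tibble::tibble(
    array_id = paste0(grid$cond, "_arr", ceiling(grid$rep / 2)),
    channel = c("Cy3", "Cy5")[(grid$rep - 1) %% 2 + 1],
    spot_id = sprintf("s%03d", grid$spot),
    gene_id = sprintf("g%03d", grid$spot),
    replica_id = paste0(grid$cond, grid$rep),
    condition = grid$cond,
    fg = fg, bg = bg, flag = 0L
  )
}
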