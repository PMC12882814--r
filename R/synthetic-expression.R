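# Synthetic expression matrices with a planted bimodal signature structure.

#' Configuration for a synthetic expression matrix
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param signature_genes gene ids carrying the planted program (must be a
#'   subset of `gene_1 .. gene_<n_genes>`; bare indices are accepted).
#' @param positive_fraction fraction of cells in the signature-positive
#'   class.
#' @param effect_size log-expression shift added to signature genes in
#'   positive cells; together with `noise_sd` it sets the separation of the
#'   two score modes.
#' @param noise_sd per-gene Gaussian dispersion of log expression.
#' @param seed integer seed.
#' @return an `expression_config` list.
#' @export
expression_config <- function(n_cells = 2000, n_genes = 300,
                              signature_genes = paste0("gene_", 1:20),
                              positive_fraction = 0.3,
                              effect_size = 1, noise_sd = 0.7, seed = 1L) {
  stop_if_not_scalar_number(n_cells, "n_cells", min = 1)
  stop_if_not_scalar_number(n_genes, "n_genes", min = 2)
  stop_if_not_scalar_number(positive_fraction, "positive_fraction", min = 0)
  if (positive_fraction > 1) stop("`positive_fraction` must be <= 1", call. = FALSE)
  stop_if_not_scalar_number(effect_size, "effect_size")
  stop_if_not_scalar_number(noise_sd, "noise_sd", min = 0)
  sig <- as.character(signature_genes)
  sig <- ifelse(grepl("^gene_", sig), sig, paste0("gene_", sig))
  if (length(sig) == 0L) stop("signature_genes must be non-empty", call. = FALSE)
  universe <- paste0("gene_", seq_len(n_genes))
  if (!all(sig %in% universe)) {
    stop("signature_genes must be within gene_1 .. gene_<n_genes>", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 signature_genes = sig, positive_fraction = positive_fraction,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "expression_config")
}

#' Generate a synthetic expression cell table
#'
#' Gene baselines are drawn uniformly on the log scale; a
#' `positive_fraction` of cells receives a `+effect_size` shift on the
#' signature genes. The ground-truth class is stored in the `truth`
#' attribute and as the `cell_type` column
#' (`"signature_pos"` / `"signature_neg"`).
#'
#' @param config an [expression_config()].
#' @return cell table with `cell_id`, `sample_id`, `x_um`, `y_um`,
#'   `cell_type` and `gene_*` columns; attribute `truth` is the logical
#'   positive-class vector.
#' @export
generate_expression <- function(config) {
  if (!inherits(config, "expression_config")) {
    stop("`config` must be created with expression_config()", call. = FALSE)
  }
  with_seed(config$seed, {
    n <- config$n_cells; g <- config$n_genes
    genes <- paste0("gene_", seq_len(g))
    mu <- runif(g, 0.5, 3)
    X <- matrix(rnorm(n * g, 0, config$noise_sd), n, g)
    X <- sweep(X, 2L, mu, "+")
    n_pos <- round(config$positive_fraction * n)
    pos <- seq_len(n) <= n_pos
    sig_idx <- match(config$signature_genes, genes)
    if (n_pos > 0L) {
      X[pos, sig_idx] <- X[pos, sig_idx] + config$effect_size
    }
    colnames(X) <- genes
    out <- data.frame(cell_id = paste0("c", seq_len(n)),
                      sample_id = "expr1",
                      x_um = runif(n, 0, 1000), y_um = runif(n, 0, 1000),
                      cell_type = ifelse(pos, "signature_pos", "signature_neg"),
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(X))
    attr(out, "truth") <- pos
    attr(out, "config") <- config
    out
  })
}
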