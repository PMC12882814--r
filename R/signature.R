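# Gene-signature scoring with expression-matched control genes and
# bimodal-threshold classification.
#
# A cell's score is the mean expression of the signature genes minus the
# mean expression of a pooled control set sampled, per signature gene, from
# genes of comparable dataset-mean expression (expression bins). Scores of
# signature-positive cells separate from the background as the upper mode of
# a bimodal distribution; classification thresholds sit in the valley
# (printed dialect cutoffs: 0.5 for the whole-panel scoring, 1.5 for the
# within-cDC scoring).

#' Score cells against a gene signature with matched controls
#'
#' @param expression cell table with `gene_*` expression columns (log scale).
#' @param signature character vector of gene ids (with or without the
#'   `gene_` column prefix). Genes absent from the panel are dropped with a
#'   message; at least one must remain.
#' @param n_bins number of expression bins for control matching (default 25).
#' @param ctrl_per_gene control genes sampled per signature gene from its
#'   bin (default 50; capped at bin size).
#' @param seed integer seed for control sampling.
#' @return a `score_result`: data.frame `cell_id`, `score`, `class`
#'   (`NA` until [threshold_classify()]), with attributes `signature_used`,
#'   `signature_missing`, `control_genes`, `n_bins`, `ctrl_per_gene`, `seed`.
#' @export
score_cells <- function(expression, signature, n_bins = 25, ctrl_per_gene = 50,
                        seed = NULL) {
  validate_cells(expression, require_type = FALSE)
  stop_if_not_scalar_number(n_bins, "n_bins", min = 1)
  stop_if_not_scalar_number(ctrl_per_gene, "ctrl_per_gene", min = 1)
  genes <- gene_columns(expression)
  if (length(genes) == 0L) stop("no gene_* expression columns", call. = FALSE)
  sig <- unique(ifelse(grepl("^gene_", signature), signature,
                       paste0("gene_", signature)))
  found <- intersect(sig, genes)
  missing <- setdiff(sig, genes)
  if (length(missing) > 0L) {
    message(sprintf("%d of %d signature genes not in the panel; dropped",
                    length(missing), length(sig)))
  }
  if (length(found) == 0L) {
    stop("no signature gene present in the expression panel", call. = FALSE)
  }
  pool_universe <- setdiff(genes, found)
  if (length(pool_universe) == 0L) {
    stop("signature covers the whole panel; no control genes available",
         call. = FALSE)
  }

  X <- as.matrix(expression[, genes, drop = FALSE])
  mode(X) <- "numeric"
  gmeans <- colMeans(X)
  # equal-occupancy bins by rank of dataset-mean expression
  br <- ceiling(rank(gmeans, ties.method = "first") / (length(genes) / n_bins))
  names(br) <- genes

  ctrl <- with_seed(seed, {
    picked <- character(0)
    for (g in found) {
      cand <- pool_universe[br[pool_universe] == br[g]]
      if (length(cand) == 0L) cand <- pool_universe
      k <- min(ctrl_per_gene, length(cand))
      picked <- c(picked, if (k == length(cand)) cand else sample(cand, k))
    }
    unique(picked)
  })

  score <- rowMeans(X[, found, drop = FALSE]) -
    rowMeans(X[, ctrl, drop = FALSE])
  out <- data.frame(cell_id = expression$cell_id, score = score,
                    class = NA_character_, stringsAsFactors = FALSE)
  attr(out, "signature_used") <- found
  attr(out, "signature_missing") <- missing
  attr(out, "control_genes") <- ctrl
  attr(out, "n_bins") <- n_bins
  attr(out, "ctrl_per_gene") <- ctrl_per_gene
  attr(out, "seed") <- seed
  class(out) <- c("score_result", "data.frame")
  out
}

#' Classify scores at a bimodal-valley cutoff
#'
#' Scores strictly above the cutoff are positive ("above" is strict: a
#' score equal to the cutoff is negative).
#'
#' @param scores a `score_result` (or data.frame with a `score` column).
#' @param cutoff score threshold (e.g. 0.5 or 1.5 depending on the scoring
#'   dialect).
#' @return `scores` with the `class` column filled
#'   (`"positive"`/`"negative"`).
#' @export
threshold_classify <- function(scores, cutoff) {
  stop_if_not_scalar_number(cutoff, "cutoff")
  check_columns(scores, "score", "scores")
  scores$class <- ifelse(scores$score > cutoff, "positive", "negative")
  attr(scores, "cutoff") <- cutoff
  scores
}

#' Locate the valley between the two largest modes of a score distribution
#'
#' Kernel-density estimate of the scores; returns the position of the
#' density minimum between the two highest local maxima. Useful when the
#' bimodal separation point is not known a priori.
#'
#' @param scores numeric vector or `score_result`.
#' @param bw bandwidth passed to [stats::density()] (default `"SJ"` with a
#'   fallback to the default rule).
#' @return the valley position, or `NA` when the density has fewer than two
#'   modes.
#' @export
find_score_valley <- function(scores, bw = "SJ") {
  x <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  d <- tryCatch(stats::density(x, bw = bw), error = function(e) stats::density(x))
  y <- d$y
  up <- diff(y) > 0
  peaks <- which(c(FALSE, up) & !c(up, FALSE))
  if (length(peaks) < 2L) return(NA_real_)
  top2 <- peaks[order(-y[peaks])][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(y[lo:hi]) - 1L
  d$x[valley]
}

#' Stimulatory and inhibitory program scores
#'
#' Two independent [score_cells()] runs on curated stimulatory and
#' inhibitory gene sets.
#'
#' @inheritParams score_cells
#' @param stimulatory,inhibitory gene sets (non-empty after intersection
#'   with the panel).
#' @return list with `stimulatory` and `inhibitory` `score_result`s.
#' @export
program_scores <- function(expression, stimulatory, inhibitory, seed = NULL) {
  list(
    stimulatory = score_cells(expression, stimulatory, seed = seed),
    inhibitory = score_cells(expression, inhibitory,
                             seed = if (is.null(seed)) NULL else seed + 1L)
  )
}
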