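# Graph-based neighborhood statistics: neighborhood composition matrices,
# permutation enrichment of a target type around selected cells, pairwise
# (asymmetric) enrichment z-scores, and group-level composition ratios.

#' Neighborhood composition matrix (nh_sum)
#'
#' For every cell, counts the cells of each type within graph distance `k`
#' ("cell layers"), excluding the cell itself. The `"all"` column is the
#' total neighborhood size and equals the row sum over type columns.
#'
#' @param cells cell table (`cell_id`, `cell_type`).
#' @param graph spatial igraph over the same cells (vertex names = cell ids).
#' @param k neighborhood radius in cell layers (default 5).
#' @return integer matrix, rows = cells (named), columns = cell types plus
#'   `"all"`.
#' @export
nh_sum <- function(cells, graph, k = 5) {
  stop_if_not_scalar_number(k, "k", min = 0)
  validate_cells(cells)
  vn <- igraph::V(graph)$name
  if (!setequal(vn, cells$cell_id)) {
    stop("graph vertices and cell ids do not match", call. = FALSE)
  }
  labels <- cells$cell_type[match(vn, cells$cell_id)]
  types <- sort(unique(labels))
  n <- length(vn)
  out <- matrix(0L, n, length(types) + 1L,
                dimnames = list(vn, c(types, "all")))
  if (k > 0) {
    nb <- igraph::ego(graph, order = k, nodes = igraph::V(graph), mindist = 1)
    for (i in seq_len(n)) {
      idx <- as.integer(nb[[i]])
      if (length(idx) == 0L) next
      tb <- tabulate(factor(labels[idx], levels = types), nbins = length(types))
      out[i, seq_along(types)] <- tb
      out[i, "all"] <- length(idx)
    }
  }
  out
}

#' Permutation test for neighborhood enrichment of a target type
#'
#' Quantifies whether `target_type` cells are enriched in the k-layer graph
#' neighborhoods of a selected cell set, against a null built by shuffling
#' the type labels of all non-selected cells (the selected cells' labels and
#' the graph stay fixed). The observed statistic is the mean per-cell
#' neighborhood density of the target type (count / neighborhood size,
#' averaged over selected cells); the enrichment score normalizes it to the
#' sample-level baseline density, the target-type fraction among
#' non-selected cells.
#'
#' @param cells cell table (`cell_id`, `cell_type`).
#' @param graph spatial igraph over the same cells.
#' @param selected character vector of selected cell ids (non-empty).
#' @param target_type the type whose enrichment is tested.
#' @param k neighborhood radius in cell layers (default 5).
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @param density `"mean_of_ratios"` (default: per-cell density averaged) or
#'   `"ratio_of_means"` (pooled counts / pooled sizes).
#' @param empty_neighborhood `"zero"` (default: cells with empty
#'   neighborhoods contribute density 0) or `"drop"`.
#' @return an `enrichment_result` list: `observed_density`, `baseline`,
#'   `score`, `null_scores` (length `n_perm`), `p_value`
#'   (add-one estimator `(1 + #[null >= observed]) / (1 + n_perm)`),
#'   `n_perm`, `seed`, `n_selected`.
#' @export
permutation_enrichment <- function(cells, graph, selected, target_type,
                                   k = 5, n_perm = 1000, seed = NULL,
                                   density = c("mean_of_ratios", "ratio_of_means"),
                                   empty_neighborhood = c("zero", "drop")) {
  density <- match.arg(density)
  empty_neighborhood <- match.arg(empty_neighborhood)
  validate_cells(cells)
  stop_if_not_scalar_number(n_perm, "n_perm", min = 1)
  selected <- as.character(selected)
  if (length(selected) == 0L) stop("`selected` must be non-empty", call. = FALSE)
  if (!all(selected %in% cells$cell_id)) {
    stop("unknown ids in `selected`", call. = FALSE)
  }
  if (!target_type %in% cells$cell_type) {
    stop(sprintf("target_type '%s' not present among cell types", target_type),
         call. = FALSE)
  }
  vn <- igraph::V(graph)$name
  if (!setequal(vn, cells$cell_id)) {
    stop("graph vertices and cell ids do not match", call. = FALSE)
  }
  labels <- cells$cell_type[match(vn, cells$cell_id)]
  n <- length(vn)
  sel_idx <- match(selected, vn)
  nonsel <- setdiff(seq_len(n), sel_idx)

  nb <- igraph::ego(graph, order = k, nodes = sel_idx, mindist = 1)
  nb <- lapply(nb, as.integer)
  sizes <- lengths(nb)
  if (empty_neighborhood == "drop") {
    keep <- sizes > 0L
    nb <- nb[keep]; sizes <- sizes[keep]
  }
  if (length(nb) == 0L) stop("no selected cell has a neighborhood", call. = FALSE)

  # incidence weights: rows = selected cells, one matvec gives all densities
  t0 <- as.numeric(labels == target_type)
  stat <- function(tvec_mat) {
    # tvec_mat: n x n_perm matrix of 0/1 target indicators
    counts <- matrix(0, length(nb), ncol(tvec_mat))
    for (i in seq_along(nb)) {
      idx <- nb[[i]]
      counts[i, ] <- if (length(idx) == 1L) tvec_mat[idx, ] else
        if (length(idx) > 1L) colSums(tvec_mat[idx, , drop = FALSE]) else 0
    }
    if (density == "mean_of_ratios") {
      dens <- counts / pmax(sizes, 1L)
      dens[sizes == 0L, ] <- 0
      colMeans(dens)
    } else {
      colSums(counts) / max(sum(sizes), 1L)
    }
  }

  observed_density <- stat(matrix(t0, ncol = 1L))[1L]
  baseline <- mean(t0[nonsel])

  null_scores <- rep(NA_real_, n_perm)
  null_density <- with_seed(seed, {
    P <- matrix(t0, n, n_perm)
    m <- length(nonsel)
    if (m > 1L) {
      for (b in seq_len(n_perm)) {
        P[nonsel, b] <- t0[nonsel][sample.int(m)]
      }
    }
    stat(P)
  })

  if (baseline > 0) {
    score <- observed_density / baseline
    null_scores <- null_density / baseline
    p_value <- (1 + sum(null_scores >= score - 1e-12)) / (1 + n_perm)
  } else {
    score <- NA_real_
    p_value <- NA_real_
  }

  structure(list(observed_density = observed_density, baseline = baseline,
                 score = score, null_scores = null_scores,
                 null_densities = null_density,
                 p_value = p_value, n_perm = as.integer(n_perm), seed = seed,
                 n_selected = length(sel_idx), target_type = target_type,
                 k = k, density = density),
            class = "enrichment_result")
}

#' Pairwise asymmetric neighborhood enrichment z-scores
#'
#' For every ordered type pair (source A, target B), the observed mean count
#' of B cells among the direct graph neighbors of A cells is compared with a
#' label-permutation null (all labels shuffled), yielding a z-score matrix
#' that is asymmetric by construction (the per-source normalization differs).
#' With `exclude_same_label` (default), edges between same-labelled cells are
#' ignored, so the diagonal contribution is zero -- the convention used when
#' enrichment should not be driven by cells of a type clustering with
#' themselves.
#'
#' @param cells cell table (`cell_id`, `cell_type`), with at least 2 types.
#' @param graph spatial igraph over the same cells.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param exclude_same_label ignore edges between same-labelled cells.
#' @return numeric types x types matrix of z-scores (rows = source A,
#'   columns = target B) with attributes `observed`, `null_mean`, `null_sd`,
#'   `degenerate` (logical per source type: singleton class or zero null
#'   variance).
#' @export
pairwise_enrichment <- function(cells, graph, n_perm = 1000, seed = NULL,
                                exclude_same_label = TRUE) {
  validate_cells(cells)
  vn <- igraph::V(graph)$name
  labels <- cells$cell_type[match(vn, cells$cell_id)]
  types <- sort(unique(labels))
  if (length(types) < 2L) stop("need at least 2 label classes", call. = FALSE)
  el <- igraph::as_edgelist(graph, names = FALSE)
  n <- length(vn)
  n_by_type <- function(L) tabulate(factor(L, levels = types), length(types))

  mean_counts <- function(L) {
    la <- factor(L[el[, 1L]], levels = types)
    lb <- factor(L[el[, 2L]], levels = types)
    tb <- table(la, lb)
    N <- unclass(tb) + t(unclass(tb)) # ordered neighbor pairs
    if (exclude_same_label) diag(N) <- 0
    sweep(N, 1L, pmax(n_by_type(L), 1L), "/")
  }

  obs <- mean_counts(labels)
  nulls <- with_seed(seed, {
    arr <- array(0, c(length(types), length(types), n_perm))
    for (b in seq_len(n_perm)) {
      arr[, , b] <- mean_counts(labels[sample.int(n)])
    }
    arr
  })
  mu <- apply(nulls, c(1L, 2L), mean)
  sdv <- apply(nulls, c(1L, 2L), stats::sd)
  z <- (obs - mu) / sdv
  z[sdv == 0] <- NA_real_
  dimnames(z) <- list(types, types)
  off_diag_zero_sd <- vapply(seq_along(types), function(i) {
    any(sdv[i, -i] == 0)
  }, logical(1L))
  degenerate <- n_by_type(labels) <= 1L | off_diag_zero_sd
  names(degenerate) <- types
  attr(z, "observed") <- obs
  attr(z, "null_mean") <- mu
  attr(z, "null_sd") <- sdv
  attr(z, "degenerate") <- degenerate
  z
}

#' Group-level neighborhood composition ratios
#'
#' Summarizes a neighborhood matrix `Y` (see [nh_sum()]) per cell group:
#' counts for each neighborhood type are summed over the group's cells and
#' normalized to the summed `"all"` column (with a pseudocount added before
#' normalization), and the same frequency is computed for all remaining
#' cells; the reported statistic is the ratio of the two -- the relative
#' enrichment or depletion of each neighborhood type around the group
#' compared with the rest of the population.
#'
#' @param Y neighborhood matrix with an `"all"` column and named rows.
#' @param groups named character/factor vector mapping cell ids to group
#'   labels (cells absent from `groups`, or `NA`, belong to no group but do
#'   count in the complement).
#' @param pseudocount added to numerator and denominator sums (default
#'   0.001).
#' @param normalize_type optional neighborhood type whose ratios are further
#'   divided by their mean across groups (to display between-group
#'   differences for that type).
#' @return numeric groups x neighborhood-type matrix of enrichment ratios.
#' @export
group_composition <- function(Y, groups, pseudocount = 0.001,
                              normalize_type = NULL) {
  if (!"all" %in% colnames(Y)) stop("`Y` must have an \"all\" column", call. = FALSE)
  if (is.null(names(groups))) stop("`groups` must be named by cell id", call. = FALSE)
  groups <- groups[!is.na(groups)]
  if (!all(names(groups) %in% rownames(Y))) {
    stop("`groups` names must be row names of Y", call. = FALSE)
  }
  glev <- sort(unique(as.character(groups)))
  types <- setdiff(colnames(Y), "all")
  out <- matrix(NA_real_, length(glev), length(types),
                dimnames = list(glev, types))
  for (g in glev) {
    ids <- names(groups)[groups == g]
    if (length(ids) == 0L) stop(sprintf("empty group '%s'", g), call. = FALSE)
    ing <- rownames(Y) %in% ids
    num_f <- (colSums(Y[ing, types, drop = FALSE]) + pseudocount) /
      (sum(Y[ing, "all"]) + pseudocount)
    den_f <- (colSums(Y[!ing, types, drop = FALSE]) + pseudocount) /
      (sum(Y[!ing, "all"]) + pseudocount)
    out[g, ] <- num_f / den_f
  }
  if (!is.null(normalize_type)) {
    if (!normalize_type %in% types) {
      stop(sprintf("normalize_type '%s' not a neighborhood type", normalize_type),
           call. = FALSE)
    }
    out[, normalize_type] <- out[, normalize_type] / mean(out[, normalize_type])
  }
  out
}
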