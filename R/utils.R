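# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic entry points route their randomness through this so that no
# call mutates global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_min && x <= min) {
    stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  }
  if (!strict_min && x < min) {
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing mandatory column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Validate a cell table (CellMap): cell_id, x_um, y_um, cell_type (+ optional
# sample_id and gene_* expression columns).
validate_cells <- function(cells, require_type = TRUE) {
  cols <- c("cell_id", "x_um", "y_um")
  if (require_type) cols <- c(cols, "cell_type")
  check_columns(cells, cols, "cell table")
  if (anyDuplicated(cells$cell_id)) {
    dup <- cells$cell_id[duplicated(cells$cell_id)][1L]
    stop(sprintf("duplicated cell_id: '%s'", dup), call. = FALSE)
  }
  if (!is.numeric(cells$x_um) || !is.numeric(cells$y_um) ||
      anyNA(cells$x_um) || anyNA(cells$y_um)) {
    stop("cell coordinates must be numeric and non-missing", call. = FALSE)
  }
  invisible(cells)
}

gene_columns <- function(cells) {
  grep("^gene_", names(cells), value = TRUE)
}
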