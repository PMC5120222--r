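# internal helpers shared across modules

LINEAGES <- c("EPI", "PrE", "DP", "DN")
CHANNELS <- c("gata6", "nanog")

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so library code never clobbers the caller's stream.
#' A `NULL` seed leaves the current stream untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic per-unit sub-seeds derived from a parent seed; kept below
# 2^31 so they remain valid R integers
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cells <- function(cells, cols = NULL) {
  if (!is.data.frame(cells)) stop("expected a cell table (data.frame)", call. = FALSE)
  need <- c("embryo_id", "cell_id", "z", "compartment", cols)
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    stop("cell table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(cells)
}
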