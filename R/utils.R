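#' Derive a reproducible child seed from a master seed
#'
#' One master seed fans out to per-stage, per-fold and per-permutation seeds
#' through a deterministic string hash, so that serial and parallel execution
#' of the resampling engines give identical results.
#'
#' @param seed Master seed (single integer).
#' @param ... Further tags (coerced to character) identifying the task, e.g.
#'   `derive_seed(7, "loocv", 12)`.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  tags <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                       character(1L)), collapse = "|")
  for (code in utf8ToInt(tags)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
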