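#' Derive a reproducible child seed from a parent seed and a path of labels
#'
#' Every stochastic operation in the package draws its randomness from a
#' child stream keyed by `(seed, stage name, indices...)`, so any single
#' scenario or replicate can be re-run independently of the others.
#'
#' @param seed Integer parent seed.
#' @param ... Labels (stage name, scenario index, iteration index, ...)
#'   coerced to character and folded into the hash.
#' @return An integer in `[0, 2^31)` suitable for [set.seed()].
#' @export
child_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                  character(1))
  h <- as.double(as.integer(seed) %% 2147483647)
  for (p in parts) {
    for (b in utf8ToInt(p)) h <- (h * 31 + b) %% 2147483629
  }
  as.integer(h)
}

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
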