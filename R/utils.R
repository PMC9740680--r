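# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the random seed, evaluates `expr`, and restores the caller's RNG
#' state afterwards, so seeded package functions never perturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a stage seed from a global seed
#'
#' Hashes the stage name together with the global seed so that every
#' pipeline stage gets its own reproducible stream and adding a stage never
#' perturbs the draws of earlier stages. Result is always a positive
#' integer below 2^31 - 1.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name (e.g. `"cohort"`, `"split"`).
#' @return Integer seed.
#' @export
#' @examples
#' derive_seed(1, "cohort")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647 # 2^31 - 1, keeps everything exact in doubles
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer((h * 1000003 + (as.numeric(seed) %% m)) %% m + 1)
}

# round-half-even at two decimals (R's default rounding mode)
round2 <- function(x) round(x, 2)

# truncate toward zero at two decimals; small epsilon guards against
# values such as 0.91 stored as 0.90999999...
trunc2 <- function(x) floor(x * 100 + 1e-9) / 100

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x) && x > 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a
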