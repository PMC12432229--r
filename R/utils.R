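#' @keywords internal
"_PACKAGE"

#' Derive a stage-specific random seed from a global seed
#'
#' All randomness in a pipeline run flows from one global seed. Per-stage seeds
#' are derived deterministically from the stage name so that changing one
#' stage's behaviour never perturbs the random stream of another.
#'
#' @param global_seed integer global seed.
#' @param stage character stage name, e.g. `"simulate"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(global_seed, stage) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(global_seed) %% 2147483647 * 2654435761 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
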