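# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operators do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a stream of sub-seeds from a master seed; kept below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_mc <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mammoconcord_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

VIEWS <- c("LCC", "RCC", "LMLO", "RMLO")
CATEGORIES <- c("missed", "prior_vis", "prior_invis")
LEVELS <- c("almost_perfect", "substantial", "moderate", "poor")
SIZE_GROUPS <- c("T1", "T2", "T3")

is_right_view <- function(view) view %in% c("RCC", "RMLO")
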