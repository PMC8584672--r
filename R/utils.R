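#' @keywords internal
"_PACKAGE"

## Internal numerical helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random stream set from `seed`, restoring the
#' previous stream afterwards so callers never perturb each other. A `NULL`
#' seed runs the code on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a named sub-seed from a master seed
#'
#' One master seed fans out to named streams (e.g. "data", "init", "gibbs",
#' "classifier") so individual pipeline stages can be re-run in isolation
#' while staying reproducible. The result is always a valid 32-bit seed.
#'
#' @param seed master integer seed.
#' @param name character stream label.
#' @return integer seed.
#' @export
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629L) + 1L
}

## Draw a {0,1} matrix of Bernoulli(prob) variables, prob a matrix.
sample_bernoulli <- function(prob) {
  out <- (matrix(stats::runif(length(prob)), nrow(prob), ncol(prob)) < prob) * 1
  out
}

stop_if_not_binary <- function(x, what = "patterns") {
  if (!all(x %in% c(0, 1))) {
    stop(sprintf("every entry of %s must be 0 or 1", what), call. = FALSE)
  }
}
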