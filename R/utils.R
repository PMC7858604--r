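#' @importFrom stats pf pt rnorm rbinom runif quantile sd var prcomp dist
#'   complete.cases phyper setNames
#' @importFrom utils head modifyList
NULL

# Classed conditions so callers/tests can distinguish failure modes.
pw_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "pairedEWAS_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

pw_warn <- function(msg, class = "pairedEWAS_warning") {
  warning(structure(
    class = c(class, "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic stream splitting: every generator seeds its own RNG stream
# derived from one root seed, so adding draws to one generator never perturbs
# another.  Sub-seeds follow a Lehmer step modulo the Mersenne prime 2^31-1,
# keeping them in valid 32-bit integer range.
sub_seed <- function(seed, stream) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  for (i in seq_len(stream)) s <- (s * 48271) %% m
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    pw_stop(sprintf("'%s' must be a single proportion in [0, 1], got %s",
                    name, deparse(x)), "pairedEWAS_config_error")
  }
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    pw_stop(sprintf("'%s' must be a single integer >= %d, got %s",
                    name, min, deparse(x)), "pairedEWAS_config_error")
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    pw_stop(sprintf("'%s' must be a single positive number, got %s",
                    name, deparse(x)), "pairedEWAS_config_error")
  }
  x
}

# Percentage helpers matching the two reporting styles used in results
# tables: one decimal for score tables, integer percent for prose summaries.
pct1 <- function(num, den) {
  if (den == 0) return(NA_real_)
  round(100 * num / den, 1)
}

pct0 <- function(num, den) {
  if (den == 0) return(NA_real_)
  round(100 * num / den)
}
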