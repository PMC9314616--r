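#' @keywords internal
"_PACKAGE"

# Deterministic seed fan-out: derive a child RNG seed from (seed, index, salt)
# using a multiplicative hash kept below 2^31 - 1. Doubles are exact up to
# 2^53, so the intermediate products never lose integer precision.
derive_seed <- function(seed, index, salt = 0L) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 +
    as.numeric(index) * 16807 +
    as.numeric(salt) * 69621
  as.integer(s %% 2147483629) + 1L
}

# Run `expr` under set.seed(seed) without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

check_probability <- function(p, what = "probability") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(what, " must be a single number in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

check_count <- function(n, what = "count", min = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < min ||
      n != as.integer(n)) {
    stop(what, " must be a single integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(n))
}
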