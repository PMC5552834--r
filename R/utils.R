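# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All randomised operations in the package go
# through this, which is what makes every exported operation a pure function of
# its seed argument.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic combination of two seeds into a valid 32-bit seed. Used to give
# sub-streams (folds within repetitions, missingness within a cohort) their own
# reproducible seeds without RNG state bleeding between stages.
mix_seed <- function(a, b) {
  s <- (abs(as.double(a)) * 7919 + abs(as.double(b)) * 104729 + 1) %% 2147483629
  as.integer(s)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Sample standard deviation (n-1 denominator) without stats::sd's overhead on
# matrices; x is a numeric vector.
sd1 <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))

is_binary01 <- function(y) all(y %in% c(0L, 1L))

# Coerce an outcome vector to the +/-1 encoding used by the least-squares
# classifier: 0/1 and logical are re-coded; any other numeric vector is passed
# through unchanged (the solver is plain penalised least squares, so
# continuous regression targets are admissible).
as_pm1 <- function(y) {
  if (is.logical(y)) return(2 * as.numeric(y) - 1)
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) return(2 * y - 1)
  y
}

# Coerce to 0/1 integer.
as_01 <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  y <- as.numeric(y)
  if (all(y %in% c(-1, 1))) return(as.integer(y == 1))
  if (all(y %in% c(0, 1))) return(as.integer(y))
  stopf("outcome must be coded 0/1 or -1/+1")
}
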