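# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never disturbs the
# user's RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit hash of strings, used to derive per-cell seeds so
# that every cell of the comparison matrix is reproducible in isolation and
# independent of evaluation order.
str_seed <- function(...) {
  s <- paste(c(...), collapse = "")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

cell_seed <- function(global_seed, left_id, right_id) {
  as.integer((as.numeric(global_seed) %% 2147483647 +
                str_seed(left_id, right_id)) %% 2147483647)
}

cross3 <- function(a, b) {
  # row-wise cross product of n x 3 matrices
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
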