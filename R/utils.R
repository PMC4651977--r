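# internal helpers: RNG scoping, sub-seed derivation, validation

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  All stochastic stages run inside this
# so that cohorts are bit-reproducible and independent of ambient RNG use.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
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
  force(code)
}

# Derive a stream of child seeds from a parent seed.  Keeps every derived
# seed in [0, 2^31 - 2] so set.seed() always accepts it.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.numeric(seed) %% 2147483647
  for (k in idx) {
    x <- (x * 48271 + as.numeric(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).", name,
      if (strict_min) "(" else "[", format(min),
      format(max), if (strict_max) ")" else "]", x
    ))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}

# cheap condition estimate of R'R from its Cholesky factor
rcond_from_chol <- function(ch) {
  dg <- diag(ch)^2
  min(dg) / max(dg)
}

# mode of an integer vector with deterministic ties: smallest class code wins
# among the modal codes, after reordering by `prefer` (a vector of codes in
# priority order)
modal_code <- function(codes, prefer) {
  tab <- table(factor(codes, levels = prefer))
  prefer[which.max(tab)]
}
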