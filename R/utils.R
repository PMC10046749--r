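# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed (if any) is restored afterwards so library code never
# perturbs user-level randomness.
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
  expr
}

# Deterministically fold a base seed and arbitrary strings into a 32-bit
# seed (always in [1, 2^31 - 2]).  Plain polynomial string hash in double
# precision modulo a Mersenne prime, so identical inputs always map to the
# same stream and nearby inputs map far apart.
derive_seed <- function(base_seed, ...) {
  mod <- 2147483647
  h <- as.numeric(base_seed) %% mod
  for (s in as.character(c(...))) {
    for (code in utf8ToInt(s)) {
      h <- (h * 131 + code) %% mod
    }
    h <- (h * 131 + 7) %% mod
  }
  as.integer(h %% (mod - 2)) + 1L
}

stop_named <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

assert_scalar_number <- function(x, name) {
  if (!is_scalar_number(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Linear-interpolation resampling matrix: W %*% v resamples a length
# `n_in` vector onto `n_out` points spanning the same support.  Used to
# rescale scalogram magnitudes to a fixed image size.
interp_matrix <- function(n_in, n_out) {
  if (n_in == 1L) {
    return(matrix(1, nrow = n_out, ncol = 1L))
  }
  pos <- seq(1, n_in, length.out = n_out)
  lo <- pmin(floor(pos), n_in - 1L)
  frac <- pos - lo
  W <- matrix(0, nrow = n_out, ncol = n_in)
  idx <- seq_len(n_out)
  W[cbind(idx, lo)] <- 1 - frac
  W[cbind(idx, lo + 1L)] <- W[cbind(idx, lo + 1L)] + frac
  W
}
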