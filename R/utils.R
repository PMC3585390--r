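# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. With seed = NULL the global stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.finite(seed) || seed != round(seed))
    stop("seed must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stationary unit-variance AR(1) sample of length n with correlation time
# tau_s at sampling interval dt_s.
ar1_process <- function(n, tau_s, dt_s) {
  phi <- exp(-dt_s / tau_s)
  x <- numeric(n)
  x[1L] <- stats::rnorm(1L)
  innov <- stats::rnorm(n - 1L, sd = sqrt(1 - phi^2))
  for (i in seq_len(n - 1L)) x[i + 1L] <- phi * x[i] + innov[i]
  x
}

# Full-precision numeric CSV writer: doubles are serialized with "%.17g" so a
# write/read round trip reproduces them bit for bit.
write_csv_exact <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

# Smoothstep sigmoid: exactly 0 for t <= t0, exactly 1 for t >= t0 + dur,
# C1-smooth cubic in between. Unlike a logistic it has no tails, so a
# stimulus gate cannot leak into the preceding baseline regime.
smoothstep <- function(t, t0, dur) {
  u <- pmin(1, pmax(0, (t - t0) / dur))
  u * u * (3 - 2 * u)
}

upper_pairs <- function(n) {
  # unordered index pairs i < j as a 2-column matrix
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}
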