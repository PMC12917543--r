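#' @include AllClasses.R
NULL

# Derive a child RNG seed from a base seed and a stream index; keeps results
# independent of evaluation order and below 2^31.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 11) %%
               2147483629)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# 1/f-amplitude ("pink", power slope -1) Gaussian noise via spectral shaping.
pinkNoise <- function(n, rate) {
  m <- n + (n %% 2L)
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- c(1, seq_len(m - 1)) * (rate / m)  # guard DC
  shape <- 1 / sqrt(f)
  shape[1] <- 0                            # remove DC
  # keep Hermitian symmetry so the inverse transform is real
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / m
  y <- y[seq_len(n)]
  y / stats::sd(y)
}

# Uniform random 3D rotation matrix (quaternion method).
randomRotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    nq <- sqrt(sum(q^2))
    if (nq > 1e-12) break
  }
  q <- q / nq
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Rows normalized to unit length.
normalizeRows <- function(m) m / sqrt(rowSums(m^2))

stopIfNot <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
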