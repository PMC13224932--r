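# Internal helpers shared across modules.

# Validation errors carry a specific class plus "lutadosim_validation" so the
# CLI can map them onto a dedicated exit code.
ld_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "lutadosim_validation", "error", "condition")))
}

ld_assert <- function(ok, msg, class) {
  if (!isTRUE(ok)) ld_abort(msg, class)
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Trapezoidal quadrature on an (x, y) grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Linear-up/log-down trapezoid: logarithmic interpolation on strictly
# declining positive segments, linear elsewhere.
auc_lin_log <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  dx <- x[-1] - x[-n]
  y1 <- y[-n]; y2 <- y[-1]
  logdown <- y2 < y1 & y2 > 0
  seg <- ifelse(logdown,
                dx * (y1 - y2) / log(pmax(y1, 1e-300) / pmax(y2, 1e-300)),
                dx * (y1 + y2) / 2)
  sum(seg)
}

# Inverse-CDF sampler for a normal truncated to [lower, upper]; deterministic
# given the RNG state, no rejection loop.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Multiplicative residual factors for the dosimetry models.
# "proportional": 1 + b * eps with negative factors resampled (truncation);
# "lognormal": exp(s * z) with s chosen so the CV matches b (median-preserving).
residual_factors <- function(n, b, model = c("proportional", "lognormal")) {
  model <- match.arg(model)
  if (b == 0) return(rep(1, n))
  if (model == "lognormal") {
    s <- sqrt(log(1 + b^2))
    return(exp(s * rnorm(n)))
  }
  f <- 1 + b * rnorm(n)
  bad <- which(f < 0)
  while (length(bad) > 0L) {
    f[bad] <- 1 + b * rnorm(length(bad))
    bad <- bad[f[bad] < 0]
  }
  f
}

# Central-difference Hessian of a scalar function; used for observed Fisher
# information (no external numerical-derivative dependency).
num_hessian <- function(fn, x, rel_h = 1e-4) {
  p <- length(x)
  h <- rel_h * pmax(abs(x), 1e-3)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <- (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# SEs from the observed Fisher information (Hessian of the negative
# log-likelihood); returns NA where the information matrix is singular.
se_from_hessian <- function(H) {
  out <- rep(NA_real_, nrow(H))
  cov <- try(solve(H), silent = TRUE)
  if (!inherits(cov, "try-error")) {
    v <- diag(cov)
    ok <- is.finite(v) & v > 0
    out[ok] <- sqrt(v[ok])
  }
  out
}

# Percentile-based bin assignment with merging of under-filled bins.
quantile_bins <- function(x, n_bins, min_per_bin = 1L) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1), type = 7))
  if (length(br) < 3L) return(rep(1L, length(x)))
  idx <- as.integer(cut(x, breaks = br, include.lowest = TRUE))
  # merge sparse bins into their left neighbour
  repeat {
    cnt <- tabulate(idx, nbins = max(idx))
    small <- which(cnt > 0 & cnt < min_per_bin)
    if (length(small) == 0L) break
    k <- small[1]
    idx[idx == k] <- if (k == 1L) 2L else k - 1L
    idx <- match(idx, sort(unique(idx)))
  }
  match(idx, sort(unique(idx)))
}
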