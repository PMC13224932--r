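# Independent oracles used across the suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Numerical ODE integration of the two-compartment system with zero-order
# input (central A1, peripheral A2, cumulative eliminated E). Independent of
# the closed-form solution under test.
ode_oracle <- function(params, doses, times, amount_scale = 1,
                       rtol = 1e-11, atol = 1e-14) {
  amt <- doses$amount * amount_scale
  starts <- doses$start_time
  ends <- doses$start_time + doses$duration
  rates <- amt / doses$duration
  k10 <- params$cl / params$vc
  k12 <- params$q / params$vc
  k21 <- params$q / params$vp
  # integrate segment by segment so the input rate is constant (smooth RHS)
  # within every deSolve call
  brk <- sort(unique(c(0, starts, ends, times)))
  state <- c(A1 = 0, A2 = 0, E = 0)
  sol <- matrix(0, length(brk), 3, dimnames = list(NULL, names(state)))
  for (i in seq_len(length(brk) - 1)) {
    t0 <- brk[i]; t1 <- brk[i + 1]
    r <- sum(rates[t0 >= starts - 1e-12 & t0 < ends - 1e-12])
    rhs <- function(t, y, parms) {
      list(c(r - (k10 + k12) * y[1] + k21 * y[2],
             k12 * y[1] - k21 * y[2],
             k10 * y[1]))
    }
    out <- deSolve::ode(state, c(t0, t1), rhs, NULL, rtol = rtol, atol = atol)
    state <- out[2, c("A1", "A2", "E")]
    sol[i + 1, ] <- state
  }
  idx <- match(times, brk)
  list(conc = sol[idx, "A1"] / params$vc,
       a1 = sol[idx, "A1"], a2 = sol[idx, "A2"], elim = sol[idx, "E"])
}

# Adaptive Gauss-Hermite quadrature of the marginal likelihood (-2 log L),
# fully independent of the compiled Laplace path: predictions come from the
# ODE oracle and the conditional mode is found with stats::optim.
agq_neg2ll <- function(model, data, n_nodes = 9) {
  gh <- pracma::gaussHermite(n_nodes)
  om <- matrix(c(model$omega_cl^2,
                 model$rho * model$omega_cl * model$omega_vc,
                 model$rho * model$omega_cl * model$omega_vc,
                 model$omega_vc^2), 2, 2)
  oinv <- solve(om)
  sig <- model$sigma_add
  total <- 0
  for (sid in data$subjects$id) {
    obs <- data$observations[data$observations$id == sid, ]
    dos <- data$doses[data$doses$id == sid, ]
    g <- function(eta) {
      p_i <- pk_params(model$theta$cl * exp(eta[1]),
                       model$theta$vc * exp(eta[2]),
                       model$theta$q, model$theta$vp)
      pred <- ode_oracle(p_i, dos, obs$time,
                         amount_scale = data$amount_scale)$conc
      pred <- pmax(pred, 0)
      r <- obs$conc - pred
      sum(0.5 * log(2 * pi * sig^2) + r^2 / (2 * sig^2) +
            pnorm(pred / sig, log.p = TRUE)) +
        log(2 * pi) + 0.5 * log(det(om)) +
        0.5 * drop(t(eta) %*% oinv %*% eta)
    }
    opt <- optim(c(0, 0), g, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 500))
    mode <- opt$par
    h <- 1e-3
    g0 <- opt$value
    H <- matrix(0, 2, 2)
    H[1, 1] <- (g(mode + c(h, 0)) - 2 * g0 + g(mode - c(h, 0))) / h^2
    H[2, 2] <- (g(mode + c(0, h)) - 2 * g0 + g(mode - c(0, h))) / h^2
    H[1, 2] <- H[2, 1] <-
      (g(mode + c(h, h)) - g(mode + c(h, -h)) -
         g(mode + c(-h, h)) + g(mode + c(-h, -h))) / (4 * h^2)
    L <- t(chol(solve(H)))
    lognode <- matrix(NA_real_, n_nodes, n_nodes)
    for (i in seq_len(n_nodes)) {
      for (j in seq_len(n_nodes)) {
        z <- c(gh$x[i], gh$x[j])
        eta <- mode + sqrt(2) * as.numeric(L %*% z)
        lognode[i, j] <- log(gh$w[i]) + log(gh$w[j]) + sum(z^2) - g(eta)
      }
    }
    m <- max(lognode)
    logL <- log(2) + log(abs(det(L))) + m + log(sum(exp(lognode - m)))
    total <- total - 2 * logL
  }
  total
}

# Random but well-conditioned disposition parameter draws.
random_pk_params <- function() {
  repeat {
    p <- try(pk_params(cl = exp(runif(1, log(0.5), log(20))),
                       vc = exp(runif(1, log(5), log(80))),
                       q = exp(runif(1, log(0.5), log(20))),
                       vp = exp(runif(1, log(20), log(500)))),
             silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
}

# Small two-subject dataset used by the IO tests.
toy_pk_dataset <- function() {
  subjects <- tibble::tibble(id = c("A", "B"), age = c(50, 60),
                             weight = c(70, 80), crcl = c(90, 110),
                             sex = c("F", "M"), study = c("adult", "adult"))
  doses <- tibble::tibble(id = c("A", "B"), amount = c(7.4, 7.4),
                          start_time = c(0, 0), duration = c(0.5, 0.5))
  obs <- tibble::tibble(id = rep(c("A", "B"), each = 2),
                        time = c(1, 24, 1, 24),
                        conc = c(5.1, 0.8, 4.7, 0.9))
  pk_dataset(subjects, doses, obs, amount_scale = 1000)
}
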