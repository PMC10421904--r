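# Adaptive explicit Runge-Kutta integration (Dormand-Prince 5(4)) for the
# three-species model, with a backward-Euler fallback should the step size
# ever collapse (the system is non-stiff at reference parameters, so the
# fallback is a safety net, not the workhorse).

# Dormand-Prince tableau
.dp_c <- c(0, 1/5, 3/10, 4/5, 8/9, 1, 1)
.dp_a <- list(
  NULL,
  c(1/5),
  c(3/40, 9/40),
  c(44/45, -56/15, 32/9),
  c(19372/6561, -25360/2187, 64448/6561, -212/729),
  c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
  c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84))
.dp_b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
.dp_b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)

# Integrate y' = f(t, y) from t0 to t1, returning the state at each time in
# t_eval (strictly increasing, within [t0, t1]). Steps land exactly on each
# requested output time, so no interpolation error enters the samples.
.rk45 <- function(f, y0, t0, t1, t_eval, rtol = 1e-8, atol = 1e-10,
                  max_steps = 200000L) {
  stopifnot(t1 > t0)
  ny <- length(y0)
  out <- matrix(NA_real_, nrow = length(t_eval), ncol = ny)
  t <- t0; y <- y0
  k <- matrix(0, nrow = ny, ncol = 7)
  k[, 1] <- f(t, y)
  h <- (t1 - t0) / 100
  hmin <- max(1e-14, (t1 - t0) * 1e-13)
  i_eval <- 1L
  while (i_eval <= length(t_eval) && t_eval[i_eval] <= t0 + hmin) {
    out[i_eval, ] <- y
    i_eval <- i_eval + 1L
  }
  steps <- 0L
  while (i_eval <= length(t_eval)) {
    target <- t_eval[i_eval]
    h <- min(h, target - t)
    if (steps >= max_steps)
      stop("ODE integration exceeded the step budget on [",
           format(t), ", ", format(target), "]", call. = FALSE)
    if (h < hmin) {
      # step-size collapse: hand the subinterval to the implicit fallback
      y <- .backward_euler(f, y, t, target, rtol = rtol, atol = atol)
      t <- target
      k[, 1] <- f(t, y)
      out[i_eval, ] <- y
      i_eval <- i_eval + 1L
      h <- (t1 - t0) / 100
      next
    }
    for (s in 2:7) {
      acc <- y
      a <- .dp_a[[s]]
      for (j in seq_along(a)) acc <- acc + h * a[j] * k[, j]
      k[, s] <- f(t + .dp_c[s] * h, acc)
    }
    y5 <- y + h * drop(k %*% .dp_b5)
    y4 <- y + h * drop(k %*% .dp_b4)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    steps <- steps + 1L
    if (!is.finite(err)) {
      h <- h / 2
      next
    }
    if (err <= 1) {
      t <- t + h
      y <- y5
      k[, 1] <- k[, 7]  # FSAL
      while (i_eval <= length(t_eval) &&
             abs(t - t_eval[i_eval]) <= hmin) {
        out[i_eval, ] <- y
        i_eval <- i_eval + 1L
      }
    }
    fac <- if (err == 0) 5 else 0.9 * err^(-0.2)
    h <- h * min(5, max(0.2, fac))
  }
  out
}

# Adaptive backward Euler with Newton iteration on the 3x3 system; only
# invoked if the explicit integrator's step collapses.
.backward_euler <- function(f, y0, t0, t1, rtol = 1e-8, atol = 1e-10) {
  t <- t0; y <- y0
  h <- (t1 - t0) / 1000
  while (t < t1 - 1e-14 * max(1, abs(t1))) {
    h <- min(h, t1 - t)
    step_once <- function(hh, ystart) {
      yn <- ystart
      for (it in 1:50) {
        Fv <- yn - ystart - hh * f(t + hh, yn)
        if (max(abs(Fv)) < 1e-12 * max(1, max(abs(yn)))) break
        J <- .num_jacobian(function(z) z - ystart - hh * f(t + hh, z), yn)
        yn <- yn - solve(J, Fv)
      }
      yn
    }
    y_full <- step_once(h, y)
    y_half <- step_once(h / 2, y)
    y_half <- { t2 <- t; t <- t + h / 2; r <- step_once(h / 2, y_half); t <- t2; r }
    sc <- atol + rtol * pmax(abs(y), abs(y_full))
    err <- max(abs(y_full - y_half) / sc)
    if (is.finite(err) && err <= 1) {
      t <- t + h
      y <- y_half
      h <- h * min(4, max(0.25, 0.9 / sqrt(max(err, 1e-10))))
    } else {
      h <- h / 2
      if (h < 1e-15)
        stop("implicit fallback failed on [", format(t), ", ",
             format(t1), "]", call. = FALSE)
    }
  }
  y
}

.num_jacobian <- function(g, x, eps = 1e-7) {
  g0 <- g(x)
  J <- matrix(0, length(g0), length(x))
  for (j in seq_along(x)) {
    dx <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + dx
    J[, j] <- (g(xp) - g0) / dx
  }
  J
}
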