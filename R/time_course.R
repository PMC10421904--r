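#' Integrate the model under a salt protocol
#'
#' Adaptive Runge-Kutta (Dormand-Prince 5(4)) integration of the
#' three-species system under piecewise-constant salt forcing. Integration
#' is restarted at every protocol breakpoint so the forcing discontinuity is
#' resolved exactly; output is sampled on a uniform time grid.
#'
#' @param params a `mirsalt_params` object.
#' @param genotype a `mirsalt_genotype` or genotype name.
#' @param protocol a `mirsalt_protocol` (see [salt_protocol()]).
#' @param t_end final time (> 0), in model time units.
#' @param init initial state `(CK, PHB, miR166)`.
#' @param n_samples number of uniformly spaced output times on `[0, t_end]`
#'   (default 501).
#' @param rtol,atol relative and absolute integration tolerances.
#' @return A `mirsalt_trajectory`: list with `times`, a `states` matrix
#'   (columns `CK`, `PHB`, `miR166`), the applied `salt` level per sample,
#'   `protocol` and `genotype`. Convert with `as.data.frame()`.
#' @examples
#' tr <- simulate_model(model_parameters(), "wild_type",
#'                      protocol = constant_salt(0.5), t_end = 10,
#'                      init = c(1, 1, 1), n_samples = 51)
#' head(as.data.frame(tr))
#' @export
simulate_model <- function(params, genotype = "wild_type",
                           protocol = constant_salt(0),
                           t_end, init, n_samples = 501L,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "mirsalt_params"),
            inherits(protocol, "mirsalt_protocol"))
  g <- .as_genotype(genotype)
  if (!is.finite(t_end) || t_end <= 0)
    stop("t_end must be positive", call. = FALSE)
  init <- .check_state(init)
  if (n_samples < 2L)
    stop("n_samples must be >= 2", call. = FALSE)
  times <- seq(0, t_end, length.out = n_samples)
  states <- .integrate_protocol(params, g, protocol, times, init,
                                rtol = rtol, atol = atol)
  colnames(states) <- c("CK", "PHB", "miR166")
  structure(list(times = times, states = states,
                 salt = salt_at(protocol, times),
                 protocol = protocol, genotype = g,
                 params = params),
            class = "mirsalt_trajectory")
}

# Integrate over arbitrary (sorted, >=0) output times, restarting at each
# protocol breakpoint. Returns a matrix of states, one row per time.
.integrate_protocol <- function(params, g, protocol, times, init,
                                rtol = 1e-8, atol = 1e-10) {
  m <- g$dPHBmiR_multiplier
  t_end <- max(times)
  brk <- protocol$start_times
  brk <- sort(unique(c(brk[brk > 0 & brk < t_end], t_end)))
  out <- matrix(NA_real_, nrow = length(times), ncol = 3L)
  if (times[1] == 0) out[times == 0, ] <- rep(init, each = sum(times == 0))
  t0 <- 0; y <- as.numeric(init)
  for (t1 in brk) {
    salt <- salt_at(protocol, t0)
    f <- function(t, y) .rhs_fast(y, params, salt, m)
    sel <- which(times > t0 & times <= t1)
    te <- unique(c(times[sel], t1))
    res <- .rk45(f, y, t0, t1, te, rtol = rtol, atol = atol)
    if (length(sel)) out[sel, ] <- res[seq_along(sel), , drop = FALSE]
    y <- res[nrow(res), ]
    t0 <- t1
  }
  out
}

#' @export
as.data.frame.mirsalt_trajectory <- function(x, ...) {
  data.frame(time = x$times,
             CK = x$states[, "CK"],
             PHB = x$states[, "PHB"],
             miR166 = x$states[, "miR166"],
             salt = x$salt)
}

#' @export
print.mirsalt_trajectory <- function(x, ...) {
  cat("<mirsalt_trajectory>", x$genotype$name, "|",
      length(x$times), "samples on [0,", format(max(x$times)), "]\n")
  cat("final state:", paste(colnames(x$states),
                            format(x$states[nrow(x$states), ], digits = 6),
                            collapse = "  "), "\n")
  invisible(x)
}

#' The reference salt-step experiment
#'
#' Convenience wrapper for the published in-silico perturbation: start from
#' the salt = 0 steady state of the given genotype, step salt to 0.5 at time
#' 0, and integrate for 50 time units. In the wild type miR165/166 falls,
#' de-repressing PHB and driving cytokinin up; in `phb_1d` the PHB and CK
#' trajectories stay flat (salt resistance).
#'
#' @inheritParams simulate_model
#' @param salt_after post-step salt level (default 0.5).
#' @param t_end total simulated time (default 50).
#' @return A `mirsalt_trajectory`.
#' @examples
#' tr <- salt_step_experiment(model_parameters(), "wild_type")
#' tail(as.data.frame(tr), 1)
#' @export
salt_step_experiment <- function(params = model_parameters(),
                                 genotype = "wild_type",
                                 salt_after = 0.5, t_end = 50,
                                 n_samples = 501L) {
  g <- .as_genotype(genotype)
  ss <- find_steady_state(params, salt = 0, genotype = g)
  simulate_model(params, g, protocol = salt_step(0, salt_after, t_step = 0),
                 t_end = t_end, init = ss$state, n_samples = n_samples)
}
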