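#' Solve for a steady state of the model
#'
#' Finds a state where all three time derivatives vanish. The solver runs a
#' damped fixed-point iteration on the steady-state relations (cheap and
#' robust because at `n = 1` the system is nearly triangular: miR and PHB
#' are explicit in CK, and CK in PHB), then polishes the result with Newton
#' iterations on the full right-hand side.
#'
#' @param params a `mirsalt_params` object.
#' @param salt nonnegative salt level.
#' @param genotype a `mirsalt_genotype` or genotype name.
#' @param tol convergence tolerance on the max-norm of the right-hand side
#'   (default 1e-10).
#' @param init optional initial guess; default `(1, 1, 1)`.
#' @param max_iter fixed-point iteration budget.
#' @param polish run the Newton polishing stage (default `TRUE`); disable
#'   to inspect the raw fixed-point iterate, e.g. when diagnosing
#'   convergence failures.
#' @return A list of class `mirsalt_steady` with `state` (named vector),
#'   `residual` (max-norm of the RHS), `converged`, and `iterations`.
#' @section Errors: if the residual cannot be brought below `tol`, an error
#'   of class `mirsalt_convergence_error` is signalled carrying the best
#'   state and residual found -- a bad state is never returned silently.
#' @examples
#' find_steady_state(model_parameters(), salt = 0)$state
#' find_steady_state(model_parameters(), salt = 0.5, genotype = "phb_1d")
#' @export
find_steady_state <- function(params, salt = 0, genotype = "wild_type",
                              tol = 1e-10, init = NULL, max_iter = 500L,
                              polish = TRUE) {
  stopifnot(inherits(params, "mirsalt_params"))
  g <- .as_genotype(genotype)
  if (!is.finite(tol) || tol <= 0) stop("tol must be positive", call. = FALSE)
  m <- g$dPHBmiR_multiplier
  y <- if (is.null(init)) c(1, 1, 1) else as.numeric(.check_state(init))
  rhs <- function(y) .rhs_fast(y, params, salt, m)
  resid <- function(y) max(abs(rhs(y)))

  # damped fixed point on the steady-state relations
  damp <- 0.5
  best <- y; best_r <- resid(y)
  it <- 0L
  while (it < max_iter && best_r >= tol) {
    it <- it + 1L
    CK <- max(y[1], 0); PHB <- max(y[2], 0)
    pr <- tryCatch(production_terms(c(CK, PHB, max(y[3], 0)), params, salt),
                   error = function(e) NULL)
    if (is.null(pr)) break
    miR_new <- pr[["miR166"]] / params$dmiR
    denom <- params$dPHB + params$dPHBmiR * m * max(miR_new, 0)
    PHB_new <- if (denom > 0) pr[["PHB"]] / denom else PHB
    prCK <- params$alphaCK +
      params$betaCK1 * hill_activation(max(PHB_new, 0), params$betaCK2,
                                       params$n)
    CK_new <- prCK / params$dCK
    y <- (1 - damp) * y + damp * c(CK_new, PHB_new, miR_new)
    r <- resid(y)
    if (r < best_r) { best_r <- r; best <- y }
  }
  y <- best

  # Newton polish
  if (polish) for (nit in 1:50) {
    r <- rhs(y)
    if (max(abs(r)) < tol) break
    J <- .num_jacobian(rhs, y)
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) break
    y_new <- y - step
    if (resid(y_new) < resid(y)) y <- y_new else break
  }
  r <- resid(y)
  if (r < best_r) { best_r <- r; best <- y }

  if (best_r >= tol) {
    cond <- structure(
      class = c("mirsalt_convergence_error", "error", "condition"),
      list(message = paste0("steady-state solver did not reach tol = ",
                            format(tol), "; best residual = ",
                            format(best_r)),
           call = sys.call(-1),
           state = best, residual = best_r))
    stop(cond)
  }
  state <- best
  names(state) <- c("CK", "PHB", "miR166")
  structure(list(state = state, residual = best_r, converged = TRUE,
                 iterations = it, salt = salt, genotype = g),
            class = "mirsalt_steady")
}

#' @export
print.mirsalt_steady <- function(x, ...) {
  cat("<mirsalt_steady>", x$genotype$name, "salt =", format(x$salt),
      "residual =", format(x$residual, digits = 3), "\n")
  print(x$state)
  invisible(x)
}

#' Steady-state sweep over a salt gradient
#'
#' Solves the steady state on a grid of salt values using continuation:
#' each grid point is seeded from the previous solution. With reference
#' parameters this reproduces the published salt-gradient response --
#' miR165/166 falls monotonically with salt while PHB and cytokinin rise
#' (wild type), and PHB/CK are salt-invariant in `phb_1d`.
#'
#' @inheritParams find_steady_state
#' @param salt_min,salt_max ends of the (inclusive) salt grid; defaults 0
#'   and 10.
#' @param n_points number of evenly spaced grid points (>= 2, default 101).
#' @return A data frame of class `mirsalt_sweep` with columns `salt`, `CK`,
#'   `PHB`, `miR166`, `residual`, `converged`, and the genotype and
#'   parameters stored as attributes.
#' @examples
#' sw <- sweep_salt(model_parameters(), "wild_type", n_points = 11)
#' sw[c(1, 11), ]
#' @export
sweep_salt <- function(params, genotype = "wild_type",
                       salt_min = 0, salt_max = 10, n_points = 101L,
                       tol = 1e-10) {
  stopifnot(inherits(params, "mirsalt_params"))
  g <- .as_genotype(genotype)
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  if (!(salt_max > salt_min) || salt_min < 0)
    stop("need 0 <= salt_min < salt_max", call. = FALSE)
  grid <- seq(salt_min, salt_max, length.out = n_points)
  states <- matrix(NA_real_, n_points, 3L)
  residual <- numeric(n_points)
  converged <- logical(n_points)
  guess <- NULL
  for (i in seq_len(n_points)) {
    ss <- tryCatch(find_steady_state(params, grid[i], g, tol = tol,
                                     init = guess),
                   mirsalt_convergence_error = function(e) e)
    if (inherits(ss, "mirsalt_steady")) {
      states[i, ] <- ss$state
      residual[i] <- ss$residual
      converged[i] <- TRUE
      guess <- ss$state
    } else {
      stop("steady-state continuation failed at salt = ", format(grid[i]),
           " (grid point ", i, "): ", conditionMessage(ss), call. = FALSE)
    }
  }
  out <- data.frame(salt = grid, CK = states[, 1], PHB = states[, 2],
                    miR166 = states[, 3], residual = residual,
                    converged = converged)
  attr(out, "genotype") <- g
  attr(out, "params") <- params
  class(out) <- c("mirsalt_sweep", "data.frame")
  out
}

#' Verify uniqueness of the steady state by multi-start
#'
#' Runs the solver from a lattice of initial guesses in `[0, 3]^3` and
#' checks that all runs converge to the same fixed point.
#'
#' @inheritParams find_steady_state
#' @param agree_tol maximum allowed spread between solutions per component.
#' @return `TRUE` invisibly if all starts agree; otherwise an error.
#' @examples
#' check_steady_state_unique(model_parameters(), salt = 0.5)
#' @export
check_steady_state_unique <- function(params, salt = 0,
                                      genotype = "wild_type",
                                      agree_tol = 1e-6) {
  starts <- as.matrix(expand.grid(c(0.1, 3), c(0.1, 3), c(0.1, 3)))
  sol <- t(apply(starts, 1, function(s)
    find_steady_state(params, salt, genotype, init = s)$state))
  spread <- apply(sol, 2, function(col) diff(range(col)))
  if (any(spread > agree_tol))
    stop("multiple steady states detected at salt = ", format(salt),
         "; component spreads: ", paste(format(spread), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
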