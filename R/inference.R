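.free_param_menu <- c("s_ref", "dmiR", "alphamiR", "time_scale")

.default_bounds <- list(s_ref = c(0, 2), dmiR = c(0.05, 5),
                        alphamiR = c(0.05, 5), time_scale = c(0.1, 10))

# Apply a free-parameter assignment on top of a dataset's metadata,
# returning list(params, s_ref, time_scale).
.apply_assignment <- function(dataset, params, assignment) {
  meta <- attr(dataset, "metadata")
  s_ref <- if (!is.null(meta$s_ref)) meta$s_ref else 0.5
  time_scale <- if (!is.null(meta$time_scale)) meta$time_scale else 2
  bad <- setdiff(names(assignment), .free_param_menu)
  if (length(bad))
    stop("free parameters must be among {",
         paste(.free_param_menu, collapse = ", "), "}; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(assignment$s_ref)) s_ref <- assignment$s_ref
  if (!is.null(assignment$time_scale)) time_scale <- assignment$time_scale
  pupd <- assignment[intersect(names(assignment), c("dmiR", "alphamiR"))]
  if (length(pupd)) params <- do.call(update_parameters, c(list(params), pupd))
  list(params = params, s_ref = s_ref, time_scale = time_scale)
}

#' Sum-of-squares loss on log2 fold changes
#'
#' Evaluates the model's noise-free fold changes at each unique
#' `(dose, time)` of the dataset under the given parameter assignment, and
#' returns the sum over records of squared log2 residuals -- the natural
#' loss under the generator's multiplicative lognormal noise.
#'
#' @param dataset a `mirsalt_dataset`.
#' @param params base model parameters (defaults to the dataset's own).
#' @param genotype genotype (defaults to the dataset's own).
#' @param assignment named list of values for free parameters among
#'   `s_ref`, `dmiR`, `alphamiR`, `time_scale`; these override the base
#'   values.
#' @return Nonnegative scalar. If the model cannot be evaluated (solver
#'   failure), a large finite penalty (`1e6`) is returned with attribute
#'   `failed = TRUE`.
#' @examples
#' d <- generate_timecourse(noise_sd_log2 = 0, seed = 1)
#' fc_loss(d)                       # self-fit: ~0
#' fc_loss(d, assignment = list(s_ref = 0.1))
#' @export
fc_loss <- function(dataset, params = NULL, genotype = NULL,
                    assignment = list()) {
  stopifnot(inherits(dataset, "mirsalt_dataset"))
  meta <- attr(dataset, "metadata")
  if (is.null(params)) {
    params <- if (!is.null(meta$params))
      do.call(model_parameters, meta$params) else model_parameters()
  }
  if (is.null(genotype))
    genotype <- if (!is.null(meta$genotype)) meta$genotype else "wild_type"
  g <- .as_genotype(genotype)
  a <- .apply_assignment(dataset, params, assignment)
  res <- tryCatch({
    control <- find_steady_state(a$params, salt = 0, genotype = g)$state
    conds <- unique(dataset[, c("dose_mM", "time_h")])
    loss <- 0
    for (i in seq_len(nrow(conds))) {
      fc <- .fold_change_at(a$params, g, control, conds$dose_mM[i],
                            conds$time_h[i], a$s_ref, a$time_scale)
      sel <- dataset$dose_mM == conds$dose_mM[i] &
        dataset$time_h == conds$time_h[i]
      model_fc <- ifelse(dataset$gene[sel] == "miR166", fc[1, 1], fc[1, 2])
      loss <- loss +
        sum((log2(dataset$fold_change[sel]) - log2(model_fc))^2)
    }
    loss
  }, error = function(e) structure(1e6, failed = TRUE))
  res
}

#' Fit free parameters to a fold-change dataset
#'
#' Multi-start bounded local optimisation (`L-BFGS-B`) of [fc_loss()] over
#' 1--3 free parameters. The first start is the midpoint of the bounds; the
#' remaining starts are drawn uniformly within bounds from the given seed,
#' so the whole fit is deterministic.
#'
#' @inheritParams fc_loss
#' @param free_params character vector (length 1--3) of parameters to fit,
#'   from `s_ref`, `dmiR`, `alphamiR`, `time_scale`.
#' @param bounds named list of `c(lower, upper)` per free parameter;
#'   defaults: `s_ref` `[0, 2]`, `dmiR` `[0.05, 5]`, `alphamiR` `[0.05, 5]`,
#'   `time_scale` `[0.1, 10]`.
#' @param n_starts number of optimisation starts (default 8).
#' @param seed integer seed for the start points.
#' @return An object of class `mirsalt_fit`: list with `estimates` (named
#'   vector), `loss`, `per_start_loss`, `convergence` codes, `n_starts`,
#'   `seed`, and `free_params`.
#' @examples
#' d <- generate_timecourse(noise_sd_log2 = 0, seed = 1)
#' fit <- fit_parameters(d, free_params = "s_ref", n_starts = 3, seed = 7)
#' fit$estimates
#' @export
fit_parameters <- function(dataset, free_params = "s_ref", bounds = NULL,
                           n_starts = 8L, seed = 1L,
                           params = NULL, genotype = NULL) {
  stopifnot(inherits(dataset, "mirsalt_dataset"))
  free_params <- as.character(free_params)
  if (length(free_params) < 1L || length(free_params) > 3L)
    stop("1 to 3 free parameters are supported (identifiability guard)",
         call. = FALSE)
  bad <- setdiff(free_params, .free_param_menu)
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  b <- .default_bounds[free_params]
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  lower <- vapply(b, `[`, numeric(1), 1L)
  upper <- vapply(b, `[`, numeric(1), 2L)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(upper <= lower))
    stop("bounds must be finite with lower < upper", call. = FALSE)

  obj <- function(x) {
    as.numeric(fc_loss(dataset, params = params, genotype = genotype,
                       assignment = as.list(stats::setNames(x, free_params))))
  }
  starts <- rbind((lower + upper) / 2,
                  if (n_starts > 1L) .with_seed(seed, matrix(
                    stats::runif((n_starts - 1L) * length(free_params),
                                 rep(lower, each = n_starts - 1L),
                                 rep(upper, each = n_starts - 1L)),
                    nrow = n_starts - 1L)))
  fits <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fits[[i]] <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4)),
      error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("all optimisation starts failed", call. = FALSE)
  losses <- vapply(fits, function(f) if (is.null(f)) Inf else f$value,
                   numeric(1))
  best <- which.min(losses)
  est <- stats::setNames(fits[[best]]$par, free_params)
  structure(list(estimates = est,
                 loss = fits[[best]]$value,
                 per_start_loss = losses,
                 convergence = vapply(fits, function(f)
                   if (is.null(f)) NA_integer_ else f$convergence,
                   integer(1)),
                 n_starts = nrow(starts),
                 seed = seed,
                 free_params = free_params),
            class = "mirsalt_fit")
}

#' @export
print.mirsalt_fit <- function(x, ...) {
  cat("<mirsalt_fit> loss =", format(x$loss, digits = 6),
      "(", x$n_starts, "starts )\n")
  print(x$estimates)
  invisible(x)
}

#' One-dimensional grid-search reference fit
#'
#' Exhaustive evaluation of [fc_loss()] on a uniform grid over one free
#' parameter. Slow but assumption-free; used as the optimiser's oracle in
#' tests.
#'
#' @inheritParams fit_parameters
#' @param free_param single parameter name.
#' @param lower,upper grid range.
#' @param step grid resolution (default 1e-3).
#' @return List with `estimate` (grid argmin) and `loss`.
#' @examples
#' d <- generate_timecourse(noise_sd_log2 = 0, seed = 1)
#' grid_fit(d, "s_ref", 0.3, 0.7, step = 0.01)$estimate
#' @export
grid_fit <- function(dataset, free_param = "s_ref", lower = 0, upper = 2,
                     step = 1e-3, params = NULL, genotype = NULL) {
  grid <- seq(lower, upper, by = step)
  losses <- vapply(grid, function(v)
    as.numeric(fc_loss(dataset, params = params, genotype = genotype,
                       assignment = stats::setNames(list(v), free_param))),
    numeric(1))
  i <- which.min(losses)
  list(estimate = grid[i], loss = losses[i])
}
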