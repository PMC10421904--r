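#' Model parameters for the salt--miR165/166--PHB--cytokinin loop
#'
#' Construct the full parameter set of the three-species ODE model. The
#' defaults are the published reference values: every rate and maximal
#' production constant equals 1 (arbitrary units), the three apparent
#' dissociation constants are `betaCK2 = 0.5`, `betaPHB2 = 0.4`,
#' `betamiR2 = 0.4`, and the Hill coefficient is `n = 1`. All
#' concentrations and times are in arbitrary units.
#'
#' The printed form of the repression terms is ambiguous, so the package
#' carries an explicit `dialect` selector:
#' \describe{
#'   \item{`"multiplicative"` (default)}{repression as
#'     `alpha * (1 - hill(CK, K, n))`; productions are always nonnegative
#'     and `betaPHB1`/`betamiR1` are inert.}
#'   \item{`"subtractive_clamped"`}{`max(0, alpha - beta1 * hill(CK, K, n))`;
#'     coincides with the multiplicative form when `alpha == beta1` and
#'     `n = 1`.}
#'   \item{`"literal_plus"`}{`alpha - beta1 / (1 + (CK/K)^n)`, the printed
#'     expression with the corrupted `1 *` denominator read as `1 +`; can go
#'     negative and is provided for comparison only.}
#' }
#'
#' @param alphaCK basal cytokinin production rate (a.u./time).
#' @param betaCK1 maximal PHB-induced cytokinin synthesis rate.
#' @param betaCK2 apparent dissociation constant for PHB activation of CK
#'   synthesis (a.u.); must be positive.
#' @param dCK cytokinin degradation rate (1/time); must be positive.
#' @param alphaPHB basal PHB transcription rate.
#' @param betaPHB1 maximal CK-inhibited PHB transcription rate.
#' @param betaPHB2 dissociation constant for CK repression of PHB (a.u.);
#'   must be positive.
#' @param dPHB baseline PHB degradation rate (1/time).
#' @param dPHBmiR rate constant for miR165/166-induced PHB degradation
#'   (1/(a.u. time)); set to 0 by the `phb_1d` genotype.
#' @param alphamiR basal miR165/166 transcription rate.
#' @param betamiR1 maximal CK-inhibited miR165/166 transcription rate.
#' @param betamiR2 dissociation constant for CK repression of miR165/166
#'   (a.u.); must be positive.
#' @param dmiR miR165/166 degradation rate (1/time); must be positive.
#' @param n Hill coefficient (dimensionless, >= 1).
#' @param dialect one of `"multiplicative"`, `"subtractive_clamped"`,
#'   `"literal_plus"`; see Details.
#'
#' @return An object of class `mirsalt_params`: a named list of validated
#'   numeric parameters plus the dialect string.
#' @examples
#' p <- model_parameters()
#' p$betaCK2
#' model_parameters(dialect = "subtractive_clamped")
#' @export
model_parameters <- function(alphaCK = 1, betaCK1 = 1, betaCK2 = 0.5,
                             dCK = 1,
                             alphaPHB = 1, betaPHB1 = 1, betaPHB2 = 0.4,
                             dPHB = 1, dPHBmiR = 1,
                             alphamiR = 1, betamiR1 = 1, betamiR2 = 0.4,
                             dmiR = 1, n = 1,
                             dialect = c("multiplicative",
                                         "subtractive_clamped",
                                         "literal_plus")) {
  dialect <- match.arg(dialect)
  p <- list(alphaCK = alphaCK, betaCK1 = betaCK1, betaCK2 = betaCK2,
            dCK = dCK,
            alphaPHB = alphaPHB, betaPHB1 = betaPHB1, betaPHB2 = betaPHB2,
            dPHB = dPHB, dPHBmiR = dPHBmiR,
            alphamiR = alphamiR, betamiR1 = betamiR1, betamiR2 = betamiR2,
            dmiR = dmiR, n = n)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be nonnegative, got ", v,
           call. = FALSE)
  }
  for (nm in c("betaCK2", "betaPHB2", "betamiR2", "dCK", "dmiR"))
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  if (p$n < 1)
    stop("Hill coefficient 'n' must be >= 1", call. = FALSE)
  p$dialect <- dialect
  structure(p, class = "mirsalt_params")
}

#' @export
print.mirsalt_params <- function(x, ...) {
  cat("<mirsalt_params> dialect =", x$dialect, "\n")
  num <- unlist(x[setdiff(names(x), "dialect")])
  print(num)
  invisible(x)
}

.param_names <- function() {
  c("alphaCK", "betaCK1", "betaCK2", "dCK",
    "alphaPHB", "betaPHB1", "betaPHB2", "dPHB", "dPHBmiR",
    "alphamiR", "betamiR1", "betamiR2", "dmiR", "n")
}

#' Update a subset of model parameters
#'
#' @param params a `mirsalt_params` object.
#' @param ... named replacements for parameter fields or `dialect`.
#' @return A revalidated `mirsalt_params` object.
#' @examples
#' update_parameters(model_parameters(), betaCK1 = 0, dmiR = 2)
#' @export
update_parameters <- function(params, ...) {
  stopifnot(inherits(params, "mirsalt_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), c(.param_names(), "dialect"))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- unclass(params)
  args[names(repl)] <- repl
  do.call(model_parameters, args)
}

#' Genotype specification
#'
#' A genotype scales the miR-dependent PHB degradation rate `dPHBmiR`.
#' `"wild_type"` keeps it unchanged; `"phb_1d"` -- the dominant mutant whose
#' PHB transcript carries a miR165/166-resistant target site -- sets it to
#' zero, severing the microRNA arm of the loop.
#'
#' @param name `"wild_type"`, `"phb_1d"`, or a custom label (then
#'   `dPHBmiR_multiplier` must be supplied).
#' @param dPHBmiR_multiplier nonnegative factor applied to `dPHBmiR`;
#'   implied by the two standard names.
#' @return An object of class `mirsalt_genotype`.
#' @examples
#' genotype("phb_1d")
#' genotype("sensitised", dPHBmiR_multiplier = 2)
#' @export
genotype <- function(name = "wild_type", dPHBmiR_multiplier = NULL) {
  if (is.null(dPHBmiR_multiplier)) {
    dPHBmiR_multiplier <- switch(name,
      wild_type = 1,
      phb_1d = 0,
      stop("unknown genotype '", name,
           "'; supply dPHBmiR_multiplier for custom genotypes",
           call. = FALSE))
  }
  if (name == "wild_type" && dPHBmiR_multiplier != 1)
    stop("wild_type implies dPHBmiR_multiplier = 1", call. = FALSE)
  if (name == "phb_1d" && dPHBmiR_multiplier != 0)
    stop("phb_1d implies dPHBmiR_multiplier = 0", call. = FALSE)
  if (!is.numeric(dPHBmiR_multiplier) || length(dPHBmiR_multiplier) != 1L ||
      !is.finite(dPHBmiR_multiplier) || dPHBmiR_multiplier < 0)
    stop("dPHBmiR_multiplier must be a single nonnegative number",
         call. = FALSE)
  structure(list(name = name, dPHBmiR_multiplier = dPHBmiR_multiplier),
            class = "mirsalt_genotype")
}

.as_genotype <- function(g) {
  if (inherits(g, "mirsalt_genotype")) return(g)
  if (is.character(g) && length(g) == 1L) return(genotype(g))
  stop("genotype must be a mirsalt_genotype or a genotype name",
       call. = FALSE)
}

#' @export
print.mirsalt_genotype <- function(x, ...) {
  cat("<mirsalt_genotype>", x$name,
      "(dPHBmiR x", format(x$dPHBmiR_multiplier), ")\n")
  invisible(x)
}

#' Piecewise-constant salt forcing
#'
#' A salt protocol is an ordered list of `(start_time, salt_value)` segments;
#' the salt level holds each value from its start time until the next
#' segment begins. The reference perturbation protocol is a step from salt 0
#' to salt 0.5 at time 0, held for 50 time units.
#'
#' @param start_times strictly increasing segment start times; the first
#'   must be 0.
#' @param salt_values nonnegative salt level for each segment.
#' @return An object of class `mirsalt_protocol`.
#' @seealso [constant_salt()], [salt_step()], [salt_at()]
#' @examples
#' salt_protocol(c(0, 10, 20), c(0, 0.5, 0))
#' @export
salt_protocol <- function(start_times, salt_values) {
  if (length(start_times) != length(salt_values) || length(start_times) < 1L)
    stop("start_times and salt_values must be equal-length, nonempty",
         call. = FALSE)
  if (start_times[1] != 0)
    stop("first segment must start at time 0", call. = FALSE)
  if (length(start_times) > 1L && any(diff(start_times) <= 0))
    stop("start_times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(salt_values)) || any(salt_values < 0))
    stop("salt values must be finite and nonnegative", call. = FALSE)
  structure(list(start_times = as.numeric(start_times),
                 salt_values = as.numeric(salt_values)),
            class = "mirsalt_protocol")
}

#' @rdname salt_protocol
#' @param salt a single nonnegative salt level.
#' @export
constant_salt <- function(salt = 0) salt_protocol(0, salt)

#' @rdname salt_protocol
#' @param salt_before,salt_after salt levels before and after the step.
#' @param t_step time of the step; a step at 0 means the protocol starts at
#'   `salt_after` (the pre-step level then only labels the initial state).
#' @export
salt_step <- function(salt_before = 0, salt_after = 0.5, t_step = 0) {
  if (t_step <= 0) return(salt_protocol(0, salt_after))
  salt_protocol(c(0, t_step), c(salt_before, salt_after))
}

#' @rdname salt_protocol
#' @param protocol a `mirsalt_protocol`.
#' @param t vector of times (>= 0).
#' @return `salt_at()` returns the salt level at each time.
#' @export
salt_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "mirsalt_protocol"))
  idx <- findInterval(t, protocol$start_times)
  idx[idx < 1L] <- 1L
  protocol$salt_values[idx]
}

#' @export
print.mirsalt_protocol <- function(x, ...) {
  cat("<mirsalt_protocol>",
      paste0("t>=", format(x$start_times), ": salt=",
             format(x$salt_values), collapse = "; "), "\n")
  invisible(x)
}
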