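#' Hill activation function
#'
#' The saturating response `x^n / (K^n + x^n)`, used for PHB activation of
#' cytokinin synthesis; `1 - hill_activation(...)` gives the repression form
#' used for cytokinin inhibition of PHB and miR165/166 transcription.
#'
#' @param x nonnegative input level (a.u.); vectorised.
#' @param K positive apparent dissociation constant (a.u.).
#' @param n Hill coefficient (>= 1).
#' @return Values in `[0, 1)`: 0 at `x = 0`, 0.5 at `x = K`, approaching 1
#'   as `x` grows.
#' @examples
#' hill_activation(0.5, 0.5, 1)   # 0.5 at half-saturation
#' hill_activation(1, 0.4, 1)     # 1/1.4
#' @export
hill_activation <- function(x, K, n) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("hill_activation: x must be finite and nonnegative", call. = FALSE)
  if (!is.finite(K) || K <= 0)
    stop("hill_activation: K must be strictly positive", call. = FALSE)
  if (!is.finite(n) || n < 1)
    stop("hill_activation: n must be >= 1", call. = FALSE)
  xn <- x^n
  xn / (K^n + xn)
}

.check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 3L || any(!is.finite(state)))
    stop("state must be a finite numeric vector (CK, PHB, miR166)",
         call. = FALSE)
  state <- as.numeric(state)
  names(state) <- c("CK", "PHB", "miR166")
  state
}

#' Production terms of the model
#'
#' Evaluate the three production (synthesis) rates at a given state and salt
#' level. Cytokinin production is `alphaCK + betaCK1 * hill(PHB, betaCK2, n)`
#' in every dialect; the PHB and miR165/166 repression terms depend on the
#' configured dialect (see [model_parameters()]). Salt enters only the miR
#' term, as the factor `alphamiR / (1 + salt)`.
#'
#' @param state numeric `(CK, PHB, miR166)`, all nonnegative.
#' @param params a `mirsalt_params` object.
#' @param salt nonnegative salt level.
#' @return Named numeric vector `c(CK=, PHB=, miR166=)` of production rates.
#'   Under the `multiplicative` and `subtractive_clamped` dialects all
#'   entries are nonnegative.
#' @examples
#' production_terms(c(1, 1, 1), model_parameters(), salt = 0)
#' @export
production_terms <- function(state, params, salt) {
  stopifnot(inherits(params, "mirsalt_params"))
  state <- .check_state(state)
  if (any(state < 0))
    stop("production_terms: state components must be nonnegative",
         call. = FALSE)
  if (!is.finite(salt) || salt < 0)
    stop("production_terms: salt must be finite and nonnegative",
         call. = FALSE)
  CK <- state[["CK"]]; PHB <- state[["PHB"]]
  prod_CK <- params$alphaCK +
    params$betaCK1 * hill_activation(PHB, params$betaCK2, params$n)
  a_miR <- params$alphamiR / (1 + salt)
  pr <- switch(params$dialect,
    multiplicative = {
      c(prod_CK,
        params$alphaPHB *
          (1 - hill_activation(CK, params$betaPHB2, params$n)),
        a_miR * (1 - hill_activation(CK, params$betamiR2, params$n)))
    },
    subtractive_clamped = {
      c(prod_CK,
        max(0, params$alphaPHB - params$betaPHB1 *
              hill_activation(CK, params$betaPHB2, params$n)),
        max(0, a_miR - params$betamiR1 *
              hill_activation(CK, params$betamiR2, params$n)))
    },
    literal_plus = {
      c(prod_CK,
        params$alphaPHB -
          params$betaPHB1 / (1 + (CK / params$betaPHB2)^params$n),
        a_miR - params$betamiR1 / (1 + (CK / params$betamiR2)^params$n))
    },
    stop("unknown dialect '", params$dialect, "'", call. = FALSE))
  names(pr) <- c("CK", "PHB", "miR166")
  pr
}

#' Right-hand side of the ODE system
#'
#' Time derivatives of `(CK, PHB, miR166)`:
#' \deqn{dCK/dt = prod_{CK} - dCK \cdot CK}
#' \deqn{dPHB/dt = prod_{PHB} - (dPHB + dPHBmiR \cdot m \cdot miR166)
#'   \cdot PHB}
#' \deqn{dmiR166/dt = prod_{miR} - dmiR \cdot miR166}
#' where `m` is the genotype's `dPHBmiR_multiplier` (0 in `phb_1d`). PHB
#' degradation is additive -- a baseline first-order term plus a
#' miR-proportional term -- so that PHB remains degraded (and bounded) in
#' the mutant.
#'
#' @inheritParams production_terms
#' @param genotype a `mirsalt_genotype` or genotype name.
#' @return Named numeric derivative vector `c(CK=, PHB=, miR166=)`.
#' @examples
#' model_rhs(c(1, 1, 1), model_parameters(), salt = 0, genotype = "wild_type")
#' @export
model_rhs <- function(state, params, salt, genotype = "wild_type") {
  g <- .as_genotype(genotype)
  pr <- production_terms(state, params, salt)
  CK <- state[[1]]; PHB <- state[[2]]; miR <- state[[3]]
  d <- c(pr[["CK"]] - params$dCK * CK,
         pr[["PHB"]] -
           (params$dPHB +
              params$dPHBmiR * g$dPHBmiR_multiplier * miR) * PHB,
         pr[["miR166"]] - params$dmiR * miR)
  names(d) <- c("CK", "PHB", "miR166")
  d
}

# Internal fast path: same maths as model_rhs without argument validation.
# Used by the integrator and steady-state solver where the inputs have
# already been checked once. States may transiently dip a hair below zero
# inside solver steps; clamp at 0 for the Hill terms only.
.rhs_fast <- function(state, params, salt, mult) {
  CK <- max(state[1], 0); PHB <- max(state[2], 0); miR <- state[3]
  n <- params$n
  hCK_PHB2 <- { xn <- CK^n; xn / (params$betaPHB2^n + xn) }
  hCK_miR2 <- { xn <- CK^n; xn / (params$betamiR2^n + xn) }
  hPHB     <- { xn <- PHB^n; xn / (params$betaCK2^n + xn) }
  a_miR <- params$alphamiR / (1 + salt)
  if (params$dialect == "multiplicative") {
    pPHB <- params$alphaPHB * (1 - hCK_PHB2)
    pmiR <- a_miR * (1 - hCK_miR2)
  } else if (params$dialect == "subtractive_clamped") {
    pPHB <- max(0, params$alphaPHB - params$betaPHB1 * hCK_PHB2)
    pmiR <- max(0, a_miR - params$betamiR1 * hCK_miR2)
  } else {
    pPHB <- params$alphaPHB - params$betaPHB1 / (1 + (CK / params$betaPHB2)^n)
    pmiR <- a_miR - params$betamiR1 / (1 + (CK / params$betamiR2)^n)
  }
  c(params$alphaCK + params$betaCK1 * hPHB - params$dCK * state[1],
    pPHB - (params$dPHB + params$dPHBmiR * mult * miR) * state[2],
    pmiR - params$dmiR * miR)
}
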