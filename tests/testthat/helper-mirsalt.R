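# Long-time-integration oracle for steady states: integrate from (1,1,1)
# to t = 500 under constant salt and return the endpoint. Independent of
# the fixed-point/Newton machinery in find_steady_state().
ss_by_integration <- function(params, salt, genotype = "wild_type",
                              t_end = 500) {
  tr <- simulate_model(params, genotype, constant_salt(salt),
                       t_end = t_end, init = c(1, 1, 1), n_samples = 2L,
                       rtol = 1e-10, atol = 1e-12)
  tr$states[2, ]
}

# Jitter every reference parameter value by up to +/- frac, reproducibly.
jittered_params <- function(seed, frac = 0.2) {
  base <- model_parameters()
  nm <- c("alphaCK", "betaCK1", "betaCK2", "dCK", "alphaPHB", "betaPHB1",
          "betaPHB2", "dPHB", "dPHBmiR", "alphamiR", "betamiR1",
          "betamiR2", "dmiR")
  set.seed(seed)
  vals <- lapply(nm, function(k) base[[k]] * stats::runif(1, 1 - frac,
                                                          1 + frac))
  names(vals) <- nm
  do.call(update_parameters, c(list(base), vals))
}

random_states <- function(n, seed, max_level = 3) {
  set.seed(seed)
  matrix(stats::runif(3 * n, 0, max_level), ncol = 3)
}
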