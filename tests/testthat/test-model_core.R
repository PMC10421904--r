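test_that("hill_activation matches its closed form and limits", {
  expect_equal(hill_activation(0, 0.5, 1), 0)
  expect_equal(hill_activation(0.5, 0.5, 1), 0.5)
  expect_equal(hill_activation(1, 0.4, 1), 1 / 1.4, tolerance = 1e-12)
  # strictly increasing, bounded in [0, 1)
  x <- seq(0, 50, length.out = 200)
  for (n in c(1, 2, 4)) {
    h <- hill_activation(x, 0.7, n)
    expect_true(all(diff(h) > 0))
    expect_true(all(h >= 0 & h < 1))
  }
  expect_error(hill_activation(-1, 0.5, 1), "nonnegative")
  expect_error(hill_activation(1, 0, 1), "positive")
  expect_error(hill_activation(1, 0.5, 0.5), ">= 1")
})

test_that("parameter constructor validates and reproduces the defaults", {
  p <- model_parameters()
  expect_s3_class(p, "mirsalt_params")
  expect_identical(p$dialect, "multiplicative")
  unit <- c("alphaCK", "betaCK1", "dCK", "alphaPHB", "betaPHB1", "dPHB",
            "dPHBmiR", "alphamiR", "betamiR1", "dmiR", "n")
  expect_true(all(unlist(p[unit]) == 1))
  expect_equal(p$betaCK2, 0.5)
  expect_equal(p$betaPHB2, 0.4)
  expect_equal(p$betamiR2, 0.4)
  expect_error(model_parameters(dCK = 0), "positive")
  expect_error(model_parameters(alphaCK = -1), "nonnegative")
  expect_error(model_parameters(n = 0.5), "n")
  expect_error(update_parameters(p, nosuch = 1), "unknown")
})

test_that("genotypes carry the dPHBmiR multiplier contract", {
  expect_equal(genotype("wild_type")$dPHBmiR_multiplier, 1)
  expect_equal(genotype("phb_1d")$dPHBmiR_multiplier, 0)
  expect_error(genotype("mystery"), "unknown genotype")
  expect_error(genotype("phb_1d", dPHBmiR_multiplier = 1), "implies")
  g <- genotype("half", dPHBmiR_multiplier = 0.5)
  expect_equal(g$dPHBmiR_multiplier, 0.5)
})

test_that("production terms evaluate the stated closed forms", {
  p <- model_parameters()
  # all Hill terms vanish at the origin
  for (d in c("multiplicative", "subtractive_clamped")) {
    pr <- production_terms(c(0, 0, 0), update_parameters(p, dialect = d), 0)
    expect_equal(unname(pr), c(1, 1, 1))
  }
  pr <- production_terms(c(1, 1, 1), p, 0)
  expect_equal(unname(pr), c(1 + 1 / 1.5, 1 - 1 / 1.4, 1 - 1 / 1.4),
               tolerance = 1e-12)
  # salt scales only the miR production
  pr_s <- production_terms(c(1, 1, 1), p, 3)
  expect_equal(pr_s[["CK"]], pr[["CK"]])
  expect_equal(pr_s[["PHB"]], pr[["PHB"]])
  expect_equal(pr_s[["miR166"]], pr[["miR166"]] / 4, tolerance = 1e-12)
  expect_error(production_terms(c(-1, 0, 0), p, 0), "nonnegative")
  expect_error(production_terms(c(1, 1, 1), p, -0.1), "salt")
})

test_that("multiplicative and subtractive_clamped dialects agree at the
           reference parameters", {
  pm <- model_parameters(dialect = "multiplicative")
  ps <- model_parameters(dialect = "subtractive_clamped")
  states <- random_states(50, seed = 11)
  for (i in seq_len(nrow(states))) {
    rm_ <- model_rhs(states[i, ], pm, salt = 0, genotype = "wild_type")
    rs_ <- model_rhs(states[i, ], ps, salt = 0, genotype = "wild_type")
    expect_lt(max(abs(rm_ - rs_)), 1e-12)
  }
})

test_that("literal_plus reproduces the printed expression verbatim", {
  p <- model_parameters(dialect = "literal_plus")
  pr <- production_terms(c(1, 1, 1), p, 0)
  expect_equal(pr[["PHB"]], 1 - 1 / (1 + 1 / 0.4), tolerance = 1e-12)
  expect_equal(pr[["miR166"]], 1 - 1 / (1 + 1 / 0.4), tolerance = 1e-12)
  # can go negative at low CK (alpha - beta1/(1+0) = 0 at CK = 0)
  pr0 <- production_terms(c(0, 0, 0), p, 0)
  expect_equal(pr0[["PHB"]], 0)
})

test_that("model_rhs combines production and degradation as documented", {
  p <- model_parameters()
  d_wt <- model_rhs(c(1, 1, 1), p, 0, "wild_type")
  expect_equal(unname(d_wt),
               c(1 + 1 / 1.5 - 1, (1 - 1 / 1.4) - 2, (1 - 1 / 1.4) - 1),
               tolerance = 1e-12)
  d_mut <- model_rhs(c(1, 1, 1), p, 0, "phb_1d")
  expect_equal(d_mut[["PHB"]], (1 - 1 / 1.4) - 1, tolerance = 1e-12)
  # pure-decay limit of CK
  p0 <- update_parameters(p, alphaCK = 0, betaCK1 = 0, dCK = 1.7)
  for (ck in c(0.3, 1, 4))
    expect_equal(model_rhs(c(ck, 1, 1), p0, 0)[["CK"]], -1.7 * ck)
})

test_that("phb_1d PHB dynamics are independent of miR166, and CK/PHB
           dynamics are independent of salt", {
  p <- model_parameters()
  states <- random_states(20, seed = 5)
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    s2 <- s; s2[3] <- s2[3] + 1
    expect_equal(model_rhs(s, p, 0, "phb_1d")[["PHB"]],
                 model_rhs(s2, p, 0, "phb_1d")[["PHB"]])
    for (comp in c("CK", "PHB")) {
      expect_equal(model_rhs(s, p, 0, "phb_1d")[[comp]],
                   model_rhs(s, p, 2.5, "phb_1d")[[comp]])
    }
  }
})

test_that("miR production decreases with salt in every dialect", {
  # Strict decrease wherever production is positive; the clamped dialect
  # sits at exactly 0 once CK saturates the repression term, so there the
  # contract weakens to non-increasing.
  states <- random_states(10, seed = 3)
  salts <- c(0, 0.25, 0.5, 1, 2, 5, 10)
  for (d in c("multiplicative", "subtractive_clamped", "literal_plus")) {
    p <- model_parameters(dialect = d)
    for (i in seq_len(nrow(states))) {
      pm <- vapply(salts, function(s)
        production_terms(states[i, ], p, s)[["miR166"]], numeric(1))
      expect_true(all(diff(pm) <= 0))
      pos <- pm[-length(pm)] > 0
      expect_true(all(diff(pm)[pos] < 0))
      if (d != "subtractive_clamped") expect_true(all(diff(pm) < 0))
    }
  }
})

test_that("salt protocols are validated and evaluated piecewise", {
  pr <- salt_protocol(c(0, 5, 20), c(0, 0.5, 0.1))
  expect_equal(salt_at(pr, c(0, 4.9, 5, 19, 20, 100)),
               c(0, 0, 0.5, 0.5, 0.1, 0.1))
  expect_error(salt_protocol(c(1, 2), c(0, 0)), "start at time 0")
  expect_error(salt_protocol(c(0, 0), c(0, 1)), "strictly increasing")
  expect_error(salt_protocol(0, -1), "nonnegative")
  expect_equal(salt_at(salt_step(0, 0.5, 0), c(0, 10)), c(0.5, 0.5))
  expect_equal(salt_at(salt_step(0, 0.5, 3), c(0, 2.9, 3)), c(0, 0, 0.5))
})

test_that("parameters load from a DCF config with unknown keys rejected", {
  cfg_file <- tempfile(fileext = ".dcf")
  writeLines(c("betaCK2: 0.7", "dialect: subtractive_clamped",
               "genotype: phb_1d"), cfg_file)
  cfg <- load_config(cfg_file)
  p <- mirsalt:::.config_params(cfg)
  expect_equal(p$betaCK2, 0.7)
  expect_identical(p$dialect, "subtractive_clamped")
  expect_identical(cfg$genotype, "phb_1d")
  # defaults survive where unset
  expect_equal(p$betamiR2, 0.4)
  writeLines("mystery: 1", cfg_file)
  expect_error(load_config(cfg_file), "unknown config key")
  expect_error(load_config(NULL, overrides = list(bogus = 2)),
               "unknown config key")
})
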