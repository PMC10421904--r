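test_that("dose_to_salt is linear through the 150 mM anchor", {
  expect_equal(dose_to_salt(c(0, 100, 150, 200)),
               c(0, 1/3, 0.5, 2/3), tolerance = 1e-12)
  expect_equal(dose_to_salt(150, s_ref = 0.8), 0.8)
  expect_error(dose_to_salt(-10), "nonnegative")
})

test_that("true fold changes match the treated/control ratio of the model", {
  p <- model_parameters()
  # dose 0: control equals itself
  fc0 <- true_fold_change(p, "wild_type", 0, c(0.5, 4))
  expect_equal(fc0$FC_miR166, c(1, 1))
  expect_equal(fc0$FC_PHB, c(1, 1))
  # long-time limit at 150 mM = ratio of steady states (salt 0.5 vs 0)
  ss0 <- find_steady_state(p, 0)$state
  ss5 <- find_steady_state(p, 0.5)$state
  fc <- true_fold_change(p, "wild_type", 150, 60)  # 120 model units
  expect_equal(fc$FC_miR166, ss5[["miR166"]] / ss0[["miR166"]],
               tolerance = 1e-6)
  expect_equal(fc$FC_PHB, ss5[["PHB"]] / ss0[["PHB"]], tolerance = 1e-6)
  # frozen external-oracle values at the published timepoints
  fc <- true_fold_change(p, "wild_type", 150, c(0.5, 1, 4))
  expect_equal(fc$FC_miR166, c(0.78917837, 0.71095331, 0.66208852),
               tolerance = 1e-6)
  expect_equal(fc$FC_PHB, c(1.01959924, 1.04162942, 1.06185562),
               tolerance = 1e-6)
})

test_that("phb_1d fold change of PHB is pinned at 1", {
  p <- model_parameters()
  for (dose in c(100, 200)) {
    fc <- true_fold_change(p, "phb_1d", dose, c(0.5, 2, 5))
    expect_lt(max(abs(fc$FC_PHB - 1)), 1e-8)
    expect_true(all(fc$FC_miR166 < 1))
  }
})

test_that("the generator is seed-deterministic and leaves the global RNG
           alone", {
  p <- model_parameters()
  set.seed(999); marker <- runif(1)
  a <- generate_timecourse(p, seed = 42)
  b <- generate_timecourse(p, seed = 42)
  expect_identical(a$fold_change, b$fold_change)
  c_ <- generate_timecourse(p, seed = 43)
  expect_false(identical(a$fold_change, c_$fold_change))
  set.seed(999)
  expect_identical(runif(1), marker)
  expect_error(generate_timecourse(p), "seed")
})

test_that("dataset layout matches the published designs", {
  d <- generate_timecourse(seed = 1)
  expect_setequal(unique(d$time_h), c(0.5, 1, 1.5, 2, 3, 4))
  expect_equal(unique(d$dose_mM), 150)
  counts <- table(d$gene, d$time_h)
  expect_true(all(counts == 3))
  expect_true(all(d$fold_change > 0))

  dr <- generate_dose_response(seed = 1)
  expect_setequal(unique(dr$dose_mM), c(0, 100, 150, 200))
  expect_equal(unique(dr$time_h), 5)
  expect_true(all(table(dr$gene, dr$dose_mM) == 3))
  expect_true(all(dr$fold_change > 0))
})

test_that("noiseless data equal the true fold changes; noiseless
           dose-response miR is strictly decreasing in dose", {
  p <- model_parameters()
  d <- generate_timecourse(p, noise_sd_log2 = 0, seed = 1)
  truth <- true_fold_change(p, "wild_type", 150, c(0.5, 1, 1.5, 2, 3, 4))
  for (i in seq_len(nrow(truth))) {
    sel <- d$time_h == truth$time_h[i]
    expect_equal(unique(d$fold_change[sel & d$gene == "miR166"]),
                 truth$FC_miR166[i], tolerance = 1e-12)
    expect_equal(unique(d$fold_change[sel & d$gene == "PHB"]),
                 truth$FC_PHB[i], tolerance = 1e-12)
  }
  expect_true(all(diff(truth$FC_miR166) < 0))
  expect_true(all(truth$FC_miR166 < 1))

  dr <- generate_dose_response(p, noise_sd_log2 = 0, seed = 1)
  m <- aggregate(fold_change ~ dose_mM, dr[dr$gene == "miR166", ], mean)
  expect_true(all(diff(m$fold_change[order(m$dose_mM)]) < 0))
  expect_equal(m$fold_change[m$dose_mM == 0], 1)
})

test_that("replicate noise is centred on the true log2 fold change", {
  p <- model_parameters()
  sd_ <- 0.15; n_reps <- 4L
  truth <- true_fold_change(p, "wild_type", 150, 1)
  hits <- 0L
  n_seeds <- 200L
  for (seed in seq_len(n_seeds)) {
    d <- generate_timecourse(p, timepoints_h = 1, n_reps = n_reps,
                             noise_sd_log2 = sd_, seed = seed)
    obs <- mean(log2(d$fold_change[d$gene == "miR166"]))
    if (abs(obs - log2(truth$FC_miR166)) <= 3 * sd_ / sqrt(n_reps))
      hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.99)
})

test_that("datasets round-trip losslessly through TSV", {
  d <- generate_dose_response(seed = 7)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(d, f)
  r <- read_dataset(f)
  expect_identical(r$fold_change, d$fold_change)
  expect_identical(r$gene, d$gene)
  expect_identical(r$dose_mM, d$dose_mM)
  meta <- attr(r, "metadata")
  expect_equal(meta$seed, 7)
  expect_equal(meta$noise_sd_log2, 0.15)
})
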