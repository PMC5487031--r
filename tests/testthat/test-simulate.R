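test_that("zero concentration always yields non-detects; determinism holds", {
  cfg <- simulation_config(true_concentration = 0)
  expect_true(all(is.na(simulate_reactions(cfg, 200, seed = 5))))
  cfg2 <- simulation_config(true_concentration = 10)
  a <- simulate_reactions(cfg2, 50, seed = 123)
  b <- simulate_reactions(cfg2, 50, seed = 123)
  expect_identical(a, b)
})

test_that("high-copy noiseless reactions sit exactly on the curve", {
  cfg <- simulation_config(true_concentration = 1e6, ct_noise_sd = 0,
                           template_volume = 1)
  ct <- simulate_reactions(cfg, 200, seed = 9)
  # Poisson CV at 1e6 is 0.1%, so realized log10 counts round to 6 at 3 dp
  expect_equal(mean(ct), 40 - 3.32 * 6, tolerance = 0.01)
  expect_lt(stats::sd(ct), 0.01)
})

test_that("detection rate calibrates to the Poisson occupancy law", {
  # the 7:3 anchor: lambda = -ln(0.3) detects 70% of the time
  cfg <- simulation_config(true_concentration = 1.2039728,
                           template_volume = 1)
  cts <- simulate_reactions(cfg, 10000, seed = 17)
  expect_equal(mean(!is.na(cts)), 0.70, tolerance = 0.02)
  # the 90.9% anchor at 2.4 copies/reaction
  cfg2 <- simulation_config(true_concentration = 2.4, template_volume = 1)
  cts2 <- simulate_reactions(cfg2, 10000, seed = 18)
  expect_equal(mean(!is.na(cts2)), detection_probability(2.4),
               tolerance = 0.02)
})

test_that("noiseless dilution series steps are evenly spaced in Ct", {
  cfg <- simulation_config(true_concentration = 1e7, ct_noise_sd = 0,
                           template_volume = 1, curve_slope = -3.32)
  ser <- simulate_dilution_series(cfg, fold = 10, n_steps = 4,
                                  reps_per_step = 3, seed = 2)
  med <- tapply(ser$ct, ser$step, mean, na.rm = TRUE)
  # Ct comes from realized Poisson copies, so spacing is exactly 3.32 only
  # in the high-copy limit (relative Poisson scatter 0.01% - 1% here)
  expect_equal(as.numeric(diff(med)), rep(3.32, 3), tolerance = 0.02)
  expect_equal(unique(ser$copies_per_reaction), 1e7 / 10^(0:3))
})

test_that("low dilution steps show Poisson-consistent partial detection", {
  cfg <- simulation_config(true_concentration = 39321.6, template_volume = 1)
  ser <- simulate_dilution_series(cfg, fold = 4, n_steps = 12,
                                  reps_per_step = 60, seed = 77)
  for (st in 9:11) {  # lambda = 9.6, 2.4, 0.6
    lam <- 39321.6 / 4^st
    rate <- mean(!is.na(ser$ct[ser$step == st]))
    p <- detection_probability(lam)
    ciw <- 3 * sqrt(p * (1 - p) / 60)
    expect_lt(abs(rate - p), max(ciw, 0.02))
  }
})

test_that("surveys produce readable plates, clean blanks and recoverable sites", {
  sites <- data.frame(sample_id = paste0("F", 1:3),
                      true_copies_per_l = c(1e5, 1e3, 0),
                      V_w = 1, V_e = 100, V_r = 5)
  sim <- simulate_survey(sites, simulation_config(), scheme = "danish",
                         seed = 101)
  expect_equal(sum(sim$plate$role == "ntc"), 4L)
  expect_equal(sum(sim$plate$role == "extraction_blank"), 2L)
  expect_true(all(is.na(sim$plate$ct[sim$plate$role != "unknown"])))
  expect_true(all(is.na(sim$plate$ct[sim$plate$sample_id == "F3"])))
  f1 <- sim$plate[sim$plate$sample_id == "F1", ]
  expect_equal(nrow(f1), 4L)
  expect_true(all(!is.na(f1$ct)))

  nor <- simulate_survey(sites, simulation_config(), scheme = "norwegian",
                         seed = 102)
  f1n <- nor$plate[nor$plate$sample_id == "F1", ]
  expect_equal(sort(f1n$dilution_factor), c(1L, 1L, 10L, 10L))
  # 10x diluted wells run about log2(10) cycles later
  expect_gt(mean(f1n$ct[f1n$dilution_factor == 10]),
            mean(f1n$ct[f1n$dilution_factor == 1]))

  # contaminated controls appear at the configured rate
  con <- simulate_survey(sites, simulation_config(), scheme = "danish",
                         contamination_rate = 1, seed = 103)
  expect_true(all(!is.na(con$plate$ct[con$plate$role == "ntc"])))
})

test_that("strong sites are quantified by the Danish rule in nearly all seeds", {
  cv <- standard_curve(-3.32, 40)
  ctx <- quantification_context(V_e = 100, V_r = 5, V_w = 1,
                                scheme = "danish")
  hits <- 0L
  for (s in 1:50) {
    sites <- data.frame(sample_id = "F1", true_copies_per_l = 1e5,
                        V_w = 1, V_e = 100, V_r = 5)
    sim <- simulate_survey(sites, simulation_config(), scheme = "danish",
                           seed = s)
    reps <- sim$plate[sim$plate$sample_id == "F1", ]
    res <- detect_danish(reps, cv, lod = 5, loq = 5, ctx)
    if (res$status == "quantified") hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.99)
})

test_that("inhibition shifts are detected and the diluted-only branch removes bias", {
  cv <- standard_curve(-3.32, 40)
  ctx <- quantification_context(V_e = 200, V_r = 2, V_w = 5,
                                scheme = "norwegian")
  flagged <- 0L; errs <- numeric(0)
  true_cl <- 1e4
  for (s in 1:40) {
    sites <- data.frame(sample_id = "F1", true_copies_per_l = true_cl,
                        V_w = 5, V_e = 200, V_r = 2, inhibition_shift = 2.0)
    sim <- simulate_survey(sites, simulation_config(), scheme = "norwegian",
                           seed = 1000 + s)
    reps <- sim$plate[sim$plate$sample_id == "F1", ]
    res <- quantify_norwegian(reps, cv, loq = 10, ctx)
    if (res$inhibition_flag == "inhibited") {
      flagged <- flagged + 1L
      errs <- c(errs, (res$copies_per_L - true_cl) / true_cl)
    }
  }
  expect_gte(flagged / 40, 0.95)
  expect_lt(abs(stats::median(errs)), 0.25)
})
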