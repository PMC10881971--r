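test_that("config validation enforces the serial-dilution plate design", {
  expect_error(sim_config(doses = numeric(0)), "empty dose")
  expect_error(sim_config(doses = c(1, 10, 100)), "decreasing")
  expect_error(sim_config(doses = c(100, 50, 10)), "constant-factor")
  expect_error(sim_config(n_control_wells_per_type = 1), "control wells")
  expect_error(sim_config(noise_cv = -0.1), "noise_cv")
  expect_silent(sim_config(doses = c(100, 10, 1)))
})

test_that("truth validation rejects malformed and misdeclared compounds", {
  fx <- matrix(1, 4, 2)
  expect_error(compound_truth("a", matrix(1, 3, 2), c(S9minus = 1, S9plus = 1)),
               "4 x 2")
  expect_error(compound_truth("a", fx, c(S9minus = -1, S9plus = 1)),
               "positive")
  # a compound whose effects imply activity cannot declare non_responsive
  fx2 <- fx; fx2[1:2, ] <- 4.5
  dimnames(fx2) <- list(pathways(), conditions())
  bad <- compound_truth("a", fx2, c(S9minus = 1e6, S9plus = 1e6),
                        intended_class = "non_responsive")
  expect_error(simulate_screen(sim_config(), list(bad)), "declares class")
  expect_error(simulate_screen(sim_config(), list(nontoxic_truth("d"),
                                                  nontoxic_truth("d"))),
               "duplicate")
})

test_that("identical seeds reproduce byte-identical well tables", {
  cfg <- sim_config(rng_seed = 7)
  s1 <- simulate_screen(cfg, default_truths(2))
  s2 <- simulate_screen(cfg, default_truths(2))
  expect_identical(s1$wells, s2$wells)
  expect_identical(s1$truth_ledger, s2$truth_ledger)
  s3 <- simulate_screen(sim_config(rng_seed = 8), default_truths(2))
  expect_false(identical(s1$wells, s3$wells))
})

test_that("noise-free well metrics equal their analytic expectations", {
  cfg <- sim_config(noise_cv = 0, rng_seed = 3)
  fx <- matrix(1, 4, 2, dimnames = list(pathways(), conditions()))
  fx["Nrf2", "S9plus"] <- 2
  ec50 <- cfg$doses[2]  # second dose
  tr <- compound_truth("hx", fx, c(S9minus = ec50, S9plus = ec50),
                       hill_slope = 8, intended_class = "non_responsive")
  sim <- simulate_screen(cfg, list(tr))
  w <- sim$wells[sim$wells$role == "treated", ]

  # Hill viability computed by hand: exactly 50% at the EC50 dose,
  # ~100% below it, ~0% above it for a steep slope
  hand_hill <- function(d) 1 / (1 + (d / ec50)^8)
  at <- function(d, pw, cond)
    w[w$dose_uM == d & w$pathway == pw & w$condition == cond, ][1, ]
  expect_equal(at(cfg$doses[2], "AP1", "S9minus")$live_fraction, 0.5,
               tolerance = 1e-12)
  expect_gt(at(cfg$doses[3], "AP1", "S9minus")$live_fraction, 0.99)
  expect_lt(at(cfg$doses[1], "AP1", "S9minus")$live_fraction, 0.01)
  for (d in cfg$doses)
    expect_equal(at(d, "P53", "S9minus")$live_fraction, hand_hill(d))

  # GFP: baseline everywhere except the induced pathway/condition, where
  # the fold is attenuated by viability below the 50% floor
  expect_equal(at(cfg$doses[4], "Nrf2", "S9plus")$gfp_mean_intensity,
               cfg$baseline_gfp * 2)
  expect_equal(at(cfg$doses[4], "Nrf2", "S9minus")$gfp_mean_intensity,
               cfg$baseline_gfp)
  v_top <- hand_hill(cfg$doses[1])
  expect_equal(at(cfg$doses[1], "Nrf2", "S9plus")$gfp_mean_intensity,
               cfg$baseline_gfp * 2 * v_top)
})

test_that("a no-effect compound has GFP ratio 1 vs negative controls", {
  cfg <- sim_config(noise_cv = 0)
  fx <- matrix(1, 4, 2, dimnames = list(pathways(), conditions()))
  tr <- compound_truth("null", fx, c(S9minus = 1e6, S9plus = 1e6),
                       intended_class = "non_responsive")
  nw <- normalize_wells(simulate_screen(cfg, list(tr))$wells)
  expect_equal(nw$gfp_ratio_neg[nw$role == "treated"],
               rep(1, sum(nw$role == "treated")))
})

test_that("positive-control wells outshine negative controls on every plate", {
  sim <- simulate_screen(sim_config(noise_cv = 0.15, rng_seed = 21),
                         default_truths(2))
  w <- sim$wells
  for (pl in unique(w$plate_id)) {
    pw <- w[w$plate_id == pl, ]
    expect_gt(mean(pw$gfp_mean_intensity[pw$role == "pos_ctrl"]),
              mean(pw$gfp_mean_intensity[pw$role == "neg_ctrl"]))
  }
})

test_that("every simulated well appears exactly once in the truth ledger", {
  sim <- simulate_screen(sim_config(rng_seed = 5), default_truths(1))
  key_w <- paste(sim$wells$plate_id, sim$wells$well)
  key_l <- paste(sim$truth_ledger$plate_id, sim$truth_ledger$well)
  expect_identical(sort(key_w), sort(key_l))
  expect_false(anyDuplicated(key_l) > 0)
})

test_that("rendered fields are seeded, ledgered, and capacity-checked", {
  f1 <- render_field(50, field_size = 128, min_separation = 10, seed = 4)
  f2 <- render_field(50, field_size = 128, min_separation = 10, seed = 4)
  expect_identical(f1$nuclei, f2$nuclei)
  expect_identical(f1$truth, f2$truth)
  expect_equal(nrow(f1$truth), 50)

  f0 <- render_field(0, field_size = 64, seed = 1)
  expect_equal(nrow(f0$truth), 0)
  # pure background: no structure beyond read noise
  expect_lt(diff(range(f0$nuclei)), 300 + 8 * 15)

  expect_error(render_field(400, field_size = 64, min_separation = 20,
                            seed = 1), "capacity")
  expect_error(render_field(10, field_size = 32, seed = 1), "field_size")
})

test_that("planted live count falls within its binomial 99% interval", {
  f <- render_field(1000, field_size = 512, live_fraction = 0.8,
                    min_separation = 0, seed = 12)
  q <- qbinom(c(0.005, 0.995), 1000, 0.8)
  expect_gte(sum(f$truth$live), q[1])
  expect_lte(sum(f$truth$live), q[2])
})

test_that("field TIFF round-trip preserves 16-bit channels", {
  f <- render_field(20, field_size = 64, min_separation = 0, seed = 6)
  dir <- withr::local_tempdir()
  write_field_tiff(f, dir, "P1", "A01")
  g <- read_field_tiff(dir, "P1", "A01")
  # 16-bit quantization: within one grey level
  expect_lt(max(abs(g$nuclei - f$nuclei)), 1.001)
  expect_lt(max(abs(g$reporter - f$reporter)), 1.001)
  expect_error(read_field_tiff(dir, "P1", "B02"), "missing channel")
})
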