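test_that("calibrate computes median density and rescales RNA samples", {
  samples <- data.frame(sample_id = c("TT_1", "RNA_1"),
                        assay = c("TT", "RNA"))
  # spike 1: labeled, L=1000; spike 2: unlabeled, L=1000
  sp <- spikein_table(c("L1", "U1"), c(1000, 1000), c(TRUE, FALSE),
                      matrix(c(10000, 100, 100, 10000), 2, byrow = TRUE),
                      samples)
  cal <- calibrate(sp)
  # TT: sigma = 10000/1000 = 10, epsilon = 100/1000 = 0.1 (pre-rescale)
  expect_equal(cal$sigma[1], 10)
  expect_equal(cal$epsilon[1], 0.1)
  expect_equal(cal$scale[1], 1)
  # RNA: raw sigma = 0.1, epsilon = 10 -> rescaled to eps = 1, scale = 10
  expect_equal(cal$epsilon[2], 1)
  expect_equal(cal$scale[2], 10)
  expect_equal(cal$sigma[2], 0.01)
  # missing class errors
  sp2 <- sp; sp2$labeled <- c(TRUE, TRUE)
  expect_error(calibrate(sp2), "labeled and unlabeled")
})

test_that("calibration from noisy spike-ins is accurate", {
  set.seed(3)
  n <- 8
  L <- round(runif(2 * n, 1000, 4000))
  lab <- rep(c(TRUE, FALSE), each = n)
  sigma_true <- 2; eps_true <- 0.5
  k <- rpois(2 * n, L * ifelse(lab, sigma_true, eps_true))
  sp <- spikein_table(paste0("s", 1:(2 * n)), L, lab,
                      matrix(k, ncol = 1),
                      data.frame(sample_id = "TT_1", assay = "TT"))
  cal <- calibrate(sp)
  expect_lt(abs(cal$sigma - sigma_true) / sigma_true, 0.1)
  expect_lt(abs(cal$epsilon - eps_true) / eps_true, 0.1)
})

test_that("fit_amounts inverts the forward observation model", {
  # alpha=2, beta=8, L=1000, (sigma_T, eps_T)=(5, .05), (sigma_R, eps_R)=(1,1)
  cal_tt <- data.frame(sigma = 5, epsilon = 0.05, scale = 1)
  cal_rna <- data.frame(sigma = 1, epsilon = 1, scale = 1)
  k_tt <- 1000 * (5 * 2 + 0.05 * 8)   # 10400
  k_rna <- 1000 * (1 * 2 + 1 * 8)     # 10000
  am <- fit_amounts(k_tt, k_rna, 1000, cal_tt, cal_rna)
  expect_equal(am$alpha, 2)
  expect_equal(am$beta, 8)
  expect_false(am$clamped)
  # zero counts give zero amounts, flagged false (exactly zero is valid)
  am0 <- fit_amounts(0, 0, 1000, cal_tt, cal_rna)
  expect_equal(c(am0$alpha, am0$beta), c(0, 0))
  # singular calibration errors
  expect_error(fit_amounts(1, 1, 1000,
                           data.frame(sigma = 1, epsilon = 1, scale = 1),
                           cal_rna), "singular")
})

test_that("replicate ML fit equals the single-pair solution at zero noise", {
  cal <- data.frame(sample_id = c("t1", "t2", "r1", "r2"),
                    assay = c("TT", "TT", "RNA", "RNA"),
                    sigma = c(5, 5, 1, 1), epsilon = c(0.05, 0.05, 1, 1),
                    scale = 1)
  k <- c(10400, 10400, 10000, 10000)
  ml <- fit_amounts_ml(k, 1000, cal)
  expect_true(ml$converged)
  expect_equal(ml$alpha, 2, tolerance = 1e-4)
  expect_equal(ml$beta, 8, tolerance = 1e-4)
})

test_that("kinetic_rates implements first-order formulas", {
  # alpha = beta forces half-life = labeling time
  r <- kinetic_rates(3, 3, t = 5)
  expect_equal(r$lambda_per_min, log(2) / 5)
  expect_equal(r$half_life_min, 5)
  # alpha=2, beta=8, t=5 (evaluated independently)
  r <- kinetic_rates(2, 8, t = 5)
  expect_equal(r$lambda_per_min, -(1 / 5) * log(0.8))
  expect_equal(r$half_life_min, log(2) / (-(1 / 5) * log(0.8)))
  expect_equal(r$mu_per_min, 10 * -(1 / 5) * log(0.8))
  expect_equal(round(r$lambda_per_min, 5), 0.04463)
  expect_equal(round(r$half_life_min, 2), 15.53)
  # boundaries
  r <- kinetic_rates(0, 5, t = 5)
  expect_equal(r$lambda_per_min, 0)
  expect_equal(r$flag, "no_labeled")
  r <- kinetic_rates(5, 0, t = 5)
  expect_equal(r$mu_per_min, 1)
  expect_equal(r$flag, "no_unlabeled")
  r <- kinetic_rates(0, 0, t = 5)
  expect_equal(r$flag, "undefined")
  expect_error(kinetic_rates(1, 1, t = 0), "positive")
})

test_that("lambda decreases in beta at fixed alpha+beta", {
  tot <- 10
  betas <- seq(0.5, 9.5, by = 0.5)
  lam <- kinetic_rates(tot - betas, betas, t = 5)$lambda_per_min
  expect_true(all(diff(lam) < 0))
})

test_that("zero-noise estimation recovers amounts exactly; Poisson noise
          keeps median relative rate errors under 10%", {
  w <- default_world()
  obs0 <- with_memo("dobs0",
    simulate_counts(w, seed = 8, noise = "none",
                    tracks_for = character(0)))
  cal0 <- calibrate(obs0$spikeins)
  k0 <- estimate_kinetics(obs0$counts, cal0, t = 5, time = 0)
  a_true <- obs0$amounts$alpha[k0$feature_id, "0"]
  b_true <- obs0$amounts$beta[k0$feature_id, "0"]
  expect_lt(max(abs(k0$alpha - a_true)), 1e-8)
  expect_lt(max(abs(k0$beta - b_true)), 1e-8)

  obs <- default_obs()
  cal <- calibrate(obs$spikeins)
  kk <- estimate_kinetics(obs$counts, cal, t = 5, time = 0)
  kin <- w$truth$kinetics
  m <- merge(kk, kin, by = "feature_id")
  use <- m$half_life_min.y >= 2 & m$half_life_min.y <= 200 &
    m$alpha > 0 & m$beta > 0
  rel_l <- abs(m$lambda_per_min.x - m$lambda_per_min.y) /
    m$lambda_per_min.y
  rel_m <- abs(m$mu_per_min - m$mu0_per_min) / m$mu0_per_min
  expect_lt(median(rel_l[use]), 0.1)
  expect_lt(median(rel_m[use]), 0.1)
})

test_that("estimated eRNA half-lives are shorter than other ncRNAs", {
  w <- default_world()
  obs <- default_obs()
  cal <- calibrate(obs$spikeins)
  kk <- estimate_kinetics(obs$counts, cal, t = 5, time = 0)
  m <- merge(kk, w$truth$kinetics[, c("feature_id", "class")],
             by = "feature_id")
  hl_e <- m$half_life_min[m$class == "eRNA" & is.finite(m$half_life_min)]
  hl_n <- m$half_life_min[m$class == "ncRNA" & is.finite(m$half_life_min)]
  p <- wilcox.test(hl_e, hl_n, alternative = "less")$p.value
  expect_lt(p, 0.01)
})
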