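test_that("residuals are zero on forward data and shift linearly with k", {
  scan <- canonical_scan()
  r0 <- brdf_residuals(canonical_params(), scan)
  expect_equal(max(abs(r0)), 0, tolerance = 1e-12)
  r1 <- brdf_residuals(c(0.3, 0.45, 2.2), scan)
  expect_equal(r1, rep(0.1 / pi, length(r1)), tolerance = 1e-12)
  expect_error(brdf_residuals(c(0.3, 0.35, 2.2), scan[0, ]), "empty")
})

test_that("goodness of fit follows its definition", {
  expect_equal(goodness_of_fit(1:4, 1:4), list(r_squared = 1, rmse = 0))
  obs <- c(1, 5, 3, 2)
  g <- goodness_of_fit(rep(mean(obs), 4), obs)
  expect_equal(g$r_squared, 0)
  g2 <- goodness_of_fit(c(1.1, 1.9, 3.2), c(1, 2, 3))
  expect_equal(g2$r_squared, 0.97, tolerance = 1e-12)
  expect_equal(g2$rmse, 0.1414214, tolerance = 1e-6)
  g3 <- goodness_of_fit(c(1, 2), c(2, 2))
  expect_true(is.na(g3$r_squared))
  expect_equal(g3$rmse, sqrt(0.5))
})

test_that("both solvers recover the reference triple from noiseless data", {
  scan <- canonical_scan()
  truth <- c(sigma = 0.3, k = 0.35, n = 2.2)
  lsq <- fit_brdf(scan, "least_squares")
  expect_lt(max(abs(coef(lsq) - truth)), 1e-3)
  expect_equal(lsq$r_squared, 1, tolerance = 1e-9)
  ags <- fit_brdf(scan, "adaptive_grid")
  expect_lt(max(abs(coef(ags) - truth)), 5e-3)
  expect_lt(max(abs(coef(ags) - coef(lsq))), 1e-2)
})

test_that("a Lambertian scan fits to pure diffuse with negligible specular energy", {
  scan <- synth_brdf_scan(brdf_params(0.5, 1, 1), noise_sd = 0, seed = 4)
  fit <- fit_brdf(scan, "least_squares")
  expect_lt(abs(coef(fit)["k"] - 1), 0.02)
  # the n >= 1.1 stability bound leaves a small unavoidable specular floor
  spec <- fit$fitted - coef(fit)["k"] / pi
  expect_lt(sum(abs(spec)) / sum(fit$fitted), 1e-2)
  noisy <- synth_brdf_scan(brdf_params(0.5, 1, 1), noise_sd = 0.01, seed = 4)
  expect_lt(abs(coef(fit_brdf(noisy))["k"] - 1), 0.02)
})

test_that("fitted parameters always respect the configured bounds", {
  cfg <- fit_config()
  for (seed in 1:4) {
    scan <- synth_brdf_scan(brdf_params(0.9, 0.05, 4.8), noise_sd = 0.1,
                            seed = seed)
    for (m in c("least_squares", "adaptive_grid")) {
      p <- coef(fit_brdf(scan, m, cfg))
      expect_true(all(p >= cfg$lower - 1e-12))
      expect_true(all(p <= cfg$upper + 1e-12))
    }
  }
})

test_that("the adaptive grid SSE trace never increases", {
  scan <- synth_brdf_scan(canonical_params(), noise_sd = 0.05, seed = 9)
  fit <- fit_brdf(scan, "adaptive_grid")
  expect_true(all(diff(fit$sse_trace) <= 1e-15))
  expect_equal(fit$sse, min(fit$sse_trace))
})

test_that("refitting the model's own predictions returns the same parameters", {
  scan <- synth_brdf_scan(canonical_params(), noise_sd = 0.05, seed = 13)
  fit <- fit_brdf(scan, "least_squares")
  replay <- scan
  replay$f_samp_sr <- fit$fitted
  refit <- fit_brdf(replay, "least_squares")
  expect_lt(max(abs(coef(refit) - coef(fit))), 1e-4)
})

test_that("noiseless recovery holds across random truths for both solvers", {
  set.seed(321)
  truths <- replicate(8, c(runif(1, 0.05, 0.95), runif(1, 0.05, 0.95),
                           runif(1, 1.15, 4.8)), simplify = FALSE)
  for (i in seq_along(truths)) {
    tr <- truths[[i]]
    scan <- synth_brdf_scan(brdf_params(tr[1], tr[2], tr[3]), noise_sd = 0,
                            seed = 500 + i)
    expect_lt(max(abs(coef(fit_brdf(scan, "least_squares")) - tr)), 1e-2)
    expect_lt(max(abs(coef(fit_brdf(scan, "adaptive_grid")) - tr)), 1e-2)
  }
})

test_that("under 5% noise sigma and k recover closely; n is the soft direction", {
  # the Fresnel factor varies slowly with n, so reflectance noise maps to a
  # wider n uncertainty than for sigma or k
  set.seed(17)
  truths <- replicate(12, c(runif(1, 0.1, 0.6), runif(1, 0.05, 0.5),
                            runif(1, 1.8, 3.5)), simplify = FALSE)
  fits <- lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]
    scan <- synth_brdf_scan(brdf_params(tr[1], tr[2], tr[3]),
                            noise_sd = 0.05, seed = 700 + i)
    fit <- fit_brdf(scan, "least_squares")
    list(err = abs(coef(fit) - tr), r2 = fit$r_squared)
  })
  med <- apply(sapply(fits, `[[`, "err"), 1, median)
  expect_lt(med["sigma"], 0.05)
  expect_lt(med["k"], 0.05)
  expect_lt(med["n"], 0.15)
  # on leaf-like parameters the fits explain the angular structure well
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  expect_gte(mean(r2 >= 0.95), 0.9)
})

test_that("multi-band scans are fitted independently per wavelength", {
  s1 <- synth_brdf_scan(brdf_params(0.3, 0.2, 2.2, 468.36), noise_sd = 0,
                        seed = 1)
  s2 <- synth_brdf_scan(brdf_params(0.3, 0.4, 2.0, 819.88), noise_sd = 0,
                        seed = 2)
  fits <- fit_brdf_scan(rbind(s1, s2))
  expect_named(fits, c("468.36", "819.88"))
  expect_lt(abs(coef(fits[["468.36"]])["k"] - 0.2), 1e-3)
  expect_lt(abs(coef(fits[["819.88"]])["k"] - 0.4), 1e-3)
})

test_that("fit objects expose the standard modelling methods", {
  scan <- synth_brdf_scan(canonical_params(), noise_sd = 0.02, seed = 8)
  fit <- fit_brdf(scan)
  expect_named(coef(fit), c("sigma", "k", "n"))
  expect_length(residuals(fit), fit$n_points)
  expect_equal(predict(fit), fit$fitted)
  nd <- data.frame(theta_leaf_deg = 30, view_zenith_deg = c(40, 60, 80))
  expect_length(predict(fit, nd), 3)
  expect_output(print(fit), "Cook-Torrance")
  expect_output(summary(fit), "residual quartiles")
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "reflectance_dataset")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
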