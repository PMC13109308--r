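test_that("every generator is a pure function of its specification and seed", {
  expect_identical(synth_brdf_scan(canonical_params(), seed = 3),
                   synth_brdf_scan(canonical_params(), seed = 3))
  expect_false(identical(synth_brdf_scan(canonical_params(), seed = 3),
                         synth_brdf_scan(canonical_params(), seed = 4)))
  expect_identical(synth_whiteboard_scan(seed = 5),
                   synth_whiteboard_scan(seed = 5))
  expect_identical(synth_section_image(6, 40, seed = 6)$pixels,
                   synth_section_image(6, 40, seed = 6)$pixels)
  expect_identical(synth_trait_dataset(60, seed = 7),
                   synth_trait_dataset(60, seed = 7))
  expect_identical(synth_canopy(2, 5, seed = 8)$triangles,
                   synth_canopy(2, 5, seed = 8)$triangles)
})

test_that("whiteboard scans follow the cosine law at the configured noise level", {
  clean <- synth_whiteboard_scan(noise_sd = 0, seed = 1)
  expect_equal(lambertian_check(clean$intensity,
                                clean$view_zenith_deg)$r_squared, 1,
               tolerance = 1e-12)
  expect_equal(nrow(clean), 19)
  expect_true(all(cos(clean$view_zenith_deg * pi / 180) > 0))
  noisy <- synth_whiteboard_scan(noise_sd = 0.01, seed = 7)
  expect_gte(lambertian_check(noisy$intensity,
                              noisy$view_zenith_deg)$r_squared, 0.99)
})

test_that("scan generator inverts the calibration exactly at zero noise", {
  scan <- synth_brdf_scan(brdf_params(0.5, 1, 1), noise_sd = 0, seed = 2)
  expect_equal(scan$f_samp_sr, rep(1 / pi, nrow(scan)), tolerance = 1e-12)
  expect_equal(scan$f_samp_sr,
               fsamp_from_fluxes(scan$flux_sample, scan$flux_reference))
})

test_that("section images carry their analytic arc-length roughness", {
  expect_equal(synth_section_image(0, 40, seed = 1)$analytic_rho, 1)
  img <- synth_section_image(8, 40, seed = 1)
  expect_equal(img$analytic_rho, 1.320658, tolerance = 1e-5)
  expect_gt(synth_section_image(16, 40, seed = 1)$analytic_rho,
            img$analytic_rho)
  expect_error(synth_section_image(8, 3, seed = 1), "period")
  expect_error(synth_section_image(120, 40, height = 200, seed = 1),
               "amplitude")
})

test_that("trait datasets reproduce the observed correlation structure", {
  d <- synth_trait_dataset(n_samples = 270, seed = 11)
  expect_equal(dim(d), c(270, 12))
  expect_true(all(el_feature_names %in% names(d)))
  expect_gt(cor(d$sigma, d$rho), 0.5)              # sigma rises with rho
  expect_gt(cor(d$k, d$wavelength_nm), 0.5)        # k rises with wavelength
  expect_lt(cor(d$n, d$thickness_mm), -0.3)        # n falls with thickness
  expect_lt(cor(d$n, d$slw_g_m2), -0.3)            # and with SLW
  expect_gt(cor(d$slw_g_m2, d$thickness_mm), 0.3)  # SLW tracks thickness
  expect_true(all(d$sigma >= 0.01 & d$sigma <= 0.99))
  expect_true(all(d$n >= 1.1 & d$n <= 5))
})

test_that("a noise-free trait dataset is predicted almost perfectly", {
  d0 <- synth_trait_dataset(n_samples = 120, noise_sd = 0, seed = 2)
  m <- train_el(d0, "sigma", cv_folds = 5)
  expect_gte(m$report$r_squared, 0.99)
})

test_that("synthetic canopies honor their layer layout", {
  mesh <- synth_canopy(10, 50, optics = c(0.3, 0.35, 1.0), seed = 4)
  expect_equal(nrow(mesh$triangles), 500)
  prof <- layer_summary(mesh, rep(1, 500), n_layers = 10, z_range = c(0, 1))
  expect_equal(prof$facet_counts, rep(50L, 10))
  one <- synth_canopy(1, 1, optics = c(0.3, 0.2, 1.0), leaf_angle_deg = 0,
                      seed = 5)
  expect_equal(nrow(one$triangles), 1)
  expect_true(one$triangles$cz > 0 && one$triangles$cz < 1)
  per_layer <- synth_canopy(2, 4, optics = list(c(0.3, 0.1, 1),
                                                c(0.3, 0.4, 2.2)), seed = 6)
  expect_equal(per_layer$triangles$k, rep(c(0.1, 0.4), each = 4))
})

test_that("forward scans round-trip through the fitters for the canopy parameter sets", {
  for (s in canopy_parameter_sets()) {
    scan <- synth_brdf_scan(brdf_params(s[1], s[2], s[3]), noise_sd = 0,
                            seed = 31)
    fit <- fit_brdf(scan, "least_squares")
    if (s[3] > 1 && s[1] <= 0.99) {
      # identifiable and inside the stability bounds: full recovery
      expect_lt(max(abs(coef(fit) - s)), 1e-2)
    } else if (s[3] > 1) {
      # sigma = 1 lies outside the stability bound [0.01, 0.99]: sigma pins
      # to the bound, the other parameters compensate slightly
      expect_equal(unname(coef(fit)["sigma"]), 0.99, tolerance = 1e-6)
      expect_lt(abs(coef(fit)["k"] - s[2]), 2e-2)
      expect_lt(abs(coef(fit)["n"] - s[3]), 1e-1)
      expect_lt(fit$rmse, 1e-3)
    } else {
      # n = 1: the specular factors drop out of the forward model, so only
      # k is identified; the n >= 1.1 bound leaves a small specular floor
      expect_lt(abs(coef(fit)["k"] - s[2]), 1e-2)
      expect_lt(fit$rmse, 5e-3)
    }
  }
})
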