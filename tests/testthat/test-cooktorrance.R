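test_that("parameter triples enforce their physical bounds", {
  p <- brdf_params(0.3, 0.35, 2.2, 556.26)
  expect_s3_class(p, "brdf_params")
  expect_error(brdf_params(-0.1, 0.5, 2), "sigma")
  expect_error(brdf_params(0.5, 1.5, 2), "k")
  expect_error(brdf_params(0.5, 0.5, 6), "n")
})

test_that("Fresnel factor matches its limits and the normal-incidence closed form", {
  expect_equal(fresnel(1, 0.8), 0)
  expect_equal(fresnel(1, runif(5)), rep(0, 5))
  for (n in c(1.2, 1.5, 2.2, 3, 4.5)) {
    expect_equal(fresnel(n, 1), ((n - 1) / (n + 1))^2, tolerance = 1e-12)
  }
  expect_equal(fresnel(2.2, 0), 1)
  expect_equal(fresnel(2.2, 1e-9), 1, tolerance = 1e-6)
  # monotone non-decreasing toward grazing for fixed n
  cosg <- seq(1, 0.001, length.out = 200)
  for (n in c(1.05, 1.5, 3)) {
    expect_true(all(diff(fresnel(n, cosg)) >= -1e-12))
  }
  expect_true(all(fresnel(1.8, runif(100)) >= 0))
  expect_true(all(fresnel(1.8, runif(100)) <= 1))
  expect_error(fresnel(2, -0.1), "cos_theta_h")
})

test_that("Beckmann distribution equals its direct formula", {
  expect_equal(beckmann(0, 0.5), 4)
  expect_equal(beckmann(0, 1), 1)
  expect_equal(beckmann(atan(0.3), 0.3), 4.856417, tolerance = 1e-6)
  # oracle equality on a grid, not a shape assumption
  a <- seq(0, 1.4, length.out = 50)
  for (s in c(0.1, 0.3, 0.8)) {
    expect_equal(beckmann(a, s), exp(-(tan(a) / s)^2) / (s^2 * cos(a)^4))
  }
  expect_error(beckmann(pi / 2, 0.3), "alpha")
  expect_error(beckmann(0.1, 0), "sigma")
})

test_that("geometric attenuation is bounded by one and unity in symmetric frames", {
  fr <- geometry_frame(theta_leaf_deg = 0, view_zenith_deg = 0)
  expect_equal(geometric_attenuation(fr), 1)
  # in-plane specular at 45 degrees: H = N, G = min(1, 2cos45/cos45) = 1
  fr45 <- geometry_frame(theta_leaf_deg = 45, view_zenith_deg = 90)
  expect_lt(fr45$alpha, 1e-6)
  expect_equal(geometric_attenuation(fr45), 1)
  set.seed(3)
  for (i in 1:50) {
    fr <- geometry_frame(theta_leaf_deg = runif(1, 0, 55),
                         view_zenith_deg = runif(1, 0, 100),
                         view_azimuth_deg = runif(1, 0, 360))
    if (!fr$degenerate) {
      expect_lte(geometric_attenuation(fr), 1)
      expect_gt(geometric_attenuation(fr), 0)
    }
  }
})

test_that("the BRDF reduces to the Lambertian value when the Fresnel term vanishes", {
  set.seed(5)
  for (i in 1:20) {
    fr <- geometry_frame(theta_leaf_deg = runif(1, 0, 50),
                         view_zenith_deg = runif(1, 0, 80))
    expect_equal(brdf_value(brdf_params(runif(1, 0.05, 0.95), 1, 1), fr),
                 1 / pi)
    expect_equal(brdf_value(brdf_params(0.3, 0.35, 1), fr), 0.35 / pi)
  }
  fr <- geometry_frame(theta_leaf_deg = 30, view_zenith_deg = 60)
  expect_equal(brdf_value(brdf_params(0.5, 0.35, 1), fr), 0.111408,
               tolerance = 1e-5)
})

test_that("the specular normalization conventions rescale the specular term only", {
  fr <- geometry_frame(theta_leaf_deg = 30, view_zenith_deg = 60)
  p <- brdf_params(0.3, 0.2, 2.2)
  f_def <- brdf_value(p, fr)
  f_pi <- brdf_value(p, fr, convention = "pi")
  f_four <- brdf_value(p, fr, convention = "four")
  spec <- f_def - p$k / pi
  expect_equal(f_pi - p$k / pi, spec * (2 * pi^2) / pi, tolerance = 1e-12)
  expect_equal(f_four - p$k / pi, spec * (2 * pi^2) / 4, tolerance = 1e-12)
  expect_error(brdf_value(p, fr, convention = "bogus"))
})

test_that("term-by-term assembly matches an independent evaluation at a specular frame", {
  # theta_i = theta_v = 30 degrees in-plane: independent evaluation of the
  # four factors composed by hand
  fr <- geometry_frame(theta_leaf_deg = 30, view_zenith_deg = 60)
  p <- brdf_params(0.3, 0.01, 2.2)
  Fv <- fresnel(2.2, fr$cos_theta_h)
  Dv <- beckmann(fr$alpha, 0.3)
  Gv <- geometric_attenuation(fr)
  by_hand <- Fv * Dv * Gv / (2 * pi^2 * fr$cos_LN * fr$cos_NV) + 0.01 / pi
  expect_equal(brdf_value(p, fr), by_hand, tolerance = 1e-12)
  expect_gt(by_hand, 0.01 / pi)
})

test_that("the BRDF errors on degenerate frames and is continuous in its parameters", {
  fr_bad <- geometry_frame(theta_leaf_deg = 0, view_zenith_deg = 120)
  expect_error(brdf_value(brdf_params(0.3, 0.3, 2), fr_bad), "degenerate")
  fr <- geometry_frame(theta_leaf_deg = 30, view_zenith_deg = 55)
  base <- brdf_value(brdf_params(0.4, 0.3, 2.0), fr)
  for (dp in list(c(1e-7, 0, 0), c(0, 1e-7, 0), c(0, 0, 1e-7))) {
    pert <- brdf_value(brdf_params(0.4 + dp[1], 0.3 + dp[2], 2.0 + dp[3]), fr)
    expect_lt(abs(pert - base), 1e-4)
  }
})

test_that("the vectorized kernel agrees with the scalar BRDF", {
  ft <- leafbrdf:::frame_table(rep(c(0, 30, 55), 4),
                               rep(seq(10, 80, by = 20), 3))
  ft <- ft[!ft$degenerate, ]
  f_vec <- leafbrdf:::brdf_eval(0.3, 0.2, 2.2, ft, 2 * pi^2)
  for (i in seq_len(nrow(ft))) {
    fr <- geometry_frame(theta_leaf_deg = ft$theta_leaf_deg[i],
                         view_zenith_deg = ft$view_zenith_deg[i])
    expect_equal(f_vec[i], brdf_value(brdf_params(0.3, 0.2, 2.2), fr),
                 tolerance = 1e-12)
  }
})
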