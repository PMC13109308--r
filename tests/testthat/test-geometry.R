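test_that("holder scale converts to leaf inclination about the 95-degree reference", {
  expect_equal(leaf_angle_from_holder(95), 0)
  expect_equal(leaf_angle_from_holder(65), 30)
  expect_equal(leaf_angle_from_holder(140), -45)
  expect_warning(leaf_angle_from_holder(200), "outside")
})

test_that("direction vectors are unit length and match their closed forms", {
  expect_equal(illumination_vector(), c(0, -1, 0))
  expect_equal(sum(illumination_vector()^2), 1)
  expect_equal(normal_vector(0), c(0, -1, 0))
  expect_equal(normal_vector(90), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(normal_vector(30), c(0.5, -0.866025, 0), tolerance = 1e-6)
  expect_equal(viewing_vector(0, 123), c(0, -1, 0))
  expect_equal(viewing_vector(90, 0), c(1, 0, 0), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:100) {
    v <- viewing_vector(runif(1, -5, 175), runif(1, 0, 360))
    expect_equal(sum(v^2), 1, tolerance = 1e-9)
  }
})

test_that("the as-printed viewing form normalizes but degenerates at zero zenith", {
  v <- viewing_vector(30, 0, v_form = "as_printed")
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
  expect_error(viewing_vector(0, 0, v_form = "as_printed"), "zero vector")
})

test_that("half-vector bisects, is symmetric, and rejects antiparallel inputs", {
  L <- c(0, -1, 0)
  expect_equal(half_vector(L, L), L)
  expect_equal(half_vector(L, c(1, 0, 0)),
               c(0.70711, -0.70711, 0), tolerance = 1e-5)
  V <- leafbrdf:::.unitize(c(0.3, -0.5, 0.2))
  expect_equal(half_vector(L, V), half_vector(V, L))
  expect_error(half_vector(L, -L), "antiparallel")
})

test_that("geometry frames populate angles and flag degenerate configurations", {
  fr <- geometry_frame(theta_leaf_deg = 0, view_zenith_deg = 0)
  expect_equal(fr$alpha, 0, tolerance = 1e-12)
  expect_equal(fr$theta_h, 0, tolerance = 1e-12)
  expect_equal(fr$L, fr$V)
  fr2 <- geometry_frame(theta_leaf_deg = 0, view_zenith_deg = 90)
  expect_equal(fr2$theta_h, pi / 4, tolerance = 1e-12)
  expect_true(fr2$degenerate)   # detector exactly in the leaf plane
  expect_false(geometry_frame(theta_leaf_deg = 0,
                              view_zenith_deg = 60)$degenerate)
  # detector behind the leaf plane
  fr3 <- geometry_frame(theta_leaf_deg = 0, view_zenith_deg = 120)
  expect_true(fr3$degenerate)
  # cosines bounded
  set.seed(7)
  for (i in 1:50) {
    fr <- geometry_frame(theta_leaf_deg = runif(1, 0, 60),
                         view_zenith_deg = runif(1, -5, 175),
                         view_azimuth_deg = runif(1, 0, 360))
    cosines <- unlist(fr[c("cos_LN", "cos_NV", "cos_NH", "cos_VH",
                           "cos_theta_h")])
    expect_true(all(abs(cosines) <= 1 + 1e-12))
  }
})

test_that("theta_h from L.H equals half the phase angle (bisector identity)", {
  set.seed(11)
  for (i in 1:50) {
    fr <- geometry_frame(theta_leaf_deg = runif(1, 0, 55),
                         view_zenith_deg = runif(1, 0, 90),
                         view_azimuth_deg = runif(1, 0, 360))
    phase <- acos(max(-1, min(1, sum(fr$L * fr$V))))
    expect_equal(fr$theta_h, phase / 2, tolerance = 1e-9)
  }
})

test_that("frames are invariant to full-turn shifts of any input angle", {
  fr1 <- geometry_frame(theta_leaf_deg = 30, view_zenith_deg = 50,
                        view_azimuth_deg = 40)
  fr2 <- geometry_frame(theta_leaf_deg = 30 + 360, view_zenith_deg = 50 + 360,
                        view_azimuth_deg = 40 + 360)
  expect_equal(fr1[c("L", "N", "V", "H", "alpha", "theta_h")],
               fr2[c("L", "N", "V", "H", "alpha", "theta_h")],
               tolerance = 1e-9)
})

test_that("the vectorized frame table matches single-frame construction", {
  tab <- leafbrdf:::frame_table(c(0, 30, 55), c(10, 60, 120), c(0, 15, 200))
  for (i in 1:3) {
    fr <- geometry_frame(theta_leaf_deg = tab$theta_leaf_deg[i],
                         view_zenith_deg = tab$view_zenith_deg[i],
                         view_azimuth_deg = tab$view_azimuth_deg[i])
    expect_equal(tab$cos_LN[i], fr$cos_LN, tolerance = 1e-12)
    expect_equal(tab$cos_NV[i], fr$cos_NV, tolerance = 1e-12)
    expect_equal(tab$alpha[i], fr$alpha, tolerance = 1e-12)
    expect_equal(tab$degenerate[i], fr$degenerate)
  }
})
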