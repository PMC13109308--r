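test_that("mesh construction validates geometry and optics", {
  tri <- rect_facets(0, 0, 1, 1, 0.5, 0.3, 0.35, 1, 0.05)
  m <- canopy_mesh(tri)
  expect_equal(nrow(m$triangles), 2)
  expect_equal(sum(m$triangles$area), 1, tolerance = 1e-12)
  expect_equal(abs(m$triangles$nz), c(1, 1), tolerance = 1e-12)
  expect_error(canopy_mesh(tri[, -1]), "v1x")
  bad <- tri; bad$v1x[1] <- NA
  expect_error(canopy_mesh(bad), "unbounded")
  bad <- tri; bad$tau <- 1.5
  expect_error(canopy_mesh(bad), "tau")
  degen <- tri; degen[1, 4:6] <- degen[1, 1:3]
  expect_error(canopy_mesh(degen), "degenerate")
})

test_that("hemispherical reflectance matches closed forms for diffuse surfaces", {
  expect_equal(directional_hemispherical_reflectance(
    brdf_params(0.5, 1, 1), c(0, 0, -1)), 1)
  expect_equal(directional_hemispherical_reflectance(
    brdf_params(0.5, 0, 1), c(0, 0, -1)), 0)
  # quadrature route must agree with the Lambertian closed form: force the
  # integration path by using n marginally above 1 with a zero-weight lobe
  p <- brdf_params(0.3, 0.35, 1 + 1e-12)
  expect_lt(abs(directional_hemispherical_reflectance(p, c(0, 0, -1)) - 0.35),
            1e-4)
  expect_error(directional_hemispherical_reflectance(
    brdf_params(0.3, 0.5, 2), c(0, 0, -1), n_quad = 4), "n_quad")
  # physical range across parameter and incidence spread
  for (n in c(1.3, 2.2, 3.5)) for (ci in c(0.95, 0.5, 0.15)) {
    R <- suppressWarnings(directional_hemispherical_reflectance(
      brdf_params(0.3, 0.2, n), c(sqrt(1 - ci^2), 0, -ci), n_quad = 32))
    expect_gte(R, 0); expect_lte(R, 1)
  }
})

test_that("scatter sampling honors event probabilities and determinism", {
  # no reflectance, no transmittance: always absorb
  set.seed(1)
  for (i in 1:20) {
    ev <- sample_scatter_direction(brdf_params(0.3, 0, 1), c(0, 0, -1),
                                   tau = 0)
    expect_identical(ev$event, "absorb")
  }
  set.seed(7); a <- replicate(30, sample_scatter_direction(
    brdf_params(0.3, 0.5, 1), c(0, 0, -1), tau = 0.3)$event)
  set.seed(7); b <- replicate(30, sample_scatter_direction(
    brdf_params(0.3, 0.5, 1), c(0, 0, -1), tau = 0.3)$event)
  expect_identical(a, b)
  expect_error(sample_scatter_direction(brdf_params(0.3, 1, 1), c(0, 0, -1),
                                        tau = 0.5), "exceeds 1")
})

test_that("Lambertian reflection directions are cosine-weighted", {
  set.seed(123)
  z <- replicate(5000, sample_scatter_direction(
    brdf_params(0.3, 1, 1), c(0, 0, -1), tau = 0)$direction[3])
  expect_true(all(z > 0))
  # cos-weighted zenith: z^2 is uniform on (0, 1)
  counts <- table(cut(z^2, breaks = seq(0, 1, by = 0.1)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("photon ledger is conserved exactly and empty meshes pass photons through", {
  r0 <- trace_photons(empty_mesh(), photon_source(n_photons = 500, seed = 2))
  expect_equal(unname(r0$ledger["exited"]), 500)
  mesh <- synth_canopy(2, 15, optics = c(0.3, 0.35, 1.0), seed = 3)
  r <- trace_photons(mesh, photon_source(n_photons = 3000, seed = 4))
  expect_identical(unname(sum(r$ledger[c("absorbed", "exited",
                                         "max_bounces")])),
                   unname(r$ledger["emitted"]))
  expect_true(all(r$facet_scattered_ppfd >= 0))
})

test_that("black facets scatter nothing", {
  tri <- rbind(rect_facets(0, 0, 1, 1, 0.8, 0.3, 0, 1, 0),
               rect_facets(0.2, 0.2, 0.8, 0.8, 0.2, 0.3, 0, 1, 0))
  r <- trace_photons(canopy_mesh(tri), photon_source(n_photons = 2000,
                                                     seed = 5))
  expect_equal(sum(r$facet_scattered_ppfd), 0)
  expect_gt(sum(r$facet_direct_ppfd), 0)
})

test_that("scattered flux scales linearly with source PPFD at fixed seed", {
  mesh <- synth_canopy(2, 15, optics = c(0.3, 0.35, 1.0), seed = 6)
  r1 <- trace_photons(mesh, photon_source(ppfd = 1000, n_photons = 4000,
                                          seed = 8))
  r2 <- trace_photons(mesh, photon_source(ppfd = 3000, n_photons = 4000,
                                          seed = 8))
  expect_equal(r2$facet_scattered_ppfd, 3 * r1$facet_scattered_ppfd,
               tolerance = 1e-12)
})

test_that("with all-Lambertian facets results are invariant to sigma", {
  m1 <- synth_canopy(2, 15, optics = c(0.1, 0.35, 1.0), seed = 9)
  m2 <- synth_canopy(2, 15, optics = c(0.9, 0.35, 1.0), seed = 9)
  src <- photon_source(n_photons = 4000, seed = 10)
  expect_equal(trace_photons(m1, src)$facet_scattered_ppfd,
               trace_photons(m2, src)$facet_scattered_ppfd)
})

test_that("bottom-to-top scattered flux matches the parallel-plate view-factor oracle", {
  # full-domain Lambertian floor; small absorbing plate suspended above it.
  # expected first-arrival scattered flux on the plate = sum over floor hits
  # of the analytic differential-element-to-parallel-rectangle view factor.
  tri <- rbind(rect_facets(0, 0, 1, 1, 0, 0.3, 1, 1, 0),
               rect_facets(0.4, 0.4, 0.6, 0.6, 0.3, 0.3, 0.01, 1, 0))
  mesh <- canopy_mesh(tri)
  src <- photon_source(ppfd = 1000, n_photons = 60000, seed = 9)
  r <- trace_photons(mesh, src)
  top_flux <- sum(r$facet_scattered_ppfd[3:4] * mesh$triangles$area[3:4])
  vf_corner <- function(a, b, h) {
    X <- a / h; Y <- b / h
    (X / sqrt(1 + X^2) * atan(Y / sqrt(1 + X^2)) +
       Y / sqrt(1 + Y^2) * atan(X / sqrt(1 + Y^2))) / (2 * pi)
  }
  g <- function(a, b, h) sign(a) * sign(b) * vf_corner(abs(a), abs(b), h)
  vf_point <- function(px, py) {
    g(0.6 - px, 0.6 - py, 0.3) - g(0.6 - px, 0.4 - py, 0.3) -
      g(0.4 - px, 0.6 - py, 0.3) + g(0.4 - px, 0.4 - py, 0.3)
  }
  gr <- seq(0.5 / 400, 1 - 0.5 / 400, length.out = 400)
  G <- outer(gr, gr, Vectorize(function(x, y) {
    if (x >= 0.4 && x <= 0.6 && y >= 0.4 && y <= 0.6) NA else vf_point(x, y)
  }))
  Evf <- mean(G, na.rm = TRUE)
  frac_open <- mean(!is.na(G))
  expected <- src$n_photons * frac_open * Evf * r$weight
  se <- r$weight * sqrt(src$n_photons * frac_open * Evf)
  expect_lt(abs(top_flux - expected), 3 * se)
})

test_that("layer summaries bin facets by centroid height with area weights", {
  mesh <- synth_canopy(2, 20, optics = c(0.3, 0.35, 1.0), seed = 12)
  ppfd <- seq_len(nrow(mesh$triangles))
  one <- layer_summary(mesh, ppfd, n_layers = 1)
  expect_equal(one$mean_scattered_ppfd,
               sum(ppfd * mesh$triangles$area) / sum(mesh$triangles$area))
  # all facets in the top half of the domain: bottom layer empty, mean 0
  tri <- rect_facets(0, 0, 1, 1, 0.9, 0.3, 0.3, 1, 0)
  tri <- rbind(tri, rect_facets(0, 0, 1, 1, 0.8, 0.3, 0.3, 1, 0))
  m2 <- canopy_mesh(tri)
  prof <- layer_summary(m2, rep(5, 4), n_layers = 2, z_range = c(0, 1))
  expect_equal(prof$facet_counts, c(0L, 4L))
  expect_equal(prof$mean_scattered_ppfd, c(0, 5))
  prof10 <- layer_summary(mesh, ppfd, n_layers = 10)
  expect_equal(sum(prof10$facet_counts), nrow(mesh$triangles))
  expect_equal(sum(prof10$histogram), nrow(mesh$triangles))
  expect_output(print(prof10), "layer profile")
})
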