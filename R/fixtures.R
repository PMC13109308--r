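## Seeded synthetic-data generators. Every generator is a pure function of
## (specification, seed): identical arguments give identical output. They
## emulate the study conditions: goniometer reflectance scans on the standard
## geometry grid, Lambertian whiteboard scans, cross-section images with a
## known analytic roughness, trait tables with the observed correlation
## structure, and small layered triangle-mesh canopies.

#' Synthetic goniometer reflectance scan
#'
#' Forward-evaluates the Cook-Torrance model on the instrument geometry grid
#' (default: incidence angles 0, 30, 45 and 55 degrees, i.e. 0, pi/6, pi/4
#' and 11pi/36; detection ring sampled every 5 degrees over -5..175 degrees),
#' inverts the whiteboard calibration to raw flux pairs (reference flux
#' proportional to the cosine of the detection angle off the surface normal),
#' applies multiplicative Gaussian noise to both fluxes, and re-calibrates.
#' Geometries with the source or detector behind the leaf plane are excluded.
#'
#' @param params True [brdf_params()].
#' @param incidence_deg Incidence (leaf inclination) angles in degrees.
#' @param ring_deg Detection-ring angles in degrees.
#' @param noise_sd Multiplicative Gaussian noise sd on each flux (default
#'   0.05, spectrometer-like; 0 gives a noiseless scan).
#' @param seed Integer seed.
#' @param convention Specular normalization tag, see [brdf_value()].
#' @param v_form Viewing-vector convention.
#' @return Calibrated reflectance dataset (as from [calibrate_scan()]).
#' @examples
#' scan <- synth_brdf_scan(brdf_params(0.3, 0.35, 2.2), noise_sd = 0, seed = 1)
#' range(scan$f_samp_sr)
#' @export
synth_brdf_scan <- function(params,
                            incidence_deg = c(0, 30, 45, 55),
                            ring_deg = seq(-5, 175, by = 5),
                            noise_sd = 0.05, seed = 1,
                            convention = c("as_printed", "pi", "four"),
                            v_form = c("corrected", "as_printed")) {
  convention <- match.arg(convention)
  v_form <- match.arg(v_form)
  if (!inherits(params, "brdf_params")) {
    params <- brdf_params(params[1], params[2], params[3])
  }
  grid <- expand.grid(theta_leaf_deg = incidence_deg,
                      view_zenith_deg = ring_deg)
  ft <- frame_table(grid$theta_leaf_deg, grid$view_zenith_deg, 0, v_form)
  ft <- ft[!ft$degenerate, , drop = FALSE]
  f_true <- brdf_eval(params$sigma, params$k, params$n, ft,
                      .convention_constant(convention))
  flux_ref <- ft$cos_NV                 # Lambertian reference, up to scale
  flux_samp <- f_true * pi * flux_ref
  set.seed(seed)
  nrows <- nrow(ft)
  flux_samp <- flux_samp * (1 + stats::rnorm(nrows, 0, noise_sd))
  flux_ref <- flux_ref * (1 + stats::rnorm(nrows, 0, noise_sd))
  flux_samp <- pmax(flux_samp, 0)
  flux_ref <- pmax(flux_ref, 1e-9)
  scan <- data.frame(
    wavelength_nm = if (is.finite(params$wavelength_nm))
      params$wavelength_nm else 556.26,
    holder_scale_deg = 95 - ft$theta_leaf_deg,
    incident_zenith_deg = ft$theta_leaf_deg,
    incident_azimuth_deg = 0,
    view_zenith_deg = ft$view_zenith_deg,
    view_azimuth_deg = ft$view_azimuth_deg,
    flux_sample = flux_samp,
    flux_reference = flux_ref
  )
  calibrate_scan(scan, v_form = v_form, quiet = TRUE)
}

#' Synthetic Lambertian whiteboard scan
#'
#' Reflected intensity proportional to the cosine of the detection angle with
#' multiplicative Gaussian noise; detection angles with negative cosine are
#' excluded.
#'
#' @param noise_sd Multiplicative noise sd (default 0.01).
#' @param angles_deg Detection zenith angles; default 19 equally spaced
#'   angles in `[0, 90)` degrees.
#' @param seed Integer seed.
#' @param intensity_scale Peak (normal-view) intensity.
#' @return Data frame with `view_zenith_deg` and `intensity`.
#' @export
synth_whiteboard_scan <- function(noise_sd = 0.01,
                                  angles_deg = utils::head(
                                    seq(0, 90, length.out = 20), 19),
                                  seed = 7, intensity_scale = 1) {
  angles_deg <- angles_deg[cos(deg2rad(angles_deg)) > 0]
  set.seed(seed)
  intensity <- intensity_scale * cos(deg2rad(angles_deg)) *
    (1 + stats::rnorm(length(angles_deg), 0, noise_sd))
  data.frame(view_zenith_deg = angles_deg, intensity = intensity)
}

#' Synthetic leaf cross-section image with known roughness
#'
#' Generates a tissue band whose upper (adaxial) boundary is the sinusoid
#' `y(x) = height/2 + amplitude * sin(2 pi x / period)` plus speckle noise,
#' and returns the analytic roughness of the generating curve: the ratio of
#' its arc length (by quadrature of `sqrt(1 + y'(x)^2)`) to the flat chord.
#'
#' @param amplitude_px Sinusoid amplitude in pixels (must be < height/2).
#' @param period_px Sinusoid period in pixels (> 4).
#' @param width,height Image size in pixels.
#' @param noise_sd Additive intensity speckle sd.
#' @param seed Integer seed.
#' @return Object of class `section_image`: list with `pixels` (height x
#'   width matrix in \[0,1\]), `analytic_rho`, and the generating `boundary`
#'   row per column.
#' @export
synth_section_image <- function(amplitude_px, period_px, width = 400,
                                height = 200, noise_sd = 0.02, seed = 1) {
  if (period_px <= 4) stop("period must exceed 4 px", call. = FALSE)
  if (amplitude_px >= height / 2) {
    stop("amplitude must be below height/2", call. = FALSE)
  }
  x <- seq_len(width)
  boundary <- height / 2 + amplitude_px * sin(2 * pi * (x - 1) / period_px)
  set.seed(seed)
  px <- matrix(0.12, nrow = height, ncol = width)
  for (j in x) {
    rows <- seq_len(height) >= boundary[j]
    px[rows, j] <- 0.75
  }
  px <- px + matrix(stats::rnorm(height * width, 0, noise_sd), height, width)
  px[px < 0] <- 0
  px[px > 1] <- 1
  arc <- if (amplitude_px == 0) 1 else {
    slope <- function(u) {
      a <- amplitude_px * 2 * pi / period_px
      sqrt(1 + (a * cos(2 * pi * u / period_px))^2)
    }
    stats::integrate(slope, 0, period_px, subdivisions = 1000L,
                     rel.tol = 1e-10)$value / period_px
  }
  structure(list(pixels = px, analytic_rho = arc, boundary = boundary,
                 scale = NA_real_),
            class = "section_image")
}

#' Default effect specification linking traits to BRDF parameters
#'
#' Encodes the observed correlation structure: roughness sigma increases
#' linearly with the image roughness rho; the diffuse coefficient k increases
#' with wavelength (visible to near-infrared); the refractive index n
#' decreases with both leaf thickness and specific leaf weight.
#' @export
el_effect_spec <- function() {
  list(sigma = c(intercept = 0.08, rho = 0.6),
       k = c(intercept = 0.08, lambda = 0.45),
       n = c(intercept = 4.2, thickness = -4.0, slw = -0.025))
}

#' Synthetic trait-to-BRDF-parameter dataset
#'
#' Generates the nine phenotypic predictors (thickness, specific leaf weight,
#' three pigments, total chlorophyll, chlorophyll a/b ratio, surface
#' roughness, wavelength) with realistic ranges and the three BRDF-parameter
#' targets from the linear effect specification plus Gaussian noise; targets
#' are clipped to the physical parameter bounds. Thickness and specific leaf
#' weight are positively correlated, as in real leaves.
#'
#' @param n_samples Number of rows (default 270).
#' @param effects Effect specification, see [el_effect_spec()].
#' @param noise_sd Gaussian noise sd on each target (default 0.03).
#' @param seed Integer seed.
#' @return Data frame with the nine feature columns (`thickness_mm`,
#'   `slw_g_m2`, `chl_a`, `chl_b`, `car`, `chl_ab`, `chl_ratio`, `rho`,
#'   `wavelength_nm`) and targets `sigma`, `k`, `n`.
#' @export
synth_trait_dataset <- function(n_samples = 270, effects = el_effect_spec(),
                                noise_sd = 0.03, seed = 1) {
  stopifnot(n_samples >= 50)
  set.seed(seed)
  thickness <- pmax(0.1, stats::rnorm(n_samples, 0.25, 0.06))
  slw <- pmax(5, 30 + 100 * (thickness - 0.25) +
                stats::rnorm(n_samples, 0, 6))
  a663 <- stats::runif(n_samples, 0.4, 0.9)
  a645 <- stats::runif(n_samples, 0.15, 0.35)
  a470 <- stats::runif(n_samples, 0.3, 0.7)
  pig <- pigment_contents(a663, a645, a470, quiet = TRUE)
  rho <- stats::runif(n_samples, 1.02, 1.6)
  wl <- sample(leaf_wavelengths, n_samples, replace = TRUE)
  lam_scaled <- (wl - 400) / 600
  e <- effects
  sigma <- e$sigma[["intercept"]] + e$sigma[["rho"]] * (rho - 1) +
    stats::rnorm(n_samples, 0, noise_sd)
  k <- e$k[["intercept"]] + e$k[["lambda"]] * lam_scaled +
    stats::rnorm(n_samples, 0, noise_sd)
  n <- e$n[["intercept"]] + e$n[["thickness"]] * thickness +
    e$n[["slw"]] * slw + stats::rnorm(n_samples, 0, noise_sd)
  data.frame(
    thickness_mm = thickness, slw_g_m2 = slw,
    chl_a = pig$chl_a, chl_b = pig$chl_b, car = pig$car,
    chl_ab = pig$chl_a + pig$chl_b,
    chl_ratio = pig$chl_a / pig$chl_b,
    rho = rho, wavelength_nm = wl,
    sigma = pmin(0.99, pmax(0.01, sigma)),
    k = pmin(0.99, pmax(0.01, k)),
    n = pmin(5, pmax(1.1, n))
  )
}

#' Synthetic layered triangle-mesh canopy
#'
#' Randomly placed, tilted triangular "leaves" inside a bounded box, arranged
#' in equal-thickness horizontal layers, each facet carrying Cook-Torrance
#' optical parameters and a transmittance. Optics may be one set for the whole
#' canopy or a list with one set per layer.
#'
#' @param n_layers Number of equal-thickness layers (>= 1).
#' @param facets_per_layer Triangles per layer (>= 1).
#' @param optics Numeric vector `c(sigma, k, n)` or list of such vectors,
#'   one per layer (bottom to top).
#' @param tau Facet transmittance in \[0, 1\] (default 0.05).
#' @param leaf_angle_deg Mean leaf inclination from horizontal; individual
#'   facets jitter by +-15 degrees.
#' @param domain Box size `c(x, y, z)` in meters (default 1 x 1 x 1).
#' @param leaf_size Triangle circumradius in meters.
#' @param seed Integer seed.
#' @return A [canopy_mesh()] object.
#' @export
synth_canopy <- function(n_layers = 3, facets_per_layer = 40,
                         optics = c(0.3, 0.35, 1.0), tau = 0.05,
                         leaf_angle_deg = 30, domain = c(1, 1, 1),
                         leaf_size = 0.08, seed = 1) {
  stopifnot(n_layers >= 1, facets_per_layer >= 1)
  if (!is.list(optics)) optics <- rep(list(optics), n_layers)
  stopifnot(length(optics) == n_layers)
  set.seed(seed)
  rows <- vector("list", n_layers * facets_per_layer)
  idx <- 1L
  dz <- domain[3] / n_layers
  for (l in seq_len(n_layers)) {
    op <- optics[[l]]
    for (f in seq_len(facets_per_layer)) {
      c0 <- c(stats::runif(1, leaf_size, domain[1] - leaf_size),
              stats::runif(1, leaf_size, domain[2] - leaf_size),
              stats::runif(1, (l - 1) * dz + 0.05 * dz, l * dz - 0.05 * dz))
      incl <- deg2rad(leaf_angle_deg + stats::runif(1, -15, 15))
      az <- stats::runif(1, 0, 2 * pi)
      nrm <- c(sin(incl) * cos(az), sin(incl) * sin(az), cos(incl))
      # orthonormal basis in the facet plane
      helper <- if (abs(nrm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u <- .unitize(pracma::cross(helper, nrm))
      v <- pracma::cross(nrm, u)
      ang <- stats::runif(1, 0, 2 * pi) + c(0, 2 * pi / 3, 4 * pi / 3)
      verts <- t(vapply(ang, function(a) {
        c0 + leaf_size * (cos(a) * u + sin(a) * v)
      }, numeric(3)))
      rows[[idx]] <- c(as.vector(t(verts)), op, tau)
      idx <- idx + 1L
    }
  }
  tri <- as.data.frame(do.call(rbind, rows))
  names(tri) <- c("v1x", "v1y", "v1z", "v2x", "v2y", "v2z",
                  "v3x", "v3y", "v3z", "sigma", "k", "n", "tau")
  canopy_mesh(tri)
}
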