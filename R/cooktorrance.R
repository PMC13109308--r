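## Cook-Torrance microfacet BRDF kernel: Fresnel factor, Beckmann slope
## distribution, geometric attenuation, and the assembled BRDF.

#' BRDF parameter triple
#'
#' Bundles the three Cook-Torrance parameters with their physical bounds:
#' roughness `sigma` (RMS microfacet slope) in \[0, 1\], diffuse reflection
#' coefficient `k` in \[0, 1\], refractive index `n` in \[1, 5\] (the usual
#' range for leaves). An optional wavelength tag records which spectral band
#' the triple belongs to.
#'
#' @param sigma,k,n Parameter values.
#' @param wavelength_nm Optional wavelength tag in nanometers.
#' @return Object of class `brdf_params`.
#' @export
brdf_params <- function(sigma, k, n, wavelength_nm = NA_real_) {
  stopifnot(is.finite(sigma), is.finite(k), is.finite(n))
  if (sigma < 0 || sigma > 1) stop("sigma must lie in [0, 1]", call. = FALSE)
  if (k < 0 || k > 1) stop("k must lie in [0, 1]", call. = FALSE)
  if (n < 1 || n > 5) stop("n must lie in [1, 5]", call. = FALSE)
  structure(list(sigma = sigma, k = k, n = n, wavelength_nm = wavelength_nm),
            class = "brdf_params")
}

#' @export
print.brdf_params <- function(x, ...) {
  cat(sprintf("BRDF parameters: sigma = %.4f, k = %.4f, n = %.4f%s\n",
              x$sigma, x$k, x$n,
              if (is.finite(x$wavelength_nm))
                sprintf(" (%.2f nm)", x$wavelength_nm) else ""))
  invisible(x)
}

#' Fresnel factor for unpolarized light
#'
#' Fraction of unpolarized incident light reflected specularly at a dielectric
#' interface of refractive index `n`, as a function of the cosine of the
#' half-angle. Uses the exact unpolarized form with
#' `g = sqrt(n^2 + cos^2 - 1)`; at `n = 1` the interface is index-matched and
#' F is exactly 0, and the grazing limit (`cos -> 0`) is 1.
#'
#' @param n Refractive index, `n >= 1` (scalar).
#' @param cos_theta_h Cosine of the angle between illumination and half-vector,
#'   in \[0, 1\] (vectorized).
#' @return Fresnel reflectance in \[0, 1\].
#' @examples
#' fresnel(1.5, 1) # ((n-1)/(n+1))^2 = 0.04 at normal incidence
#' @export
fresnel <- function(n, cos_theta_h) {
  stopifnot(length(n) == 1, is.finite(n), n >= 1)
  ct <- cos_theta_h
  if (any(!is.finite(ct)) || any(ct < 0) || any(ct > 1 + 1e-12)) {
    stop("cos_theta_h must lie in [0, 1]", call. = FALSE)
  }
  ct <- pmin(ct, 1)
  if (n == 1) return(rep(0, length(ct)))
  g <- sqrt(n^2 + ct^2 - 1)
  a <- (g - ct) / (g + ct)
  b <- (ct * (g + ct) - 1) / (ct * (g - ct) + 1)
  pmin(1, pmax(0, 0.5 * a^2 * (1 + b^2)))
}

#' Beckmann microfacet slope distribution
#'
#' `D(alpha, sigma) = exp(-(tan(alpha)/sigma)^2) / (sigma^2 cos^4(alpha))`,
#' the density of microfacet normals at angle `alpha` from the mean surface
#' normal for RMS slope `sigma`. Implemented exactly in this form (without
#' the `1/pi` prefactor used by some renderers) to match the reflectance
#' model fitted here.
#'
#' @param alpha Angle between surface normal and microfacet normal, radians,
#'   in `[0, pi/2)` (vectorized).
#' @param sigma RMS roughness, `> 0` (scalar).
#' @return Non-negative density values.
#' @examples
#' beckmann(0, 0.5) # 1/sigma^2 = 4
#' @export
beckmann <- function(alpha, sigma) {
  stopifnot(length(sigma) == 1, is.finite(sigma))
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha >= pi / 2)) {
    stop("alpha must lie in [0, pi/2)", call. = FALSE)
  }
  exp(-(tan(alpha) / sigma)^2) / (sigma^2 * cos(alpha)^4)
}

#' Geometric attenuation factor
#'
#' Shadowing/masking between microfacets:
#' `G = min(1, 2 (V.N)(N.H)/(V.H), 2 (L.N)(N.H)/(V.H))`, bounded by 1.
#'
#' @param frame A `geometry_frame` (see [geometry_frame()]), or a list/row with
#'   fields `cos_LN`, `cos_NV`, `cos_NH`, `cos_VH`.
#' @return Attenuation in (0, 1\].
#' @export
geometric_attenuation <- function(frame) {
  cVH <- frame$cos_VH
  if (any(cVH <= 0)) {
    stop("degenerate geometry: V.H must be positive", call. = FALSE)
  }
  pmin(1, 2 * frame$cos_NV * frame$cos_NH / cVH,
       2 * frame$cos_LN * frame$cos_NH / cVH)
}

.convention_constant <- function(convention) {
  switch(convention,
         as_printed = 2 * pi^2,
         pi = pi,
         four = 4,
         stop("unknown normalization convention: ", convention, call. = FALSE))
}

#' Cook-Torrance bidirectional reflectance
#'
#' Evaluates the Cook-Torrance BRDF
#' `f = F(n, theta_h) D(alpha, sigma) G / (c (L.N)(N.V)) + k/pi`
#' for one geometry frame. The specular normalization constant `c` depends on
#' `convention`: `"as_printed"` uses `2 pi^2` (the form the model was fitted
#' under here), `"pi"` and `"four"` give the classical Cook-Torrance
#' normalizations so fits can be rerun and compared across conventions.
#' With `n = 1` the Fresnel factor vanishes and the model reduces to the
#' Lambertian value `k/pi` at every geometry.
#'
#' @param params A [brdf_params()] object (or list with `sigma`, `k`, `n`).
#' @param frame A non-degenerate `geometry_frame`.
#' @param convention Specular normalization tag; see Details.
#' @return Bidirectional reflectance in 1/steradian.
#' @examples
#' fr <- geometry_frame(theta_leaf_deg = 30, view_zenith_deg = 60)
#' brdf_value(brdf_params(0.3, 0.35, 2.2), fr)
#' @export
brdf_value <- function(params, frame,
                       convention = c("as_printed", "pi", "four")) {
  convention <- match.arg(convention)
  if (isTRUE(frame$degenerate)) {
    stop("degenerate frame: source or detector behind the surface",
         call. = FALSE)
  }
  cc <- .convention_constant(convention)
  if (params$n == 1) return(params$k / pi)
  f_spec <- fresnel(params$n, max(0, frame$cos_theta_h)) *
    beckmann(frame$alpha, max(params$sigma, 1e-12)) *
    geometric_attenuation(frame) /
    (cc * frame$cos_LN * frame$cos_NV)
  f_spec + params$k / pi
}

## Vectorized kernel over a frame table (non-degenerate rows only).
## Used by the fitters, the forward generators and the tracer.
brdf_eval <- function(sigma, k, n, ft, cnorm = 2 * pi^2) {
  diff_term <- k / pi
  if (n == 1 || sigma <= 0) {
    return(rep(diff_term, nrow(ft)))
  }
  Fv <- fresnel(n, pmax(0, pmin(1, ft$cos_theta_h)))
  Dv <- exp(-(tan(ft$alpha) / sigma)^2) / (sigma^2 * cos(ft$alpha)^4)
  Gv <- pmin(1, 2 * ft$cos_NV * ft$cos_NH / ft$cos_VH,
             2 * ft$cos_LN * ft$cos_NH / ft$cos_VH)
  Fv * Dv * Gv / (cnorm * ft$cos_LN * ft$cos_NV) + diff_term
}
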