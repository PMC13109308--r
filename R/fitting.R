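## Estimation of the three BRDF parameters from a calibrated reflectance
## dataset: bounded Levenberg-Marquardt least squares and a two-layer
## adaptive grid search (cyclic coordinate descent on coarse then fine grids).

#' Fitting configuration
#'
#' Defaults follow the standard protocol: initial point (0.5, 0.5, 3),
#' box bounds (0.01, 0.01, 1.1)-(0.99, 0.99, 5) for numerical stability
#' inside the physical ranges sigma, k in \[0,1\], n in \[1,5\], and grid
#' steps 1e-2 (coarse) and 1e-4 (fine) for the adaptive grid search.
#'
#' @param initial Starting triple (sigma0, k0, n0).
#' @param lower,upper Bound triples in (sigma, k, n) order.
#' @param coarse_step,fine_step Grid steps for the adaptive grid search.
#' @param max_sweeps Maximum coordinate-descent sweeps per grid layer.
#' @param tol Relative SSE improvement below which sweeps stop.
#' @param convention Specular normalization tag, see [brdf_value()].
#' @return List of class `fit_config`.
#' @export
fit_config <- function(initial = c(0.5, 0.5, 3),
                       lower = c(0.01, 0.01, 1.1),
                       upper = c(0.99, 0.99, 5),
                       coarse_step = 1e-2, fine_step = 1e-4,
                       max_sweeps = 100, tol = 1e-12,
                       convention = c("as_printed", "pi", "four")) {
  convention <- match.arg(convention)
  stopifnot(length(initial) == 3, length(lower) == 3, length(upper) == 3,
            all(lower < upper), all(initial >= lower), all(initial <= upper),
            coarse_step > 0, fine_step > 0, max_sweeps >= 1)
  if (upper[1] > 1 || upper[2] > 1 || upper[3] > 5 ||
      lower[1] < 0 || lower[2] < 0 || lower[3] < 1) {
    stop("bounds must stay inside sigma,k in [0,1] and n in [1,5]",
         call. = FALSE)
  }
  structure(list(initial = initial, lower = lower, upper = upper,
                 coarse_step = coarse_step, fine_step = fine_step,
                 max_sweeps = max_sweeps, tol = tol,
                 convention = convention),
            class = "fit_config")
}

.theta_leaf_of <- function(data) {
  if (!is.null(data$theta_leaf_deg)) return(data$theta_leaf_deg)
  if (!is.null(data$holder_scale_deg)) {
    return(leaf_angle_from_holder(data$holder_scale_deg))
  }
  if (!is.null(data$incident_zenith_deg)) return(data$incident_zenith_deg)
  stop("dataset carries no leaf-angle information", call. = FALSE)
}

.usable_frames <- function(data) {
  required <- c("cos_LN", "cos_NV", "cos_NH", "cos_VH", "cos_theta_h",
                "alpha", "f_samp_sr")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    stop("dataset lacks column(s): ", paste(missing, collapse = ", "),
         " (run calibrate_scan first)", call. = FALSE)
  }
  keep <- if ("degenerate" %in% names(data)) !data$degenerate else
    rep(TRUE, nrow(data))
  data[keep, , drop = FALSE]
}

#' Model residuals for a parameter triple
#'
#' Element i is `model(params, frame_i) - f_samp_i`, in row order, over the
#' non-degenerate records of the dataset.
#'
#' @param params A [brdf_params()] object or numeric triple (sigma, k, n).
#' @param data A calibrated reflectance dataset (see [calibrate_scan()]).
#' @param convention Specular normalization tag.
#' @return Numeric residual vector.
#' @export
brdf_residuals <- function(params, data,
                           convention = c("as_printed", "pi", "four")) {
  convention <- match.arg(convention)
  if (inherits(params, "brdf_params")) {
    params <- c(params$sigma, params$k, params$n)
  }
  ft <- .usable_frames(data)
  if (nrow(ft) == 0) stop("empty dataset after degenerate-frame filtering",
                          call. = FALSE)
  brdf_eval(params[1], params[2], params[3], ft,
            .convention_constant(convention)) - ft$f_samp_sr
}

#' Goodness-of-fit statistics
#'
#' `R^2 = 1 - SSE/SStot` about the observed mean and `RMSE = sqrt(SSE/n)`.
#' When the observed values are constant, R-squared is undefined and reported
#' as `NA` while the RMSE remains valid.
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 2).
#' @return List with `r_squared` and `rmse`.
#' @export
goodness_of_fit <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 2)
  sse <- sum((predicted - observed)^2)
  sstot <- sum((observed - mean(observed))^2)
  list(r_squared = if (sstot <= 0) NA_real_ else 1 - sse / sstot,
       rmse = sqrt(sse / length(observed)))
}

## SSE of the model over a pre-filtered frame table.
.sse <- function(p, ft, cnorm) {
  sum((brdf_eval(p[1], p[2], p[3], ft, cnorm) - ft$f_samp_sr)^2)
}

## Unpolarized Fresnel as a matrix over (frame cosines x grid of n values).
.fresnel_mat <- function(ct, n_grid) {
  n2 <- matrix(rep(n_grid^2, each = length(ct)), nrow = length(ct))
  ctm <- matrix(ct, nrow = length(ct), ncol = length(n_grid))
  g <- n2 + ctm^2 - 1
  g[g < 0] <- 0
  g <- sqrt(g)
  a <- (g - ctm) / (g + ctm)
  b <- (ctm * (g + ctm) - 1) / (ctm * (g - ctm) + 1)
  Fm <- 0.5 * a^2 * (1 + b^2)
  Fm[, n_grid == 1] <- 0
  Fm[Fm < 0] <- 0
  Fm[Fm > 1] <- 1
  Fm
}

## Coordinate-descent adaptive grid search. Per-frame quantities are
## precomputed once; each sweep evaluates the whole 1-D grid as a matrix.
## Ties on equal SSE break to the smaller parameter value (grids ascend and
## which.min returns the first minimum).
.fit_adaptive_grid <- function(ft, config) {
  cnorm <- .convention_constant(config$convention)
  lo <- config$lower; hi <- config$upper
  t2 <- tan(ft$alpha)^2
  c4 <- cos(ft$alpha)^4
  G <- pmin(1, 2 * ft$cos_NV * ft$cos_NH / ft$cos_VH,
            2 * ft$cos_LN * ft$cos_NH / ft$cos_VH)
  A <- G / (cnorm * ft$cos_LN * ft$cos_NV)   # specular geometry factor
  ct <- pmax(0, pmin(1, ft$cos_theta_h))
  fobs <- ft$f_samp_sr
  nfr <- length(fobs)

  beck <- function(sigma) exp(-t2 / sigma^2) / (sigma^2 * c4)
  model_sse <- function(p) {
    Fv <- fresnel(p[3], ct)
    sum((Fv * beck(p[1]) * A + p[2] / pi - fobs)^2)
  }
  sweep_sse <- function(j, grid, p) {
    if (j == 1) {            # sigma sweep: Beckmann matrix over the grid
      w <- fresnel(p[3], ct) * A
      Dm <- exp(-outer(t2, 1 / grid^2)) /
        (matrix(c4, nfr, length(grid)) *
           matrix(rep(grid^2, each = nfr), nfr))
      colSums((w * Dm + p[2] / pi - fobs)^2)
    } else if (j == 2) {     # k sweep: quadratic in k, closed form
      r0 <- fresnel(p[3], ct) * beck(p[1]) * A - fobs
      sum(r0^2) + 2 * (grid / pi) * sum(r0) + nfr * (grid / pi)^2
    } else {                 # n sweep: Fresnel matrix over the grid
      Dv <- beck(p[1]) * A
      Fm <- .fresnel_mat(ct, grid)
      colSums((Fm * Dv + p[2] / pi - fobs)^2)
    }
  }

  run_layer <- function(p, sse_cur, trace, step, windowed) {
    for (sweep in seq_len(config$max_sweeps)) {
      sse_prev <- sse_cur
      for (j in 1:3) {
        if (windowed) {
          g_lo <- max(lo[j], p[j] - config$coarse_step)
          g_hi <- min(hi[j], p[j] + config$coarse_step)
        } else {
          g_lo <- lo[j]; g_hi <- hi[j]
        }
        grid <- seq(g_lo, g_hi, by = step)
        if (grid[length(grid)] < g_hi) grid <- c(grid, g_hi)
        sse <- sweep_sse(j, grid, p)
        i <- which.min(sse)
        if (sse[i] <= sse_cur) {
          p[j] <- grid[i]; sse_cur <- sse[i]
        }
      }
      trace <- c(trace, sse_cur)
      if (sse_prev - sse_cur <= config$tol * max(sse_prev, 1e-300)) break
    }
    list(p = p, sse = sse_cur, trace = trace)
  }

  ## Joint (sigma, n) grid sweep with the closed-form optimal k per node.
  ## sigma and n are strongly coupled through the height and width of the
  ## specular lobe, so per-parameter sweeps zig-zag along a diagonal valley;
  ## sweeping the pair jointly (k enters the model linearly and has an exact
  ## per-node optimum) reaches the valley floor in one pass.
  sumf <- sum(fobs); sumf2 <- sum(fobs^2)
  joint_layer <- function(p, step, window) {
    if (is.null(window)) {
      s_grid <- seq(lo[1], hi[1], by = step)
      n_grid <- seq(lo[3], hi[3], by = step)
    } else {
      s_grid <- seq(max(lo[1], p[1] - window), min(hi[1], p[1] + window),
                    by = step)
      n_grid <- seq(max(lo[3], p[3] - window), min(hi[3], p[3] + window),
                    by = step)
    }
    Dm <- exp(-outer(t2, 1 / s_grid^2)) /
      (matrix(c4, nfr, length(s_grid)) *
         matrix(rep(s_grid^2, each = nfr), nfr))        # nfr x ns
    Fm <- .fresnel_mat(ct, n_grid)                      # nfr x nn
    DA <- Dm * A
    S2 <- crossprod(Fm^2, DA^2)                         # nn x ns
    S1 <- crossprod(Fm, DA * fobs)
    S0 <- crossprod(Fm, DA)
    copt <- (sumf - S0) / nfr
    copt[copt < lo[2] / pi] <- lo[2] / pi
    copt[copt > hi[2] / pi] <- hi[2] / pi
    sse_grid <- S2 - 2 * S1 + sumf2 + 2 * copt * (S0 - sumf) + nfr * copt^2
    i_best <- arrayInd(which.min(sse_grid), dim(sse_grid))
    q <- c(s_grid[i_best[2]], copt[i_best] * pi, n_grid[i_best[1]])
    ## snap k onto the same grid step
    k_grid <- seq(lo[2], hi[2], by = step)
    sse_k <- sweep_sse(2, k_grid, q)
    q_snap <- q; q_snap[2] <- k_grid[which.min(sse_k)]
    if (min(sse_k) <= model_sse(q)) list(p = q_snap, sse = min(sse_k))
    else list(p = q, sse = model_sse(q))
  }

  ## coarse layer: joint grid over the full bounds, then coordinate sweeps
  j0 <- joint_layer(config$initial, config$coarse_step, window = NULL)
  coarse <- run_layer(j0$p, j0$sse, j0$sse, config$coarse_step,
                      windowed = FALSE)
  ## fine layer: re-centered joint grids within one coarse step, then
  ## coordinate sweeps on the fine grid
  p <- coarse$p; sse_cur <- coarse$sse; trace <- coarse$trace
  for (it in seq_len(30)) {
    jf <- joint_layer(p, config$fine_step, window = config$coarse_step)
    if (jf$sse > sse_cur - config$tol * max(sse_cur, 1e-300)) break
    p <- jf$p; sse_cur <- jf$sse; trace <- c(trace, sse_cur)
  }
  fine <- run_layer(p, sse_cur, trace, config$fine_step, windowed = TRUE)
  list(par = fine$p, sse = fine$sse, sse_trace = fine$trace,
       converged = TRUE)
}

## Bounded least squares: a PORT quasi-Newton descent on the SSE surface
## (robust against the constrained local minima that trap plain
## Levenberg-Marquardt at the parameter bounds) followed by an LM polish for
## solver-grade final accuracy. Deterministic from the configured initial.
.fit_least_squares <- function(ft, config) {
  cnorm <- .convention_constant(config$convention)
  resid_fn <- function(p) {
    brdf_eval(p[1], p[2], p[3], ft, cnorm) - ft$f_samp_sr
  }
  stage1 <- stats::nlminb(config$initial, function(p) sum(resid_fn(p)^2),
                          lower = config$lower, upper = config$upper,
                          control = list(eval.max = 2000, iter.max = 1000,
                                         rel.tol = 1e-15))
  out <- minpack.lm::nls.lm(
    par = pmin(config$upper, pmax(config$lower, stage1$par)), fn = resid_fn,
    lower = config$lower, upper = config$upper,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  converged <- out$info %in% 1:4
  par <- pmin(config$upper, pmax(config$lower, out$par))
  sse <- out$deviance
  if (stage1$objective < sse) {  # keep the better of the two stages
    par <- pmin(config$upper, pmax(config$lower, stage1$par))
    sse <- stage1$objective
  }
  if (!converged) {
    warning("least-squares solver did not converge cleanly (info = ",
            out$info, "): ", out$message)
  }
  list(par = par, sse = sse, sse_trace = NULL, converged = converged,
       solver_info = out$info)
}

#' Fit Cook-Torrance BRDF parameters to a calibrated scan
#'
#' Estimates (sigma, k, n) for one wavelength/surface from a calibrated
#' reflectance dataset by minimizing the unweighted sum of squared residuals
#' over all non-degenerate geometries, pooled across incidence angles.
#' Two solvers are available: bounded Levenberg-Marquardt least squares
#' (`"least_squares"`) and the two-layer adaptive grid search
#' (`"adaptive_grid"`), a cyclic coordinate descent that sweeps each parameter
#' over a coarse 1e-2 grid spanning the full bounds until the SSE stops
#' improving, then re-sweeps on a fine 1e-4 grid within one coarse step of the
#' incumbent. Both are deterministic for fixed input.
#'
#' @param data A calibrated reflectance dataset (from [calibrate_scan()] or
#'   [synth_brdf_scan()]), with at least 4 usable records.
#' @param method `"least_squares"` (default) or `"adaptive_grid"`.
#' @param config A [fit_config()].
#' @return Object of class `brdf_fit`: estimated `params` ([brdf_params()]),
#'   `r_squared`, `rmse`, `residuals`, `n_points`, `method`, `convention`,
#'   `sse`, `sse_trace` (adaptive grid only), `converged`, and the filtered
#'   `data` used for the fit.
#' @examples
#' scan <- synth_brdf_scan(brdf_params(0.3, 0.35, 2.2), noise_sd = 0, seed = 1)
#' fit <- fit_brdf(scan, method = "least_squares")
#' coef(fit)
#' @export
fit_brdf <- function(data, method = c("least_squares", "adaptive_grid"),
                     config = fit_config()) {
  method <- match.arg(method)
  stopifnot(inherits(config, "fit_config"))
  ft <- .usable_frames(data)
  if (nrow(ft) < 4) {
    stop("need at least 4 usable records to fit 3 parameters", call. = FALSE)
  }
  res <- switch(method,
                least_squares = .fit_least_squares(ft, config),
                adaptive_grid = .fit_adaptive_grid(ft, config))
  pred <- brdf_eval(res$par[1], res$par[2], res$par[3], ft,
                    .convention_constant(config$convention))
  gof <- goodness_of_fit(pred, ft$f_samp_sr)
  wl <- if ("wavelength_nm" %in% names(ft) &&
            length(unique(ft$wavelength_nm)) == 1)
    ft$wavelength_nm[1] else NA_real_
  structure(list(
    params = brdf_params(res$par[1], res$par[2], res$par[3], wl),
    r_squared = gof$r_squared, rmse = gof$rmse,
    residuals = pred - ft$f_samp_sr,
    fitted = pred, n_points = nrow(ft),
    method = method, convention = config$convention,
    sse = res$sse, sse_trace = res$sse_trace,
    converged = res$converged, config = config, data = ft
  ), class = "brdf_fit")
}

#' Fit BRDF parameters per wavelength of a multi-band scan
#'
#' Splits a calibrated scan by wavelength and fits each band independently.
#'
#' @param data Calibrated reflectance dataset with a `wavelength_nm` column.
#' @param wavelengths Wavelengths to fit; default all present.
#' @inheritParams fit_brdf
#' @return Named list of `brdf_fit` objects, one per wavelength.
#' @export
fit_brdf_scan <- function(data, wavelengths = NULL,
                          method = c("least_squares", "adaptive_grid"),
                          config = fit_config()) {
  method <- match.arg(method)
  if (is.null(wavelengths)) wavelengths <- sort(unique(data$wavelength_nm))
  fits <- lapply(wavelengths, function(wl) {
    fit_brdf(data[data$wavelength_nm == wl, , drop = FALSE], method, config)
  })
  stats::setNames(fits, format(wavelengths))
}

#' @export
coef.brdf_fit <- function(object, ...) {
  c(sigma = object$params$sigma, k = object$params$k, n = object$params$n)
}

#' @export
print.brdf_fit <- function(x, ...) {
  cat(sprintf("Cook-Torrance BRDF fit (%s, convention %s)\n",
              x$method, x$convention))
  cat(sprintf("  sigma = %.4f, k = %.4f, n = %.4f\n",
              x$params$sigma, x$params$k, x$params$n))
  cat(sprintf("  R^2 = %.4f, RMSE = %.3g over %d geometries\n",
              x$r_squared, x$rmse, x$n_points))
  if (!x$converged) cat("  [solver did not converge cleanly]\n")
  invisible(x)
}

#' @export
summary.brdf_fit <- function(object, ...) {
  cat(sprintf("Cook-Torrance BRDF fit by %s\n", object$method))
  if (is.finite(object$params$wavelength_nm)) {
    cat(sprintf("  wavelength: %.2f nm\n", object$params$wavelength_nm))
  }
  cat(sprintf("  parameters: sigma = %.4f, k = %.4f, n = %.4f\n",
              object$params$sigma, object$params$k, object$params$n))
  cat(sprintf("  geometries: %d  |  SSE = %.4g\n",
              object$n_points, object$sse))
  cat(sprintf("  R^2 = %.4f  RMSE = %.4g\n", object$r_squared, object$rmse))
  cat("  residual quartiles:\n")
  print(stats::quantile(object$residuals))
  invisible(object)
}

#' Predict bidirectional reflectance from a fitted model
#'
#' @param object A `brdf_fit`.
#' @param newdata Optional data frame with either precomputed frame columns or
#'   raw angle columns (`holder_scale_deg` or `theta_leaf_deg`,
#'   `view_zenith_deg`, `view_azimuth_deg`). Defaults to the fitting data.
#' @param ... Unused.
#' @return Predicted reflectance (1/sr) per non-degenerate row.
#' @export
predict.brdf_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (!all(c("cos_LN", "cos_NV", "cos_NH", "cos_VH", "cos_theta_h", "alpha")
           %in% names(newdata))) {
    theta_leaf <- if ("theta_leaf_deg" %in% names(newdata))
      newdata$theta_leaf_deg else
        leaf_angle_from_holder(newdata$holder_scale_deg)
    phi <- if ("view_azimuth_deg" %in% names(newdata))
      newdata$view_azimuth_deg else 0
    newdata <- frame_table(theta_leaf, newdata$view_zenith_deg, phi)
  }
  keep <- if ("degenerate" %in% names(newdata)) !newdata$degenerate else
    rep(TRUE, nrow(newdata))
  p <- coef(object)
  brdf_eval(p[1], p[2], p[3], newdata[keep, , drop = FALSE],
            .convention_constant(object$convention))
}

#' @export
residuals.brdf_fit <- function(object, ...) object$residuals

#' Diagnostic plot for a BRDF fit
#'
#' Observed versus fitted reflectance with the 1:1 line, and (optionally)
#' the reflectance profile against viewing angle per incidence angle.
#'
#' @param x A `brdf_fit`.
#' @param which `"scatter"` (observed vs fitted) or `"profile"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.brdf_fit <- function(x, which = c("scatter", "profile"), ...) {
  which <- match.arg(which)
  if (which == "scatter") {
    graphics::plot(x$data$f_samp_sr, x$fitted,
                   xlab = "measured f (1/sr)", ylab = "fitted f (1/sr)", ...)
    graphics::abline(0, 1, lty = 2)
  } else {
    d <- x$data
    inc <- factor(round(.theta_leaf_of(d), 3))
    graphics::plot(d$view_zenith_deg, d$f_samp_sr, col = as.integer(inc),
                   xlab = "viewing zenith (deg)", ylab = "f (1/sr)", ...)
    o <- order(d$view_zenith_deg)
    for (lv in levels(inc)) {
      sel <- inc == lv
      oo <- order(d$view_zenith_deg[sel])
      graphics::lines(d$view_zenith_deg[sel][oo], x$fitted[sel][oo],
                      col = which(levels(inc) == lv))
    }
  }
  invisible(x)
}

#' Simulate noisy scans from a fitted model
#'
#' Forward-generates flux tables at the fit's own geometry with multiplicative
#' Gaussian measurement noise, mirroring the synthetic scan generator.
#'
#' @param object A `brdf_fit`.
#' @param nsim Number of simulated scans.
#' @param seed Optional seed.
#' @param noise_sd Multiplicative noise standard deviation (default 0.05).
#' @param ... Unused.
#' @return List of calibrated scan data frames.
#' @export
simulate.brdf_fit <- function(object, nsim = 1, seed = NULL,
                              noise_sd = 0.05, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- coef(object)
  incidences <- unique(.theta_leaf_of(object$data))
  ring <- sort(unique(object$data$view_zenith_deg))
  lapply(seq_len(nsim), function(i) {
    synth_brdf_scan(brdf_params(p[1], p[2], p[3]),
                    incidence_deg = incidences, ring_deg = ring,
                    noise_sd = noise_sd,
                    seed = sample.int(.Machine$integer.max, 1),
                    convention = object$convention)
  })
}
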