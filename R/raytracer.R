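## Minimal Monte-Carlo photon tracer over a triangle-mesh canopy.
## Photon fate at each leaf hit is reflect / transmit / absorb with
## probabilities {R(incidence), tau, 1 - R - tau}, where R is the
## directional-hemispherical reflectance of the facet's Cook-Torrance BRDF.
## Reflected directions mix a cosine-weighted diffuse lobe with an
## importance-sampled Beckmann specular lobe; transmission is cosine-weighted
## into the far hemisphere (diffuse, as leaf transmission is close to
## Lambertian). Scattered PPFD on a facet counts only photons arriving after
## at least one prior surface interaction, so the direct beam is excluded.

#' Triangle-mesh canopy with per-facet optics
#'
#' Validates and annotates a triangle table: one row per facet with vertex
#' coordinates `v1x..v3z` (meters, Z vertical), Cook-Torrance parameters
#' `sigma`, `k`, `n` and transmittance `tau`. Degenerate (zero-area)
#' triangles and out-of-range optics are rejected.
#'
#' @param triangles Data frame with columns `v1x, v1y, v1z, v2x, v2y, v2z,
#'   v3x, v3y, v3z, sigma, k, n, tau`. May have zero rows (empty canopy).
#' @return Object of class `canopy_mesh`: the triangle table plus unit facet
#'   normals, areas, centroids and domain bounds.
#' @export
canopy_mesh <- function(triangles) {
  req <- c("v1x", "v1y", "v1z", "v2x", "v2y", "v2z", "v3x", "v3y", "v3z",
           "sigma", "k", "n", "tau")
  missing <- setdiff(req, names(triangles))
  if (length(missing)) {
    stop("triangle table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tr <- as.data.frame(triangles)
  if (nrow(tr) > 0) {
    if (any(!is.finite(as.matrix(tr[, req])))) {
      stop("unbounded mesh domain: non-finite vertex or optics value",
           call. = FALSE)
    }
    if (any(tr$tau < 0 | tr$tau > 1)) {
      stop("tau must lie in [0, 1]", call. = FALSE)
    }
    if (any(tr$sigma < 0 | tr$sigma > 1 | tr$k < 0 | tr$k > 1 |
            tr$n < 1 | tr$n > 5)) {
      stop("facet optics outside physical bounds", call. = FALSE)
    }
    e1 <- cbind(tr$v2x - tr$v1x, tr$v2y - tr$v1y, tr$v2z - tr$v1z)
    e2 <- cbind(tr$v3x - tr$v1x, tr$v3y - tr$v1y, tr$v3z - tr$v1z)
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    nrm2 <- sqrt(rowSums(cr^2))
    if (any(nrm2 < 1e-12)) stop("degenerate (zero-area) triangle",
                                call. = FALSE)
    tr$area <- nrm2 / 2
    tr$nx <- cr[, 1] / nrm2; tr$ny <- cr[, 2] / nrm2; tr$nz <- cr[, 3] / nrm2
    tr$cx <- (tr$v1x + tr$v2x + tr$v3x) / 3
    tr$cy <- (tr$v1y + tr$v2y + tr$v3y) / 3
    tr$cz <- (tr$v1z + tr$v2z + tr$v3z) / 3
  } else {
    tr$area <- tr$nx <- tr$ny <- tr$nz <- tr$cx <- tr$cy <- tr$cz <- numeric(0)
  }
  xs <- c(tr$v1x, tr$v2x, tr$v3x); ys <- c(tr$v1y, tr$v2y, tr$v3y)
  zs <- c(tr$v1z, tr$v2z, tr$v3z)
  bounds <- if (length(xs)) rbind(lo = c(min(xs), min(ys), min(zs)),
                                  hi = c(max(xs), max(ys), max(zs)))
  else rbind(lo = c(0, 0, 0), hi = c(1, 1, 1))
  colnames(bounds) <- c("x", "y", "z")
  structure(list(triangles = tr, bounds = bounds), class = "canopy_mesh")
}

#' @export
print.canopy_mesh <- function(x, ...) {
  b <- x$bounds
  cat(sprintf("Canopy mesh: %d facets, domain %.2f x %.2f x %.2f m\n",
              nrow(x$triangles), b["hi", "x"] - b["lo", "x"],
              b["hi", "y"] - b["lo", "y"], b["hi", "z"] - b["lo", "z"]))
  invisible(x)
}

#' Directional-hemispherical reflectance of the Cook-Torrance BRDF
#'
#' Integrates `f(incident, outgoing) cos(theta_o)` over the exit hemisphere
#' by product Gauss-Legendre quadrature (`n_quad` nodes in the zenith cosine
#' times `n_quad` in azimuth). For the pure-diffuse model the integral equals
#' `k` exactly; the raw integral is clipped to \[0, 1\] with a warning if the
#' specular lobe pushes it above 1 (possible at grazing incidence for high
#' `n`).
#'
#' @param params A [brdf_params()] triple.
#' @param incident Incident propagation direction (3-vector pointing toward
#'   the surface; local surface normal is +Z, so `incident[3] < 0`).
#' @param n_quad Nodes per dimension (>= 8; default 64).
#' @param convention Specular normalization tag.
#' @return Reflectance fraction in \[0, 1\].
#' @examples
#' directional_hemispherical_reflectance(brdf_params(0.3, 0.35, 1),
#'                                       c(0, 0, -1)) # 0.35 (Lambertian)
#' @export
directional_hemispherical_reflectance <- function(params,
                                                  incident = c(0, 0, -1),
                                                  n_quad = 64,
                                                  convention = c("as_printed",
                                                                 "pi",
                                                                 "four")) {
  convention <- match.arg(convention)
  if (n_quad < 8) stop("n_quad must be at least 8", call. = FALSE)
  if (!inherits(params, "brdf_params")) {
    params <- brdf_params(params[1], params[2], params[3])
  }
  L <- .unitize(-incident)
  if (L[3] <= 0) stop("incident direction must point at the surface",
                      call. = FALSE)
  if (params$n == 1) return(min(1, params$k))
  gl_mu <- pracma::gaussLegendre(n_quad, 0, 1)
  gl_ph <- pracma::gaussLegendre(n_quad, 0, 2 * pi)
  mu <- rep(gl_mu$x, times = n_quad)
  wmu <- rep(gl_mu$w, times = n_quad)
  ph <- rep(gl_ph$x, each = n_quad)
  wph <- rep(gl_ph$w, each = n_quad)
  st <- sqrt(pmax(0, 1 - mu^2))
  Vx <- st * cos(ph); Vy <- st * sin(ph); Vz <- mu
  Hx <- L[1] + Vx; Hy <- L[2] + Vy; Hz <- L[3] + Vz
  hn <- sqrt(Hx^2 + Hy^2 + Hz^2)
  Hx <- Hx / hn; Hy <- Hy / hn; Hz <- Hz / hn
  ft <- data.frame(
    cos_LN = L[3], cos_NV = mu, cos_NH = Hz,
    cos_VH = Vx * Hx + Vy * Hy + Vz * Hz,
    cos_theta_h = L[1] * Hx + L[2] * Hy + L[3] * Hz)
  ft$alpha <- acos(pmin(1, pmax(-1, ft$cos_NH)))
  ok <- ft$cos_VH > 1e-9 & ft$alpha < pi / 2 - 1e-9
  f <- rep(params$k / pi, length(mu))
  f[ok] <- brdf_eval(params$sigma, params$k, params$n, ft[ok, , drop = FALSE],
                     .convention_constant(convention))
  R <- sum(f * mu * wmu * wph)
  if (R > 1) {
    warning(sprintf("raw hemispherical reflectance %.3f > 1; clipped", R))
    R <- 1
  }
  max(0, R)
}

## Reflectance lookup per optics group: R as a function of incidence cosine.
.reflectance_tables <- function(optics, n_quad = 32,
                                convention = "as_printed") {
  cos_grid <- seq(0.02, 1, length.out = 16)
  lapply(seq_len(nrow(optics)), function(i) {
    p <- brdf_params(optics$sigma[i], optics$k[i], optics$n[i])
    if (p$n == 1) {
      list(cos = cos_grid, R = rep(min(1, p$k), length(cos_grid)))
    } else {
      R <- vapply(cos_grid, function(ci) {
        si <- sqrt(1 - ci^2)
        suppressWarnings(directional_hemispherical_reflectance(
          p, c(si, 0, -ci), n_quad = n_quad, convention = convention))
      }, numeric(1))
      list(cos = cos_grid, R = R)
    }
  })
}

## Orthonormal basis rows for unit normals (vectorized).
.basis_rows <- function(nrm) {
  helper <- matrix(rep(c(0, 0, 1), each = nrow(nrm)), ncol = 3)
  swap <- abs(nrm[, 3]) > 0.9
  helper[swap, ] <- matrix(rep(c(1, 0, 0), each = sum(swap)), ncol = 3)
  u <- cbind(helper[, 2] * nrm[, 3] - helper[, 3] * nrm[, 2],
             helper[, 3] * nrm[, 1] - helper[, 1] * nrm[, 3],
             helper[, 1] * nrm[, 2] - helper[, 2] * nrm[, 1])
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(nrm[, 2] * u[, 3] - nrm[, 3] * u[, 2],
             nrm[, 3] * u[, 1] - nrm[, 1] * u[, 3],
             nrm[, 1] * u[, 2] - nrm[, 2] * u[, 1])
  list(u = u, v = v)
}

## Cosine-weighted directions about unit normals (rows). Uses 2 uniforms/row.
.cosine_sample_rows <- function(nrm) {
  n <- nrow(nrm)
  u1 <- stats::runif(n); u2 <- stats::runif(n)
  r <- sqrt(u1); phi <- 2 * pi * u2
  b <- .basis_rows(nrm)
  lx <- r * cos(phi); ly <- r * sin(phi); lz <- sqrt(pmax(0, 1 - u1))
  b$u * lx + b$v * ly + nrm * lz
}

#' Sample a scattering event and direction at a leaf surface
#'
#' Draws the photon fate at a hit — reflect with probability `R` (the
#' directional-hemispherical reflectance at this incidence), transmit with
#' probability `tau`, absorb otherwise — and, for scattering events, an
#' outgoing direction. Reflection mixes a cosine-weighted diffuse lobe
#' (weight `k / R`) with a Beckmann specular lobe: a microfacet normal is
#' drawn from the Beckmann slope density, the incident ray is mirrored about
#' it, and candidates are thinned by the Fresnel-and-shadowing factors so the
#' accepted directions follow the specular lobe of the model. Transmission is
#' cosine-weighted into the far hemisphere. Uses the current RNG state; seed
#' with `set.seed()` for reproducibility.
#'
#' @param params A [brdf_params()] triple.
#' @param incident Propagation direction toward the surface (unit 3-vector).
#' @param normal Surface normal on the incoming side (default `c(0, 0, 1)`).
#' @param tau Transmittance in \[0, 1\].
#' @param R Optional precomputed reflectance probability; computed by
#'   quadrature when `NULL`.
#' @return List with `event` (`"reflect"`, `"transmit"` or `"absorb"`) and
#'   `direction` (unit 3-vector, `NULL` for absorption).
#' @export
sample_scatter_direction <- function(params, incident, normal = c(0, 0, 1),
                                     tau = 0.05, R = NULL) {
  if (!inherits(params, "brdf_params")) {
    params <- brdf_params(params[1], params[2], params[3])
  }
  incident <- .unitize(incident); normal <- .unitize(normal)
  ci <- -sum(incident * normal)
  if (ci <= 0) stop("incident direction must oppose the normal",
                    call. = FALSE)
  if (is.null(R)) {
    R <- if (params$n == 1) min(1, params$k) else
      suppressWarnings(directional_hemispherical_reflectance(
        params, c(sqrt(1 - ci^2), 0, -ci), n_quad = 32))
  }
  if (R + tau > 1 + 1e-9) {
    stop("configuration error: reflectance + transmittance exceeds 1",
         call. = FALSE)
  }
  u <- stats::runif(1)
  if (u < R) {
    w_diff <- if (R > 0) min(1, params$k / R) else 1
    if (params$n == 1 || stats::runif(1) < w_diff) {
      dir <- as.numeric(.cosine_sample_rows(matrix(normal, nrow = 1)))
    } else {
      dir <- .sample_specular(params, incident, normal)
    }
    list(event = "reflect", direction = dir)
  } else if (u < R + tau) {
    dir <- as.numeric(.cosine_sample_rows(matrix(-normal, nrow = 1)))
    list(event = "transmit", direction = dir)
  } else {
    list(event = "absorb", direction = NULL)
  }
}

## Beckmann-lobe specular sampling with Fresnel/shadowing rejection.
## Proposes microfacet normals h with tan(alpha) = sigma * sqrt(-log(u)),
## mirrors the incident ray about h, and accepts with probability
## proportional to F * G * (L.h)/cos(alpha); after `max_tries` the mirror
## direction about the mean normal is returned (documented fallback).
.sample_specular <- function(params, incident, normal, max_tries = 200) {
  L <- -incident
  b <- .basis_rows(matrix(normal, nrow = 1))
  u_ax <- as.numeric(b$u); v_ax <- as.numeric(b$v)
  for (i in seq_len(max_tries)) {
    ta <- params$sigma * sqrt(-log(stats::runif(1)))
    alpha <- atan(ta)
    phi <- 2 * pi * stats::runif(1)
    h <- sin(alpha) * (cos(phi) * u_ax + sin(phi) * v_ax) +
      cos(alpha) * normal
    lh <- sum(L * h)
    if (lh <= 0) next
    wo <- 2 * lh * h - L
    cNV <- sum(wo * normal)
    if (cNV <= 1e-6) next
    fr <- geometry_frame_from_vectors(L, normal, wo)
    if (fr$degenerate || fr$cos_VH <= 0) next
    Fv <- fresnel(params$n, max(0, min(1, lh)))
    Gv <- geometric_attenuation(fr)
    accept <- min(1, Fv * Gv * lh / (2 * cos(alpha)))
    if (stats::runif(1) < accept) return(wo)
  }
  mirror <- 2 * sum(L * normal) * normal - L
  .unitize(mirror)
}

## Moller-Trumbore: nearest triangle hit for a batch of rays.
## origins/dirs: N x 3 matrices. Returns list(t, tri) with Inf/NA for misses.
.nearest_hit <- function(origins, dirs, tr) {
  n <- nrow(origins)
  tbest <- rep(Inf, n)
  ibest <- rep(NA_integer_, n)
  if (nrow(tr) == 0 || n == 0) return(list(t = tbest, tri = ibest))
  eps <- 1e-9
  for (m in seq_len(nrow(tr))) {
    v0 <- c(tr$v1x[m], tr$v1y[m], tr$v1z[m])
    e1 <- c(tr$v2x[m] - v0[1], tr$v2y[m] - v0[2], tr$v2z[m] - v0[3])
    e2 <- c(tr$v3x[m] - v0[1], tr$v3y[m] - v0[2], tr$v3z[m] - v0[3])
    px <- dirs[, 2] * e2[3] - dirs[, 3] * e2[2]
    py <- dirs[, 3] * e2[1] - dirs[, 1] * e2[3]
    pz <- dirs[, 1] * e2[2] - dirs[, 2] * e2[1]
    det <- e1[1] * px + e1[2] * py + e1[3] * pz
    ok <- abs(det) > eps
    if (!any(ok)) next
    tx <- origins[, 1] - v0[1]; ty <- origins[, 2] - v0[2]
    tz <- origins[, 3] - v0[3]
    u <- (tx * px + ty * py + tz * pz) / det
    qx <- ty * e1[3] - tz * e1[2]
    qy <- tz * e1[1] - tx * e1[3]
    qz <- tx * e1[2] - ty * e1[1]
    v <- (dirs[, 1] * qx + dirs[, 2] * qy + dirs[, 3] * qz) / det
    tt <- (e2[1] * qx + e2[2] * qy + e2[3] * qz) / det
    hit <- ok & u >= 0 & v >= 0 & (u + v) <= 1 & tt > 1e-7 & tt < tbest
    tbest[hit] <- tt[hit]
    ibest[hit] <- m
  }
  list(t = tbest, tri = ibest)
}

#' Photon source above the canopy
#'
#' @param ppfd Photosynthetic photon flux density at the canopy top
#'   (micromol per square meter per second).
#' @param n_photons Number of photons to trace (>= 1).
#' @param direction Propagation direction; must point downward
#'   (`direction[3] < 0`). Default vertical.
#' @param seed Integer seed.
#' @return List of class `photon_source`.
#' @export
photon_source <- function(ppfd = 1500, n_photons = 10000,
                          direction = c(0, 0, -1), seed = 1) {
  direction <- .unitize(direction)
  if (direction[3] >= 0) stop("source direction must point downward",
                              call. = FALSE)
  stopifnot(n_photons >= 1, ppfd >= 0)
  structure(list(ppfd = ppfd, n_photons = as.integer(n_photons),
                 direction = direction, seed = as.integer(seed)),
            class = "photon_source")
}

#' Trace photons through a canopy mesh
#'
#' Emits photons uniformly over the horizontal extent of the mesh just above
#' its top, traces each through nearest-triangle intersections, and resolves
#' every hit into reflection, transmission or absorption via
#' [sample_scatter_direction()] probabilities (reflectance interpolated from
#' a per-optics lookup of the directional-hemispherical reflectance).
#' A facet's scattered PPFD accumulates the flux of photons arriving after at
#' least one earlier surface interaction; direct-beam hits are tallied
#' separately. Each photon carries
#' `ppfd x domain_area / n_photons` units of flux; facet PPFD is accumulated
#' flux divided by facet area. The photon ledger is exact:
#' absorbed + exited + terminated-at-max-bounces = emitted.
#'
#' @param mesh A [canopy_mesh()].
#' @param source A [photon_source()].
#' @param max_bounces Hard bounce cap (default 20).
#' @param chunk_size Photons per vectorized batch.
#' @return List of class `trace_result`: `facet_scattered_ppfd`,
#'   `facet_direct_ppfd` (per facet), `ledger` (named counts), and the flux
#'   `weight` per photon.
#' @export
trace_photons <- function(mesh, source, max_bounces = 20,
                          chunk_size = 20000) {
  stopifnot(inherits(mesh, "canopy_mesh"), inherits(source, "photon_source"))
  tr <- mesh$triangles
  b <- mesh$bounds
  area_dom <- max(b["hi", "x"] - b["lo", "x"], 1e-12) *
    max(b["hi", "y"] - b["lo", "y"], 1e-12)
  w <- source$ppfd * area_dom / source$n_photons
  n_fac <- nrow(tr)
  scat_flux <- numeric(n_fac)
  dir_flux <- numeric(n_fac)
  ledger <- c(absorbed = 0L, exited = 0L, max_bounces = 0L)
  rtab <- if (n_fac > 0) .reflectance_tables(tr) else list()
  any_specular <- n_fac > 0 && any(tr$n > 1)
  set.seed(source$seed)
  remaining <- source$n_photons
  while (remaining > 0) {
    nb <- min(chunk_size, remaining)
    remaining <- remaining - nb
    pos <- cbind(stats::runif(nb, b["lo", "x"], b["hi", "x"]),
                 stats::runif(nb, b["lo", "y"], b["hi", "y"]),
                 b["hi", "z"] + 1e-6)
    dirs <- matrix(rep(source$direction, each = nb), ncol = 3)
    interacted <- rep(FALSE, nb)
    active <- rep(TRUE, nb)
    for (bounce in seq_len(max_bounces + 1)) {
      idx <- which(active)
      if (length(idx) == 0) break
      hit <- .nearest_hit(pos[idx, , drop = FALSE],
                          dirs[idx, , drop = FALSE], tr)
      miss <- !is.finite(hit$t)
      ledger["exited"] <- ledger["exited"] + sum(miss)
      active[idx[miss]] <- FALSE
      hidx <- idx[!miss]
      if (length(hidx) == 0) break
      tri <- hit$tri[!miss]
      tt <- hit$t[!miss]
      pos[hidx, ] <- pos[hidx, , drop = FALSE] +
        dirs[hidx, , drop = FALSE] * tt
      # tally arrival flux
      sc <- interacted[hidx]
      if (any(sc)) {
        tab <- tapply(rep(w, sum(sc)), tri[sc], sum)
        scat_flux[as.integer(names(tab))] <-
          scat_flux[as.integer(names(tab))] + tab
      }
      if (any(!sc)) {
        tab <- tapply(rep(w, sum(!sc)), tri[!sc], sum)
        dir_flux[as.integer(names(tab))] <-
          dir_flux[as.integer(names(tab))] + tab
      }
      if (bounce == max_bounces + 1) {
        ledger["max_bounces"] <- ledger["max_bounces"] + length(hidx)
        active[hidx] <- FALSE
        break
      }
      # oriented normals against the incoming direction
      nrm <- cbind(tr$nx[tri], tr$ny[tri], tr$nz[tri])
      sgn <- -sign(rowSums(nrm * dirs[hidx, , drop = FALSE]))
      graze <- sgn == 0
      if (any(graze)) { # grazing hit: treat as absorbed
        ledger["absorbed"] <- ledger["absorbed"] + sum(graze)
        active[hidx[graze]] <- FALSE
      }
      keep <- !graze
      hidx <- hidx[keep]; tri <- tri[keep]
      nrm <- nrm[keep, , drop = FALSE] * sgn[keep]
      if (length(hidx) == 0) next
      ci <- -rowSums(nrm * dirs[hidx, , drop = FALSE])
      Rp <- vapply(seq_along(tri), function(i) {
        tb <- rtab[[tri[i]]]
        stats::approx(tb$cos, tb$R, xout = ci[i], rule = 2)$y
      }, numeric(1))
      tau <- tr$tau[tri]
      if (any(Rp + tau > 1 + 1e-9)) {
        stop("configuration error: reflectance + transmittance exceeds 1",
             call. = FALSE)
      }
      u <- stats::runif(length(hidx))
      refl <- u < Rp
      trans <- !refl & u < Rp + tau
      absb <- !refl & !trans
      ledger["absorbed"] <- ledger["absorbed"] + sum(absb)
      active[hidx[absb]] <- FALSE
      # reflection: diffuse vs specular mixture
      if (any(refl)) {
        ridx <- which(refl)
        kdif <- tr$k[tri[ridx]]
        wdif <- ifelse(Rp[ridx] > 0, pmin(1, kdif / Rp[ridx]), 1)
        is_spec <- any_specular &
          (tr$n[tri[ridx]] > 1) & (stats::runif(length(ridx)) >= wdif)
        dif <- ridx[!is_spec]
        if (length(dif)) {
          dirs[hidx[dif], ] <- .cosine_sample_rows(nrm[dif, , drop = FALSE])
        }
        for (s in ridx[is_spec]) {
          p <- brdf_params(tr$sigma[tri[s]], tr$k[tri[s]], tr$n[tri[s]])
          dirs[hidx[s], ] <- .sample_specular(p, dirs[hidx[s], ], nrm[s, ])
        }
        interacted[hidx[ridx]] <- TRUE
      }
      if (any(trans)) {
        tidx <- which(trans)
        dirs[hidx[tidx], ] <- .cosine_sample_rows(-nrm[tidx, , drop = FALSE])
        interacted[hidx[tidx]] <- TRUE
      }
    }
  }
  ledger <- c(ledger, emitted = source$n_photons)
  structure(list(
    facet_scattered_ppfd = if (n_fac) scat_flux / tr$area else numeric(0),
    facet_direct_ppfd = if (n_fac) dir_flux / tr$area else numeric(0),
    ledger = ledger, weight = w
  ), class = "trace_result")
}

#' Layer-wise summary of facet PPFD
#'
#' Assigns facets to horizontal layers of equal thickness by centroid height,
#' computes area-weighted layer means, and bins facet values into intensity
#' classes (defaults: 0-40, 40-80, 80-150, >150 micromol/m^2/s).
#'
#' @param mesh A [canopy_mesh()].
#' @param facet_ppfd Per-facet PPFD values (e.g. `facet_scattered_ppfd`).
#' @param n_layers Number of layers (>= 1).
#' @param bins Intensity bin edges.
#' @param z_range Vertical extent `c(zlo, zhi)` to slice into layers;
#'   defaults to the mesh's own vertical bounds. Layers holding no facet
#'   report a mean of 0.
#' @return Object of class `layer_profile`: per-layer bounds, area-weighted
#'   mean PPFD, facet counts, and the intensity histogram.
#' @export
layer_summary <- function(mesh, facet_ppfd, n_layers = 10,
                          bins = c(0, 40, 80, 150, Inf), z_range = NULL) {
  stopifnot(inherits(mesh, "canopy_mesh"), n_layers >= 1)
  tr <- mesh$triangles
  stopifnot(length(facet_ppfd) == nrow(tr))
  if (is.null(z_range)) {
    z_range <- c(mesh$bounds["lo", "z"], mesh$bounds["hi", "z"])
  }
  edges <- seq(z_range[1], z_range[2], length.out = n_layers + 1)
  layer <- pmin(n_layers, pmax(1L, findInterval(tr$cz, edges,
                                               rightmost.closed = TRUE)))
  mean_ppfd <- vapply(seq_len(n_layers), function(l) {
    sel <- layer == l
    if (!any(sel)) return(0)
    sum(facet_ppfd[sel] * tr$area[sel]) / sum(tr$area[sel])
  }, numeric(1))
  counts <- tabulate(layer, nbins = n_layers)
  hist <- table(cut(facet_ppfd, breaks = bins, include.lowest = TRUE,
                    right = FALSE))
  structure(list(n_layers = n_layers, z_edges = edges,
                 mean_scattered_ppfd = mean_ppfd, facet_counts = counts,
                 histogram = hist, facet_layer = layer),
            class = "layer_profile")
}

#' @export
print.layer_profile <- function(x, ...) {
  cat(sprintf("Canopy layer profile (%d layers, bottom to top)\n",
              x$n_layers))
  for (l in seq_len(x$n_layers)) {
    cat(sprintf("  layer %2d [%.2f, %.2f) m: mean PPFD %8.3f  (%d facets)\n",
                l, x$z_edges[l], x$z_edges[l + 1],
                x$mean_scattered_ppfd[l], x$facet_counts[l]))
  }
  cat("  intensity histogram:\n")
  print(x$histogram)
  invisible(x)
}

#' @export
plot.layer_profile <- function(x, ...) {
  mid <- (x$z_edges[-1] + x$z_edges[-length(x$z_edges)]) / 2
  graphics::plot(x$mean_scattered_ppfd, mid, type = "b",
                 xlab = "mean scattered PPFD (umol m-2 s-1)",
                 ylab = "canopy height (m)", ...)
  invisible(x)
}
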