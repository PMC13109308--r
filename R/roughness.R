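## Leaf surface roughness from cross-section micrographs: segment the tissue,
## trace the surface edge, and compute rho = l_inner / l_outer, the ratio of
## the exact (pixel-path) edge length to its Gaussian-smoothed counterpart.

.as_pixels <- function(image) {
  if (inherits(image, "section_image")) return(image$pixels)
  if (is.matrix(image)) return(image)
  stop("image must be a matrix or a section_image", call. = FALSE)
}

#' Read a cross-section micrograph as a grayscale matrix
#'
#' Reads PNG or TIFF; RGB images are converted to grayscale by channel mean.
#' Rows are image rows (top of the image is row 1).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix with values in \[0, 1\].
#' @export
read_section_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}

#' Extract the leaf surface edge inside a region of interest
#'
#' Segments the ROI by a global Otsu threshold, keeps the largest connected
#' tissue component, and traces the per-column extremal foreground pixel:
#' topmost for the adaxial (upper) surface, bottommost for the abaxial
#' surface. The result is an x-monotone pixel path ordered left to right.
#'
#' @param image Grayscale matrix or `section_image`.
#' @param roi Integer vector `c(x0, y0, x1, y1)` in pixel coordinates
#'   (columns x, rows y), or `NULL` for the full image. Must be at least
#'   20 px wide.
#' @param side `"adaxial"` (top surface) or `"abaxial"` (bottom surface).
#' @return Object of class `edge_curve`: list with integer vectors `x`
#'   (columns, in image coordinates) and `y` (rows), and the `side`.
#' @export
extract_surface_edge <- function(image, roi = NULL,
                                 side = c("adaxial", "abaxial")) {
  side <- match.arg(side)
  px <- .as_pixels(image)
  if (is.null(roi)) roi <- c(1, 1, ncol(px), nrow(px))
  x0 <- max(1L, as.integer(roi[1])); y0 <- max(1L, as.integer(roi[2]))
  x1 <- min(ncol(px), as.integer(roi[3])); y1 <- min(nrow(px), as.integer(roi[4]))
  if (x1 - x0 + 1 < 20) stop("ROI must be at least 20 px wide", call. = FALSE)
  sub <- px[y0:y1, x0:x1, drop = FALSE]
  if (diff(range(sub)) < 0.1) {
    stop("segmentation error: no tissue/background contrast in ROI",
         call. = FALSE)
  }
  thr <- EBImage::otsu(EBImage::Image(sub), range = c(0, 1))
  bw <- sub > thr
  if (!any(bw)) stop("segmentation error: no foreground in ROI", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(bw))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  ys <- apply(mask, 2, function(col) {
    w <- which(col)
    if (length(w) == 0) return(NA_integer_)
    if (side == "adaxial") min(w) else max(w)
  })
  keep <- !is.na(ys)
  if (sum(keep) < 20) {
    stop("segmentation error: tissue component spans fewer than 20 columns",
         call. = FALSE)
  }
  structure(list(x = (seq_len(ncol(sub))[keep]) + x0 - 1L,
                 y = ys[keep] + y0 - 1L, side = side),
            class = "edge_curve")
}

#' Exact (inner) edge length of a surface curve
#'
#' Pixel-path length under the 8-connected metric: between adjacent columns a
#' row change of `d` contributes `min(1, |d|) * sqrt(2) + | |d| - 1 |`
#' generalized to column gaps, i.e. diagonal steps count `sqrt(2)` and axial
#' steps count 1.
#'
#' @param curve An `edge_curve` (or list with `x`, `y`), length >= 2 points.
#' @return Path length in pixels.
#' @export
inner_length <- function(curve) {
  x <- as.numeric(curve$x); y <- as.numeric(curve$y)
  if (length(x) < 2) stop("curve needs at least 2 points", call. = FALSE)
  dx <- abs(diff(x)); dy <- abs(diff(y))
  dmin <- pmin(dx, dy); dmax <- pmax(dx, dy)
  sum(dmin * sqrt(2) + (dmax - dmin))
}

## 1-D Gaussian smoothing with reflect padding.
.gauss_smooth <- function(y, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  ypad <- c(rev(y[seq_len(min(r, length(y)))]), y,
            rev(y[seq(length(y) - min(r, length(y)) + 1, length(y))]))
  if (r > length(y)) { # extend reflection periodically for very wide kernels
    while (length(ypad) < length(y) + 2 * r) {
      ypad <- c(rev(ypad[seq_len(length(y))]), ypad)
      ypad <- ypad[seq_len(length(y) + 2 * r)]
    }
  }
  as.numeric(stats::filter(ypad, kern, sides = 2))[r + seq_along(y)]
}

#' Smoothed (outer) edge length
#'
#' Arc length of the surface profile after 1-D Gaussian smoothing of the row
#' profile (reflect padding), measured as the polyline length
#' `sum(sqrt(dx^2 + dy^2))`. Smoothing a profile never lengthens it, so the
#' outer length is a lower envelope of the inner length.
#'
#' @param curve An `edge_curve`.
#' @param gaussian_sigma Kernel standard deviation in pixels (> 0). Default:
#'   2% of the curve width.
#' @return Smoothed path length in pixels.
#' @export
outer_length <- function(curve, gaussian_sigma = NULL) {
  x <- as.numeric(curve$x); y <- as.numeric(curve$y)
  if (length(x) < 2) stop("curve needs at least 2 points", call. = FALSE)
  if (is.null(gaussian_sigma)) gaussian_sigma <- 0.02 * diff(range(x))
  if (gaussian_sigma <= 0) stop("gaussian_sigma must be positive",
                                call. = FALSE)
  if (gaussian_sigma >= length(y)) {
    stop("gaussian_sigma too large: profile collapses", call. = FALSE)
  }
  ys <- .gauss_smooth(y, gaussian_sigma)
  sum(sqrt(diff(x)^2 + diff(ys)^2))
}

#' Roughness ratio
#'
#' `rho = l_inner / l_outer`: 1 for a perfectly smooth surface, larger for
#' rougher surfaces.
#'
#' @param l_inner Exact edge length.
#' @param l_outer Smoothed edge length (> 0).
#' @return Dimensionless roughness.
#' @export
roughness_ratio <- function(l_inner, l_outer) {
  if (any(l_outer <= 0)) stop("outer length must be positive", call. = FALSE)
  l_inner / l_outer
}

#' Roughness of one region of interest
#'
#' Convenience pipeline: edge extraction, inner and outer lengths, ratio.
#'
#' @inheritParams extract_surface_edge
#' @param gaussian_sigma Smoothing sd in pixels; default 2% of the ROI width.
#' @return List with `rho`, `l_inner`, `l_outer` and the `curve`.
#' @export
leaf_roughness <- function(image, roi = NULL,
                           side = c("adaxial", "abaxial"),
                           gaussian_sigma = NULL) {
  side <- match.arg(side)
  curve <- extract_surface_edge(image, roi, side)
  li <- inner_length(curve)
  lo <- outer_length(curve, gaussian_sigma)
  list(rho = roughness_ratio(li, lo), l_inner = li, l_outer = lo,
       curve = curve)
}

#' Replicated roughness with randomized regions of interest
#'
#' Draws `n_replicates` ROIs with randomized width (uniform between 30% and
#' 80% of the image width) and horizontal position, computes the roughness of
#' each, and summarises. Randomizing the ROI mitigates user bias in manual
#' region selection; the seeded generator makes replicates reproducible.
#'
#' @param image Grayscale matrix or `section_image`.
#' @param side `"adaxial"` or `"abaxial"`.
#' @param n_replicates Number of ROIs (default 5).
#' @param seed Integer seed.
#' @param gaussian_sigma Smoothing sd in pixels; default 2% of each ROI width.
#' @return Object of class `roughness_result`: `replicates` (per-ROI rho),
#'   `mean`, `se`, `l_inner`, `l_outer`, and the ROI table.
#' @export
replicate_roughness <- function(image, side = c("adaxial", "abaxial"),
                                n_replicates = 5, seed = 1,
                                gaussian_sigma = NULL) {
  side <- match.arg(side)
  px <- .as_pixels(image)
  W <- ncol(px); H <- nrow(px)
  set.seed(seed)
  widths <- round(stats::runif(n_replicates, 0.3, 0.8) * W)
  x0s <- vapply(widths, function(w) {
    sample.int(max(1L, W - w + 1L), 1L)
  }, integer(1))
  rois <- cbind(x0 = x0s, y0 = 1L, x1 = pmin(W, x0s + widths - 1L), y1 = H)
  res <- vector("list", n_replicates)
  failures <- character(0)
  for (i in seq_len(n_replicates)) {
    r <- tryCatch(
      leaf_roughness(px, roi = rois[i, ], side = side,
                     gaussian_sigma = gaussian_sigma),
      error = function(e) e)
    if (inherits(r, "error")) {
      failures <- c(failures, sprintf("ROI %d [%d..%d]: %s", i, rois[i, 1],
                                      rois[i, 3], conditionMessage(r)))
    } else res[[i]] <- r
  }
  if (length(failures)) {
    stop("fewer than ", n_replicates, " valid ROIs:\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  }
  rhos <- vapply(res, `[[`, numeric(1), "rho")
  structure(list(
    replicates = rhos,
    mean = mean(rhos),
    se = stats::sd(rhos) / sqrt(length(rhos)),
    l_inner = vapply(res, `[[`, numeric(1), "l_inner"),
    l_outer = vapply(res, `[[`, numeric(1), "l_outer"),
    rois = rois, side = side, seed = seed
  ), class = "roughness_result")
}

#' @export
print.roughness_result <- function(x, ...) {
  cat(sprintf("Leaf surface roughness (%s side, %d randomized ROIs)\n",
              x$side, length(x$replicates)))
  cat(sprintf("  rho = %.4f +- %.4f (mean +- SE)\n", x$mean, x$se))
  cat("  replicates:", paste(sprintf("%.4f", x$replicates), collapse = ", "),
      "\n")
  invisible(x)
}
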