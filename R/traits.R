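## Leaf phenotypic traits: pigment contents from spectrophotometer
## absorbances, specific leaf weight, and derived chlorophyll features.

#' Pigment contents from absorbance readings
#'
#' Chlorophyll a, chlorophyll b and carotenoid contents from absorbances at
#' 663, 645 and 470 nm:
#' `Chl.a = 12.72 A663 - 2.59 A645`,
#' `Chl.b = 22.88 A645 - 4.67 A663`,
#' `Car = (1000 A470 - 3.27 Chl.a - 104 Chl.b) / 229`.
#' Outputs are in the extract-concentration units of the formulas; conversion
#' to mass per leaf area requires extract volume and disc area (see
#' [pigments_per_area()]). Negative outputs are possible for unusual
#' absorbance combinations and are returned with a warning rather than
#' clamped, so downstream feature matrices are not silently distorted.
#'
#' @param a663,a645,a470 Non-negative absorbance values (vectorized).
#' @param quiet Suppress the negative-value warning.
#' @return Data frame with columns `chl_a`, `chl_b`, `car` and a logical
#'   `flag_negative`.
#' @examples
#' pigment_contents(0.8, 0.3, 0.5)
#' @export
pigment_contents <- function(a663, a645, a470, quiet = FALSE) {
  stopifnot(all(a663 >= 0), all(a645 >= 0), all(a470 >= 0))
  chl_a <- 12.72 * a663 - 2.59 * a645
  chl_b <- 22.88 * a645 - 4.67 * a663
  car <- (1000 * a470 - 3.27 * chl_a - 104 * chl_b) / 229
  neg <- chl_a < 0 | chl_b < 0 | car < 0
  if (any(neg) && !quiet) {
    warning(sum(neg), " sample(s) yielded negative pigment values")
  }
  data.frame(chl_a = chl_a, chl_b = chl_b, car = car, flag_negative = neg)
}

#' Convert extract pigment concentrations to content per leaf area
#'
#' @param conc Concentration from [pigment_contents()] (mg/L-equivalent
#'   formula units).
#' @param volume_ml Extract volume in milliliters.
#' @param disc_area_cm2 Leaf disc area in square centimeters.
#' @return Content in mg per square decimeter.
#' @export
pigments_per_area <- function(conc, volume_ml, disc_area_cm2) {
  stopifnot(volume_ml > 0, disc_area_cm2 > 0)
  conc * (volume_ml / 1000) / (disc_area_cm2 / 100)
}

#' Specific leaf weight
#'
#' Leaf dry mass per unit area, `SLW = dry_weight / area`, in g per square
#' meter.
#'
#' @param dry_weight_g Dry weight in grams (>= 0).
#' @param area_m2 Leaf area in square meters (> 0).
#' @return SLW in g/m^2.
#' @examples
#' specific_leaf_weight(0.03, 6e-4) # a ~6 cm^2 disc weighing 30 mg -> 50
#' @export
specific_leaf_weight <- function(dry_weight_g, area_m2) {
  if (any(area_m2 <= 0)) stop("leaf area must be positive", call. = FALSE)
  if (any(dry_weight_g < 0)) stop("dry weight must be non-negative",
                                  call. = FALSE)
  dry_weight_g / area_m2
}

#' Derive total-chlorophyll and ratio features
#'
#' Fills `chl_ab = chl_a + chl_b` and `chl_ratio = chl_a / chl_b` in a trait
#' record (data frame or list). With `chl_b = 0` the ratio is undefined and
#' recorded as `NA`. Idempotent: re-deriving leaves the record unchanged.
#'
#' @param record Data frame or list containing `chl_a` and `chl_b`.
#' @return The record with `chl_ab` and `chl_ratio` columns filled.
#' @export
derive_features <- function(record) {
  if (is.null(record$chl_a) || is.null(record$chl_b)) {
    stop("record must contain chl_a and chl_b", call. = FALSE)
  }
  record$chl_ab <- record$chl_a + record$chl_b
  record$chl_ratio <- ifelse(record$chl_b == 0, NA_real_,
                             record$chl_a / record$chl_b)
  record
}

#' Compute trait features for a raw trait table
#'
#' Takes a table with columns `thickness_mm, dry_weight_g, area_m2, a663,
#' a645, a470, rho` and appends the computed columns: `slw_g_m2`, pigment
#' contents, `chl_ab` and `chl_ratio`.
#'
#' @param traits Data frame of raw trait measurements.
#' @return The input with computed columns appended.
#' @export
compute_trait_features <- function(traits) {
  required <- c("thickness_mm", "dry_weight_g", "area_m2",
                "a663", "a645", "a470")
  missing <- setdiff(required, names(traits))
  if (length(missing)) {
    stop("trait table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  traits$slw_g_m2 <- specific_leaf_weight(traits$dry_weight_g, traits$area_m2)
  pig <- pigment_contents(traits$a663, traits$a645, traits$a470, quiet = TRUE)
  traits$chl_a <- pig$chl_a
  traits$chl_b <- pig$chl_b
  traits$car <- pig$car
  derive_features(traits)
}
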