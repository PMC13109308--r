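# Shared fixtures, cached so expensive objects are built once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# canonical noiseless scan at the reference parameter triple
canonical_params <- function() brdf_params(0.3, 0.35, 2.2)

canonical_scan <- function() {
  cached("canonical_scan",
         synth_brdf_scan(canonical_params(), noise_sd = 0, seed = 1))
}

# the six canopy-simulation parameter triples (sigma, k, n)
canopy_parameter_sets <- function() {
  list(c(0.3, 0.01, 1.0), c(0.3, 0.35, 1.0), c(1.0, 0.01, 1.0),
       c(0.3, 0.01, 2.2), c(1.0, 0.35, 2.2), c(0.3, 0.35, 2.2))
}

# 270-row trait benchmark and its fitted sigma ensemble (trains once)
el_benchmark_data <- function() {
  cached("el_data", synth_trait_dataset(n_samples = 270, seed = 11))
}

el_benchmark_model <- function() {
  cached("el_model", train_el(el_benchmark_data(), target = "sigma",
                              split_seed = 42))
}

# two triangles tiling an axis-aligned horizontal rectangle
rect_facets <- function(x0, y0, x1, y1, z, sigma, k, n, tau) {
  rbind(
    data.frame(v1x = x0, v1y = y0, v1z = z, v2x = x1, v2y = y0, v2z = z,
               v3x = x1, v3y = y1, v3z = z, sigma = sigma, k = k, n = n,
               tau = tau),
    data.frame(v1x = x0, v1y = y0, v1z = z, v2x = x1, v2y = y1, v2z = z,
               v3x = x0, v3y = y1, v3z = z, sigma = sigma, k = k, n = n,
               tau = tau))
}

empty_mesh <- function() {
  canopy_mesh(data.frame(v1x = numeric(0), v1y = numeric(0),
                         v1z = numeric(0), v2x = numeric(0),
                         v2y = numeric(0), v2z = numeric(0),
                         v3x = numeric(0), v3y = numeric(0),
                         v3z = numeric(0), sigma = numeric(0),
                         k = numeric(0), n = numeric(0), tau = numeric(0)))
}
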