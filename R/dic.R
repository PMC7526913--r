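#' DIC contrast model for refractive-index matching assays
#'
#' Nomarski DIC contrast of a transparent specimen grows with the
#' refractive-index (RI) mismatch between specimen and medium and reaches
#' its floor of 1 (max gray / min gray of a featureless field) at an exact
#' match. The model assumes the medium RI is linear in the iodixanol
#' concentration: `ri(c) = medium_ri_at_0pct + ri_slope_per_pct * c`, and
#'
#'   `contrast(c) = 1 + contrast_gain * |sample_ri - ri(c)| + noise`.
#'
#' Defaults anchor the line at RI 1.334 for plain egg-salt buffer (0%) and
#' 1.379 at 30% iodixanol, the measured RI of a C. elegans embryo-matched
#' medium, giving a slope of 0.0015 per percent.
#'
#' @param sample_ri specimen refractive index.
#' @param medium_ri_at_0pct buffer RI without iodixanol.
#' @param ri_slope_per_pct RI increase per percent iodixanol.
#' @param contrast_gain slope of contrast vs RI mismatch (per RI unit).
#' @param noise_sd replicate-to-replicate Gaussian noise on contrast.
#' @return A `dic_model` list.
#' @export
dic_model <- function(sample_ri = 1.379,
                      medium_ri_at_0pct = 1.334,
                      ri_slope_per_pct = 0.0015,
                      contrast_gain = 20,
                      noise_sd = 0.05) {
  if (contrast_gain <= 0) stop("contrast_gain must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(
    sample_ri = sample_ri,
    medium_ri_at_0pct = medium_ri_at_0pct,
    ri_slope_per_pct = ri_slope_per_pct,
    contrast_gain = contrast_gain,
    noise_sd = noise_sd
  ), class = "dic_model")
}

#' @rdname dic_model
#' @param model a `dic_model`.
#' @param concentration_pct iodixanol concentration(s) in percent.
#' @return `expected_contrast()`: the noise-free model contrast.
#' @export
expected_contrast <- function(model, concentration_pct) {
  stopifnot(inherits(model, "dic_model"))
  ri <- model$medium_ri_at_0pct + model$ri_slope_per_pct * concentration_pct
  1 + model$contrast_gain * abs(model$sample_ri - ri)
}

#' Simulate a concentration series of DIC contrast measurements
#'
#' Draws `n_replicates` noisy contrast values per concentration from a
#' [dic_model()], emulating the dilution-series experiment used to find a
#' refractive-index matching medium.
#'
#' @param model a [dic_model()].
#' @param concentrations_pct concentrations (percent iodixanol); the
#'   default is the experimental dilution series.
#' @param n_replicates replicates per concentration (>= 1).
#' @param seed integer RNG seed.
#' @return A `contrast_series` data frame with columns
#'   `concentration_pct`, `replicate`, `contrast`.
#' @examples
#' s <- simulate_contrast_series(dic_model(noise_sd = 0), n_replicates = 1)
#' find_matching_concentration(s)$concentration_pct
#' @export
simulate_contrast_series <- function(model,
                                     concentrations_pct =
                                       c(0, 10, 20, 25, 30, 40, 50, 60),
                                     n_replicates = 14,
                                     seed = 1) {
  stopifnot(inherits(model, "dic_model"))
  if (length(concentrations_pct) == 0) stop("concentrations must be nonempty")
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  mu <- expected_contrast(model, concentrations_pct)
  vals <- withr::with_seed(seed, {
    rep(mu, each = n_replicates) +
      if (model$noise_sd > 0)
        stats::rnorm(length(mu) * n_replicates, 0, model$noise_sd) else 0
  })
  out <- data.frame(
    concentration_pct = rep(concentrations_pct, each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = length(concentrations_pct)),
    contrast = vals
  )
  class(out) <- c("contrast_series", "data.frame")
  out
}

#' @rdname simulate_contrast_series
#' @param x a data frame with columns `concentration_pct`, `contrast` (and
#'   optionally `replicate`).
#' @return `as_contrast_series()`: the validated `contrast_series`.
#' @export
as_contrast_series <- function(x) {
  if (!all(c("concentration_pct", "contrast") %in% names(x)))
    stop("need columns concentration_pct and contrast")
  if (nrow(x) == 0) stop("contrast series must have at least one entry")
  if (!"replicate" %in% names(x)) {
    x$replicate <- stats::ave(x$contrast, x$concentration_pct,
                              FUN = seq_along)
  }
  class(x) <- c("contrast_series", "data.frame")
  x
}
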