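#' Depth-dependent optical degradation model
#'
#' First-order emulation of spherical-aberration-like image degradation in
#' a confocal z-stack: lateral blur whose width grows linearly with depth,
#' exponential loss of signal with depth, a constant camera background,
#' optional shot noise and Gaussian read noise. Slice 1 (z = 0 um) is the
#' coverslip-proximal face. The `severity` of the model stands in for the
#' degree of refractive-index mismatch between the specimen and the
#' mounting medium (matched medium: mild degradation; plain buffer:
#' strong degradation).
#'
#' @param attenuation_per_um exponential intensity decay rate lambda
#'   (1/um): a slice at depth z is scaled by `exp(-lambda * z)`.
#' @param base_sigma_um lateral blur sigma at the coverslip (um).
#' @param sigma_growth_per_um blur growth rate r (um of sigma per um of
#'   depth): `sigma(z) = base_sigma_um + r * z`.
#' @param background_offset constant camera offset added to every voxel.
#' @param read_noise_sd standard deviation of additive Gaussian read noise
#'   (0 disables).
#' @param photon_scale photons per intensity unit for Poisson shot noise
#'   (0 disables shot noise).
#' @param speckle_per_um growth rate of the multiplicative speckle
#'   contrast with depth (fraction per um): aberration does not dim a
#'   slice uniformly but in smooth patches, so the signal is multiplied
#'   by `1 + speckle_per_um * z * F` where `F` is a unit-variance smooth
#'   random field. This spatially correlated heterogeneity is what
#'   creates spurious watershed basins in deep slices (0 disables).
#' @param speckle_scale_um correlation length of the speckle field.
#' @param seed integer seed for the noise draws.
#' @return An `optics_params` list.
#' @seealso [optics_preset()] for the two study conditions.
#' @export
optics_params <- function(attenuation_per_um = 0.01,
                          base_sigma_um = 0.2,
                          sigma_growth_per_um = 0.01,
                          background_offset = 100,
                          read_noise_sd = 30,
                          photon_scale = 1,
                          speckle_per_um = 0.004,
                          speckle_scale_um = 1.5,
                          seed = 1) {
  vals <- c(attenuation_per_um, base_sigma_um, sigma_growth_per_um,
            background_offset, read_noise_sd, photon_scale,
            speckle_per_um, speckle_scale_um)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all optics parameters must be nonnegative and finite")
  structure(list(
    attenuation_per_um = attenuation_per_um,
    base_sigma_um = base_sigma_um,
    sigma_growth_per_um = sigma_growth_per_um,
    background_offset = background_offset,
    read_noise_sd = read_noise_sd,
    photon_scale = photon_scale,
    speckle_per_um = speckle_per_um,
    speckle_scale_um = speckle_scale_um,
    seed = as.integer(seed)
  ), class = "optics_params")
}

#' @rdname optics_params
#' @param condition `"matched"` for refractive-index-matched mounting
#'   (mild depth degradation, the 30%-iodixanol-like condition) or
#'   `"mismatched"` for plain aqueous buffer (strong degradation, the
#'   0%-iodixanol-like condition).
#' @export
optics_preset <- function(condition = c("matched", "mismatched"), seed = 1) {
  condition <- match.arg(condition)
  if (condition == "matched") {
    optics_params(attenuation_per_um = 0.01, base_sigma_um = 0.2,
                  sigma_growth_per_um = 0.01, speckle_per_um = 0.004,
                  seed = seed)
  } else {
    optics_params(attenuation_per_um = 0.03, base_sigma_um = 0.2,
                  sigma_growth_per_um = 0.025, speckle_per_um = 0.012,
                  seed = seed)
  }
}

#' Apply depth-dependent degradation to a stack
#'
#' Each slice at depth `z` um is blurred laterally with a Gaussian of
#' sigma `base_sigma_um + sigma_growth_per_um * z` (converted to voxels
#' per axis), scaled by `exp(-attenuation_per_um * z)`, then offset by the
#' camera background; finally Poisson shot noise and Gaussian read noise
#' are added if enabled. Deterministic given `optics$seed`.
#'
#' @param image a [voxel_grid()] of nonnegative intensities.
#' @param optics an [optics_params()].
#' @param voxel_size_um voxel size override when `image` is a bare array.
#' @return A degraded [voxel_grid()].
#' @export
apply_optical_degradation <- function(image, optics, voxel_size_um = NULL) {
  stopifnot(inherits(optics, "optics_params"))
  vs <- resolve_voxel_size(image, voxel_size_um)
  a <- as_bare_array(image)
  if (min(a) < 0) stop("input image must be nonnegative")
  d <- dim(a)
  out <- array(0, d)
  for (z in seq_len(d[3])) {
    depth_um <- (z - 1) * vs[3]
    sig_um <- optics$base_sigma_um + optics$sigma_growth_per_um * depth_um
    slice <- a[, , z]
    if (sig_um > 0) {
      kx <- gaussian_kernel(sig_um / vs[1])
      ky <- gaussian_kernel(sig_um / vs[2])
      slice <- convolve_axis2(convolve_axis2(slice, kx, 1L), ky, 2L)
    }
    out[, , z] <- slice * exp(-optics$attenuation_per_um * depth_um)
  }
  noisy <- optics$photon_scale > 0 || optics$read_noise_sd > 0 ||
    optics$speckle_per_um > 0
  if (noisy) {
    out <- withr::with_seed(optics$seed, {
      x <- out
      if (optics$speckle_per_um > 0) {
        f <- speckle_field(d, vs, optics$speckle_scale_um)
        depth <- rep((seq_len(d[3]) - 1) * vs[3], each = d[1] * d[2])
        x <- x * pmax(0, 1 + optics$speckle_per_um * depth * f)
      }
      x <- x + optics$background_offset
      if (optics$photon_scale > 0) {
        x <- stats::rpois(length(x), as.vector(x) * optics$photon_scale) /
          optics$photon_scale
      }
      if (optics$read_noise_sd > 0) {
        x <- x + stats::rnorm(length(x), 0, optics$read_noise_sd)
      }
      array(x, d)
    })
    out <- pmax(out, 0)
  } else {
    out <- out + optics$background_offset
  }
  voxel_grid(out, vs)
}

# Unit-variance smooth Gaussian random field with the given correlation
# length (um), as a plain vector over the array.
speckle_field <- function(d, vs, scale_um) {
  w <- array(stats::rnorm(prod(d)), d)
  for (axis in 1:3) {
    s <- scale_um / vs[axis]
    if (s > 0) w <- convolve_axis3(w, gaussian_kernel(s), axis)
  }
  as.vector(w) / stats::sd(w)
}
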