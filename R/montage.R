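#' Build a quasi-uniform spherical electrode montage
#'
#' Places `n_channels` sensors on the unit sphere using the Fibonacci lattice,
#' a deterministic construction whose nearest-neighbour spacing is close to
#' uniform. Serves as a stand-in geometry for high-density sensor nets when
#' only the relative layout matters (synthetic data, spline interpolation).
#'
#' Coordinates are head-centred and right-handed, with +z through the vertex.
#' The optional jitter perturbs each site tangentially (then re-projects onto
#' the sphere) to break exact symmetries; `seed` only affects the jitter.
#'
#' @param n_channels number of electrodes (>= 3).
#' @param seed integer seed for the jitter; ignored when `jitter = 0`.
#' @param jitter standard deviation (radians) of tangential jitter, default 0.
#' @return numeric matrix `n_channels x 3` of unit-norm xyz coordinates, with
#'   row names `E001, E002, ...`.
#' @examples
#' m <- build_spherical_montage(64)
#' range(sqrt(rowSums(m^2)))  # all 1
#' @export
build_spherical_montage <- function(n_channels, seed = 1L, jitter = 0) {
  if (n_channels < 3) ms_stop("a montage needs at least 3 channels")
  i <- seq_len(n_channels) - 0.5
  phi <- pi * (1 + sqrt(5)) * i          # golden-angle longitude
  z <- 1 - 2 * i / n_channels
  r <- sqrt(pmax(0, 1 - z^2))
  xyz <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  if (jitter > 0) {
    xyz <- with_seed(derive_seed(seed, "montage-jitter"), {
      pert <- xyz + matrix(stats::rnorm(3 * n_channels, sd = jitter), ncol = 3)
      pert / sqrt(rowSums(pert^2))
    })
  }
  rownames(xyz) <- sprintf("E%03d", seq_len(n_channels))
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

validate_montage <- function(montage, n_channels = NULL) {
  if (is.null(montage)) return(invisible(NULL))
  if (!is.matrix(montage) || ncol(montage) != 3L)
    ms_stop("montage must be an n x 3 matrix of xyz coordinates")
  if (!is.null(n_channels) && nrow(montage) != n_channels)
    ms_stop(sprintf("montage has %d rows but the recording has %d channels",
                    nrow(montage), n_channels),
            class = "microstatr_structure_error")
  norms <- sqrt(rowSums(montage^2))
  if (any(abs(norms - 1) > 1e-6))
    ms_stop("montage coordinates must lie on the unit sphere (|norm - 1| <= 1e-6)")
  invisible(montage)
}

# Pairwise great-circle (angular) distances between montage points, radians.
montage_angles <- function(montage) {
  ip <- tcrossprod(montage)
  ip[ip > 1] <- 1; ip[ip < -1] <- -1
  acos(ip)
}
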