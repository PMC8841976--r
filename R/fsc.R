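#' Fourier shell correlation between two half-volumes
#'
#' Cross-correlates the discrete Fourier transforms of two independently
#' produced half-volumes within spherical shells of physical spatial
#' frequency: `FSC(S) = Re(sum_{f in S} A(f) conj(B(f))) /
#' sqrt(sum |A|^2 sum |B|^2)`. Anisotropic voxel sizes give ellipsoidal
#' index shells that are spherical in physical frequency. The DC term is
#' excluded; shell width defaults to one frequency voxel of the coarsest
#' axis. No mask or apodization is applied by default.
#'
#' @param half_a,half_b [vol3d()] volumes of identical shape and voxel
#'   size, both non-constant.
#' @param shell_width Shell width as a multiple of the base frequency step
#'   (default 1).
#' @return An `fsc_curve` tibble with columns `freq_per_nm` (shell centre),
#'   `fsc`, `n_voxels`.
#' @export
fsc_curve <- function(half_a, half_b, shell_width = 1) {
  stopifnot(is_vol3d(half_a), is_vol3d(half_b))
  if (!identical(dim(half_a$data), dim(half_b$data)))
    stop("half-volumes must have identical shape", call. = FALSE)
  if (max(abs(half_a$voxel_size - half_b$voxel_size)) > 1e-9)
    stop("half-volumes must have identical voxel size", call. = FALSE)
  if (min(half_a$data) == max(half_a$data) ||
      min(half_b$data) == max(half_b$data))
    stop("constant input: FSC undefined", call. = FALSE)
  d <- dim(half_a$data)
  vs <- half_a$voxel_size
  A <- stats::fft(half_a$data)
  B <- stats::fft(half_b$data)
  freq_axis <- function(n, s) {
    i <- 0:(n - 1)
    k <- ifelse(i <= n / 2, i, i - n)
    k / (n * s)
  }
  fz <- freq_axis(d[1], vs[1])
  fy <- freq_axis(d[2], vs[2])
  fx <- freq_axis(d[3], vs[3])
  fmag <- sqrt(outer(outer(fz^2, fy^2, "+"), fx^2, "+"))
  df <- max(1 / (d * vs)) * shell_width      # base shell width, 1/nm
  nyq <- 1 / (2 * max(vs))
  shell <- as.integer(round(fmag / df))
  shell[shell < 1L] <- 0L                    # DC excluded
  max_shell <- as.integer(floor(nyq / df + 0.5))
  keep <- shell >= 1L & shell <= max_shell
  s <- shell[keep]
  num <- Re(A[keep] * Conj(B[keep]))
  pa <- Mod(A[keep])^2
  pb <- Mod(B[keep])^2
  agg_num <- tapply(num, s, sum)
  agg_pa <- tapply(pa, s, sum)
  agg_pb <- tapply(pb, s, sum)
  agg_n <- tapply(rep(1L, length(s)), s, sum)
  sh <- as.integer(names(agg_num))
  denom <- sqrt(agg_pa * agg_pb)
  fsc <- ifelse(denom > 0, agg_num / denom, 0)
  out <- tibble::tibble(freq_per_nm = sh * df,
                        fsc = as.numeric(fsc),
                        n_voxels = as.integer(agg_n))
  out <- out[order(out$freq_per_nm), ]
  attr(out, "voxel_size") <- vs
  attr(out, "nyquist_per_nm") <- nyq
  class(out) <- c("fsc_curve", class(out))
  out
}

#' Resolution at an FSC criterion
#'
#' Locates the first crossing of the criterion from above by linear
#' interpolation between the bracketing shells and returns the
#' corresponding real-space resolution `1 / frequency` in nm. The default
#' criterion is 0.143, the standard half-volume threshold.
#'
#' @param curve An `fsc_curve` (see [fsc_curve()]).
#' @param criterion FSC threshold in (0, 1), default 0.143.
#' @return A list with `resolution_nm`, `criterion` and `flag`; `flag` is
#'   `"ok"` for a regular crossing, `"nyquist_limited"` when the curve
#'   never drops below the criterion (resolution is then the finest shell
#'   measured), or `"below_criterion"` when the curve starts below it
#'   (resolution is then the first shell, and should not be trusted).
#' @export
resolution_at <- function(curve, criterion = 0.143) {
  stopifnot(nrow(curve) > 0, criterion > 0, criterion < 1)
  f <- curve$freq_per_nm
  v <- curve$fsc
  if (v[1] < criterion) {
    return(list(resolution_nm = 1 / f[1], criterion = criterion,
                flag = "below_criterion"))
  }
  below <- which(v < criterion)
  if (length(below) == 0L) {
    return(list(resolution_nm = 1 / f[length(f)], criterion = criterion,
                flag = "nyquist_limited"))
  }
  j <- below[1]
  i <- j - 1L
  fcross <- f[i] + (f[j] - f[i]) * (v[i] - criterion) / (v[i] - v[j])
  list(resolution_nm = 1 / fcross, criterion = criterion, flag = "ok")
}

#' Band-limit a volume at a real-space cutoff
#'
#' Sharp low-pass filter in the Fourier domain: coefficients at physical
#' spatial frequencies above `1 / cutoff_nm` are zeroed. Used to create
#' half-volumes of known resolution for validating [resolution_at()].
#'
#' @param vol A [vol3d()].
#' @param cutoff_nm Real-space cutoff in nm (resolution of the result).
#' @return A [vol3d()] of the filtered volume.
#' @export
lowpass_volume <- function(vol, cutoff_nm) {
  stopifnot(is_vol3d(vol), cutoff_nm > 0)
  d <- dim(vol$data)
  vs <- vol$voxel_size
  freq_axis <- function(n, s) {
    i <- 0:(n - 1)
    k <- ifelse(i <= n / 2, i, i - n)
    k / (n * s)
  }
  fz <- freq_axis(d[1], vs[1])
  fy <- freq_axis(d[2], vs[2])
  fx <- freq_axis(d[3], vs[3])
  fmag <- sqrt(outer(outer(fz^2, fy^2, "+"), fx^2, "+"))
  keep <- fmag <= 1 / cutoff_nm
  ft <- stats::fft(vol$data) * keep
  out <- Re(stats::fft(ft, inverse = TRUE)) / length(ft)
  vol3d(array(out, d), voxel_size = vs, origin = vol$origin)
}

#' Write an FSC curve as CSV
#' @param curve An `fsc_curve`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_fsc_csv <- function(curve, path) {
  readr::write_csv(tibble::as_tibble(curve), path)
  invisible(path)
}
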