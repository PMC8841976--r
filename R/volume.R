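#' 3D volume with physical voxel size
#'
#' A `vol3d` wraps a 3D numeric (or logical) array together with the
#' physical voxel size in nanometres and an origin offset. Array axes are
#' ordered `(z, y, x)`; the physical centre of voxel `(i, j, k)` (1-based)
#' is `(i - 0.5) * voxel_size + origin` along each axis, so that voxel
#' `(1,1,1)` sits half a voxel inside the volume.
#'
#' @param data 3D array of finite values.
#' @param voxel_size Voxel edge length in nm; a scalar (isotropic) or a
#'   length-3 vector ordered `(z, y, x)`.
#' @param origin Physical offset of the volume corner in nm, length 3.
#' @return An object of class `vol3d`.
#' @examples
#' v <- vol3d(array(rnorm(8 * 8 * 8), c(8, 8, 8)), voxel_size = 4)
#' dim(v$data)
#' @export
vol3d <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("`data` must be non-empty on all axes", call. = FALSE)
  if (!all(is.finite(data)))
    stop("`data` must be finite everywhere", call. = FALSE)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0))
    stop("`voxel_size` must be strictly positive on all axes", call. = FALSE)
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(data = data, voxel_size = voxel_size, origin = origin),
            class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol3d> %d x %d x %d voxels (z,y,x), voxel %s nm\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  cat(sprintf("  physical extent %s nm, range [%.4g, %.4g]\n",
              paste(signif(d * x$voxel_size, 4), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.vol3d <- function(x) dim(x$data)

is_vol3d <- function(x) inherits(x, "vol3d")

as_vol3d <- function(x, voxel_size = NULL, origin = c(0, 0, 0)) {
  if (is_vol3d(x)) return(x)
  if (is.null(voxel_size))
    stop("`voxel_size` is required when the input is a bare array",
         call. = FALSE)
  vol3d(x, voxel_size, origin)
}

#' Physical voxel-centre coordinates along one axis
#' @keywords internal
#' @noRd
axis_centers <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  (seq_len(n) - 0.5) * vol$voxel_size[axis] + vol$origin[axis]
}

# ---------------------------------------------------------------- MRC I/O
# Minimal MRC2014 mode-2 (float32) support. The 1024-byte header stores the
# grid size, the cell dimensions (in Angstrom per MRC convention; voxel
# sizes in nm are multiplied by 10 on write and divided on read) and the
# axis-order fields for an x-fastest layout.

#' Write a volume as an MRC file
#'
#' Writes mode-2 (32-bit float) MRC2014 with the voxel size stored in the
#' cell-dimension header fields.
#'
#' @param vol A [vol3d()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path) {
  stopifnot(is_vol3d(vol))
  d <- dim(vol$data) # (nz, ny, nx)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(d[3], d[2], d[1]))      # nx, ny, nz
  wi(2L)                       # mode 2: float32
  wi(c(0L, 0L, 0L))            # nxstart, nystart, nzstart
  wi(c(d[3], d[2], d[1]))      # mx, my, mz
  wf(c(d[3] * vol$voxel_size[3], d[2] * vol$voxel_size[2],
       d[1] * vol$voxel_size[1]) * 10) # cella in Angstrom
  wf(c(90, 90, 90))            # cell angles
  wi(c(1L, 2L, 3L))            # mapc, mapr, maps
  wf(c(min(vol$data), max(vol$data), mean(vol$data)))
  wi(c(0L, 0L))                # ispg, nsymbt
  writeBin(raw(100), con)      # extra
  wf(vol$origin[c(3, 2, 1)] * 10) # origin (x,y,z) in Angstrom
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # little-endian stamp
  wf(stats::sd(as.numeric(vol$data)))
  wi(0L)                       # nlabl
  writeBin(raw(800), con)      # labels
  # data, x fastest
  writeBin(as.numeric(aperm(vol$data, c(3, 2, 1))), con, size = 4L,
           endian = "little")
  invisible(path)
}

#' Read an MRC volume
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16) with the
#' standard x-fastest axis order.
#'
#' @param path MRC file path.
#' @return A [vol3d()] with voxel size (nm) taken from the header.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  nxyz <- ri(3)
  mode <- ri(1)
  ri(3)                        # starts
  mxyz <- ri(3)
  cella <- rf(3)
  rf(3)                        # angles
  maps <- ri(3)
  if (!identical(maps, c(1L, 2L, 3L)))
    stop("only x-fastest MRC axis order is supported", call. = FALSE)
  rf(3); ri(2)
  readBin(con, "raw", 100)
  orig <- rf(3)
  readBin(con, "raw", 816) # MAP stamp, rms, labels
  n <- prod(nxyz)
  raw_data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2L, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n, size = 2L, signed = FALSE,
                             endian = "little")),
    stop(sprintf("unsupported MRC mode %d", mode), call. = FALSE))
  arr <- aperm(array(raw_data, dim = nxyz), c(3, 2, 1)) # -> (z,y,x)
  vs <- ifelse(mxyz > 0, cella / mxyz, 1) / 10          # Angstrom -> nm
  vol3d(arr, voxel_size = vs[c(3, 2, 1)], origin = orig[c(3, 2, 1)] / 10)
}

# --------------------------------------------------------------- TIFF I/O

#' Write a volume as a multi-page TIFF
#'
#' One 32-bit float page per z slice. TIFF carries no 3D voxel size, so the
#' size must be supplied again on read.
#'
#' @param vol A [vol3d()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(vol, path) {
  stopifnot(is_vol3d(vol))
  # the tiff package writes floats as-is with bits.per.sample = 32
  pages <- lapply(seq_len(dim(vol$data)[1]),
                  function(i) vol$data[i, , , drop = TRUE])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as a volume
#'
#' @param path TIFF file path.
#' @param voxel_size Voxel size in nm (scalar or `(z,y,x)` vector).
#' @param invert Invert contrast (`max - x`), for TEM data in which
#'   particles are darker than background.
#' @return A [vol3d()].
#' @export
read_tiff_stack <- function(path, voxel_size, invert = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1] # drop extra channels
    p
  })
  d <- dim(pages[[1]])
  arr <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  if (invert) arr <- max(arr) - arr
  vol3d(arr, voxel_size = voxel_size)
}
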