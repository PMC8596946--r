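#' Mask geometry for voxel-wise analysis
#'
#' Binds a binary analysis mask to its voxel grid: dimensions, voxel size (mm),
#' the mm offset of the centre of voxel (0,0,0), and a bijection between
#' in-mask voxel coordinates and column indices of the flattened data matrices
#' used throughout the package. Voxel indices are 0-based; a voxel's mm
#' coordinate is `origin + index * voxel_size`.
#'
#' @param mask logical (or 0/1 numeric) 3-D array; `TRUE` marks in-mask voxels.
#' @param voxel_size numeric length 1 or 3, voxel edge length in mm per axis.
#' @param origin numeric length 3, mm coordinate of the centre of voxel (0,0,0).
#' @return An object of class `mask_geometry` with fields `dims`, `voxel_size`,
#'   `origin`, `mask` (logical array), `n_vox` (number of in-mask voxels),
#'   `vox_index` (`n_vox` x 3 integer matrix of 0-based voxel indices, one row
#'   per data column) and `lut` (integer array over the grid: 0 outside the
#'   mask, otherwise the data column index).
#' @export
mask_geometry <- function(mask, voxel_size = c(3, 3, 3), origin = c(0, 0, 0)) {
  if (length(dim(mask)) != 3L)
    stop("mask must be a 3-D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("mask contains NA")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0), length(origin) == 3L)
  dims <- dim(mask)
  flat <- which(mask)                       # column-major order of in-mask voxels
  lut <- array(0L, dim = dims)
  lut[flat] <- seq_along(flat)
  vox_index <- arrayInd(flat, dims) - 1L    # 0-based
  structure(list(
    dims = dims, voxel_size = as.numeric(voxel_size),
    origin = as.numeric(origin), mask = mask,
    n_vox = length(flat), flat = flat, vox_index = vox_index, lut = lut
  ), class = "mask_geometry")
}

#' @export
print.mask_geometry <- function(x, ...) {
  cat(sprintf("mask_geometry: %d x %d x %d grid, %.3g x %.3g x %.3g mm voxels, %d in-mask voxels\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$n_vox))
  invisible(x)
}

#' Convert 0-based voxel indices to mm coordinates
#'
#' @param geometry a [mask_geometry()].
#' @param vox integer matrix (n x 3) of 0-based voxel indices; defaults to all
#'   in-mask voxels in column order.
#' @return n x 3 matrix of mm coordinates (`origin + index * voxel_size`).
#' @export
voxel_to_mm <- function(geometry, vox = geometry$vox_index) {
  vox <- matrix(as.numeric(vox), ncol = 3L)
  sweep(sweep(vox, 2L, geometry$voxel_size, `*`), 2L, geometry$origin, `+`)
}

#' Embed an in-mask vector into a full 3-D array
#'
#' Out-of-mask voxels are set to `fill` (default 0).
#' @param values numeric vector of length `geometry$n_vox`.
#' @inheritParams voxel_to_mm
#' @param fill value for out-of-mask voxels.
#' @return 3-D numeric array with the grid dimensions.
#' @export
unmask <- function(values, geometry, fill = 0) {
  if (length(values) != geometry$n_vox)
    stop(sprintf("values has length %d but mask has %d voxels",
                 length(values), geometry$n_vox))
  vol <- array(fill, dim = geometry$dims)
  vol[geometry$flat] <- values
  vol
}

# Precompute in-mask neighbor pairs along one axis (for smoothness estimation)
# or full connectivity lists (for cluster labeling).
axis_neighbor_pairs <- function(geometry, axis) {
  d <- geometry$dims
  idx <- geometry$vox_index
  shifted <- idx
  shifted[, axis] <- shifted[, axis] + 1L
  ok <- shifted[, axis] < d[axis]
  flat_next <- shifted[ok, 1L] + 1L + d[1L] * (shifted[ok, 2L] + d[2L] * shifted[ok, 3L])
  j <- geometry$lut[flat_next]
  keep <- j > 0L
  cbind(which(ok)[keep], j[keep])
}

# Offsets for 6-, 18-, 26-connectivity
connectivity_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6"  = nz == 1,
                 "18" = nz >= 1 & nz <= 2,
                 "26" = nz >= 1)
  g[keep, , drop = FALSE]
}

# Label connected components of a logical vector over in-mask voxels.
# Returns integer labels (0 = below threshold), BFS over precomputed offsets.
label_components <- function(above, geometry, connectivity = 6L) {
  stopifnot(length(above) == geometry$n_vox)
  labels <- integer(geometry$n_vox)
  sel <- which(above)
  if (length(sel) == 0L) return(labels)
  d <- geometry$dims
  offs <- connectivity_offsets(connectivity)
  lut <- geometry$lut
  idx <- geometry$vox_index
  in_set <- logical(geometry$n_vox)
  in_set[sel] <- TRUE
  stack <- integer(length(sel))
  cur <- 0L
  for (s in sel) {
    if (labels[s] != 0L) next
    cur <- cur + 1L
    labels[s] <- cur
    stack[1L] <- s
    top <- 1L
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L
      p <- idx[v, ]
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 0L) || any(q >= d)) next
        j <- lut[q[1L] + 1L, q[2L] + 1L, q[3L] + 1L]
        if (j > 0L && in_set[j] && labels[j] == 0L) {
          labels[j] <- cur
          top <- top + 1L
          stack[top] <- j
        }
      }
    }
  }
  labels
}
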