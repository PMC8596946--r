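# Cluster-extent correction: spatial smoothness of the maps is estimated
# from the first-neighbor variance ratio, a Monte-Carlo simulation of smooth
# Gaussian null fields calibrates the minimum cluster size controlling the
# familywise rate at the cluster level, and suprathreshold clusters of the
# BSR map larger than that minimum are reported.

#' Estimate spatial smoothness (FWHM) of parameter maps
#'
#' Per axis, the first-neighbor variance-ratio estimator
#' `FWHM = dx * sqrt(-2 log 2 / log(1 - s2_diff / (2 s2)))`, where `s2_diff`
#' is the variance of in-mask neighbor differences along the axis and `s2`
#' the in-mask value variance; averaged over maps. Maps rougher than white
#' noise (the log argument non-positive) contribute FWHM 0 with a warning.
#'
#' @param maps numeric matrix, rows are maps over in-mask voxels (typically
#'   residual maps after removing session means).
#' @param geometry [mask_geometry()].
#' @return object of class `smoothness_estimate`: `fwhm` (per-axis, mm),
#'   `fwhm_mean` (geometric mean over axes), `n_maps`.
#' @export
estimate_fwhm <- function(maps, geometry) {
  if (is.vector(maps)) maps <- matrix(maps, nrow = 1L)
  stopifnot(ncol(maps) == geometry$n_vox)
  if (geometry$n_vox < 100L) warning("mask has fewer than 100 voxels")
  pairs <- lapply(1:3, function(ax) axis_neighbor_pairs(geometry, ax))
  n_maps <- nrow(maps)
  acc <- matrix(NA_real_, n_maps, 3L)
  warned <- FALSE
  for (i in seq_len(n_maps)) {
    x <- maps[i, ]
    s2 <- var(x)
    if (s2 == 0) {
      warning("map ", i, " has zero variance; FWHM set to 0")
      acc[i, ] <- 0
      next
    }
    for (ax in 1:3) {
      pr <- pairs[[ax]]
      dvar <- var(x[pr[, 1]] - x[pr[, 2]])
      arg <- 1 - dvar / (2 * s2)
      if (arg <= 0) {
        if (!warned) {
          warning("map rougher than white noise along axis ", ax,
                  "; FWHM set to 0")
          warned <- TRUE
        }
        acc[i, ax] <- 0
      } else {
        acc[i, ax] <- geometry$voxel_size[ax] * sqrt(-2 * log(2) / log(arg))
      }
    }
  }
  fwhm <- colMeans(acc)
  structure(list(fwhm = fwhm,
                 fwhm_mean = exp(mean(log(pmax(fwhm, 1e-12)))) *
                   (if (all(fwhm > 0)) 1 else 0),
                 n_maps = n_maps), class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("smoothness_estimate: FWHM = %.2f x %.2f x %.2f mm (geometric mean %.2f) from %d maps\n",
              x$fwhm[1], x$fwhm[2], x$fwhm[3], x$fwhm_mean, x$n_maps))
  invisible(x)
}

#' Monte-Carlo minimum cluster-extent threshold
#'
#' Simulates `n_sim` smooth standard-normal null fields within the mask,
#' applies the two-sided voxel threshold `|z| > qnorm(1 - voxel_p / 2)`,
#' records the largest suprathreshold cluster in each field, and returns one
#' more than the `ceiling((1 - alpha) * n_sim)`-th order statistic: the
#' smallest cluster size whose null familywise probability is below `alpha`.
#'
#' @param geometry [mask_geometry()].
#' @param fwhm smoothness of the null fields in mm (scalar; e.g.
#'   `fwhm_mean` from [estimate_fwhm()]).
#' @param voxel_p two-sided voxel-level p threshold (default 0.005).
#' @param alpha cluster-level familywise rate (default 0.05).
#' @param n_sim number of null fields (default 2000; < 200 warns).
#' @param connectivity 6, 18 or 26 (default 6, faces only).
#' @param seed integer seed; deterministic given it.
#' @return minimum cluster size in voxels (integer).
#' @export
simulate_cluster_threshold <- function(geometry, fwhm, voxel_p = 0.005,
                                       alpha = 0.05, n_sim = 2000L,
                                       connectivity = 6L, seed = 1L) {
  if (n_sim < 200L) warning("n_sim < 200 gives an unstable cluster threshold")
  zthr <- qnorm(1 - voxel_p / 2)
  maxes <- integer(n_sim)
  with_seed(seed, {
    done <- 0L
    while (done < n_sim) {
      batch <- min(200L, n_sim - done)
      fields <- smooth_gaussian_field(geometry$dims, geometry$voxel_size,
                                      fwhm, n = batch)
      for (j in seq_len(batch)) {
        z <- fields[geometry$flat, j]
        above <- abs(z) > zthr
        maxes[done + j] <- if (!any(above)) 0L else {
          lab <- label_components(above, geometry, connectivity)
          max(tabulate(lab))
        }
      }
      done <- done + batch
    }
  })
  sort(maxes)[ceiling((1 - alpha) * n_sim)] + 1L
}

#' Extract suprathreshold clusters from a statistic map
#'
#' Binarizes at `|stat| >= qnorm(1 - voxel_p / 2)`, labels connected
#' components, drops those smaller than `min_size`, and reports each
#' surviving cluster's |stat|-weighted centre of mass (mm), volume (mm^3)
#' and peak signed statistic, sorted by size descending.
#'
#' @param stat numeric vector over in-mask voxels (e.g. voxel BSRs).
#' @param geometry [mask_geometry()].
#' @param voxel_p two-sided voxel threshold (default 0.005).
#' @param min_size minimum cluster size in voxels (default 1).
#' @param connectivity 6, 18 or 26.
#' @return object of class `cluster_table`: data.frame with `cluster`,
#'   `com_x/y/z` (mm), `size_vox`, `size_mm3`, `peak`; attribute `voxels` is
#'   a list of in-mask column indices per cluster.
#' @export
extract_clusters <- function(stat, geometry, voxel_p = 0.005, min_size = 1L,
                             connectivity = 6L) {
  if (any(!is.finite(stat))) stat[!is.finite(stat)] <- sign(stat[!is.finite(stat)]) * 1e6
  zthr <- qnorm(1 - voxel_p / 2)
  above <- abs(stat) >= zthr
  lab <- label_components(above, geometry, connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_size)
  vol_vox <- prod(geometry$voxel_size)
  rows <- list(); vox_list <- list()
  for (i in seq_along(keep)) {
    vox <- which(lab == keep[i])
    w <- abs(stat[vox])
    com <- colSums(voxel_to_mm(geometry, geometry$vox_index[vox, , drop = FALSE]) *
                     w) / sum(w)
    rows[[i]] <- data.frame(com_x = com[1], com_y = com[2], com_z = com[3],
                            size_vox = length(vox),
                            size_mm3 = length(vox) * vol_vox,
                            peak = stat[vox[which.max(w)]])
    vox_list[[i]] <- vox
  }
  if (length(rows) == 0L) {
    tab <- data.frame(cluster = integer(0), com_x = numeric(0),
                      com_y = numeric(0), com_z = numeric(0),
                      size_vox = integer(0), size_mm3 = numeric(0),
                      peak = numeric(0))
    attr(tab, "voxels") <- list()
    class(tab) <- c("cluster_table", "data.frame")
    return(tab)
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$size_vox)
  tab <- tab[ord, , drop = FALSE]
  vox_list <- vox_list[ord]
  tab <- cbind(cluster = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  attr(tab, "voxels") <- vox_list
  class(tab) <- c("cluster_table", "data.frame")
  tab
}
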