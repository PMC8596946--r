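#' @importFrom stats median mad sd var cor quantile rnorm runif rbinom qnorm
#'   pnorm pchisq optimize setNames complete.cases p.adjust psignrank pwilcox
#'   prcomp
#' @importFrom utils read.csv write.csv head
NULL

SESSIONS <- c("ACU", "RTP", "YR1")
MODALITIES <- c("CBF", "FA", "MD")

MANIFEST_COLS <- c("subject_id", "group", "sex", "age", "hoc", "n_prior",
                   "months_since_last", "sport", "days_to_rtp",
                   "session", "modality", "volume_path")

#' Validate a subject demographics table
#'
#' Checks the invariants of the cohort data model: `group` in
#' control/concussed, `sex` and `hoc` binary (0 = male, 1 = female;
#' 0/1 history of concussion), `days_to_rtp` only for concussed athletes,
#' and `n_prior > 0` exactly when `hoc = 1`.
#'
#' @param subjects data.frame with columns `subject_id`, `group`, `sex`,
#'   `age`, `hoc`, `n_prior`, `months_since_last`, `sport`, `days_to_rtp`.
#' @return the validated data.frame (invisibly usable), with `group` as
#'   character.
#' @export
validate_subjects <- function(subjects) {
  need <- c("subject_id", "group", "sex", "age", "hoc")
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    stop("subject table is missing columns: ", paste(miss, collapse = ", "))
  subjects$group <- as.character(subjects$group)
  if (!all(subjects$group %in% c("control", "concussed")))
    stop("group must be 'control' or 'concussed'")
  if (!all(subjects$sex %in% c(0, 1))) stop("sex must be 0 (male) or 1 (female)")
  if (!all(subjects$hoc %in% c(0, 1))) stop("hoc must be 0 or 1")
  if (!is.null(subjects$days_to_rtp)) {
    bad <- !is.na(subjects$days_to_rtp) & subjects$group == "control"
    if (any(bad)) stop("days_to_rtp present for control subject(s): ",
                       paste(subjects$subject_id[bad], collapse = ", "))
  }
  if (!is.null(subjects$n_prior)) {
    ok <- is.na(subjects$n_prior) | ((subjects$n_prior > 0) == (subjects$hoc == 1))
    if (!all(ok)) stop("n_prior > 0 must hold exactly when hoc = 1 (subjects: ",
                       paste(subjects$subject_id[!ok], collapse = ", "), ")")
  }
  subjects
}

#' Read a cohort: manifest, parameter maps, and analysis mask
#'
#' Loads the CSV manifest, the shared binary mask and every referenced NIfTI
#' volume, extracting in-mask values in the geometry's column order. One map
#' row is produced per (subject, session, modality) manifest row.
#'
#' @param manifest_path CSV with columns `subject_id, group, sex, age, hoc,
#'   n_prior, months_since_last, sport, days_to_rtp, session, modality,
#'   volume_path`.
#' @param volume_dir directory that relative `volume_path` entries are
#'   resolved against.
#' @param mask_path NIfTI binary mask defining the analysis geometry.
#' @return list with `subjects` (one row per subject), `maps` (a `map_set`:
#'   `values` matrix of maps x voxels plus an `info` data.frame), and
#'   `geometry` ([mask_geometry()]).
#' @export
read_cohort <- function(manifest_path, volume_dir, mask_path) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  miss <- setdiff(MANIFEST_COLS, names(man))
  if (length(miss))
    stop("manifest is missing required columns: ", paste(miss, collapse = ", "))
  geometry <- read_mask(mask_path)
  values <- matrix(NA_real_, nrow(man), geometry$n_vox)
  for (i in seq_len(nrow(man))) {
    path <- man$volume_path[i]
    if (!file.exists(path)) path <- file.path(volume_dir, man$volume_path[i])
    if (!file.exists(path))
      stop("volume file not found: ", man$volume_path[i])
    vol <- as.array(RNifti::readNifti(path))
    if (!identical(dim(vol), geometry$dims))
      stop(sprintf("volume %s has dims %s but mask has %s",
                   man$volume_path[i], paste(dim(vol), collapse = "x"),
                   paste(geometry$dims, collapse = "x")))
    v <- vol[geometry$flat]
    if (any(!is.finite(v)))
      stop(sprintf("non-finite voxel values inside mask for subject %s (%s/%s)",
                   man$subject_id[i], man$session[i], man$modality[i]))
    values[i, ] <- v
  }
  subjects <- validate_subjects(unique(man[, setdiff(MANIFEST_COLS,
    c("session", "modality", "volume_path"))]))
  rownames(subjects) <- NULL
  maps <- map_set(values, man[, c("subject_id", "session", "modality")], geometry)
  list(subjects = subjects, maps = maps, geometry = geometry)
}

#' Construct a map set
#'
#' Container for a stack of masked parameter maps: a maps-by-voxels value
#' matrix plus per-row metadata.
#'
#' @param values numeric matrix, rows are maps, columns in-mask voxels.
#' @param info data.frame with `subject_id`, `session`, `modality` per row.
#' @param geometry [mask_geometry()].
#' @export
map_set <- function(values, info, geometry) {
  stopifnot(is.matrix(values), nrow(values) == nrow(info),
            ncol(values) == geometry$n_vox)
  structure(list(values = values, info = info, geometry = geometry),
            class = "map_set")
}

#' @export
print.map_set <- function(x, ...) {
  cat(sprintf("map_set: %d maps x %d voxels (%s)\n", nrow(x$values),
              ncol(x$values), paste(unique(x$info$modality), collapse = ", ")))
  invisible(x)
}

#' Read a NIfTI mask as geometry
#'
#' Voxels with value > 0.5 are in-mask. Voxel size comes from the NIfTI
#' pixdim; the origin from the stored transform's translation.
#' @param path NIfTI file.
#' @return [mask_geometry()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  vol <- as.array(img)
  vox <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else unname(xf[1:3, 4])
  mask_geometry(vol > 0.5, voxel_size = vox, origin = origin)
}

#' Write an in-mask statistic vector as a NIfTI volume
#'
#' Out-of-mask voxels are written as 0. Data are stored as float32 (the
#' conventional statistical-map dtype); in-memory computation stays double.
#'
#' @param values numeric vector over in-mask voxels.
#' @param geometry [mask_geometry()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_stat_map <- function(values, geometry, path) {
  vol <- unmask(values, geometry)
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- geometry$voxel_size
  xf <- diag(c(geometry$voxel_size, 1))
  xf[1:3, 4] <- geometry$origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a mask as NIfTI
#' @inheritParams write_stat_map
#' @export
write_mask <- function(geometry, path) {
  write_stat_map(rep(1, geometry$n_vox), geometry, path)
}

check_prob_map <- function(p, name) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop(name, " must contain probabilities in [0, 1]")
  invisible(p)
}

#' Gray-matter analysis mask from tissue probabilities and perfusion floor
#'
#' A voxel enters the mask when its gray-matter probability exceeds the sum
#' of white-matter and CSF probabilities, and the mean control CBF exceeds a
#' perfusion floor (strict `> cbf_floor`), which guards against white-matter
#' partial-volume voxels.
#'
#' @param p_gm,p_wm,p_csf tissue probability arrays in \[0, 1\], same dims.
#' @param mean_control_cbf array of mean control CBF (ml/100 g/min).
#' @param cbf_floor perfusion floor, default 20 ml/100 g/min.
#' @param exclusion_mask optional logical array of voxels to drop (e.g.
#'   manually traced ventricles).
#' @return logical array (the mask).
#' @export
build_gm_mask <- function(p_gm, p_wm, p_csf, mean_control_cbf, cbf_floor = 20,
                          exclusion_mask = NULL) {
  check_prob_map(p_gm, "p_gm"); check_prob_map(p_wm, "p_wm")
  check_prob_map(p_csf, "p_csf")
  stopifnot(identical(dim(p_gm), dim(p_wm)), identical(dim(p_gm), dim(p_csf)),
            identical(dim(p_gm), dim(mean_control_cbf)))
  m <- (p_gm > p_wm + p_csf) & (mean_control_cbf > cbf_floor)
  if (!is.null(exclusion_mask)) m <- m & !exclusion_mask
  m
}

#' White-matter analysis mask from a template FA map
#'
#' Voxels with template fractional anisotropy strictly above `fa_floor`
#' (default 0.30) are retained, minus an optional exclusion mask (e.g. brain
#' stem, where field inhomogeneity corrupts DTI fits).
#'
#' @param template_fa FA array in \[0, 1\].
#' @param fa_floor FA threshold, default 0.30.
#' @param exclusion_mask optional logical array to drop.
#' @return logical array.
#' @export
build_wm_mask <- function(template_fa, fa_floor = 0.30, exclusion_mask = NULL) {
  check_prob_map(template_fa, "template_fa")
  m <- template_fa > fa_floor
  if (!is.null(exclusion_mask)) m <- m & !exclusion_mask
  if (!any(m)) warning("white-matter mask is empty")
  m
}
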