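# Cohort simulator: smooth Gaussian voxel noise, demographic baseline
# offsets, planted session-varying group and sex-by-group effects, MCAR
# session dropout, and SCAT-style symptom tables, all reproducible from a
# single seed so downstream inference can be scored against known truth.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-h:h)^2) / (2 * sigma_vox^2))
  k / sqrt(sum(k^2))        # unit L2 norm: smoothed white noise keeps variance 1
}

circulant <- function(k, d) {
  h <- (length(k) - 1L) / 2L
  K <- matrix(0, d, d)
  for (j in seq_along(k)) {
    off <- j - 1L - h
    idx <- ((seq_len(d) - 1L + off) %% d) + 1L
    K[cbind(idx, seq_len(d))] <- K[cbind(idx, seq_len(d))] + k[j]
  }
  K
}

# Smooth n stacked white-noise fields with a separable Gaussian kernel using
# circular (wrap-around) convolution, which keeps the field stationary with
# exactly unit marginal variance.
smooth_white_fields <- function(white, dims, sigma_vox) {
  n <- ncol(white)
  x <- white
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    K <- circulant(gaussian_kernel_1d(sigma_vox[ax]), dims[ax])
    perm <- c(ax, setdiff(1:3, ax), 4L)
    a <- aperm(array(x, dim = c(dims, n)), perm)
    m <- K %*% matrix(a, nrow = dims[ax])
    a <- array(m, dim = c(dims[ax], dims[setdiff(1:3, ax)], n))
    x <- matrix(aperm(a, order(perm)), ncol = n)
  }
  x
}

#' Spatially smooth standard Gaussian random field
#'
#' White noise convolved with an isotropic Gaussian kernel of the requested
#' full width at half maximum, renormalized to unit marginal variance.
#' Convolution is circular, so the field is stationary on the torus; with a
#' kernel much smaller than the grid this is indistinguishable from an
#' infinite-domain field in the grid interior.
#'
#' @param dims integer length 3, grid dimensions.
#' @param voxel_size mm per axis (length 1 or 3).
#' @param fwhm smoothing kernel FWHM in mm (0 = i.i.d. white noise).
#' @param n number of independent fields.
#' @param seed optional integer; when given the caller's RNG state is left
#'   untouched.
#' @return matrix of `prod(dims)` rows (full grid, column-major) by `n`
#'   fields.
#' @export
smooth_gaussian_field <- function(dims, voxel_size = c(3, 3, 3), fwhm = 6,
                                  n = 1, seed = NULL) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  with_seed(seed, {
    white <- matrix(rnorm(prod(dims) * n), ncol = n)
    sigma_vox <- (fwhm / sqrt(8 * log(2))) / voxel_size
    smooth_white_fields(white, dims, sigma_vox)
  })
}

#' Default ellipsoidal analysis mask
#'
#' A brain-interior ellipsoid occupying roughly the central portion of the
#' grid, mimicking the compact analysis masks obtained from tissue
#' segmentation.
#' @param dims grid dimensions.
#' @param voxel_size mm per axis.
#' @param scale semi-axes as a fraction of the half-grid (default 0.5,
#'   giving roughly 950 voxels on the default grid).
#' @return a [mask_geometry()] with origin placing mm (0,0,0) at the grid
#'   centre.
#' @export
default_mask <- function(dims = c(24, 28, 24), voxel_size = 3, scale = 0.5) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  ctr <- (dims - 1) / 2
  semi <- pmax(ctr * scale, 1)
  g <- expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1), z = 0:(dims[3] - 1))
  r2 <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2
  mask <- array(r2 <= 1, dim = dims)
  mask_geometry(mask, voxel_size = voxel_size, origin = -ctr * voxel_size)
}

#' Grow a compact region inside a mask
#'
#' The `n` in-mask voxels nearest (Euclidean, voxel units) to a fractional
#' grid position; deterministic given the geometry.
#' @param geometry [mask_geometry()].
#' @param centre_frac length-3 fractional position in the grid (0-1).
#' @param n number of voxels.
#' @return integer vector of in-mask column indices.
#' @export
grow_region <- function(geometry, centre_frac, n) {
  stopifnot(n >= 1, n <= geometry$n_vox)
  ctr <- centre_frac * (geometry$dims - 1)
  d2 <- rowSums(sweep(geometry$vox_index, 2L, ctr, `-`)^2)
  order(d2)[seq_len(n)]
}

default_modality_params <- function() {
  list(
    CBF = list(mean = 55,     noise_sd = 6,     sex_offset = 6,
               age_slope = -0.4,  hoc_offset = -1),
    FA  = list(mean = 0.45,   noise_sd = 0.03,  sex_offset = -0.01,
               age_slope = 0.001, hoc_offset = -0.005),
    MD  = list(mean = 7.5e-4, noise_sd = 3e-5,  sex_offset = 1e-5,
               age_slope = -1e-6, hoc_offset = 2e-6)
  )
}

#' Simulation configuration
#'
#' Defines the cohort and signal model for [simulate_cohort()]. Defaults
#' reproduce the study conditions the pipeline targets: 167 controls, 61
#' concussed athletes imaged acutely (ACU), at return to play (RTP) and one
#' year later (YR1), with session dropout rates 8/61, 10/61 and 29/61; smooth
#' Gaussian voxel noise (6 mm FWHM at 3 mm voxels); additive sex, age and
#' history-of-concussion baseline offsets; a session-varying concussion main
#' effect in one compact region; and a session-varying sex-by-concussion
#' effect in a second, disjoint region.
#'
#' Effect amplitudes are expressed in units of the per-modality noise SD. The
#' sex effect is planted with its sign tied to the sex code (+a for females,
#' -a for males, concussed only), so the planted female-minus-male contrast
#' is `2a` while the concussed group mean is unshifted in expectation.
#'
#' @param n_control,n_concussed cohort sizes.
#' @param dims,voxel_size grid (default 24 x 28 x 24 at 3 mm).
#' @param geometry analysis mask; default [default_mask()].
#' @param modalities subset of CBF/FA/MD to simulate.
#' @param modality_params per-modality list of `mean`, `noise_sd`,
#'   `sex_offset`, `age_slope`, `hoc_offset` (map units).
#' @param noise_fwhm spatial noise correlation FWHM in mm.
#' @param intercept_sd subject random-intercept SD in noise-SD units.
#' @param main_effect list(`n_voxels`, `amplitudes` named ACU/RTP/YR1,
#'   noise-SD units) for the concussion main effect.
#' @param sex_effect same structure for the sex-by-concussion effect.
#' @param dropout_probs per-session probability a concussed athlete misses
#'   that scan (missing completely at random).
#' @param balanced_concussed_sex force an exact floor/ceil male/female split
#'   in the concussed group instead of Bernoulli(0.5).
#' @param seed integer master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_control = 167, n_concussed = 61,
                       dims = c(24, 28, 24), voxel_size = 3,
                       geometry = NULL,
                       modalities = c("CBF", "FA", "MD"),
                       modality_params = default_modality_params(),
                       noise_fwhm = 6, intercept_sd = 1,
                       main_effect = list(n_voxels = 150,
                         amplitudes = c(ACU = -0.5, RTP = -0.7, YR1 = -1.0)),
                       sex_effect = list(n_voxels = 150,
                         amplitudes = c(ACU = 0.4, RTP = 0.8, YR1 = 0.6)),
                       dropout_probs = c(ACU = 8 / 61, RTP = 10 / 61, YR1 = 29 / 61),
                       balanced_concussed_sex = FALSE,
                       seed = 1L) {
  stopifnot(n_control > 0, n_concussed > 0,
            all(dropout_probs >= 0), all(dropout_probs <= 1))
  if (is.null(geometry)) geometry <- default_mask(dims, voxel_size)
  cfg <- list(n_control = n_control, n_concussed = n_concussed,
              geometry = geometry, modalities = match.arg(modalities,
                MODALITIES, several.ok = TRUE),
              modality_params = modality_params, noise_fwhm = noise_fwhm,
              intercept_sd = intercept_sd, main_effect = main_effect,
              sex_effect = sex_effect,
              dropout_probs = dropout_probs[SESSIONS],
              balanced_concussed_sex = balanced_concussed_sex,
              seed = as.integer(seed))
  names(cfg$dropout_probs) <- SESSIONS
  class(cfg) <- "sim_config"
  cfg
}

resolve_region <- function(spec, geometry, centre_frac) {
  if (!is.null(spec$voxels)) {
    v <- as.integer(spec$voxels)
    if (any(v < 1) || any(v > geometry$n_vox))
      stop("effect region lies outside the analysis mask")
    return(v)
  }
  if (is.null(spec$n_voxels) || spec$n_voxels == 0) return(integer(0))
  grow_region(geometry, centre_frac, spec$n_voxels)
}

sim_demographics <- function(n, prefix, group, balanced_sex = FALSE) {
  age <- pmin(pmax(round(rnorm(n, 20.3, 2)), 17), 28)
  sex <- if (balanced_sex) {
    s <- c(rep(0, floor(n / 2)), rep(1, ceiling(n / 2)))
    sample(s)
  } else rbinom(n, 1, 0.5)
  hoc <- rbinom(n, 1, 0.5)
  n_prior <- ifelse(hoc == 1, sample(1:3, n, replace = TRUE), 0L)
  months <- ifelse(hoc == 1, round(runif(n, 6, 48)), NA_real_)
  sports <- c("hockey", "rugby", "football", "soccer", "basketball",
              "volleyball", "lacrosse")
  data.frame(
    subject_id = sprintf("%s%03d", prefix, seq_len(n)),
    group = group, sex = sex, age = as.numeric(age), hoc = hoc,
    n_prior = as.integer(n_prior), months_since_last = months,
    sport = sample(sports, n, replace = TRUE),
    days_to_rtp = if (group == "concussed")
      round(exp(rnorm(n, log(14), 0.5))) else NA_real_,
    stringsAsFactors = FALSE
  )
}

sim_symptom_items <- function(n, intensity) {
  # intensity: expected per-item endorsement probability and severity scale
  p <- intensity[1]; lam <- intensity[2]
  on <- matrix(rbinom(n * 22L, 1, p), n, 22L)
  sev <- matrix(pmin(1L + stats::rpois(n * 22L, lam), 6L), n, 22L)
  on * sev
}

#' Simulate a full synthetic cohort
#'
#' Generates demographics, masked parameter maps for every retained
#' (subject, session, modality), SCAT-style symptom tables (baseline for
#' everyone; baseline/ACU/RTP for concussed athletes, elevated acutely and
#' near baseline at RTP) and a ground-truth record. Controls are imaged once
#' (session `CONTROL`); concussed athletes at ACU/RTP/YR1 minus MCAR dropout.
#'
#' Each map is `mean + sex_offset*sex + age_slope*(age-20) + hoc_offset*hoc +
#' intercept_s + planted effects + noise_sd * smooth field`, with the main
#' effect added to all concussed athletes in region 1 and the sex effect
#' added as +a (female) / -a (male) in region 2.
#'
#' @param config a [sim_config()].
#' @return list with `subjects`, `maps` (a `map_set`), `symptoms`
#'   (subject x session item table), `truth` (regions, amplitude schedules,
#'   intercepts, dropout realization) and `geometry`.
#' @export
simulate_cohort <- function(config) {
  geometry <- config$geometry
  with_seed(config$seed, {
    controls <- sim_demographics(config$n_control, "C", "control")
    concussed <- sim_demographics(config$n_concussed, "P", "concussed",
                                  config$balanced_concussed_sex)
    subjects <- rbind(controls, concussed)

    main_idx <- resolve_region(config$main_effect, geometry, c(0.32, 0.35, 0.50))
    sex_idx <- resolve_region(config$sex_effect, geometry, c(0.68, 0.65, 0.50))

    retained <- matrix(TRUE, config$n_concussed, 3L,
                       dimnames = list(concussed$subject_id, SESSIONS))
    for (t in 1:3)
      retained[, t] <- runif(config$n_concussed) >= config$dropout_probs[t]

    # schedule of map rows (same for every modality)
    sched <- data.frame(i = seq_len(config$n_control), session = "CONTROL",
                        stringsAsFactors = FALSE)
    for (j in seq_len(config$n_concussed)) for (t in 1:3)
      if (retained[j, t])
        sched <- rbind(sched, data.frame(i = config$n_control + j,
                                         session = SESSIONS[t]))
    n_maps <- nrow(sched)

    info_list <- list(); value_list <- list()
    intercepts <- list()
    for (mod in config$modalities) {
      mp <- config$modality_params[[mod]]
      b_int <- rnorm(nrow(subjects), 0, config$intercept_sd * mp$noise_sd)
      names(b_int) <- subjects$subject_id
      intercepts[[mod]] <- b_int
      base <- mp$mean + mp$sex_offset * subjects$sex +
        mp$age_slope * (subjects$age - 20) + mp$hoc_offset * subjects$hoc + b_int

      noise <- smooth_gaussian_field(geometry$dims, geometry$voxel_size,
                                     config$noise_fwhm, n = n_maps)
      vals <- matrix(0, n_maps, geometry$n_vox)
      for (r in seq_len(n_maps)) {
        i <- sched$i[r]; sess <- sched$session[r]
        v <- base[i] + mp$noise_sd * noise[geometry$flat, r]
        if (sess != "CONTROL") {
          t <- match(sess, SESSIONS)
          v[main_idx] <- v[main_idx] +
            config$main_effect$amplitudes[t] * mp$noise_sd
          v[sex_idx] <- v[sex_idx] +
            config$sex_effect$amplitudes[t] * mp$noise_sd *
              (2 * subjects$sex[i] - 1)
        }
        if (mod == "FA") v <- pmin(pmax(v, 0), 1)
        vals[r, ] <- v
      }
      info_list[[mod]] <- data.frame(subject_id = subjects$subject_id[sched$i],
                                     session = sched$session, modality = mod,
                                     stringsAsFactors = FALSE)
      value_list[[mod]] <- vals
    }
    maps <- map_set(do.call(rbind, value_list), do.call(rbind, info_list),
                    geometry)

    # symptoms: baseline for everyone; ACU elevated / RTP near baseline for
    # concussed athletes only
    symp <- list()
    base_items <- sim_symptom_items(nrow(subjects), c(0.12, 0.3))
    symp[[1]] <- data.frame(subject_id = subjects$subject_id,
                            session = "baseline", base_items)
    acu_items <- sim_symptom_items(config$n_concussed, c(0.55, 1.4))
    symp[[2]] <- data.frame(subject_id = concussed$subject_id,
                            session = "ACU", acu_items)
    rtp_items <- sim_symptom_items(config$n_concussed, c(0.10, 0.3))
    symp[[3]] <- data.frame(subject_id = concussed$subject_id,
                            session = "RTP", rtp_items)
    symptoms <- do.call(rbind, symp)
    names(symptoms)[3:24] <- sprintf("item_%02d", 1:22)
    rownames(symptoms) <- NULL

    truth <- structure(list(
      main_region = main_idx, sex_region = sex_idx,
      main_amplitudes = config$main_effect$amplitudes,
      sex_amplitudes = config$sex_effect$amplitudes,
      modality_params = config$modality_params[config$modalities],
      intercepts = intercepts, retained = retained,
      seed = config$seed), class = "synthetic_truth")

    list(subjects = subjects, maps = maps, symptoms = symptoms,
         truth = truth, geometry = geometry)
  })
}

#' Ground-truth contrast table for a simulated cohort
#'
#' Per modality, session and planted region: the true group-mean difference
#' contrast (main-effect region) and the true female-minus-male contrast
#' (sex-effect region, `2 * amplitude * noise_sd` under the sign-tied
#' planting), in map units.
#'
#' @param truth the `truth` element returned by [simulate_cohort()].
#' @return data.frame with columns `modality`, `region`, `session`,
#'   `true_contrast`, `n_voxels`.
#' @export
truth_report <- function(truth) {
  rows <- list(); r <- 0L
  for (mod in names(truth$modality_params)) {
    sdv <- truth$modality_params[[mod]]$noise_sd
    for (t in 1:3) {
      r <- r + 1L
      rows[[r]] <- data.frame(modality = mod, region = "main",
        session = SESSIONS[t],
        true_contrast = unname(truth$main_amplitudes[t]) * sdv,
        n_voxels = length(truth$main_region))
      r <- r + 1L
      rows[[r]] <- data.frame(modality = mod, region = "sex",
        session = SESSIONS[t],
        true_contrast = 2 * unname(truth$sex_amplitudes[t]) * sdv,
        n_voxels = length(truth$sex_region))
    }
  }
  do.call(rbind, rows)
}

#' Write a simulated cohort in the on-disk layout `read_cohort()` expects
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return list with `manifest_path`, `mask_path`, `volume_dir`.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(file.path(dir, "vols"), recursive = TRUE, showWarnings = FALSE)
  geom <- sim$geometry
  write_mask(geom, file.path(dir, "mask.nii.gz"))
  info <- sim$maps$info
  paths <- sprintf("vols/%s_%s_%s.nii.gz", info$subject_id, info$session,
                   info$modality)
  for (i in seq_len(nrow(info)))
    write_stat_map(sim$maps$values[i, ], geom, file.path(dir, paths[i]))
  man <- merge(info, sim$subjects, by = "subject_id", sort = FALSE)
  man$volume_path <- paths
  man <- man[, MANIFEST_COLS]
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(sim$symptoms, file.path(dir, "symptoms.csv"), row.names = FALSE)
  list(manifest_path = file.path(dir, "manifest.csv"),
       mask_path = file.path(dir, "mask.nii.gz"),
       volume_dir = dir)
}
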