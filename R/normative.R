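# Normative difference scoring: each concussed athlete's maps are referenced
# to the robust voxelwise mean of a demographically matched control subgroup
# (same sex, same history of concussion, age within a fixed gap), yielding
# difference maps delta = x - m that isolate deviation from a comparable
# uninjured cohort. The same matched subgroup is reused for all of that
# athlete's imaging sessions so the longitudinal baseline is consistent.

#' Control matching criteria
#'
#' @param max_age_gap maximum absolute age difference in years (inclusive;
#'   default 2).
#' @return list of class `match_criteria`.
#' @export
match_criteria <- function(max_age_gap = 2) {
  stopifnot(max_age_gap >= 0)
  structure(list(max_age_gap = max_age_gap), class = "match_criteria")
}

#' Match normative controls to a concussed athlete
#'
#' Returns every control with the same sex, the same history-of-concussion
#' status, and an age within `max_age_gap` years (inclusive) of the athlete.
#'
#' @param athlete one-row data.frame (or list) with `sex`, `hoc`, `age`,
#'   `subject_id`.
#' @param controls data.frame of control subjects.
#' @param criteria a [match_criteria()].
#' @return character vector of matched control `subject_id`s (possibly empty,
#'   with a warning).
#' @export
match_controls <- function(athlete, controls, criteria = match_criteria()) {
  if (nrow(controls) == 0L) stop("no controls supplied")
  ok <- controls$sex == athlete$sex &
    controls$hoc == athlete$hoc &
    abs(controls$age - athlete$age) <= criteria$max_age_gap
  ids <- controls$subject_id[ok]
  if (length(ids) == 0L)
    warning("no controls matched athlete ", athlete$subject_id)
  ids
}

#' Huber location M-estimator
#'
#' Robust mean minimizing `sum(rho_k((x - mu) / s))` where `rho_k` is the
#' Huber loss with tuning constant `k` and `s = 1.4826 * MAD` (consistent at
#' the normal). Solved by iteratively reweighted least squares from the
#' median; the objective is convex so the iteration converges. If the MAD is
#' zero (more than half the values tied) the median is returned.
#'
#' @param x numeric vector with at least one finite value.
#' @param k Huber tuning constant (default 1.35, ~95% normal efficiency).
#' @param tol convergence tolerance on the location update.
#' @param max_iter iteration cap.
#' @return the location estimate (scalar).
#' @export
huber_location <- function(x, k = 1.35, tol = 1e-8, max_iter = 100L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("huber_location: no finite values")
  drop(huber_location_cols(matrix(x, ncol = 1L), k = k, tol = tol,
                           max_iter = max_iter))
}

#' Columnwise Huber location for matrices
#'
#' Vectorized IRLS over the columns of `X` (observations in rows), used to
#' compute robust voxelwise control means efficiently.
#'
#' @param X numeric matrix (observations x variables).
#' @inheritParams huber_location
#' @return numeric vector of length `ncol(X)`.
#' @export
huber_location_cols <- function(X, k = 1.35, tol = 1e-8, max_iter = 100L) {
  stopifnot(is.matrix(X), nrow(X) >= 1L)
  mu <- apply(X, 2L, median)
  s <- 1.4826 * apply(abs(sweep(X, 2L, mu, `-`)), 2L, median)
  live <- s > 0                       # zero-MAD columns keep the median
  if (!any(live)) return(mu)
  for (it in seq_len(max_iter)) {
    r <- sweep(X[, live, drop = FALSE], 2L, mu[live], `-`)
    u <- sweep(r, 2L, s[live], `/`)
    w <- pmin(k / pmax(abs(u), .Machine$double.eps), 1)
    mu_new <- colSums(w * X[, live, drop = FALSE]) / colSums(w)
    delta <- abs(mu_new - mu[live])
    mu[live] <- mu_new
    if (max(delta / pmax(s[live], 1)) < tol) break
  }
  mu
}

#' Difference maps against matched-control robust means
#'
#' For each concussed athlete: match a control subgroup once
#' ([match_controls()]), compute the voxelwise Huber robust mean `m` over the
#' matched controls' maps, and form `delta = x - m` for every available
#' session. The same `m` is reused across ACU/RTP/YR1.
#'
#' @param subjects full subject table (controls + concussed).
#' @param maps a `map_set` for a single modality (controls: session
#'   `CONTROL`; concussed: ACU/RTP/YR1).
#' @param criteria a [match_criteria()].
#' @param k Huber tuning constant.
#' @param min_controls minimum matched subgroup size (default 3).
#' @return object of class `delta_set`: `delta` (athlete x session x voxel
#'   array, `NA` across missing sessions), `available` (athlete x session
#'   logical), `athletes` (data.frame), `matched` (list of control id
#'   vectors), `m` (athlete x voxel robust-mean matrix), `geometry`,
#'   `modality`, and `match_report` (athlete, subgroup size).
#' @export
difference_maps <- function(subjects, maps, criteria = match_criteria(),
                            k = 1.35, min_controls = 3L) {
  modality <- unique(maps$info$modality)
  if (length(modality) != 1L)
    stop("difference_maps expects a single-modality map_set")
  controls <- subjects[subjects$group == "control", , drop = FALSE]
  athletes <- subjects[subjects$group == "concussed", , drop = FALSE]
  if (nrow(athletes) == 0L) stop("no concussed athletes in cohort")
  with_map <- athletes$subject_id %in%
    maps$info$subject_id[maps$info$session %in% SESSIONS]
  if (!all(with_map)) {
    warning(sum(!with_map), " athlete(s) with no imaging session dropped: ",
            paste(athletes$subject_id[!with_map], collapse = ", "))
    athletes <- athletes[with_map, , drop = FALSE]
  }
  V <- maps$geometry$n_vox
  n <- nrow(athletes)

  ctrl_rows <- which(maps$info$session == "CONTROL")
  ctrl_ids <- maps$info$subject_id[ctrl_rows]

  delta <- array(NA_real_, dim = c(n, 3L, V),
                 dimnames = list(athletes$subject_id, SESSIONS, NULL))
  available <- matrix(FALSE, n, 3L,
                      dimnames = list(athletes$subject_id, SESSIONS))
  m <- matrix(NA_real_, n, V)
  matched <- vector("list", n)
  names(matched) <- athletes$subject_id

  # athletes sharing an identical matched subgroup share the robust mean
  m_cache <- new.env(parent = emptyenv())
  for (a in seq_len(n)) {
    ath <- athletes[a, ]
    ids <- match_controls(ath, controls, criteria)
    if (length(ids) < min_controls)
      stop(sprintf("athlete %s matched only %d controls (< %d)",
                   ath$subject_id, length(ids), min_controls))
    matched[[a]] <- ids
    key <- paste(sort(ids), collapse = ",")
    if (is.null(m_cache[[key]])) {
      rows <- ctrl_rows[ctrl_ids %in% ids]
      m_cache[[key]] <- huber_location_cols(
        maps$values[rows, , drop = FALSE], k = k)
    }
    m[a, ] <- m_cache[[key]]
    for (t in 1:3) {
      row <- which(maps$info$subject_id == ath$subject_id &
                     maps$info$session == SESSIONS[t])
      if (length(row) == 1L) {
        delta[a, t, ] <- maps$values[row, ] - m[a, ]
        available[a, t] <- TRUE
      }
    }
  }
  structure(list(delta = delta, available = available, athletes = athletes,
                 matched = matched, m = m, geometry = maps$geometry,
                 modality = modality,
                 match_report = data.frame(subject_id = athletes$subject_id,
                   n_matched = lengths(matched))),
            class = "delta_set")
}

#' @export
print.delta_set <- function(x, ...) {
  cat(sprintf("delta_set (%s): %d athletes x 3 sessions x %d voxels; matched controls median %.0f\n",
              x$modality, nrow(x$athletes), dim(x$delta)[3],
              median(x$match_report$n_matched)))
  invisible(x)
}
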