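# Shared fixtures: tiny geometries and cohorts built in code.

tiny_geometry <- function(dims = c(6, 6, 6), voxel_size = 3) {
  mask_geometry(array(TRUE, dim = dims), voxel_size = voxel_size)
}

# small cohort sized so every athlete finds >= 3 matched controls
small_cohort_config <- function(dims = c(12, 14, 12), n_control = 120,
                                n_concussed = 16, seed = 11,
                                dropout_probs = c(ACU = 0, RTP = 0, YR1 = 0),
                                ...) {
  sim_config(n_control = n_control, n_concussed = n_concussed,
             geometry = default_mask(dims, 3),
             modalities = "CBF",
             main_effect = list(n_voxels = 0, amplitudes = c(ACU = 0, RTP = 0, YR1 = 0)),
             sex_effect = list(n_voxels = 0, amplitudes = c(ACU = 0, RTP = 0, YR1 = 0)),
             dropout_probs = dropout_probs,
             seed = seed, ...)
}

# delta_set built directly from an array (bypasses map plumbing) for unit
# tests of PLS / bootstrap internals
make_delta_set <- function(delta, available = NULL, sex = NULL,
                           geometry = NULL) {
  n <- dim(delta)[1]
  if (is.null(available)) available <- matrix(TRUE, n, 3)
  if (is.null(sex)) sex <- rep(c(0, 1), length.out = n)
  if (is.null(geometry)) {
    V <- dim(delta)[3]
    d1 <- ceiling(V^(1 / 3))
    g <- array(FALSE, dim = c(d1, d1, ceiling(V / d1^2)))
    g[seq_len(V)] <- TRUE
    geometry <- mask_geometry(g, 3)
  }
  dimnames(delta) <- list(sprintf("P%03d", seq_len(n)), c("ACU", "RTP", "YR1"),
                          NULL)
  dimnames(available) <- dimnames(delta)[1:2]
  structure(list(delta = delta, available = available,
                 athletes = data.frame(subject_id = sprintf("P%03d", seq_len(n)),
                                       group = "concussed", sex = sex,
                                       age = 20, hoc = 0),
                 matched = NULL, m = NULL, geometry = geometry,
                 modality = "CBF",
                 match_report = data.frame(subject_id = sprintf("P%03d", seq_len(n)),
                                           n_matched = NA)),
            class = "delta_set")
}
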