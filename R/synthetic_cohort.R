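#' Specify a synthetic resting-state cohort
#'
#' Defines the generative model for a cohort of parcellated ROI time series:
#' each subject's brain switches between a segregated state S (block-modular
#' covariance, weak cross-module coupling) and an integrated state I (denser
#' cross-module coupling) under a first-order Markov chain whose transition
#' probabilities depend on sex, so that state occupancy differs between the
#' sexes. Frames are zero-mean unit-variance multivariate Gaussian draws from
#' the covariance of the current state.
#'
#' Defaults mirror a large public test-retest cohort: TR 0.720 s, a
#' near-balanced sex split, and per-sex switch probabilities chosen so the
#' stationary occupancy of state S is about 35% in males and 48% in females
#' with mean S-dwell times of roughly 40 s and 52 s respectively.
#'
#' @param n_subjects number of subjects.
#' @param sex_labels integer vector of per-subject codes (1 = male,
#'   2 = female); default alternates for a near-balanced split.
#' @param n_rois number of ROIs (columns of each time series).
#' @param n_modules number of equally sized modules; must divide `n_rois`.
#' @param n_frames frames per subject.
#' @param tr_seconds repetition time in seconds.
#' @param within_r within-module correlation, in (0, 1); shared by both states.
#' @param between_r_segregated cross-module correlation in state S, in
#'   `[0, within_r)`.
#' @param between_r_integrated cross-module correlation in state I, in
#'   `(between_r_segregated, within_r]`.
#' @param switch_prob_by_sex list with elements `male` and `female`, each a
#'   numeric pair `c(p_si, p_is)`: the per-frame probabilities of switching
#'   S -> I and I -> S.
#' @param seed integer seed; expanded deterministically into independent
#'   per-subject streams.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 80,
                        sex_labels = rep_len(c(1L, 2L), n_subjects),
                        n_rois = 20,
                        n_modules = 4,
                        n_frames = 1200,
                        tr_seconds = 0.720,
                        within_r = 0.6,
                        between_r_segregated = 0.10,
                        between_r_integrated = 0.45,
                        switch_prob_by_sex = list(
                          male   = c(p_si = 0.0180, p_is = 0.0097),
                          female = c(p_si = 0.0139, p_is = 0.0128)
                        ),
                        seed = 1L) {
  stopifnot(
    n_subjects >= 1, length(sex_labels) == n_subjects,
    all(sex_labels %in% c(1L, 2L)),
    n_rois >= 2, n_modules >= 1, n_rois %% n_modules == 0,
    n_frames >= 2, tr_seconds > 0,
    within_r > 0, within_r < 1,
    between_r_segregated >= 0, between_r_segregated < within_r,
    between_r_integrated > between_r_segregated,
    between_r_integrated <= within_r
  )
  for (sx in c("male", "female")) {
    p <- switch_prob_by_sex[[sx]]
    stopifnot(length(p) == 2, all(p >= 0), all(p < 1))
  }
  spec <- list(
    n_subjects = as.integer(n_subjects),
    sex_labels = as.integer(sex_labels),
    n_rois = as.integer(n_rois),
    n_modules = as.integer(n_modules),
    n_frames = as.integer(n_frames),
    tr_seconds = tr_seconds,
    within_r = within_r,
    between_r_segregated = between_r_segregated,
    between_r_integrated = between_r_integrated,
    switch_prob_by_sex = switch_prob_by_sex,
    seed = as.integer(seed)
  )
  ## both implied covariances must be valid correlation matrices
  make_state_covariances(n_rois, n_modules, within_r, between_r_segregated)
  make_state_covariances(n_rois, n_modules, within_r, between_r_integrated)
  structure(spec, class = "cohort_spec")
}

#' Specify the behavioral mediation model
#'
#' Behavioral outcomes are generated from a single-mediator linear model:
#' `M = a * sex + e_m` (when a fresh mediator is drawn) and
#' `Y = c' * sex + b * M + e_y`, so the total sex effect is `c' + a * b`
#' in expectation.
#'
#' @param a_effect path a, sex -> mediator.
#' @param b_effect path b, mediator -> outcome.
#' @param c_prime direct path c', sex -> outcome.
#' @param noise_sd_m,noise_sd_y residual standard deviations.
#' @param seed integer seed.
#' @return an object of class `mediation_spec`.
#' @export
mediation_spec <- function(a_effect = 0.4, b_effect = 0.3, c_prime = 0.2,
                           noise_sd_m = 1, noise_sd_y = 1, seed = 1L) {
  stopifnot(noise_sd_m > 0, noise_sd_y > 0)
  structure(
    list(a_effect = a_effect, b_effect = b_effect, c_prime = c_prime,
         noise_sd_m = noise_sd_m, noise_sd_y = noise_sd_y,
         seed = as.integer(seed)),
    class = "mediation_spec"
  )
}

#' Block-modular state covariance matrix
#'
#' Builds the correlation matrix of one brain state: 1 on the diagonal,
#' `within_r` inside each of `n_modules` equal contiguous ROI blocks and
#' `between_r` across blocks. The matrix must be positive semi-definite;
#' for this block-constant structure the binding constraint is
#' `1 + (s - 1) * within_r + s * (n_modules - 1) * between_r >= 0` together
#' with `between_r <= within_r < 1` (s = module size).
#'
#' @param n_rois number of ROIs.
#' @param n_modules number of equal modules dividing `n_rois`.
#' @param within_r within-module correlation.
#' @param between_r cross-module correlation.
#' @return `n_rois x n_rois` covariance (correlation) matrix.
#' @export
make_state_covariances <- function(n_rois, n_modules, within_r, between_r) {
  stopifnot(n_rois >= 1, n_modules >= 1, n_rois %% n_modules == 0,
            within_r >= 0, within_r < 1)
  modules <- rep(seq_len(n_modules), each = n_rois / n_modules)
  same <- outer(modules, modules, "==")
  sigma <- ifelse(same, within_r, between_r)
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop(sprintf(
      paste0("covariance is not positive semi-definite ",
             "(smallest eigenvalue %.3g); require between_r <= within_r ",
             "and 1 + (s-1)*within_r + s*(m-1)*between_r >= 0 ",
             "with s = %d ROIs/module, m = %d modules"),
      min(ev), n_rois %/% n_modules, n_modules))
  }
  sigma
}

#' Simulate a two-state Markov chain of frame labels
#'
#' First-order chain over states `"S"` and `"I"` with per-frame switch
#' probabilities `p_si` (S -> I) and `p_is` (I -> S). The initial state is
#' drawn from the stationary distribution `pi_S = p_is / (p_si + p_is)`
#' (0.5 when both probabilities are zero, a degenerate case permitted for
#' testing).
#'
#' @param p_si,p_is switch probabilities in `[0, 1)`.
#' @param n_frames chain length.
#' @param seed optional integer seed.
#' @return character vector of `"S"`/`"I"` labels, length `n_frames`.
#' @export
simulate_state_sequence <- function(p_si, p_is, n_frames, seed = NULL) {
  stopifnot(p_si >= 0, p_si < 1, p_is >= 0, p_is < 1, n_frames >= 1)
  with_seed(seed, {
    pi_s <- if (p_si + p_is == 0) 0.5 else p_is / (p_si + p_is)
    u <- stats::runif(n_frames)
    states <- character(n_frames)
    states[1] <- if (u[1] < pi_s) "S" else "I"
    if (n_frames > 1) {
      for (t in 2:n_frames) {
        p_switch <- if (states[t - 1] == "S") p_si else p_is
        states[t] <- if (u[t] < p_switch) {
          if (states[t - 1] == "S") "I" else "S"
        } else {
          states[t - 1]
        }
      }
    }
    states
  })
}

#' Simulate one subject's ROI time series
#'
#' Draws the subject's true state sequence with that subject's sex-specific
#' switch probabilities, then draws each frame from a zero-mean multivariate
#' Gaussian with the covariance of the frame's true state. Output is
#' deterministic given `(spec$seed, subject_index)`.
#'
#' @param spec a [cohort_spec()].
#' @param subject_index subject number in `1:n_subjects`.
#' @return list with elements `ts` (a `roi_ts` object, see [roi_ts()]) and
#'   `true_states` (character frame labels).
#' @export
simulate_subject <- function(spec, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"),
            subject_index >= 1, subject_index <= spec$n_subjects)
  sex <- spec$sex_labels[subject_index]
  probs <- spec$switch_prob_by_sex[[if (sex == 1L) "male" else "female"]]
  seed_i <- subject_seed(spec$seed, subject_index)

  sigma_s <- make_state_covariances(spec$n_rois, spec$n_modules,
                                    spec$within_r, spec$between_r_segregated)
  sigma_i <- make_state_covariances(spec$n_rois, spec$n_modules,
                                    spec$within_r, spec$between_r_integrated)
  chol_s <- chol(sigma_s + diag(1e-10, spec$n_rois))
  chol_i <- chol(sigma_i + diag(1e-10, spec$n_rois))

  with_seed(seed_i, {
    states <- simulate_state_sequence(probs[[1]], probs[[2]], spec$n_frames)
    z <- matrix(stats::rnorm(spec$n_frames * spec$n_rois),
                spec$n_frames, spec$n_rois)
    x <- matrix(0, spec$n_frames, spec$n_rois)
    is_s <- states == "S"
    if (any(is_s))  x[is_s, ]  <- z[is_s, , drop = FALSE] %*% chol_s
    if (any(!is_s)) x[!is_s, ] <- z[!is_s, , drop = FALSE] %*% chol_i
    ts <- roi_ts(
      data = x,
      tr_seconds = spec$tr_seconds,
      subject_id = sprintf("sub-%03d", subject_index),
      roi_names = sprintf("ROI%02d", seq_len(spec$n_rois))
    )
    list(ts = ts, true_states = states)
  })
}

#' Simulate behavioral variables with planted mediation structure
#'
#' Generates `Y = c' * sex + b * M + e_y`; when `mediator_values` is `NULL` a
#' fresh mediator `M = a * sex + e_m` is drawn, otherwise the supplied
#' mediator (for example a subject's true integrated-state occupancy) is used
#' unchanged.
#'
#' @param mspec a [mediation_spec()].
#' @param sex_labels integer codes (1 = male, 2 = female).
#' @param mediator_values optional per-subject mediator.
#' @param seed optional seed overriding `mspec$seed`.
#' @return data.frame with columns `sex`, `mediator`, `outcome`.
#' @export
simulate_behavior <- function(mspec, sex_labels, mediator_values = NULL,
                              seed = NULL) {
  stopifnot(inherits(mspec, "mediation_spec"), all(sex_labels %in% 1:2))
  n <- length(sex_labels)
  with_seed(if (is.null(seed)) mspec$seed else seed, {
    m <- if (is.null(mediator_values)) {
      mspec$a_effect * sex_labels + stats::rnorm(n, sd = mspec$noise_sd_m)
    } else {
      stopifnot(length(mediator_values) == n)
      mediator_values
    }
    y <- mspec$c_prime * sex_labels + mspec$b_effect * m +
      stats::rnorm(n, sd = mspec$noise_sd_y)
    data.frame(sex = as.integer(sex_labels), mediator = m, outcome = y)
  })
}

#' Simulate a framewise-displacement series
#'
#' Baseline head motion is drawn from a gamma distribution calibrated to a
#' median FD near 0.14 mm (essentially never reaching 0.5 mm); a controlled
#' fraction of frames is then replaced by motion spikes in `[0.5, 1.5)` mm so
#' the participant-level QC rule can be exercised exactly. The spike count is
#' `round(outlier_frac * n_frames)`.
#'
#' @param n_frames series length.
#' @param outlier_frac fraction of frames at or above 0.5 mm, in `[0, 1]`.
#' @param seed optional integer seed.
#' @return nonnegative numeric vector of length `n_frames`.
#' @export
simulate_fd_series <- function(n_frames, outlier_frac = 0, seed = NULL) {
  stopifnot(n_frames >= 1, outlier_frac >= 0, outlier_frac <= 1)
  with_seed(seed, {
    fd <- stats::rgamma(n_frames, shape = 4, rate = 28)
    fd <- pmin(fd, 0.49)  # baseline never trips the threshold
    n_out <- round(outlier_frac * n_frames)
    if (n_out > 0) {
      idx <- sample.int(n_frames, n_out)
      fd[idx] <- stats::runif(n_out, 0.5, 1.5)
    }
    fd
  })
}

#' Simulate a full cohort
#'
#' Runs [simulate_subject()] for every subject, attaches an FD series per
#' subject (QC failures planted via `fd_fail_subjects`), and generates the
#' behavioral table with the subject's true integrated-state occupancy
#' (percent of frames in state I) as the mediator.
#'
#' @param spec a [cohort_spec()].
#' @param mspec a [mediation_spec()]; `NULL` skips the behavioral table.
#' @param fd_fail_subjects integer indices of subjects given > 7.5% motion
#'   spikes so they fail QC.
#' @return list of class `synthetic_cohort` with elements `subjects` (list of
#'   per-subject `ts`, `true_states`, `fd`), `manifest` (data.frame),
#'   `behavior` (data.frame or NULL), and `spec`.
#' @export
simulate_cohort <- function(spec, mspec = NULL, fd_fail_subjects = integer()) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- vector("list", spec$n_subjects)
  true_prev_i <- numeric(spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    sub <- simulate_subject(spec, i)
    frac <- if (i %in% fd_fail_subjects) 0.10 else 0
    sub$fd <- simulate_fd_series(spec$n_frames, frac,
                                 seed = subject_seed(spec$seed + 7L, i))
    subjects[[i]] <- sub
    true_prev_i[i] <- 100 * mean(sub$true_states == "I")
  }
  manifest <- data.frame(
    subject_id = vapply(subjects, function(s) s$ts$subject_id, character(1)),
    sex = spec$sex_labels,
    tr_seconds = spec$tr_seconds,
    n_frames = spec$n_frames
  )
  behavior <- NULL
  if (!is.null(mspec)) {
    behavior <- simulate_behavior(mspec, spec$sex_labels, true_prev_i)
    behavior <- cbind(subject_id = manifest$subject_id, behavior)
  }
  structure(
    list(subjects = subjects, manifest = manifest, behavior = behavior,
         true_prev_i = true_prev_i, spec = spec),
    class = "synthetic_cohort"
  )
}

#' Write a synthetic cohort to delimited-text files
#'
#' Layout: `manifest.tsv`; `timeseries/<subject_id>.tsv` (frames x ROIs, ROI
#' name header); `fd/<subject_id>.tsv` (one column `fd_mm`); `behavior.tsv`.
#' Downstream stages consume these files unchanged, and real exported data in
#' the same dialect is accepted.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "fd"), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (sub in cohort$subjects) {
    ts_df <- as.data.frame(sub$ts$data)
    names(ts_df) <- sub$ts$roi_names
    utils::write.table(ts_df,
                       file.path(dir, "timeseries", paste0(sub$ts$subject_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(fd_mm = sub$fd),
                       file.path(dir, "fd", paste0(sub$ts$subject_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cohort$behavior)) {
    utils::write.table(cohort$behavior, file.path(dir, "behavior.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list with `manifest`, `subjects` (list of `ts`, `fd`), and
#'   `behavior` (NULL when absent).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"))
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$subject_id[i]
    x <- as.matrix(utils::read.delim(file.path(dir, "timeseries", paste0(id, ".tsv"))))
    fd_path <- file.path(dir, "fd", paste0(id, ".tsv"))
    fd <- if (file.exists(fd_path)) utils::read.delim(fd_path)$fd_mm else NULL
    list(ts = roi_ts(x, manifest$tr_seconds[i], id, colnames(x)), fd = fd)
  })
  beh_path <- file.path(dir, "behavior.tsv")
  behavior <- if (file.exists(beh_path)) utils::read.delim(beh_path) else NULL
  list(manifest = manifest, subjects = subjects, behavior = behavior)
}
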