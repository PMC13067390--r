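#' Pool windowed connectivity across subjects
#'
#' Stacks the upper-triangle vectorizations of every subject's window
#' matrices into one pool for group-level clustering (one state model over
#' all subjects' windows, so the two centroids are shared by the cohort).
#'
#' @param windowed list of `windowed_fc` objects (one per subject).
#' @return object of class `state_pool`: `vectors` (rows = windows),
#'   `subject_id` and `window_index` per row, `n_rois`.
#' @export
build_state_pool <- function(windowed) {
  stopifnot(length(windowed) >= 1,
            all(vapply(windowed, inherits, logical(1), "windowed_fc")))
  vecs <- do.call(rbind, lapply(windowed, `[[`, "vectors"))
  ids <- unlist(lapply(windowed, function(w) {
    rep(w$subject_id, nrow(w$vectors))
  }))
  win <- unlist(lapply(windowed, function(w) seq_len(nrow(w$vectors))))
  structure(
    list(vectors = vecs, subject_id = ids, window_index = win,
         n_rois = windowed[[1]]$n_rois),
    class = "state_pool"
  )
}

## k-means++ style seeding on unit vectors under cosine distance.
kmeanspp_init <- function(Xn, k) {
  n <- nrow(Xn)
  centers <- matrix(0, k, ncol(Xn))
  idx <- sample.int(n, 1)
  centers[1, ] <- Xn[idx, ]
  if (k > 1) {
    for (j in 2:k) {
      sim <- Xn %*% t(centers[seq_len(j - 1), , drop = FALSE])
      d <- 1 - apply(sim, 1, max)
      d <- pmax(d, 0)
      prob <- if (sum(d) > 0) d / sum(d) else rep(1 / n, n)
      centers[j, ] <- Xn[sample.int(n, 1, prob = prob), ]
    }
  }
  centers
}

## One spherical k-means run on row-normalized X; returns assignments,
## normalized centroids and inertia (sum of cosine distances).
skmeans_once <- function(Xn, k, max_iter, tol) {
  centers <- kmeanspp_init(Xn, k)
  assign_old <- rep(0L, nrow(Xn))
  inertia <- Inf
  for (iter in seq_len(max_iter)) {
    sim <- Xn %*% t(centers)
    assign_new <- max.col(sim, ties.method = "first")
    for (j in seq_len(k)) {        # refill empty cluster with worst-fit point
      if (!any(assign_new == j)) {
        worst <- which.min(sim[cbind(seq_len(nrow(Xn)), assign_new)])
        assign_new[worst] <- j
      }
    }
    for (j in seq_len(k)) {
      mu <- colMeans(Xn[assign_new == j, , drop = FALSE])
      nrm <- sqrt(sum(mu^2))
      centers[j, ] <- if (nrm > 0) mu / nrm else centers[j, ]
    }
    sim <- Xn %*% t(centers)
    inertia_new <- sum(1 - sim[cbind(seq_len(nrow(Xn)), assign_new)])
    converged <- all(assign_new == assign_old) ||
      abs(inertia - inertia_new) < tol
    assign_old <- assign_new
    inertia <- inertia_new
    if (converged) break
  }
  list(assignment = assign_old, centers = centers, inertia = inertia)
}

#' Fit the two-state model by cosine k-means
#'
#' k-means (k = 2) with distance `1 - cosine similarity`, i.e. spherical
#' k-means on L2-normalized window vectors with mean-then-renormalize
#' centroid updates and k-means++ style seeding; the best (lowest cosine
#' inertia) of `n_init` seeded initializations is kept. Centroids are
#' returned un-normalized as the mean of the raw vectors assigned to each
#' state, for interpretability, and labeled I/S by [label_states()].
#'
#' @param pool a [build_state_pool()] result.
#' @param n_init number of restarts (default 100).
#' @param max_iter maximum iterations per run (default 300).
#' @param tol inertia convergence tolerance (default 1e-6).
#' @param seed integer seed.
#' @param label call [label_states()] on the fitted model (default TRUE).
#' @return object of class `state_model`: `centroids` (2 x edges raw means),
#'   `state_of_centroid` (`"I"`/`"S"` per row after labeling), `assignment`
#'   (pool row -> centroid row), `inertia`, `label_metrics` (E and Q per
#'   centroid), `n_rois`.
#' @export
fit_states <- function(pool, n_init = 100, max_iter = 300, tol = 1e-6,
                       seed = 1L, label = TRUE) {
  stopifnot(inherits(pool, "state_pool"))
  X <- pool$vectors
  if (nrow(unique(X)) < 2) stop("degenerate pool: fewer than 2 distinct vectors")
  Xn <- X / pmax(sqrt(rowSums(X^2)), .Machine$double.eps)
  best <- NULL
  for (r in seq_len(n_init)) {
    run <- with_seed(seed + r, skmeans_once(Xn, 2L, max_iter, tol))
    if (is.null(best) || run$inertia < best$inertia - 1e-12) best <- run
  }
  centroids <- rbind(
    colMeans(X[best$assignment == 1L, , drop = FALSE]),
    colMeans(X[best$assignment == 2L, , drop = FALSE])
  )
  model <- structure(
    list(centroids = centroids, assignment = best$assignment,
         inertia = best$inertia, n_rois = pool$n_rois,
         state_of_centroid = NULL, label_metrics = NULL),
    class = "state_model"
  )
  if (label) model <- label_states(model)
  model
}

#' Label the fitted centroids as integrated (I) or segregated (S)
#'
#' Each centroid vector is reshaped to matrix form and its global efficiency
#' and modularity computed (after [to_graph()] preparation). The centroid
#' with the higher global efficiency is labeled I; by the two-state premise
#' it should also have the lower modularity, and a warning is emitted if the
#' two orderings disagree (efficiency decides).
#'
#' @param model an unlabeled `state_model`.
#' @return the model with `state_of_centroid` and `label_metrics` filled in.
#' @export
label_states <- function(model) {
  stopifnot(inherits(model, "state_model"))
  mats <- lapply(1:2, function(j) fc_unvectorize(model$centroids[j, ], model$n_rois))
  eff <- vapply(mats, function(m) global_efficiency(to_graph(m)), numeric(1))
  qs <- vapply(mats, function(m) modularity(to_graph(m), seed = 1L)$q, numeric(1))
  if (abs(eff[1] - eff[2]) < 1e-12) {
    stop("centroids have equal global efficiency; states are unlabelable")
  }
  i_row <- which.max(eff)
  if (qs[i_row] >= qs[3 - i_row]) {
    warning("integrated-labeled centroid does not have lower modularity; ",
            "labels follow global efficiency")
  }
  model$state_of_centroid <- ifelse(seq_len(2) == i_row, "I", "S")
  model$label_metrics <- data.frame(
    state = model$state_of_centroid,
    global_efficiency = eff, modularity = qs
  )
  model
}

#' Assign a subject's windows to the nearest state
#'
#' Each window vector is assigned to the cosine-nearest centroid; exact ties
#' are broken toward state S.
#'
#' @param model a labeled `state_model`.
#' @param windowed the subject's `windowed_fc` (or a windows x edges matrix).
#' @param tr_seconds TR override when `windowed` is a bare matrix.
#' @param subject_id id override when `windowed` is a bare matrix.
#' @return object of class `state_sequence`: `labels` (`"I"`/`"S"` per
#'   window), `step_seconds`, `subject_id`.
#' @export
assign_windows <- function(model, windowed, tr_seconds = NULL,
                           subject_id = NULL) {
  stopifnot(inherits(model, "state_model"),
            !is.null(model$state_of_centroid))
  if (inherits(windowed, "windowed_fc")) {
    V <- windowed$vectors
    tr_seconds <- windowed$tr_seconds
    subject_id <- windowed$subject_id
  } else {
    V <- as.matrix(windowed)
  }
  sim <- cosine_similarity(V, model$centroids)
  labels <- character(nrow(V))
  s_col <- which(model$state_of_centroid == "S")
  for (i in seq_len(nrow(V))) {
    if (abs(sim[i, 1] - sim[i, 2]) < 1e-15) {
      labels[i] <- "S"
    } else {
      labels[i] <- model$state_of_centroid[which.max(sim[i, ])]
    }
  }
  structure(
    list(labels = labels, step_seconds = tr_seconds, subject_id = subject_id),
    class = "state_sequence"
  )
}

seq_labels <- function(seq) {
  if (inherits(seq, "state_sequence")) seq$labels else as.character(seq)
}

seq_step <- function(seq, step_seconds) {
  if (!is.null(step_seconds)) return(step_seconds)
  if (inherits(seq, "state_sequence") && !is.null(seq$step_seconds)) {
    return(seq$step_seconds)
  }
  1
}

#' State prevalence
#'
#' Percent of a subject's windows assigned to each state;
#' `prev_s + prev_i = 100` exactly.
#'
#' @param seq a `state_sequence` or character label vector.
#' @return named numeric `c(prev_s, prev_i)`.
#' @export
prevalence <- function(seq) {
  labels <- seq_labels(seq)
  stopifnot(length(labels) >= 1, all(labels %in% c("S", "I")))
  prev_s <- 100 * sum(labels == "S") / length(labels)
  c(prev_s = prev_s, prev_i = 100 - prev_s)
}

#' Mean dwell time
#'
#' The sequence is decomposed into maximal constant runs; the mean dwell
#' time of a state is the mean length of that state's runs times the window
#' step in seconds. Boundary (censored) runs at the start and end of the
#' scan are included. `NA` when the state is never visited (such subjects
#' are excluded from that parameter's group statistics).
#'
#' @param seq a `state_sequence` or character label vector.
#' @param state `"S"` or `"I"`.
#' @param step_seconds step override for bare label vectors (default 1 s).
#' @return mean dwell time in seconds, or `NA`.
#' @export
mean_dwell_time <- function(seq, state, step_seconds = NULL) {
  labels <- seq_labels(seq)
  step <- seq_step(seq, step_seconds)
  stopifnot(state %in% c("S", "I"))
  r <- rle(labels)
  lens <- r$lengths[r$values == state]
  if (length(lens) == 0) return(NA_real_)
  mean(lens) * step
}

#' Inter-transition interval
#'
#' Transition times are the window indices at which the label changes; the
#' ITI is the mean spacing between consecutive transitions, in seconds.
#' `NA` with fewer than two transitions (such subjects are excluded from the
#' ITI group statistics). For interior runs the ITI equals the mean run
#' duration, so it approximates the mean of the two dwell times.
#'
#' @param seq a `state_sequence` or character label vector.
#' @param step_seconds step override for bare label vectors (default 1 s).
#' @return ITI in seconds, or `NA`.
#' @export
inter_transition_interval <- function(seq, step_seconds = NULL) {
  labels <- seq_labels(seq)
  step <- seq_step(seq, step_seconds)
  trans <- which(labels[-1] != labels[-length(labels)]) + 1
  if (length(trans) < 2) return(NA_real_)
  mean(diff(trans)) * step
}

#' State variability
#'
#' Dispersion of the subject's within-state window cloud: 100 times the mean
#' cosine distance of the state-assigned window vectors from the subject's
#' own mean vector for that state. A single window in a state gives 0; `NA`
#' when the state is unvisited.
#'
#' @param seq a `state_sequence` or character label vector.
#' @param windows the subject's `windowed_fc` or windows x edges matrix
#'   (rows aligned with `seq`).
#' @param state `"S"` or `"I"`.
#' @return dispersion score (0-200 scale, typically well under 100), or `NA`.
#' @export
state_variability <- function(seq, windows, state) {
  labels <- seq_labels(seq)
  V <- if (inherits(windows, "windowed_fc")) windows$vectors else as.matrix(windows)
  stopifnot(nrow(V) == length(labels), state %in% c("S", "I"))
  rows <- which(labels == state)
  if (length(rows) == 0) return(NA_real_)
  if (length(rows) == 1) return(0)
  sub <- V[rows, , drop = FALSE]
  mu <- colMeans(sub)
  sim <- cosine_similarity(sub, matrix(mu, 1))
  100 * mean(1 - sim)
}

#' Per-subject dynamics summary
#'
#' Computes all dynamic parameters for one subject: prevalence (percent),
#' mean dwell times and inter-transition interval (seconds), and state
#' variability for both states.
#'
#' @param seq the subject's `state_sequence`.
#' @param windows the subject's `windowed_fc` (needed for Var).
#' @return one-row data.frame with columns `subject_id`, `prev_s`, `prev_i`,
#'   `mdt_s`, `mdt_i`, `iti`, `var_s`, `var_i`.
#' @export
dynamics_summary <- function(seq, windows) {
  prev <- prevalence(seq)
  data.frame(
    subject_id = if (!is.null(seq$subject_id)) seq$subject_id else NA_character_,
    prev_s = unname(prev["prev_s"]),
    prev_i = unname(prev["prev_i"]),
    mdt_s = mean_dwell_time(seq, "S"),
    mdt_i = mean_dwell_time(seq, "I"),
    iti = inter_transition_interval(seq),
    var_s = state_variability(seq, windows, "S"),
    var_i = state_variability(seq, windows, "I")
  )
}

#' Group-level state centroids
#'
#' For each subject and state, the elementwise median of that subject's
#' state-assigned window matrices; for each group and state, the elementwise
#' mean of the subject medians ("averaged median matrices of individual
#' brain states within groups").
#'
#' @param sequences list of `state_sequence`, one per subject.
#' @param windowed list of `windowed_fc`, aligned with `sequences`.
#' @param group_labels per-subject group code (e.g. sex).
#' @return nested list `result[[group]][[state]]` of centroid matrices
#'   (`NULL` when no subject in the group visits the state).
#' @export
group_centroids <- function(sequences, windowed, group_labels) {
  stopifnot(length(sequences) == length(windowed),
            length(group_labels) == length(sequences))
  n_rois <- windowed[[1]]$n_rois
  out <- list()
  for (grp in unique(group_labels)) {
    gi <- which(group_labels == grp)
    out[[as.character(grp)]] <- lapply(c(S = "S", I = "I"), function(st) {
      meds <- list()
      for (i in gi) {
        rows <- which(seq_labels(sequences[[i]]) == st)
        if (length(rows) == 0) next
        V <- windowed[[i]]$vectors[rows, , drop = FALSE]
        meds[[length(meds) + 1]] <- apply(V, 2, stats::median)
      }
      if (length(meds) == 0) return(NULL)
      fc_unvectorize(Reduce(`+`, meds) / length(meds), n_rois)
    })
  }
  out
}
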