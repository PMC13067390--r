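make_two_cluster_pool <- function(n_per = 25, p = 6, sep = 4, seed = 31) {
  set.seed(seed)
  edges <- p * (p - 1) / 2
  mu1 <- rnorm(edges); mu2 <- rnorm(edges) + sep
  X <- rbind(
    matrix(rnorm(n_per * edges, sd = 0.3), n_per, edges, byrow = TRUE) +
      matrix(mu1, n_per, edges, byrow = TRUE),
    matrix(rnorm(n_per * edges, sd = 0.3), n_per, edges, byrow = TRUE) +
      matrix(mu2, n_per, edges, byrow = TRUE)
  )
  structure(list(vectors = X, subject_id = rep("s", 2 * n_per),
                 window_index = seq_len(2 * n_per), n_rois = p),
            class = "state_pool")
}

test_that("cosine k-means separates planted clusters and ignores row scale", {
  pool <- make_two_cluster_pool()
  m <- fit_states(pool, n_init = 20, seed = 1, label = FALSE)
  truth <- rep(1:2, each = 25)
  agree <- max(mean(m$assignment == truth), mean(m$assignment == 3 - truth))
  expect_equal(agree, 1)

  # cosine distance is invariant to positive per-row scaling
  pool2 <- pool
  set.seed(2)
  pool2$vectors <- pool$vectors * runif(50, 0.2, 5)
  m2 <- fit_states(pool2, n_init = 20, seed = 1, label = FALSE)
  same <- mean(m$assignment == m2$assignment)
  expect_true(same == 1 || same == 0)  # up to cluster relabeling

  # degenerate pool rejected
  pool3 <- pool
  pool3$vectors <- matrix(1, 10, 15)
  expect_error(fit_states(pool3), "degenerate")
})

test_that("fitted cosine inertia attains the exhaustive 2-partition optimum", {
  set.seed(3)
  for (rep in 1:3) {
    X <- matrix(rnorm(12 * 10), 12, 10)
    pool <- structure(list(vectors = X, subject_id = rep("s", 12),
                           window_index = 1:12, n_rois = 5),
                      class = "state_pool")
    m <- fit_states(pool, n_init = 100, seed = rep, label = FALSE)
    expect_equal(m$inertia, oracle_best_2partition_inertia(X),
                 tolerance = 1e-9)
  }
})

test_that("centroid labeling follows the generative identity and is order-invariant", {
  z_s <- fisher_z_ref(make_state_covariances(6, 2, 0.6, 0.05))
  z_i <- fisher_z_ref(make_state_covariances(6, 2, 0.6, 0.45))
  mk_model <- function(c1, c2) {
    structure(list(
      centroids = rbind(fc_vectorize(c1), fc_vectorize(c2)),
      assignment = NULL, inertia = 0, n_rois = 6,
      state_of_centroid = NULL, label_metrics = NULL
    ), class = "state_model")
  }
  m1 <- label_states(mk_model(z_s, z_i))
  expect_equal(m1$state_of_centroid, c("S", "I"))
  m2 <- label_states(mk_model(z_i, z_s))
  expect_equal(m2$state_of_centroid, c("I", "S"))
  expect_error(label_states(mk_model(z_s, z_s)), "unlabelable")
})

test_that("window assignment is nearest-centroid with ties toward S", {
  z_s <- fisher_z_ref(make_state_covariances(6, 2, 0.6, 0.05))
  z_i <- fisher_z_ref(make_state_covariances(6, 2, 0.6, 0.45))
  model <- structure(list(
    centroids = rbind(fc_vectorize(z_i), fc_vectorize(z_s)),
    n_rois = 6, state_of_centroid = c("I", "S")
  ), class = "state_model")

  # a window equal to a centroid gets that centroid's label
  seq1 <- assign_windows(model, rbind(fc_vectorize(z_i), fc_vectorize(z_s)),
                         tr_seconds = 1)
  expect_equal(seq1$labels, c("I", "S"))

  # brute-force nearest-centroid recomputation
  set.seed(4)
  V <- matrix(rnorm(40 * 15), 40, 15)
  got <- assign_windows(model, V, tr_seconds = 1)$labels
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  want <- apply(V, 1, function(v) {
    sims <- c(cosv(v, model$centroids[1, ]), cosv(v, model$centroids[2, ]))
    model$state_of_centroid[which.max(sims)]
  })
  expect_equal(got, want)

  # exact tie: equidistant vector goes to S
  tie_model <- structure(list(
    centroids = rbind(c(1, 0, 0), c(0, 1, 0)),
    n_rois = 3, state_of_centroid = c("I", "S")
  ), class = "state_model")
  expect_equal(assign_windows(tie_model, rbind(c(1, 1, 0)), tr_seconds = 1)$labels, "S")
})

test_that("prevalence counts windows and always sums to 100", {
  expect_equal(prevalence(c("S", "S", "I", "I")),
               c(prev_s = 50, prev_i = 50))
  expect_equal(prevalence(rep("S", 7)), c(prev_s = 100, prev_i = 0))
  set.seed(5)
  for (rep in 1:10) {
    labs <- sample(c("S", "I"), 1000, replace = TRUE, prob = c(runif(1), 1))
    p <- prevalence(labs)
    expect_equal(unname(p["prev_s"]), 100 * sum(labs == "S") / 1000)
    expect_identical(unname(p["prev_s"] + p["prev_i"]), 100)
  }
})

test_that("dwell times follow run-length arithmetic with censored runs included", {
  labs <- c("S", "S", "I", "I", "S", "S", "S")
  expect_equal(mean_dwell_time(labs, "S"), 2.5)  # runs of 2 and 3
  expect_equal(mean_dwell_time(labs, "I"), 2)
  expect_equal(mean_dwell_time(rep("I", 9), "I", step_seconds = 0.72), 9 * 0.72)
  expect_true(is.na(mean_dwell_time(rep("I", 9), "S")))

  # brute-force scan oracle + exact time accounting
  set.seed(6)
  for (rep in 1:10) {
    labs <- sample(c("S", "I"), 200, replace = TRUE)
    r <- rle(labs)
    for (st in c("S", "I")) {
      expect_equal(mean_dwell_time(labs, st),
                   mean(r$lengths[r$values == st]))
    }
    total <- sum(vapply(c("S", "I"), function(st) {
      mean_dwell_time(labs, st) * sum(r$values == st)
    }, numeric(1)), na.rm = TRUE)
    expect_equal(total, 200)
  }
})

test_that("inter-transition interval averages transition spacings", {
  # transitions at windows 3 and 5: spacing 2
  expect_equal(inter_transition_interval(c("S", "S", "I", "I", "S", "S")), 2)
  expect_equal(inter_transition_interval(rep(c("S", "I"), 10),
                                         step_seconds = 0.5), 0.5)
  expect_true(is.na(inter_transition_interval(c("S", "S", "I", "I"))))

  # on a long alternating-run sequence the ITI matches the mean interior
  # run duration (it "approximates the mean of the dwell times")
  labs <- simulate_state_sequence(0.1, 0.15, 5000, seed = 7)
  r <- rle(labs)
  interior <- r$lengths[-c(1, length(r$lengths))]
  expect_equal(inter_transition_interval(labs), mean(interior),
               tolerance = 1e-12)
})

test_that("state variability measures the within-state cosine cloud", {
  V <- matrix(rep(c(1, 2, 3), 4), 4, 3, byrow = TRUE)
  expect_equal(state_variability(rep("S", 4), V, "S"), 0)
  expect_true(is.na(state_variability(rep("S", 4), V, "I")))
  expect_equal(state_variability(c("S", rep("I", 3)), V, "S"), 0)  # single window

  # two windows symmetric about their mean: equal distances
  V2 <- rbind(c(1, 0.5), c(0.5, 1))
  labs2 <- c("S", "S")
  mu <- colMeans(V2)
  cosd <- function(a, b) 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_equal(state_variability(labs2, V2, "S"),
               100 * cosd(V2[1, ], mu), tolerance = 1e-12)

  # brute-force recomputation on random windows
  set.seed(8)
  V3 <- matrix(rnorm(30 * 6), 30, 6)
  labs3 <- sample(c("S", "I"), 30, replace = TRUE)
  for (st in c("S", "I")) {
    rows <- labs3 == st
    mu <- colMeans(V3[rows, , drop = FALSE])
    want <- 100 * mean(apply(V3[rows, , drop = FALSE], 1, cosd, b = mu))
    expect_equal(state_variability(labs3, V3, st), want, tolerance = 1e-12)
  }
})

test_that("relabeling I and S swaps the paired parameters and fixes ITI", {
  set.seed(9)
  labs <- sample(c("S", "I"), 300, replace = TRUE)
  V <- matrix(rnorm(300 * 10), 300, 10)
  swapped <- ifelse(labs == "S", "I", "S")
  expect_equal(unname(prevalence(labs)["prev_s"]),
               unname(prevalence(swapped)["prev_i"]))
  expect_equal(mean_dwell_time(labs, "S"), mean_dwell_time(swapped, "I"))
  expect_equal(state_variability(labs, V, "S"), state_variability(swapped, V, "I"))
  expect_equal(inter_transition_interval(labs),
               inter_transition_interval(swapped))
})

test_that("group centroids are the mean of per-subject median matrices", {
  co <- make_test_cohort(n_subjects = 4, n_frames = 150, seed = 13, n_rois = 4)
  windowed <- lapply(co$subjects, function(s) sliding_window_fc(s$ts, 55))
  pool <- build_state_pool(windowed)
  model <- fit_states(pool, n_init = 10, seed = 1)
  seqs <- lapply(windowed, function(w) assign_windows(model, w))
  cents <- group_centroids(seqs, windowed, co$manifest$sex)

  # brute-force median-then-mean for one group/state
  grp <- which(co$manifest$sex == 1)
  for (st in c("S", "I")) {
    meds <- list()
    for (i in grp) {
      rows <- which(seqs[[i]]$labels == st)
      if (length(rows) == 0) next
      meds[[length(meds) + 1]] <-
        apply(windowed[[i]]$vectors[rows, , drop = FALSE], 2, median)
    }
    if (length(meds) == 0) next
    want <- fc_unvectorize(Reduce(`+`, meds) / length(meds), 4)
    expect_equal(cents[["1"]][[st]], want, tolerance = 1e-12)
  }

  # single subject, single window: centroid equals that window
  w1 <- windowed[[1]]
  one <- structure(list(vectors = w1$vectors[1, , drop = FALSE],
                        window_starts = 1L, window_trs = w1$window_trs,
                        tr_seconds = w1$tr_seconds, subject_id = "solo",
                        n_rois = 4, matrices = w1$matrices[1]),
                   class = "windowed_fc")
  sq <- structure(list(labels = "S", step_seconds = 1, subject_id = "solo"),
                  class = "state_sequence")
  solo <- group_centroids(list(sq), list(one), "g")
  expect_equal(solo[["g"]][["S"]], fc_unvectorize(one$vectors[1, ], 4),
               tolerance = 1e-12)
})

test_that("recovered prevalence tracks the generative occupancy across subjects", {
  spec <- cohort_spec(n_subjects = 40, n_rois = 8, n_modules = 2,
                      n_frames = 300, between_r_segregated = 0.05,
                      between_r_integrated = 0.45, seed = 77)
  co <- simulate_cohort(spec)
  windowed <- lapply(co$subjects, function(s) sliding_window_fc(s$ts, 55))
  model <- fit_states(build_state_pool(windowed), n_init = 10, seed = 1)
  prev_s <- vapply(windowed, function(w) {
    unname(prevalence(assign_windows(model, w))["prev_s"])
  }, numeric(1))
  true_s <- vapply(co$subjects, function(s) mean(s$true_states == "S"),
                   numeric(1))
  expect_gt(cor(prev_s, true_s, method = "spearman"), 0.9)
})
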