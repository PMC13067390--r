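## Independent brute-force oracles used across the suite. These never call
## the package functions they are checked against.

## All set partitions of n elements as restricted-growth strings.
all_set_partitions <- function(n) {
  parts <- list()
  recurse <- function(labels, next_label) {
    k <- length(labels)
    if (k == n) {
      parts[[length(parts) + 1]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(next_label)) {
      recurse(c(labels, lab), max(next_label, lab + 1))
    }
  }
  recurse(integer(), 1L)
  parts
}

## Newman weighted modularity computed directly from the definition.
oracle_modularity_q <- function(w, membership, gamma = 1) {
  W <- sum(w) / 2
  total <- 0
  for (cc in unique(membership)) {
    nodes <- which(membership == cc)
    e_cc <- sum(w[nodes, nodes]) / 2
    a_c <- sum(w[nodes, ]) / 2
    total <- total + e_cc / W - gamma * (a_c / W)^2
  }
  total
}

## Best modularity over every partition (exhaustive, n <= 8).
oracle_best_modularity <- function(w, gamma = 1) {
  best <- -Inf
  for (p in all_set_partitions(nrow(w))) {
    q <- oracle_modularity_q(w, p, gamma)
    if (q > best) best <- q
  }
  best
}

## All-pairs shortest paths by Floyd-Warshall on edge lengths 1/weight.
oracle_global_efficiency <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

## Cosine inertia of a 2-partition: each side's optimal unit centroid is the
## normalized mean of its normalized vectors.
oracle_cosine_inertia <- function(X, side) {
  Xn <- X / sqrt(rowSums(X^2))
  total <- 0
  for (s in unique(side)) {
    sub <- Xn[side == s, , drop = FALSE]
    mu <- colMeans(sub)
    mu <- mu / sqrt(sum(mu^2))
    total <- total + sum(1 - sub %*% mu)
  }
  total
}

## Best 2-partition cosine inertia by exhaustive enumeration (n <= ~16).
oracle_best_2partition_inertia <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {        # fix point 1 in group 1
    side <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)])
    if (length(unique(side)) < 2) next
    best <- min(best, oracle_cosine_inertia(X, side))
  }
  best
}

## Exact Mann-Whitney p by enumerating all group assignments (no ties).
oracle_mwu_exact <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  n1 <- length(x)
  combos <- utils::combn(length(pooled), n1)
  u_of <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_of(x, y)
  us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

## Reference Fisher-z matrix of a correlation matrix (zero diagonal).
fisher_z_ref <- function(r) {
  z <- atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
  diag(z) <- 0
  z
}

## Small well-separated two-state cohort used by several tests.
make_test_cohort <- function(n_subjects = 8, n_frames = 300, seed = 11,
                             n_rois = 8) {
  spec <- cohort_spec(
    n_subjects = n_subjects, n_rois = n_rois, n_modules = 2,
    n_frames = n_frames, between_r_segregated = 0.05,
    between_r_integrated = 0.45, seed = seed
  )
  simulate_cohort(spec, mediation_spec())
}
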