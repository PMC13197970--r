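test_that("two point-masses split perfectly at k = 2", {
  m <- rbind(rep(0L, 13), c(rep(3L, 6), rep(0L, 7)))
  D <- posticu:::lcs_dist_matrix_cpp(m)
  fit <- weighted_pam(D, k = 2, weights = c(40, 25))
  expect_equal(fit$objective, 0)
  expect_setequal(fit$medoids, 1:2)
  expect_equal(fit$avg_silhouette, 1)
})

test_that("weighted PAM attains the brute-force optimum on small instances", {
  set.seed(11)
  for (r in 1:25) {
    m <- sample(4:8, 1)
    seqs <- unique(random_sequences(m + 4, len = 8, seed = 100 + r))[seq_len(m), , drop = FALSE]
    D <- posticu:::lcs_dist_matrix_cpp(seqs)
    w <- sample(1:9, m, TRUE)
    for (k in 2:min(4, m - 1)) {
      fit <- weighted_pam(D, k = k, weights = w)
      bf <- pam_bruteforce(D, w, k)
      expect_equal(fit$objective, bf$objective, tolerance = 1e-12)
    }
  }
})

test_that("weighted PAM agrees with an unweighted reference implementation", {
  skip_if_not_installed("cluster")
  set.seed(3)
  seqs <- unique(random_sequences(40, len = 13, seed = 9))
  D <- posticu:::lcs_dist_matrix_cpp(seqs)
  fit <- weighted_pam(D, k = 3, weights = rep(1, nrow(D)))
  ref <- cluster::pam(stats::as.dist(D), k = 3)
  # both are local optima of the same objective; ours must not be worse
  ref_obj <- sum(apply(D[, ref$id.med, drop = FALSE], 1, min))
  expect_lte(fit$objective, ref_obj + 1e-9)
})

test_that("replicating sequences r times equals giving them weight r", {
  m <- unique(random_sequences(12, len = 10, seed = 21))
  D <- posticu:::lcs_dist_matrix_cpp(m)
  w <- sample(1:4, nrow(m), TRUE)
  fit_w <- weighted_pam(D, k = 3, weights = w)
  # explicit replication
  idx <- rep(seq_len(nrow(m)), times = w)
  Dr <- D[idx, idx]
  fit_r <- weighted_pam(Dr, k = 3, weights = rep(1, length(idx)))
  expect_equal(fit_w$objective, fit_r$objective, tolerance = 1e-12)
  med_w <- sort(fit_w$medoids)
  med_r <- sort(unique(idx[fit_r$medoids]))
  expect_equal(med_w, med_r)
  # doubling all weights doubles the objective, medoids unchanged
  fit_2w <- weighted_pam(D, k = 3, weights = 2 * w)
  expect_equal(fit_2w$objective, 2 * fit_w$objective, tolerance = 1e-12)
  expect_equal(sort(fit_2w$medoids), med_w)
})

test_that("silhouette matches a direct hand evaluation on a 5-point instance", {
  D <- matrix(c(0, 1, 4, 5, 6,
                1, 0, 3, 4, 5,
                4, 3, 0, 1, 2,
                5, 4, 1, 0, 1,
                6, 5, 2, 1, 0), 5, 5, byrow = TRUE)
  cl <- c(1, 1, 2, 2, 2)
  w <- rep(1, 5)
  # direct formula evaluation, written out independently
  s_hand <- numeric(5)
  for (i in 1:5) {
    own <- which(cl == cl[i] & seq_len(5) != i)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(c2) mean(D[i, cl == c2]), numeric(1)))
    s_hand[i] <- (b - a) / max(a, b)
  }
  expect_equal(silhouette_width(D, cl, w), mean(s_hand), tolerance = 1e-12)
})

test_that("silhouette is bounded and near zero for random labels", {
  set.seed(5)
  n <- 500
  x <- matrix(rnorm(2 * n), ncol = 2)
  D <- as.matrix(stats::dist(x))
  cl <- sample(1:2, n, TRUE)
  s <- silhouette_width(D, cl, rep(1, n))
  expect_lt(abs(s), 0.1)
  for (k in 2:4) {
    cl2 <- sample(1:k, n, TRUE)
    s2 <- silhouette_width(D, cl2, rep(1, n))
    expect_gte(s2, -1); expect_lte(s2, 1)
  }
  expect_error(silhouette_width(D, rep(1, n), rep(1, n)), "at least 2")
})

test_that("k selection recovers two well-separated archetypes", {
  set.seed(8)
  arch1 <- rep(0L, 13)
  arch2 <- c(rep(3L, 7), rep(4L, 6))
  noisy <- function(base, n) t(replicate(n, {
    s <- base
    w <- sample(13, 1)
    if (s[w] == 0L) s[w] <- 1L
    s
  }))
  mat <- rbind(noisy(arch1, 120), noisy(arch2, 80))
  ks <- select_k(sequence_distance_matrix(seq_tibble(mat)), k_range = 2:6)
  expect_equal(ks$best_k, 2L)
  # forced single-candidate range
  ks2 <- select_k(sequence_distance_matrix(seq_tibble(mat)), k_range = 2)
  expect_equal(ks2$best_k, 2L)
})

test_that("invalid k is rejected", {
  m <- unique(random_sequences(6, len = 8, seed = 2))
  D <- posticu:::lcs_dist_matrix_cpp(m)
  expect_error(weighted_pam(D, k = nrow(m) + 1, weights = rep(1, nrow(m))),
               "exceeds")
})
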