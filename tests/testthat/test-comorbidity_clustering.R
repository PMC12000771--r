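test_that("feature matrices honour mode contracts", {
  pr <- data.frame(record_id = "r1", a = 1L, b = 0L,
                   morbidity_count = 1L, burden_class = "single")
  expect_identical(unname(build_feature_matrix(pr, "binary")[1, ]), c(1, 0))
  corpus <- list(c("asthma", "asthma", "gdm"), "gdm", "gdm")
  cm <- build_feature_matrix(corpus, "count")
  expect_identical(unname(cm[1, ]), c(2, 1))
  # a term present in every record gets the minimum idf, ln(1) + 1 = 1
  N <- nrow(cm); df <- colSums(cm > 0)
  idf <- log((1 + N) / (1 + df)) + 1
  expect_equal(unname(idf["gdm"]), 1)
  tf <- build_feature_matrix(corpus, "tfidf")
  norms <- sqrt(rowSums(tf^2))
  expect_equal(norms, rep(1, 3), tolerance = 1e-9)
  expect_error(build_feature_matrix(pr, "bogus"))
})

test_that("tfidf rows have unit norm except all-zero rows, on random counts", {
  set.seed(503)
  corpus <- replicate(200, sample(letters[1:12], rpois(1, 3), TRUE),
                      simplify = FALSE)
  corpus[[7]] <- character(0)
  tf <- build_feature_matrix(corpus, "tfidf")
  norms <- sqrt(rowSums(tf^2))
  nz <- lengths(corpus) > 0
  expect_equal(norms[nz], rep(1, sum(nz)), tolerance = 1e-9)
  expect_identical(unname(norms[7]), 0)
})

test_that("k-means solves separable cases exactly", {
  X <- matrix(c(0, 0, 10, 10), ncol = 1)
  fit <- kmeans_fit(X, 2, seed = 1)
  expect_identical(sort(drop(fit$centroids)), c(0, 10))
  expect_identical(fit$inertia, 0)
  # k = 1 has the closed form: centroid = mean, inertia = total SS
  X2 <- matrix(rnorm(40), ncol = 2)
  f1 <- kmeans_fit(X2, 1, seed = 2)
  expect_equal(drop(f1$centroids), colMeans(X2))
  expect_equal(f1$inertia, sum(sweep(X2, 2, colMeans(X2))^2))
  expect_error(kmeans_fit(matrix(c(1, 1, 1, 1), 2), 3), "distinct")
})

test_that("fits are reproducible and internally consistent", {
  g <- planted_cohort(600, seed = 509)
  X <- build_feature_matrix(g$truth[, paste0("cond_", letters[1:9])],
                            "binary")
  f1 <- kmeans_fit(X, 3, seed = 42)
  f2 <- kmeans_fit(X, 3, seed = 42)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$centroids, f2$centroids)
  # every record sits at its nearest centroid; inertia recomputes
  D <- pregmorbid:::sq_dist_to(X, f1$centroids)
  nearest <- apply(D, 1, which.min)
  own <- D[cbind(seq_len(nrow(X)), f1$assignments)]
  best <- D[cbind(seq_len(nrow(X)), nearest)]
  expect_true(all(own - best <= 1e-9))
  expect_equal(f1$inertia, sum(own), tolerance = 1e-9)
})

test_that("inertia matches an independent k-means on separable data", {
  g <- planted_cohort(900, seed = 521, p_in = 0.95, p_out = 0.05)
  X <- build_feature_matrix(g$truth[, paste0("cond_", letters[1:9])],
                            "binary")
  ours <- kmeans_fit(X, 3, seed = 5)
  set.seed(5)
  ref <- stats::kmeans(X, centers = 3, nstart = 10, iter.max = 100)
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("planted comorbidity profiles are recovered (ARI) and the elbow finds k", {
  skip_if_not_installed("mclust")
  g <- planted_cohort(3000, seed = 523)
  X <- build_feature_matrix(g$truth[, paste0("cond_", letters[1:9])],
                            "binary")
  fit <- kmeans_fit(X, 3, seed = 7)
  ari <- mclust::adjustedRandIndex(fit$assignments, g$truth$cluster_id)
  expect_gte(ari, 0.9)
  elbow <- elbow_select_k(X, 1, 8, seed = 7)
  expect_identical(attr(elbow, "chosen_k"), 3L)
  expect_true(all(diff(elbow$inertia) <= 1e-6 * abs(elbow$inertia[-1]) + 1e-6))
})

test_that("a no-elbow (linear) inertia decline falls back to k_min with a warning", {
  # two distinct rows: the k = 1..2 polyline has no interior point, so no
  # elbow exists and the scan must fall back to k_min
  flat <- matrix(rep(c(0, 1), each = 20), ncol = 1)
  expect_warning(out <- elbow_select_k(flat, 1, 2, seed = 1, n_init = 2),
                 "no elbow")
  expect_identical(attr(out, "chosen_k"), 1L)
  expect_error(elbow_select_k(flat, 1, 10), "distinct")
  expect_error(elbow_select_k(flat, 2, 2), "k_min")
})

test_that("cluster characterisation orders conditions by prevalence", {
  g <- planted_cohort(1500, seed = 541)
  X <- build_feature_matrix(g$truth[, paste0("cond_", letters[1:9])],
                            "binary")
  fit <- kmeans_fit(X, 3, seed = 11)
  prof_df <- g$truth[, paste0("cond_", letters[1:9])]
  ch <- characterize_clusters(fit, prof_df, top_m = 3)
  expect_identical(length(ch), 3L)
  for (cl in ch) {
    expect_true(all(diff(cl$prevalence) <= 0))
    expect_gte(cl$prevalence[1], 0.7)  # a planted high-probability block
  }
  # a cluster of identical profiles has prevalence exactly 1 on its set bits
  ident <- data.frame(x = rep(1L, 5), y = rep(0L, 5))
  fit1 <- kmeans_fit(as.matrix(ident), 1, seed = 1)
  ch1 <- characterize_clusters(fit1, ident, top_m = 2)
  expect_identical(ch1$cluster_1$prevalence, c(1, 0))
})

test_that("per-cluster risks and pairwise tests behave on planted risk gaps", {
  fake <- list(k = 2L, assignments = c(1L, 1L, 2L, 2L))
  class(fake) <- "comorbidity_km"
  r <- cluster_outcome_risk(fake, c(1, 0, 1, 1))
  expect_identical(r$risk$risk, c(0.5, 1.0))
  set.seed(547)
  big <- list(k = 2L, assignments = rep(1:2, each = 2000))
  class(big) <- "comorbidity_km"
  o_gap <- c(rbinom(2000, 1, 0.30), rbinom(2000, 1, 0.15))
  rg <- cluster_outcome_risk(big, o_gap)
  expect_lt(rg$pairwise_p[1, 2], 0.001)
  expect_identical(rg$pairwise_p[1, 2], rg$pairwise_p[2, 1])
  # identical outcome proportions leave the pairwise p near 1
  o_same <- c(rbinom(2000, 1, 0.2), rbinom(2000, 1, 0.2))
  rs <- cluster_outcome_risk(big, o_same)
  expect_gt(rs$pairwise_p[1, 2], 0.05)
  # marginal: cluster event counts sum to the total
  expect_identical(sum(rg$risk$events), sum(o_gap))
})

test_that("elbow inertia is non-increasing in k on arbitrary binary data", {
  set.seed(557)
  X <- matrix(rbinom(400 * 8, 1, 0.3), ncol = 8)
  elbow <- elbow_select_k(X, 1, 8, seed = 3, n_init = 10)
  slack <- 1e-6 * pmax(abs(elbow$inertia[-nrow(elbow)]), 1)
  expect_true(all(diff(elbow$inertia) <= slack))
})
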