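test_that("baseline normalization divides by the window mean", {
  tt <- seq(0, 6, 2)
  vals <- rbind(c(2, 2, 4, 6), c(5, 5, 5, 5))
  set <- trajectory_set(vals, tt)
  norm <- normalize_baseline(set, window = c(0, 2))
  expect_equal(unname(norm$values[1, ]), c(1, 1, 2, 3))
  expect_equal(unname(norm$values[2, ]), rep(1, 4))
  # idempotent on an already-normalized set
  norm2 <- normalize_baseline(norm, window = c(0, 2))
  expect_equal(norm2$values, norm$values, tolerance = 1e-12)
})

test_that("cells with nonpositive baselines are dropped and counted", {
  set <- trajectory_set(rbind(c(1, 2), c(0, 5), c(-1, 3)), c(0, 2))
  expect_message(norm <- normalize_baseline(set, c(0, 0)), "2 cell")
  expect_equal(n_cells(norm), 1)
  expect_equal(attr(norm, "dropped"), 2)
})

test_that("dtw_distance matches its worked examples", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtw_distance(c(0, 0), c(1, 1)), 2)
  expect_equal(dtw_distance(c(0, 1, 2), c(0, 2)), 1)
  expect_error(dtw_distance(numeric(0), 1), "empty")
})

test_that("dtw_distance equals exhaustive path enumeration", {
  short <- all_int_series(3)
  for (x in short)
    for (y in short) {
      expect_equal(dtw_distance(x, y), dtw_oracle(x, y))
    }
  # seeded random longer pairs, both step patterns
  set.seed(99)
  for (rep in 1:60) {
    x <- sample(0:2, sample(4:6, 1), replace = TRUE)
    y <- sample(0:2, sample(4:6, 1), replace = TRUE)
    expect_equal(dtw_distance(x, y), dtw_oracle(x, y))
    expect_equal(dtw_distance(x, y, "symmetric2"),
                 dtw_oracle(x, y, symmetric2 = TRUE))
  }
})

test_that("jm_distance has the stated bounds and closed forms", {
  expect_equal(jm_distance(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(jm_distance(c(1, 0), c(0, 1)), 2)
  expect_equal(jm_distance(c(1, 0), c(0.5, 0.5)), 2 - sqrt(2))
  expect_error(jm_distance(c(0.7, 0.7), c(0.5, 0.5)), "normalized")
  expect_error(jm_distance(c(1, 0), c(1, 0, 0)), "binning")
})

test_that("jm_distance equals twice one minus the Bhattacharyya coefficient", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(2:12, 1)
    p <- stats::runif(n); p <- p / sum(p)
    q <- stats::runif(n); q <- q / sum(q)
    expect_equal(jm_distance(p, q), 2 * (1 - sum(sqrt(p * q))),
                 tolerance = 1e-12)
  }
})

test_that("population_distance spans [0, 1] with the documented anchors", {
  tt <- seq(0, 10, 1)
  set.seed(1)
  a <- trajectory_set(matrix(rnorm(20 * 11), 20), tt)
  expect_equal(population_distance(a, a)$d_popul, 0)

  # disjoint ranges at every timepoint
  b <- trajectory_set(a$values + 100, tt)
  expect_equal(population_distance(a, b)$d_popul, 1)

  # disjoint at exactly half of an even number of timepoints
  tt2 <- seq(0, 7, 1)
  va <- matrix(rnorm(10 * 8), 10)
  vb <- va
  vb[, 1:4] <- vb[, 1:4] + 100
  pa <- trajectory_set(va, tt2)
  pb <- trajectory_set(vb, tt2)
  expect_equal(population_distance(pa, pb)$d_popul, 0.5)

  expect_error(population_distance(a, trajectory_set(va, tt2)), "grid")
})

test_that("population_distance is symmetric, order-invariant and monotone in shift", {
  fx <- generate_ev2b_fixture(n_per_pop = 60, mean_separation = 1, seed = 5)
  d1 <- population_distance(fx$a, fx$b)$d_popul
  expect_equal(population_distance(fx$b, fx$a)$d_popul, d1)
  perm <- sample(n_cells(fx$a))
  expect_equal(population_distance(subset_cells(fx$a, perm), fx$b)$d_popul,
               d1)
  shifts <- c(0, 0.5, 1, 2, 4)
  d <- vapply(shifts, function(s) {
    f <- generate_ev2b_fixture(n_per_pop = 60, mean_separation = s, seed = 5)
    population_distance(f$a, f$b)$d_popul
  }, numeric(1))
  expect_true(all(diff(d) > -1e-9))
})

test_that("hcluster recovers planted structure and is permutation-stable", {
  fx <- generate_two_cluster_fixture(n_a = 25, n_b = 25, seed = 3)
  for (metric in c("dtw", "manhattan", "euclidean")) {
    cl <- hcluster(fx$set, metric = metric, linkage = "ward", k = 2)
    expect_equal(ari(cl$labels, fx$labels), 1)
  }
  cl1 <- hcluster(fx$set, "dtw", "ward", k = 2)
  expect_true(all(hcluster(fx$set, "dtw", "ward", k = 1)$labels == 1))
  expect_error(hcluster(fx$set, "dtw", "ward", k = 99), "exceeds")

  perm <- sample(n_cells(fx$set))
  cl2 <- hcluster(subset_cells(fx$set, perm), "dtw", "ward", k = 2)
  expect_equal(ari(cl2$labels, cl1$labels[perm]), 1)
})

test_that("cluster_summary reports means, CIs and compositions", {
  fx <- generate_two_cluster_fixture(n_a = 20, n_b = 40, noise_sd = 0.01,
                                     seed = 4)
  s <- cluster_summary(fx$set, fx$labels)
  expect_equal(dim(s$means), c(2, length(fx$set$time)))
  expect_equal(unname(s$n), c(20, 40))
  # per-condition composition rows sum to 1; the two templates separate
  expect_true(all(abs(rowSums(s$composition) - 1) < 1e-12))
  expect_equal(unname(s$composition["transient_NA", "cluster_1"]), 1)

  # single cluster: fraction 1 everywhere
  s1 <- cluster_summary(fx$set, rep(1L, n_cells(fx$set)))
  expect_true(all(s1$composition == 1))

  # CI half-width scales as 1/sqrt(n)
  tt <- seq(0, 8, 2)
  set.seed(8)
  base <- matrix(rnorm(20 * 5), 20)
  big <- rbind(base, base, base, base)
  ci_small <- cluster_summary(trajectory_set(base, tt),
                              rep(1L, 20))$ci_half
  ci_big <- cluster_summary(trajectory_set(big, tt), rep(1L, 80))$ci_half
  # approximate because the sample sd uses n - 1
  expect_equal(unname(ci_big), unname(ci_small / 2), tolerance = 0.02)
})

test_that("separability_dendrogram orders conditions sensibly", {
  tt <- seq(0, 5, 1)
  set.seed(11)
  base <- matrix(rnorm(30 * 6), 30)
  a <- trajectory_set(base, tt)
  b <- trajectory_set(base, tt)          # identical copy of a
  c3 <- trajectory_set(base + 5, tt)
  sep <- separability_dendrogram(list(a = a, b = b, c = c3))
  expect_true(isSymmetric(sep$distance))
  expect_true(all(diag(sep$distance) == 0))
  expect_equal(sep$distance["a", "b"], 0)
  merge1 <- sep$hclust$merge[1, ]
  expect_setequal(abs(merge1), c(1, 2))  # a and b merge first
  expect_error(separability_dendrogram(list(a = a)), "two conditions")
})

test_that("pca_project decomposes and projects consistently", {
  fx <- generate_two_cluster_fixture(n_a = 15, n_b = 15, seed = 6)
  p <- pca_project(fx$set)
  expect_equal(sum(p$explained), 1)

  # collinear data: one component explains everything
  tt <- seq(0, 8, 2)
  line <- outer(seq_len(10), c(1, 2, 3, 4, 5))
  pl <- pca_project(trajectory_set(line, tt))
  expect_equal(pl$explained[1], 1, tolerance = 1e-12)

  # projecting the training set returns its own scores
  p2 <- pca_project(fx$set, extra = fx$set)
  expect_equal(unname(p2$extra_scores), unname(p2$scores),
               tolerance = 1e-10)
})

test_that("classify_phase recognizes aligned, inverted and flat responses", {
  sched <- make_schedule("multi_pulse", 25, width_min = 3, pause_min = 20,
                         n_pulses = 4)
  g <- sample_grid(sched)
  square <- as.numeric(g$dose_ng_ml > 0)
  expect_equal(classify_phase(square, sched), "in_phase")
  expect_equal(classify_phase(1 - square, sched), "anti_phase")
  expect_equal(classify_phase(rep(1, nrow(g)), sched), "undetermined")
  two <- make_schedule("multi_pulse", 25, width_min = 3, pause_min = 20,
                       n_pulses = 2)
  expect_error(classify_phase(rep(1, nrow(sample_grid(two))), two),
               "at least 3")
})
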