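test_that("quasi-linear score matches the worked log-sum-exp value and limits", {
  expect_equal(round(quasi_linear_score(c(5, 2, -1, -4)), 3), 5.051)
  # K = 1 reduction is exact
  expect_identical(quasi_linear_score(3.7), 3.7)
  # all-equal scores: c + log K
  expect_equal(quasi_linear_score(rep(2.5, 4)), 2.5 + log(4))
  expect_error(quasi_linear_score(numeric(0)), "empty")
})

test_that("linear scores are the per-cluster affine forms", {
  part <- marker_partition(c(1, 2))
  expect_equal(linear_scores(c(0.3, -0.2), c(1, 1), c(1, 1), part),
               c(1.3, 0.8))
  # zero coefficients leave the intercepts
  expect_equal(linear_scores(c(5, -5), c(2, -3), c(0, 0), part), c(2, -3))
  # brute-force dot products on random inputs
  withr::with_seed(42, {
    for (rep in 1:10) {
      p <- sample(3:8, 1)
      K <- sample(2:3, 1)
      cl <- sample(rep(seq_len(K), length.out = p))
      x <- rnorm(p); a <- rnorm(K); b <- rnorm(p)
      byhand <- vapply(seq_len(K), function(k) {
        s <- a[k]
        for (j in seq_len(p)) if (cl[j] == k) s <- s + b[j] * x[j]
        s
      }, numeric(1))
      expect_equal(linear_scores(x, a, b, marker_partition(cl)), byhand)
    }
  })
  expect_error(linear_scores(c(1, 2), c(1, 1, 1), c(1, 2), part), "alpha")
})

test_that("max score and dominant cluster agree with sort/scan oracles", {
  expect_equal(max_score(c(5, 2, -1, -4)), 5)
  expect_equal(max_score(c(2, 2)), 2)
  expect_equal(dominant_cluster(c(5, 2, -1, -4)), 1L)
  expect_equal(dominant_cluster(c(2, 2)), 1L) # tie: lowest index
  withr::with_seed(9, {
    for (rep in 1:20) {
      s <- rnorm(sample(1:6, 1))
      expect_equal(max_score(s), sort(s, decreasing = TRUE)[1])
      expect_equal(dominant_cluster(s), which(s == max(s))[1])
    }
  })
  expect_error(max_score(numeric(0)), "empty")
})

test_that("tempered score interpolates between mean and max", {
  s <- c(5, 2, -1, -4)
  expect_equal(tempered_score(s, tau = 1), quasi_linear_score(s))
  expect_lt(abs(tempered_score(s, tau = 100) - 5), 1e-3)
  expect_lt(abs(tempered_score(s, tau = 1e-6, normalized = TRUE) - 0.5), 1e-4)
  # normalized form is nondecreasing in tau
  withr::with_seed(11, {
    for (rep in 1:20) {
      sc <- rnorm(4, sd = 2)
      taus <- sort(stats::runif(6, 0.01, 20))
      vals <- vapply(taus, function(t) tempered_score(sc, t, TRUE), numeric(1))
      expect_true(all(diff(vals) >= -1e-10))
      expect_lt(abs(tempered_score(sc, 1e-7, TRUE) - mean(sc)), 1e-4)
      expect_lt(abs(tempered_score(sc, 1e4, TRUE) - max(sc)), 1e-3)
    }
  })
  expect_error(tempered_score(s, tau = 0), "positive")
  expect_error(tempered_score(s, tau = -1), "positive")
})

test_that("Kolmogorov-Nagumo average generalizes sum and soft maximum", {
  s <- c(5, 2, -1, -4)
  expect_equal(round(kn_average(s, exp, log), 3), 5.051)
  expect_equal(kn_average(c(1, 2, 3), identity, identity), 6)
  withr::with_seed(5, {
    for (rep in 1:10) {
      sc <- rnorm(4)
      expect_equal(kn_average(sc, function(z) z^3,
                              function(z) sign(z) * abs(z)^(1 / 3)),
                   sign(sum(sc^3)) * abs(sum(sc^3))^(1 / 3))
    }
  })
  # a non-invertible phi on the input range is rejected
  expect_error(kn_average(c(-1, 1), function(z) z^2, sqrt), "invert")
})

test_that("softmax weights live on the simplex and gate the top cluster", {
  expect_equal(softmax_weights(c(3, 3)), c(0.5, 0.5))
  w <- softmax_weights(c(5, 2, -1, -4))
  expect_gt(w[1], 0.94)
  withr::with_seed(13, {
    for (rep in 1:50) {
      w <- softmax_weights(rnorm(sample(1:6, 1), sd = 5))
      expect_lt(abs(sum(w) - 1), 1e-12)
      expect_true(all(w > 0 & w < 1 + 1e-15))
    }
  })
})

test_that("sandwich, permutation invariance, dominance and overflow safety hold", {
  withr::with_seed(101, {
    for (rep in 1:10000) {
      s <- stats::runif(sample(1:5, 1), -50, 50)
      Q <- quasi_linear_score(s)
      M <- max_score(s)
      expect_true(M <= Q + 1e-12 && Q <= M + log(length(s)) + 1e-12)
    }
    for (rep in 1:50) {
      s <- rnorm(5, sd = 3)
      pm <- sample(5)
      expect_equal(quasi_linear_score(s[pm]), quasi_linear_score(s))
      expect_equal(max_score(s[pm]), max_score(s))
      expect_equal(tempered_score(s[pm], 2.5, TRUE), tempered_score(s, 2.5, TRUE))
    }
    # dominance: a 20-unit gap makes Q numerically equal to the top score
    for (rep in 1:50) {
      rest <- stats::runif(3, -30, 0)
      top <- max(rest) + stats::runif(1, 20, 40)
      expect_lt(abs(quasi_linear_score(c(top, rest)) - top), 1e-8)
    }
    # magnitudes up to 1e4 stay finite under the max-shift
    for (rep in 1:50) {
      s <- stats::runif(4, -1e4, 1e4)
      expect_true(is.finite(quasi_linear_score(s)))
    }
  })
})

test_that("marker partitions enforce disjoint exhaustive clusters", {
  p <- marker_partition(c(a = 1, b = 1, c = 2))
  expect_s3_class(p, "marker_partition")
  expect_equal(partition_k(p), 2L)
  expect_equal(partition_sizes(p), c(2L, 1L))
  expect_equal(sum(partition_sizes(p)), length(p))
  expect_error(marker_partition(c(1, 3)), "empty")
  expect_error(marker_partition(c(0, 1)), ">= 1")
  expect_error(marker_partition(integer(0)), "non-empty")
  tb <- as_tibble(marker_partition(data.frame(marker = c("m1", "m2"),
                                              cluster = c(2, 1))))
  expect_equal(tb$cluster, c(2L, 1L))
  # conformity with data dimensions is checked downstream
  expect_error(linear_scores(c(1, 2, 3), c(0, 0), c(1, 1, 1), p), NA)
  expect_error(linear_scores(c(1, 2), c(0, 0), c(1, 1), p), "partition")
})

test_that("batch score table matches single-sample evaluation", {
  td <- toy_dataset(n = 15)
  a <- c(0.2, -0.4); b <- rnorm(6)
  tab <- ql_score_table(td$X, a, b, td$partition)
  expect_equal(nrow(tab), 15)
  for (i in c(1, 7, 15)) {
    L <- linear_scores(td$X[i, ], a, b, td$partition)
    expect_equal(unlist(tab[i, c("L1", "L2")], use.names = FALSE), L)
    expect_equal(tab$Q[i], quasi_linear_score(L))
    expect_equal(tab$M[i], max_score(L))
    expect_equal(tab$dominant_cluster[i], dominant_cluster(L))
  }
})
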