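test_that("fuzzy measure invariants are enforced", {
  expect_length(subset_keys(3), 6)
  expect_length(subset_keys(4), 14)

  um <- uniform_measure(3)
  expect_equal(measure_value(um, integer(0)), 0)
  expect_equal(measure_value(um, 1:3), 1)
  expect_equal(measure_value(um, c(2, 3)), 2 / 3)

  # At n = 2 any [0,1] singletons are monotone; at n = 3 violations fail.
  expect_s3_class(fuzzy_measure(2, c(0.9, 0.2)), "fuzzy_measure")
  expect_error(fuzzy_measure(3, c(0.9, 0.1, 0.1, 0.5, 0.95, 0.2)),
               "monotone")
  expect_error(fuzzy_measure(2, c(1.4, 0.2)), "\\[0, 1\\]")
})

test_that("Choquet integral matches hand expansion, idempotence and extremes", {
  mu <- fuzzy_measure(2, c(0.3, 0.5))  # mu({x1})=0.3, mu({x2})=0.5
  expect_equal(choquet_integral(c(0.2, 0.8), mu), 0.2 * 1 + 0.6 * 0.5)

  expect_equal(choquet_integral(c(0.4, 0.4), mu), 0.4)   # idempotence

  n <- 3
  f <- c(0.15, 0.7, 0.4)
  mx <- fuzzy_measure(n, rep(1, 2^n - 2))   # all subsets 1 -> max
  mn <- fuzzy_measure(n, rep(0, 2^n - 2))   # all subsets 0 -> min
  expect_equal(choquet_integral(f, mx), max(f))
  expect_equal(choquet_integral(f, mn), min(f))

  # Additive symmetric measure: arithmetic mean.
  expect_equal(choquet_integral(f, uniform_measure(3)), mean(f))

  expect_error(choquet_integral(c(0.2, 1.4), mu), "\\[0, 1\\]")
})

test_that("Choquet integral equals the brute-force layer-cake oracle for n <= 4", {
  set.seed(10)
  for (n in 2:4) {
    for (rep in 1:50) {
      mu <- random_measure(n)
      f <- runif(n)
      expect_equal(choquet_integral(f, mu), choquet_oracle(f, mu),
                   tolerance = 1e-12)
    }
    # Ties in f are handled consistently too.
    mu <- random_measure(n)
    f <- rep(round(runif(n), 1), length.out = n)
    expect_equal(choquet_integral(f, mu), choquet_oracle(f, mu),
                 tolerance = 1e-12)
  }
})

test_that("Choquet integral is bounded and monotone in each coordinate", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(2:4, 1)
    mu <- random_measure(n)
    f <- runif(n)
    z <- choquet_integral(f, mu)
    expect_gte(z, min(f) - 1e-12)
    expect_lte(z, max(f) + 1e-12)
    i <- sample(n, 1)
    f2 <- f
    f2[i] <- min(1, f[i] + runif(1, 0, 1 - f[i]))
    expect_gte(choquet_integral(f2, mu), z - 1e-12)
  }
})

test_that("global confidence fuses per-class columns and classification breaks ties low", {
  measures <- list(uniform_measure(2), uniform_measure(2),
                   uniform_measure(2))
  P <- rbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3))
  g <- global_confidence(P, measures)
  expect_equal(g, colMeans(P))

  # Identical classifiers: global equals the shared value.
  P2 <- rbind(c(0.7, 0.2, 0.1), c(0.7, 0.2, 0.1))
  expect_equal(global_confidence(P2, measures), c(0.7, 0.2, 0.1))

  expect_equal(classify_fused(P, measures), 1)
  Pt <- rbind(c(0.5, 0.5, 0), c(0.5, 0.5, 0))
  expect_message(cls <- classify_fused(Pt, measures), "tie")
  expect_equal(cls, 1)
  expect_error(global_confidence(P, measures[1:2]), "one fuzzy measure per")
})

test_that("the measure QP has m*(2^n-2) variables and reproduces the direct objective", {
  set.seed(12)
  profiles <- list()
  labels <- integer(0)
  for (k in 1:12) {
    labels[k] <- ((k - 1) %% 2) + 1
    profiles[[k]] <- matrix(runif(4), 2, 2)
  }
  qp <- build_measure_qp(profiles, labels, n_classes = 2, n_classifiers = 2)
  expect_length(qp$d, 4)          # 2 * (2^2 - 2) variables
  expect_equal(nrow(qp$D), 4)

  # Quadratic form equals the direct squared-margin error for random mu.
  for (rep in 1:50) {
    mu <- runif(4)
    measures <- emofuse:::unstack_measures(mu, 2, 2, repair = FALSE)
    direct <- emofuse:::measure_training_error(profiles, labels, measures)
    expect_equal(qp_objective(qp, mu), direct, tolerance = 1e-8)
  }

  # Three classifiers: the monotonicity constraint set rejects a
  # non-monotone measure and accepts the uniform one.
  profiles3 <- lapply(1:8, function(k) matrix(runif(6), 3, 2))
  qp3 <- build_measure_qp(profiles3, rep(1:2, 4), 2, 3)
  bad <- c(0.9, 0.1, 0.1, 0.2, 0.95, 0.2)   # mu({1}) > mu({1,2})
  mu_bad <- c(bad, bad)
  expect_true(any(qp3$A %*% mu_bad > qp3$b + 1e-12))
  mu_unif <- emofuse:::stack_measures(list(uniform_measure(3),
                                           uniform_measure(3)))
  expect_true(all(qp3$A %*% mu_unif <= qp3$b + 1e-12))
})

test_that("measure learning prefers the better classifier and beats the uniform measure", {
  set.seed(13)
  profiles <- list()
  labels <- integer(0)
  for (k in 1:60) {
    t <- ((k - 1) %% 2) + 1
    p1 <- if (t == 1) c(0.9, 0.1) else c(0.1, 0.9)   # reliable
    p2 <- runif(1)                                   # uninformative
    profiles[[k]] <- rbind(p1, c(p2, 1 - p2))
    labels[k] <- t
  }
  ms <- learn_fuzzy_measures(profiles, labels, 2, 2)
  for (j in 1:2)
    expect_gt(measure_value(ms[[j]], 1), measure_value(ms[[j]], 2))
  qp <- build_measure_qp(profiles, labels, 2, 2)
  expect_lte(attr(ms, "objective"),
             qp_objective(qp, emofuse:::stack_measures(
               list(uniform_measure(2), uniform_measure(2)))) + 1e-9)
})

test_that("measure learning attains the objective of a known generating measure", {
  # Profiles whose margins are consistent with a known measure.
  true_mu <- list(fuzzy_measure(2, c(0.8, 0.2)), fuzzy_measure(2, c(0.8, 0.2)))
  set.seed(14)
  profiles <- list()
  labels <- integer(0)
  for (k in 1:40) {
    t <- ((k - 1) %% 2) + 1
    base <- matrix(runif(4, 0.05, 0.95), 2, 2)
    base[, t] <- pmax(base[, t], base[, 3 - t] + 0.3)  # margin toward truth
    profiles[[k]] <- pmin(base, 1)
    labels[k] <- t
  }
  ms <- learn_fuzzy_measures(profiles, labels, 2, 2)
  j_true <- emofuse:::measure_training_error(profiles, labels, true_mu)
  expect_lte(attr(ms, "objective"), j_true + 1e-6)
})

test_that("symmetric classifiers receive equal singleton coefficients", {
  set.seed(15)
  profiles <- list()
  labels <- integer(0)
  for (k in 1:40) {
    t <- ((k - 1) %% 2) + 1
    p <- if (t == 1) c(0.8, 0.2) else c(0.2, 0.8)
    noise <- rnorm(2, 0, 0.05)
    pr <- rbind(pmin(pmax(p + noise[1], 0), 1),
                pmin(pmax(p + noise[2], 0), 1))
    profiles[[k]] <- pr[sample(2), , drop = FALSE]  # exchangeable rows
    labels[k] <- t
  }
  # Symmetrize exactly: average each profile with its row swap.
  profiles <- lapply(profiles, function(P) (P + P[2:1, , drop = FALSE]) / 2)
  ms <- learn_fuzzy_measures(profiles, labels, 2, 2)
  for (j in 1:2)
    expect_lt(abs(measure_value(ms[[j]], 1) - measure_value(ms[[j]], 2)),
              1e-3)
})

test_that("modality SVMs separate a separable toy set with unit-sum confidences", {
  set.seed(16)
  x <- rbind(matrix(runif(40, 0, 0.3), 20, 2),
             matrix(runif(40, 0.7, 1), 20, 2))
  y <- rep(1:2, each = 20)
  fit <- train_modality_classifier(x, y)
  expect_equal(mean(predict(fit, x) == y), 1)
  conf <- predict_confidence(fit, x)
  expect_equal(rowSums(conf), rep(1, 40), tolerance = 1e-6)
  expect_true(all(conf >= 0 & conf <= 1))
  expect_error(train_modality_classifier(x, rep(1, 40)), "single class")
})
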