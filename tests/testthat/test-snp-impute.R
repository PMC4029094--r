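test_that("R and theta follow the platform convention", {
  rt <- compute_r_theta(c(3, 5, 1, 0), c(3, 0, 3, 4))
  expect_equal(rt$r, c(6, 5, 4, 4))
  expect_equal(rt$theta[1], 0.5)                       # symmetric intensities
  expect_equal(rt$theta[2], 0)                         # axis case
  expect_equal(rt$theta[3], (2 / pi) * atan(3))        # 0.7952...
  expect_equal(rt$theta[4], 1)

  # complementarity: theta(x, y) + theta(y, x) = 1
  set.seed(4)
  x <- runif(50, 0.1, 5); y <- runif(50, 0.1, 5)
  expect_equal(compute_r_theta(x, y)$theta + compute_r_theta(y, x)$theta,
               rep(1, 50), tolerance = 1e-12)

  dead <- compute_r_theta(0, 0)
  expect_true(is.na(dead$r) && is.na(dead$theta))      # no-signal flag
  expect_error(compute_r_theta(-1, 2), "non-negative")
})

test_that("knn prediction honours its vote and tie-break contracts", {
  centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE,
                    dimnames = list(c("0-2", "1-1", "2-0"), NULL))
  blobs <- make_blobs(centers, n_each = 60, sd = 1, seed = 12)

  # k = 1 on a training point returns that point's label
  expect_equal(unname(knn_predict(blobs$x, blobs$labels,
                                  blobs$x[c(1, 61, 121), , drop = FALSE], k = 1)),
               blobs$labels[c(1, 61, 121)])

  # k = n is a global majority vote
  lab_unbal <- c(rep("0-2", 100), rep("1-1", 80))
  expect_equal(unname(knn_predict(blobs$x, lab_unbal,
                                  matrix(c(5, 5), 1), k = nrow(blobs$x))),
               "0-2")

  # widely separated clusters classify perfectly at k = 8
  q <- make_blobs(centers, n_each = 100, sd = 1, seed = 13)
  pred <- knn_predict(blobs$x, blobs$labels, q$x, k = 8)
  expect_equal(mean(pred != q$labels), 0)

  expect_error(knn_predict(blobs$x, blobs$labels, q$x, k = 500), "exceeds")
})

test_that("knn agrees with an independent implementation on tie-free data", {
  skip_if_not_installed("class")
  blobs <- make_blobs(matrix(c(0, 0, 3, 1, 1, 4), 3, 2, byrow = TRUE,
                             dimnames = list(c("a", "b", "c"), NULL)),
                      n_each = 70, sd = 0.6, seed = 15)
  q <- make_blobs(matrix(c(0, 0, 3, 1, 1, 4), 3, 2, byrow = TRUE,
                         dimnames = list(c("a", "b", "c"), NULL)),
                  n_each = 40, sd = 0.6, seed = 16)
  for (k in c(1, 3, 7)) {   # odd k on 3 classes: vote ties still possible but rare
    mine <- knn_predict(blobs$x, blobs$labels, q$x, k = k, standardize = FALSE)
    ref <- as.character(class::knn(blobs$x, q$x, factor(blobs$labels), k = k))
    expect_gt(mean(mine == ref), 0.97)
  }
})

test_that("knn is invariant to feature order and location shifts of R", {
  blobs <- make_blobs(matrix(c(0, 0, 4, 2), 2, 2, byrow = TRUE,
                             dimnames = list(c("0-2", "1-1"), NULL)),
                      n_each = 50, sd = 0.5, seed = 17)
  colnames(blobs$x) <- c("r_a", "theta_a")
  q <- blobs$x[1:20, , drop = FALSE]
  p1 <- knn_predict(blobs$x, blobs$labels, q, k = 5)
  p2 <- knn_predict(blobs$x[, 2:1], blobs$labels, q[, 2:1], k = 5)
  expect_equal(p1, p2)
  shift <- blobs$x; shift[, "r_a"] <- shift[, "r_a"] + 100
  qs <- shift[1:20, , drop = FALSE]
  expect_equal(unname(knn_predict(shift, blobs$labels, qs, k = 5)), unname(p1))
})

test_that("LOOCV error matches exhaustive small-sample oracles", {
  # duplicated training points: each left-out point still has its twin
  pts <- matrix(c(0, 0, 1, 1, 2, 2, 0, 0, 1, 1, 2, 2), 6, 2, byrow = TRUE)
  labs <- c("a", "b", "c", "a", "b", "c")
  expect_equal(loocv_error(pts, labs, k = 1)$mean_error, 0)

  # one training sample per class, k = 1: every prediction is wrong
  singletons <- matrix(c(0, 0, 5, 0, 0, 5), 3, 2, byrow = TRUE)
  expect_equal(loocv_error(singletons, c("a", "b", "c"), k = 1)$mean_error, 1)

  # random labels: asymptotic error = 1 - max class frequency
  set.seed(19)
  n <- 400
  x <- matrix(runif(2 * n), n, 2)
  labs <- sample(c("a", "b"), n, TRUE, c(0.7, 0.3))
  err <- loocv_error(x, labs, k = 151)$mean_error
  expect_lt(abs(err - 0.3), 0.05)

  # cohort strata are computed on the stratum's own training set
  blobs <- make_blobs(matrix(c(0, 0, 6, 0), 2, 2, byrow = TRUE,
                             dimnames = list(c("0-2", "2-0"), NULL)),
                      n_each = 40, sd = 0.5, seed = 20)
  res <- loocv_error(blobs$x, blobs$labels, k = 3,
                     cohort = rep(c("case", "control"), 40))
  expect_setequal(res$cohort, c("combined", "case", "control"))
  expect_equal(res$mean_error, rep(0, 3))
})

test_that("model selection prefers informative SNPs and breaks ties minimally", {
  cfg <- kir_sim_config(n_cases = 250, n_controls = 250, seed = 23,
                        snp_r_sd = 0.08, snp_theta_sd = 0.03)
  sim <- simulate_cohort(cfg)
  sig <- simulate_snp_signals(sim$truth, cfg, snps = "rs592645", noise_snps = 1)
  labels <- matrix(sim$truth$group, ncol = 2, nrow = nrow(sim$truth),
                   dimnames = list(sim$truth$sample_id, NULL))
  sel <- select_knn_model(sig, labels,
                          candidates = list(info = "rs592645",
                                            noise = "rsNOISE001",
                                            both = c("rs592645", "rsNOISE001")),
                          k_grid = c(4, 8))
  expect_equal(sel$best_set, "info")
  noise_err <- min(sel$table$mean_error[sel$table$set == "noise"])
  info_err <- min(sel$table$mean_error[sel$table$set == "info"])
  expect_gt(noise_err, info_err + 0.2)

  # identical candidates: tie falls to the smaller subset, then smaller k
  sel2 <- select_knn_model(sig, labels,
                           candidates = list(a = "rs592645",
                                             dup = c("rs592645", "rs592645")),
                           k_grid = c(8, 4))
  expect_equal(sel2$best_set, "a")
})

test_that("the training-size curve reduces to full-sample LOOCV at fraction 1", {
  blobs <- make_blobs(matrix(c(0, 0, 4, 0, 2, 3), 3, 2, byrow = TRUE,
                             dimnames = list(c("0-2", "1-1", "2-0"), NULL)),
                      n_each = 50, sd = 0.8, seed = 29)
  full <- loocv_error(blobs$x, blobs$labels, k = 5)$mean_error
  curve <- training_size_curve(blobs$x, blobs$labels, fractions = c(0.3, 1),
                               k_grid = 5, n_repeats = 4, seed = 31)
  expect_equal(curve$mean_error[curve$fraction == 1], full)
  expect_identical(curve,
                   training_size_curve(blobs$x, blobs$labels,
                                       fractions = c(0.3, 1), k_grid = 5,
                                       n_repeats = 4, seed = 31))
})

test_that("SNP screening finds planted copy-number signal at the nominal type-I rate", {
  set.seed(33)
  n <- 200
  theta <- runif(n)
  copy <- 1 + 2 * theta + rnorm(n, 0, 0.01)
  grp <- paste0(pmin(round(copy), 3), "-0")   # joint label whose s-part carries the signal
  sig <- data.frame(sample_id = sprintf("S%03d", 1:n), snp_id = "rsX",
                    r = runif(n), theta = theta, cohort = "case")
  calls <- matrix(grp, n, 2, dimnames = list(sig$sample_id, NULL))
  res <- screen_snps(sig, calls)
  expect_lt(res$p_value[res$gene == "3DS1"], 1e-10)
  expect_true(res$passes[res$gene == "3DS1"])
  # constant response: p = 1 by convention
  flat <- matrix("1-1", n, 2, dimnames = list(sig$sample_id, NULL))
  expect_equal(screen_snps(sig, flat)$p_value, c(1, 1))

  # null simulation: rejection rate compatible with alpha = 0.05
  reps <- 400
  hits <- 0
  for (i in seq_len(reps)) {
    cp <- sample(1:2, 120, TRUE)
    hits <- hits + (kircnv:::regression_f_p(cp, runif(120), runif(120)) < 0.05)
  }
  expect_lt(abs(hits / reps - 0.05), 0.045)  # 4 binomial SEs
})
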