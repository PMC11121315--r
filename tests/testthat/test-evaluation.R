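# Metrics against hand-computed values and brute-force sweep oracles

test_that("average precision matches hand-computed and swept values", {
  # ranked labels 1,0,1: AP = 0.5*1 + 0.5*(2/3)
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1)), 5 / 6,
               tolerance = 1e-12)
  # perfect ranking
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_warning(ap0 <- average_precision(c(0.5, 0.4), c(0, 0)), "no positive")
  expect_true(is.na(ap0))
  set.seed(51)
  for (rep in 1:60) {
    n <- 50
    s <- round(runif(n), 2) # rounding forces ties
    y <- rbinom(n, 1, 0.3)
    if (sum(y) == 0) y[1] <- 1
    expect_equal(average_precision(s, y), bf_average_precision(s, y),
                 tolerance = 1e-9)
  }
})

test_that("binary-annotation AP is precision times recall", {
  # P = 0.8 (4 of 5 predicted), R = 0.5 (4 of 8 true)
  y <- c(rep(1, 8), rep(0, 12))
  a <- c(rep(1, 4), rep(0, 4), 1, rep(0, 11))
  expect_equal(binary_average_precision(y, a), 0.8 * 0.5)
  expect_equal(binary_average_precision(y, y), 1)
  expect_warning(z <- binary_average_precision(y, rep(0, 20)), "predicted")
  expect_equal(z, 0)
})

test_that("trapezoidal AUC matches the rank-statistic oracle and pROC", {
  expect_equal(auc_roc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(auc_roc(rep(0.5, 10), rbinom(10, 1, 0.5) + c(1, rep(0, 9)) * 0),
               0.5) # all-tied scores: a single trapezoid
  set.seed(52)
  for (rep in 1:60) {
    n <- 50
    s <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0) y[1] <- 1
    if (sum(y) == n) y[1] <- 0
    expect_equal(auc_roc(s, y), bf_auc_mwu(s, y), tolerance = 1e-9)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(53)
    s <- runif(80); y <- rbinom(80, 1, 0.3); y[1] <- 1; y[2] <- 0
    expect_equal(auc_roc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-9)
  }
  expect_warning(a <- auc_roc(runif(5), rep(1, 5)), "single-class")
  expect_true(is.na(a))
})

test_that("top-k precision/recall at L fractions match hand counts and the oracle", {
  # 10 pairs, contacts ranked 1st and 3rd, L = 5 -> k = 5
  s <- seq(1, 0.1, length.out = 10)
  y <- c(1, 0, 1, rep(0, 7))
  pairs <- data.frame(i = 1:10, j = 21:30)
  tk <- topk_precision_recall(s, y, L = 5, pairs = pairs)
  expect_equal(tk$k[1], 5L)
  expect_equal(tk$precision[1], 2 / 5)
  expect_equal(tk$recall[1], 1)
  # floor(L/10) = 0 clamps to k = 1; top pair is a contact
  expect_equal(tk$k[4], 1L)
  expect_equal(tk$precision[4], 1)
  set.seed(54)
  for (rep in 1:30) {
    n <- 40
    s <- round(runif(n), 1)
    y <- rbinom(n, 1, 0.3); if (sum(y) == 0) y[5] <- 1
    pr <- data.frame(i = sample(n), j = sample(n) + 50)
    L <- sample(5:30, 1)
    tk <- topk_precision_recall(s, y, L, pairs = pr)
    for (r in seq_len(nrow(tk))) {
      ref <- bf_topk(s, y, tk$k[r], pr)
      expect_equal(tk$precision[r], unname(ref["precision"]))
      expect_equal(tk$recall[r], unname(ref["recall"]))
    }
    # recall is non-decreasing in k (fractions are decreasing)
    expect_true(all(diff(rev(tk$recall)) >= 0))
  }
})

test_that("AP and AUC are invariant under strictly monotone score transforms", {
  set.seed(55)
  s <- runif(60); y <- rbinom(60, 1, 0.3); y[1] <- 1; y[2] <- 0
  for (f in list(function(x) 2 * x + 3, function(x) x^3, plogis)) {
    expect_equal(average_precision(f(s), y), average_precision(s, y),
                 tolerance = 1e-12)
    expect_equal(auc_roc(f(s), y), auc_roc(s, y), tolerance = 1e-12)
  }
})

test_that("pooled feature statistics are the matrix-wide mean and sd", {
  expect_equal(feature_statistics(matrix(-1, 4, 5)),
               c(mean = -1, sd = 0))
  m <- matrix(c(-1, 1), 10, 10)
  st <- feature_statistics(m)
  expect_equal(unname(st["mean"]), 0)
  expect_equal(unname(st["sd"]), stats::sd(as.numeric(m)))
  set.seed(56)
  X <- matrix(rnorm(200), 20, 10)
  # two-pass oracle
  v <- as.numeric(X); mu <- sum(v) / length(v)
  expect_equal(unname(feature_statistics(X)["mean"]), mu, tolerance = 1e-12)
  expect_equal(unname(feature_statistics(X)["sd"]),
               sqrt(sum((v - mu)^2) / (length(v) - 1)), tolerance = 1e-12)
  expect_error(feature_statistics(matrix(0, 0, 3)), "empty")
})

test_that("per-sequence reports aggregate means over sequences", {
  sd4 <- synthetic_dataset(3, seed = 61)
  fs <- build_dataset(sd4$chains, sd4$annotations, "SDF")
  set.seed(62)
  scores <- runif(nrow(fs$X))
  rep_ <- eval_report(fs, scores, sd4$annotations)
  expect_equal(nrow(rep_$per_sequence), 3L)
  ap_mean <- mean(rep_$per_sequence$AP, na.rm = TRUE)
  expect_equal(rep_$aggregate$mean[rep_$aggregate$metric == "AP"], ap_mean)
  # binary mode applies P x R per sequence
  ann01 <- as.numeric(scores > 0.5)
  repb <- eval_report(fs, ann01, sd4$annotations, binary = TRUE)
  id1 <- repb$per_sequence$chain_id[1]
  sel <- fs$meta$chain_id == id1
  expect_equal(repb$per_sequence$AP[1],
               suppressWarnings(
                 binary_average_precision(fs$labels[sel], ann01[sel])))
})

test_that("cross-validation partitions chains and is seed-deterministic", {
  sd6 <- synthetic_dataset(6, seed = 63)
  cfg <- contact_net_config(epochs = 2L, seed = 3L)
  cv <- crossvalidate(sd6$chains, sd6$annotations, "SDF", config = cfg,
                      k = 3L, repeats = 2L)
  for (r in 1:2) {
    fold_of <- cv$folds[[r]]
    expect_setequal(names(fold_of), names(sd6$chains))
    # every chain is validated exactly once per repeat
    rows <- cv$per_sequence[cv$per_sequence$repeat_id == r, ]
    expect_setequal(rows$chain_id, names(sd6$chains))
    expect_equal(nrow(rows), 6L)
  }
  cv2 <- crossvalidate(sd6$chains, sd6$annotations, "SDF", config = cfg,
                       k = 3L, repeats = 2L)
  expect_identical(cv$per_sequence, cv2$per_sequence)
  expect_error(crossvalidate(sd6$chains[1:2], sd6$annotations, "SDF",
                             config = cfg, k = 3L), "fewer chains")
})
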