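# Split, gating, the regularized tournament, CCC, and validation.

test_that("the split is disjoint, exhaustive, stratified and deterministic", {
  co <- generate_cohort(100, c(HV = 0.5, RRMS = 0.5), 2, seed = 30)
  s <- co$subjects
  sp1 <- split_cohort(s, 0.8, seed = 3)
  sp2 <- split_cohort(s, 0.8, seed = 3)
  expect_identical(sp1, sp2)
  expect_length(intersect(sp1$train, sp1$validation), 0)
  expect_setequal(c(sp1$train, sp1$validation), s$subject_id)
  expect_equal(length(sp1$train), 80)
  # per-stratum counts within rounding of 80%
  for (g in unique(s$diagnosis)) {
    ids <- s$subject_id[s$diagnosis == g]
    expect_equal(sum(sp1$train %in% ids), round(0.8 * length(ids)))
  }
  expect_error(split_cohort(s, 1.0), "train_fraction")
  expect_error(split_cohort(s, 0), "train_fraction")
})

test_that("feature gating is the conjunction of reliability and correlation", {
  rel <- data.frame(
    feature = paste0("f", 1:4),
    icc = c(0.9, 0.4, 0.8, 0.7),
    retained = c(TRUE, FALSE, TRUE, TRUE),
    n_subjects_used = 50)
  cors <- data.frame(
    feature = c("f1", "f2", "f3", "f4", "f4"),
    outcome = c("edss", "edss", "edss", "edss", "other"),
    p_adjusted = c(0.20, 0.001, 0.01, 0.30, 0.001))
  # f1: reliable but no significant correlation -> out
  # f2: significant but unreliable -> out
  # f3: both -> in; f4: significant only for an irrelevant outcome -> out
  expect_equal(select_model_features(rel, cors, "edss"), "f3")
  expect_setequal(select_model_features(rel, cors, c("edss", "other")),
                  c("f3", "f4"))
  expect_error(select_model_features(rel, cors, character(0)), "empty")
})

test_that("a constructed gate admits exactly the qualifying features", {
  set.seed(31)
  n <- 120
  good <- paste0("g", 1:5)
  feats <- data.frame(matrix(rnorm(n * 20), n))
  names(feats) <- c(good, paste0("x", 1:15))
  y <- rowSums(feats[good]) + rnorm(n, 0, 0.5)
  scr <- correlation_screen(feats, data.frame(edss = y))
  rel <- data.frame(feature = names(feats),
                    icc = c(rep(0.9, 5), rep(0.2, 15)),
                    retained = c(rep(TRUE, 5), rep(FALSE, 15)),
                    n_subjects_used = n)
  expect_setequal(select_model_features(rel, scr, "edss"), good)
})

test_that("ccc matches its closed forms and Monte Carlo null", {
  x <- rnorm(100)
  expect_equal(ccc(x, x), 1)
  # shift case: ccc(x, x+c) = 2v/(2v + c^2) with population v
  v <- mean((x - mean(x))^2)
  expect_equal(ccc(x, x + 1), 2 * v / (2 * v + 1), tolerance = 1e-12)
  expect_equal(ccc(x, x + 3), 2 * v / (2 * v + 9), tolerance = 1e-12)
  set.seed(32)
  expect_equal(ccc(rnorm(1e5), rnorm(1e5)), 0, tolerance = 0.01)
  expect_error(ccc(1:3, 1:2), "mismatch")
  expect_error(ccc(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("|CCC| never exceeds |Pearson r|, with equality iff calibrated", {
  set.seed(33)
  for (i in 1:200) {
    x <- rnorm(30)
    y <- runif(1, -2, 2) * x + rnorm(30, runif(1, -1, 1), runif(1, 0.1, 2))
    expect_lte(abs(ccc(x, y)), abs(cor(x, y)) + 1e-12)
  }
  x <- rnorm(50)
  expect_equal(ccc(x, x), cor(x, x))
})

test_that("the tournament rejects degenerate inputs", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(fit_and_select(X[, 1, drop = FALSE], rnorm(20)), "2 features")
  expect_error(fit_and_select(X[1:5, ], rnorm(5)), "10 training")
  expect_error(fit_and_select(X, rep(1, 20)), "zero variance")
})

test_that("dense correlated signal favors ridge/elastic-net over lasso", {
  set.seed(34)
  better <- replicate(15, {
    n <- 150; L <- rnorm(n)
    X <- sapply(1:12, function(j) L + rnorm(n, 0, 0.8))
    colnames(X) <- paste0("f", 1:12)
    y <- rowMeans(X) + rnorm(n, 0, 0.3)
    m <- fit_and_select(X, y, seed = sample.int(1e6, 1))
    tab <- m$cv_table[m$cv_table$space == "raw", ]
    mean(tab$cv_r2[tab$penalty != "lasso"]) >= tab$cv_r2[tab$penalty == "lasso"] - 0.02
  })
  expect_gte(mean(better), 0.8)
})

test_that("evaluation metrics hit their definitional anchors", {
  set.seed(35)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- X[, 1] + rnorm(n, 0, 0.2)
  itr <- 1:45
  m <- fit_and_select(X[itr, ], y[itr], seed = 1)
  # perfect predictor: overwrite the closure with the truth
  m$predict <- function(Xnew) y[-itr]
  m1 <- evaluate_model(m, X[itr, ], y[itr], X[-itr, ], y[-itr])
  expect_equal(unname(m1$metrics), c(1, 1, 1), tolerance = 1e-12)
  # constant prediction at the training mean: R^2 <= 0, CCC ~ 0
  m$predict <- function(Xnew) rep(mean(y[itr]), nrow(Xnew))
  m2 <- evaluate_model(m, X[itr, ], y[itr], X[-itr, ], y[-itr])
  expect_lte(m2$metrics[["r_squared"]], 0)
  expect_equal(m2$metrics[["ccc"]], 0)
  expect_equal(m2$metrics[["pearson_r"]], 0)
  # the best single predictor is the truly informative feature
  expect_equal(m2$best_single$feature, "f1")
})

test_that("evaluation refuses overlapping train/validation rows", {
  X <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("s", 1:30), NULL))
  y <- rnorm(30)
  m <- fit_and_select(X[1:20, ], y[1:20], seed = 1)
  expect_error(evaluate_model(m, X[1:20, ], y[1:20], X[15:30, ], y[15:30]),
               "overlap")
})

test_that("combined blocks beat single blocks when both carry signal", {
  set.seed(36)
  wins <- replicate(15, {
    n <- 150
    Ls <- rnorm(n); Ld <- rnorm(n)
    sway <- sapply(1:4, function(j) Ls + rnorm(n, 0, 0.5))
    drift <- sapply(1:4, function(j) Ld + rnorm(n, 0, 0.5))
    X <- cbind(sway, drift)
    colnames(X) <- c(paste0("s", 1:4), paste0("d", 1:4))
    y <- Ls + Ld + rnorm(n, 0, 0.4)
    itr <- sample(n, 120)
    res <- combined_test_models(paste0("s", 1:4), paste0("d", 1:4),
                                X[itr, ], y[itr], X[-itr, ], y[-itr],
                                seed = sample.int(1e6, 1))
    r2 <- res$comparison$validation_r2
    names(r2) <- res$comparison$model
    r2[["combined"]] > r2[["sway_only"]] && r2[["combined"]] > r2[["drift_only"]]
  })
  expect_gte(mean(wins), 0.8)
})

test_that("one-block outcomes make the combined model no better than the block", {
  set.seed(37)
  diffs <- replicate(10, {
    n <- 150
    Ls <- rnorm(n)
    sway <- sapply(1:4, function(j) Ls + rnorm(n, 0, 0.5))
    drift <- matrix(rnorm(n * 4), n)
    X <- cbind(sway, drift)
    colnames(X) <- c(paste0("s", 1:4), paste0("d", 1:4))
    y <- Ls + rnorm(n, 0, 0.4)
    itr <- sample(n, 120)
    res <- combined_test_models(paste0("s", 1:4), paste0("d", 1:4),
                                X[itr, ], y[itr], X[-itr, ], y[-itr],
                                seed = sample.int(1e6, 1))
    r2 <- res$comparison$validation_r2
    names(r2) <- res$comparison$model
    r2[["combined"]] - r2[["sway_only"]]
  })
  expect_lt(abs(mean(diffs)), 0.1)
})
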