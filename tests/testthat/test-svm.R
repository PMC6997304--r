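test_that("standardize centers, scales, drops zero variance, and reuses params", {
  set.seed(51)
  x <- cbind(a = rnorm(30, 5, 2), b = runif(30), const = rep(3, 30))
  expect_warning(st <- standardize(x), "zero-variance")
  expect_identical(st$dropped, "const")
  expect_equal(unname(colMeans(st$x)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(st$x, 2, sd)), c(1, 1), tolerance = 1e-12)
  # reusing training params maps new data with the training moments
  x2 <- cbind(a = rnorm(10, 5, 2), b = runif(10), const = rep(3, 10))
  st2 <- standardize(x2, params = st$params)
  expect_equal(st2$x[, "a"], (x2[, "a"] - st$center["a"]) / st$scale["a"],
               ignore_attr = TRUE)
})

test_that("one-class SVM: nu bounds the strict-outlier training fraction", {
  set.seed(52)
  x <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("u", "v", "w")))
  m <- train_ocsvm(x, nu = 0.05)
  sc <- svm_score(m, x)
  # boundary support vectors sit at numerical zero; count strict outliers
  strict <- sum(sc < -1e-2)
  expect_lte(strict / nrow(x), 0.05 + 1e-9)
  # a far-away point scores clearly negative
  far <- matrix(10, 1, 3, dimnames = list(NULL, c("u", "v", "w")))
  expect_lt(svm_score(m, far), 0)
})

test_that("one-class SVM input validation", {
  x <- matrix(rnorm(9), 3, 3)
  expect_error(train_ocsvm(x), ">= 10")
  expect_error(train_ocsvm(matrix(rnorm(60), 20, 3), nu = 1.5), "nu")
})

test_that("cost-weighted two-class SVM separates an imbalanced dataset", {
  ds <- generate_feature_dataset(n_non_broken = 140, n_broken = 12,
                                 n_noise_features = 5, seed = 7)
  m <- train_tcsvm(ds$x, ds$labels, budget = 12L, seed = 3L)
  expect_s3_class(m, "svm_model")
  expect_identical(m$minority, "broken")
  rep <- classify(m, ds$x, truth = ds$labels)
  expect_gte(rep$recall_broken_pct, 90)
  expect_gte(rep$accuracy_pct, 95)
  # class weights are inverse-frequency
  expect_gt(m$class_weights[["broken"]], m$class_weights[["non_broken"]])
})

test_that("removing the class signal drops accuracy to near chance", {
  ds <- generate_feature_dataset(n_non_broken = 60, n_broken = 30,
                                 n_noise_features = 5, effect_size = 0,
                                 seed = 9)
  m <- train_tcsvm(ds$x, ds$labels, budget = 8L, seed = 3L)
  set.seed(10)
  x_new <- generate_feature_dataset(n_non_broken = 60, n_broken = 30,
                                    n_noise_features = 5, effect_size = 0,
                                    seed = 11)
  rep <- classify(m, x_new$x, truth = x_new$labels)
  # balanced recall cannot beat chance without signal: accuracy well below
  # the separable case
  expect_lt(rep$accuracy_pct, 85)
})

test_that("svm_score enforces the training feature contract", {
  set.seed(53)
  x <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("p", "q")))
  m <- train_ocsvm(x, nu = 0.1)
  bad <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("p", "zz")))
  expect_error(svm_score(m, bad), "lacks training features")
})

test_that("classify arithmetic from precomputed scores", {
  scores <- c(2.5, 0.4, -0.2, -1.7, 1.1, -0.6)
  truth <- c("non_broken", "non_broken", "broken", "broken",
             "broken", "non_broken")
  rep <- classify(scores = scores, truth = truth)
  expect_identical(unname(rep$confusion),
                   c(2L, 1L, 2L, 1L))  # TP FP TN FN
  expect_equal(rep$accuracy_pct, 100 * 4 / 6)
  expect_equal(rep$precision_broken_pct, 100 * 2 / 3)
  expect_equal(rep$recall_broken_pct, 100 * 2 / 3)
  expect_equal(rep$fp_rate_pct, 100 * 1 / 3)
  # in-margin flag uses the closed interval [-1, 1]
  expect_identical(rep$calls$in_margin, c(FALSE, TRUE, TRUE, FALSE,
                                          FALSE, TRUE))
})

test_that("SVM JSON export round-trips the kernel parameters", {
  set.seed(54)
  x <- matrix(rnorm(80 * 2), 80, 2, dimnames = list(NULL, c("p", "q")))
  m <- train_ocsvm(x, nu = 0.02)
  f <- tempfile(fileext = ".json")
  write_svm_json(m, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(back$kind, "one_class")
  expect_equal(back$gamma, m$gamma)
  expect_equal(back$nu, m$nu)
  expect_identical(back$features, c("p", "q"))
  expect_equal(length(back$coefs), nrow(m$fit$SV))
  unlink(f)
})
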