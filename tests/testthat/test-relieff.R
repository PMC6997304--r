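test_that("relieff weights match the brute-force oracle exactly", {
  set.seed(31)
  n <- 24
  lab <- rep(c("a", "b"), c(16, 8))
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  x[lab == "b", 2] <- x[lab == "b", 2] + 2
  for (k in c(1, 3, 7)) {
    got <- relieff(x, lab, k = k)
    want <- oracle_relieff(x, lab, k)
    expect_equal(got$weights$weight, want, tolerance = 1e-12)
  }
})

test_that("informative features outrank pure noise", {
  set.seed(32)
  n <- 60
  lab <- rep(c("good", "bad"), c(45, 15))
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  x[lab == "bad", 1] <- x[lab == "bad", 1] + 3
  x[lab == "bad", 2] <- x[lab == "bad", 2] - 3
  r <- relieff(x, lab)
  expect_true(all(c("f1", "f2") %in% head(r$ranking, 3)))
  expect_gt(min(r$weights$weight[1:2]), max(r$weights$weight[3:10]))
})

test_that("default k is the smallest class count", {
  lab <- c(rep("non_broken", 854), rep("broken", 23))
  expect_identical(relieff_default_k(lab), 23L)
  expect_identical(relieff_default_k(c(broken = 23, non_broken = 854)), 23L)
})

test_that("k validation and degenerate inputs error", {
  x <- matrix(rnorm(20), 10, 2)
  lab <- rep(c("a", "b"), c(7, 3))
  expect_error(relieff(x, lab, k = 4), "smallest class size")
  expect_error(relieff(x, rep("a", 10)), "two classes")
  expect_error(relieff(x, rep(c("a", "b"), c(9, 1))), ">= 2 observations")
})

test_that("select_top_features picks the first ranked name per category", {
  reg <- feature_registry()
  # craft a fake result whose ranking starts with known category members
  shape1 <- reg$name[reg$category == "shape"][1]
  size1 <- reg$name[reg$category == "size"][1]
  surf1 <- reg$name[reg$category == "surface"][1]
  shape2 <- reg$name[reg$category == "shape"][2]
  fake <- structure(list(ranking = c(shape1, shape2, size1, surf1),
                         weights = NULL, k = 5, priors = NULL),
                    class = "relieff_result")
  sel <- select_top_features(fake)
  expect_identical(unname(sel["shape"]), shape1)
  expect_identical(unname(sel["size"]), size1)
  expect_identical(unname(sel["surface"]), surf1)
})

test_that("feature diagnostics find the discriminative feature", {
  set.seed(33)
  lab <- rep(c("a", "b"), c(30, 10))
  x <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("f", 1:4)))
  x[lab == "b", 3] <- x[lab == "b", 3] + 4
  d <- feature_diagnostics(x, lab)
  expect_identical(d$feature[which.max(d$f_score)], "f3")
  expect_identical(d$feature[which.min(d$p_value)], "f3")
})
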