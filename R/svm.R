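# ---------------------------------------------------------------------------
# One-class and two-class RBF support vector machines for broken-pellet
# detection, with feature standardization, cost weighting for the class
# imbalance, and Bayesian hyperparameter selection for the two-class model.
# The quadratic programs are solved by libsvm (via e1071); the model
# contract here fixes standardization, score orientation (positive =
# non-broken / inlier, negative = broken / outlier) and the [-1, 1] margin.

#' Standardize a feature table
#'
#' Per-feature zero mean and unit standard deviation on the training data;
#' zero-variance features are dropped with a warning. The returned
#' parameters must be reused verbatim on test data (no leakage).
#'
#' @param x Numeric matrix or data.frame.
#' @param params Optional previously computed parameters to apply.
#' @return List with `x` (standardized matrix), `center`, `scale`,
#'   `dropped` (names of removed features).
#' @export
standardize <- function(x, params = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(params)) {
    sdv <- apply(x, 2, sd)
    dropped <- colnames(x)[sdv == 0]
    if (length(dropped))
      warning(sprintf("dropping %d zero-variance feature(s): %s",
                      length(dropped), paste(dropped, collapse = ", ")),
              call. = FALSE)
    keep <- sdv > 0
    x <- x[, keep, drop = FALSE]
    center <- colMeans(x)
    scale <- sdv[keep]
    params <- list(center = center, scale = scale, dropped = dropped)
  } else {
    x <- x[, names(params$center), drop = FALSE]
  }
  xs <- sweep(sweep(x, 2, params$center), 2, params$scale, "/")
  list(x = xs, center = params$center, scale = params$scale,
       dropped = params$dropped, params = params)
}

#' Train a one-class SVM on the majority class
#'
#' RBF one-class model trained on non-broken pellets only, drawing a tight
#' decision boundary around the majority population; observations outside
#' score negative. The nu parameter bounds the training outlier fraction.
#'
#' @param x Feature matrix of majority-class observations (unstandardized;
#'   standardization is handled internally and stored).
#' @param nu Upper bound on the training outlier fraction (default 0.01 for
#'   a tight, outlier-sensitive boundary).
#' @param gamma RBF kernel coefficient; default `1 / n_features` on the
#'   standardized scale.
#' @return An `svm_model` (kind `"one_class"`).
#' @export
train_ocsvm <- function(x, nu = 0.01, gamma = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 10) stop("need >= 10 training observations", call. = FALSE)
  if (nu <= 0 || nu >= 1) stop("nu must be in (0, 1)", call. = FALSE)
  st <- standardize(x)
  if (is.null(gamma)) gamma <- 1 / ncol(st$x)
  fit <- e1071::svm(st$x, y = NULL, type = "one-classification",
                    kernel = "radial", nu = nu, gamma = gamma,
                    scale = FALSE)
  structure(list(kind = "one_class", fit = fit, standardize = st$params,
                 nu = nu, gamma = gamma,
                 features = colnames(st$x)),
            class = "svm_model")
}

#' Train a cost-weighted two-class SVM
#'
#' Soft-margin RBF SVM with per-class misclassification costs inversely
#' proportional to the class frequencies (so errors on the rare broken
#' class are penalized ~n_majority/n_minority times harder, shifting the
#' separating hyperplane towards the majority class). The box constraint
#' and kernel scale are selected by Bayesian optimization (Gaussian-process
#' surrogate, expected improvement, 30 evaluations) of the weighted
#' misclassification loss under stratified 4-fold cross-validation;
#' seed-reproducible.
#'
#' @param x Feature matrix.
#' @param labels Binary labels; the rarer level is treated as "broken".
#' @param priors Optional named class prior weights for the costs; default
#'   inverse class frequencies normalized to mean 1.
#' @param cv_folds Cross-validation folds.
#' @param budget Bayesian-optimization evaluations.
#' @param seed Integer seed.
#' @return An `svm_model` (kind `"two_class"`) with the selected
#'   hyperparameters in `box_constraint` and `kernel_gamma`.
#' @export
train_tcsvm <- function(x, labels, priors = NULL, cv_folds = 4L,
                        budget = 30L, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) == 1)
    stop("single-class input: use train_ocsvm for one-class modelling",
         call. = FALSE)
  stopifnot(nlevels(labels) == 2)
  st <- standardize(x)
  counts <- table(labels)
  if (is.null(priors)) {
    w <- as.numeric(sum(counts)) / (2 * as.numeric(counts))
    names(w) <- names(counts)
  } else {
    w <- priors[levels(labels)]
  }

  cv_loss <- function(log10C, log10gamma) {
    C <- 10^log10C; gam <- 10^log10gamma
    set.seed(seed)
    folds <- stratified_folds(labels, cv_folds)
    loss <- 0
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      fit <- tryCatch(
        e1071::svm(st$x[tr, , drop = FALSE], labels[tr], type = "C-classification",
                   kernel = "radial", cost = C, gamma = gam,
                   class.weights = w, scale = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) return(1)
      pred <- predict(fit, st$x[!tr, , drop = FALSE])
      err <- pred != labels[!tr]
      loss <- loss + sum(w[as.character(labels[!tr])] * err)
    }
    loss / sum(w[as.character(labels)])
  }

  opt <- bayes_optimize(cv_loss,
                        lower = c(-3, -2), upper = c(3, 2),
                        budget = budget, seed = seed)
  C <- 10^opt$par[1]; gam <- 10^opt$par[2]
  fit <- e1071::svm(st$x, labels, type = "C-classification",
                    kernel = "radial", cost = C, gamma = gam,
                    class.weights = w, scale = FALSE)
  # orient scores: positive for the majority (non-broken) class
  majority <- names(counts)[which.max(counts)]
  dv <- attr(predict(fit, st$x, decision.values = TRUE), "decision.values")
  dv_class <- colnames(dv)[1]  # "A/B": positive scores favor class A
  flip <- !startsWith(dv_class, paste0(majority, "/"))
  structure(list(kind = "two_class", fit = fit, standardize = st$params,
                 box_constraint = C, kernel_gamma = gam,
                 class_weights = w, majority = majority,
                 minority = names(counts)[which.min(counts)],
                 flip_score = flip, cv_loss = opt$value,
                 features = colnames(st$x)),
            class = "svm_model")
}

stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> %s RBF\n", x$kind))
  if (x$kind == "two_class")
    cat(sprintf("  box constraint %.4g, kernel gamma %.4g, CV loss %.4g\n",
                x$box_constraint, x$kernel_gamma, x$cv_loss))
  else
    cat(sprintf("  nu %.3g, gamma %.4g\n", x$nu, x$gamma))
  invisible(x)
}

#' SVM decision scores
#'
#' Scores follow the hyperplane contract: 0 on the optimal separating
#' hyperplane, the margin at scores in \[-1, 1\]; positive scores are
#' non-broken / inlier.
#'
#' @param model An `svm_model`.
#' @param x Feature matrix on the original (unstandardized) scale.
#' @return Numeric score vector.
#' @export
svm_score <- function(model, x) {
  x <- as.matrix(x)
  missing <- setdiff(model$features, colnames(x))
  if (length(missing))
    stop(sprintf("test table lacks training features: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  xs <- standardize(x[, model$features, drop = FALSE],
                    params = model$standardize)$x
  pred <- predict(model$fit, xs, decision.values = TRUE)
  dv <- as.numeric(attr(pred, "decision.values"))
  if (isTRUE(model$flip_score)) dv <- -dv
  dv
}

#' Classify pellets and report metrics
#'
#' Labels by score sign (negative = broken), flags observations inside the
#' closed margin interval \[-1, 1\] for review, and computes confusion
#' counts, accuracy and per-class precision/recall when true labels are
#' given.
#'
#' @param model An `svm_model`, or NULL when `scores` are supplied
#'   directly.
#' @param x Feature matrix (ignored when `scores` given).
#' @param truth Optional true labels (`"broken"` / `"non_broken"` or the
#'   training levels).
#' @param scores Optional precomputed score vector.
#' @param broken_label Label naming the broken class in `truth`.
#' @return A `classification_report`: data.frame `calls` (score, predicted,
#'   in_margin), and when truth is given `confusion`, `accuracy_pct`,
#'   `precision_broken_pct`, `recall_broken_pct`, `fp_rate_pct`,
#'   `margin_counts`.
#' @export
classify <- function(model = NULL, x = NULL, truth = NULL, scores = NULL,
                     broken_label = "broken") {
  if (is.null(scores)) scores <- svm_score(model, x)
  predicted <- ifelse(scores >= 0, "non_broken", "broken")
  in_margin <- scores >= -1 & scores <= 1
  calls <- data.frame(score = scores, predicted = predicted,
                      in_margin = in_margin)
  out <- list(calls = calls)
  if (!is.null(truth)) {
    truth_b <- ifelse(as.character(truth) == broken_label,
                      "broken", "non_broken")
    tp <- sum(predicted == "broken" & truth_b == "broken")
    fp <- sum(predicted == "broken" & truth_b == "non_broken")
    tn <- sum(predicted == "non_broken" & truth_b == "non_broken")
    fn <- sum(predicted == "non_broken" & truth_b == "broken")
    out$confusion <- c(TP = tp, FP = fp, TN = tn, FN = fn)
    out$accuracy_pct <- 100 * (tp + tn) / length(scores)
    out$precision_broken_pct <- if (tp + fp > 0) 100 * tp / (tp + fp)
    else NA_real_
    out$recall_broken_pct <- if (tp + fn > 0) 100 * tp / (tp + fn)
    else NA_real_
    out$fp_rate_pct <- if (fp + tn > 0) 100 * fp / (fp + tn) else NA_real_
    out$margin_counts <- c(
      non_broken = sum(in_margin & truth_b == "non_broken"),
      broken = sum(in_margin & truth_b == "broken"))
  }
  structure(out, class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> n = %d, in margin = %d\n",
              nrow(x$calls), sum(x$calls$in_margin)))
  if (!is.null(x$confusion)) {
    cat(sprintf("  accuracy %.2f%%, broken precision %.2f%%, recall %.2f%%, FP rate %.2f%%\n",
                x$accuracy_pct, x$precision_broken_pct, x$recall_broken_pct,
                x$fp_rate_pct))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Minimal Gaussian-process Bayesian optimizer (expected improvement) for the
# 2-parameter SVM search. Inputs are scaled to [0, 1]^d; the surrogate uses
# a squared-exponential kernel with fixed length-scale 0.2 and a small
# nugget; EI is maximized over a random candidate set. Deterministic per
# seed.
bayes_optimize <- function(fn, lower, upper, budget = 30L, n_init = 8L,
                           seed = 1L) {
  d <- length(lower)
  set.seed(seed)
  X01 <- lhs::randomLHS(n_init, d)
  unscale <- function(u) lower + u * (upper - lower)
  X <- t(apply(X01, 1, unscale))
  y <- apply(X, 1, function(p) fn(p[1], p[2]))
  ell <- 0.2; nug <- 1e-6
  kern <- function(A, B) {
    D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    exp(-0.5 * pmax(D2, 0) / ell^2)
  }
  while (length(y) < budget) {
    mu_y <- mean(y); sd_y <- max(sd(y), 1e-9)
    yn <- (y - mu_y) / sd_y
    K <- kern(X01, X01) + diag(nug, nrow(X01))
    Ki <- tryCatch(solve(K), error = function(e) NULL)
    if (is.null(Ki)) { nug <- nug * 10; next }
    cand <- matrix(runif(500 * d), ncol = d)
    ks <- kern(cand, X01)
    mu <- as.numeric(ks %*% Ki %*% yn)
    var_c <- pmax(1 - rowSums((ks %*% Ki) * ks), 1e-12)
    s <- sqrt(var_c)
    best <- min(yn)
    z <- (best - mu) / s
    ei <- s * (z * pnorm(z) + dnorm(z))
    pick <- cand[which.max(ei), , drop = FALSE]
    X01 <- rbind(X01, pick)
    pnew <- unscale(as.numeric(pick))
    X <- rbind(X, pnew)
    y <- c(y, fn(pnew[1], pnew[2]))
  }
  i <- which.min(y)
  list(par = X[i, ], value = y[i], X = X, y = y)
}

#' @importFrom stats dnorm pnorm predict
NULL

#' Serialize an SVM model to JSON
#'
#' Stores kind, kernel parameters, standardization and support-vector data
#' so a model can be archived alongside its report.
#'
#' @param model An `svm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svm_json <- function(model, path) {
  obj <- list(kind = model$kind,
              features = model$features,
              standardize = model$standardize,
              gamma = if (model$kind == "one_class") model$gamma
              else model$kernel_gamma,
              nu = model$nu,
              box_constraint = model$box_constraint,
              support_vectors = unname(as.matrix(model$fit$SV)),
              coefs = as.numeric(model$fit$coefs),
              rho = model$fit$rho)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
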