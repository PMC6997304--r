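# ---------------------------------------------------------------------------
# ReliefF feature weighting for binary (or multi-class) labelled feature
# tables. Every observation serves as an anchor (m = n); for each anchor the
# k nearest hits (same class) and k nearest misses per other class update
# the feature weights, with misses weighted by the class prior renormalized
# over the non-anchor classes. diff() is the range-normalized absolute
# difference, so weights live in [-1, 1].

#' ReliefF feature ranking
#'
#' @param x Numeric matrix or data.frame (observations x features).
#' @param labels Class labels (length `nrow(x)`).
#' @param k Number of nearest neighbors per class; must not exceed the
#'   smallest class count. When the anchor's own class offers fewer than
#'   `k` other members, all of them are used and the update is normalized
#'   by the actual neighbor count. Defaults to [relieff_default_k()] of
#'   the labels.
#' @return A `relieff_result`: data.frame `weights` (feature, weight, rank),
#'   `ranking` (feature names by descending weight), `k`, `priors`.
#' @export
relieff <- function(x, labels, k = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop("need at least two classes", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2)) stop("need >= 2 observations per class", call. = FALSE)
  if (is.null(k)) k <- relieff_default_k(labels)
  if (k > min(counts))
    stop(sprintf("k = %d exceeds the smallest class size (%d)",
                 k, min(counts)), call. = FALSE)
  n <- nrow(x); p <- ncol(x)
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1  # constant features contribute zero diff anyway
  xn <- sweep(sweep(x, 2, apply(x, 2, min)), 2, rng, "/")
  priors <- as.numeric(counts[cls]) / n
  names(priors) <- cls

  W <- numeric(p)
  idx_by_class <- split(seq_len(n), labels)
  for (i in seq_len(n)) {
    di <- colSums(abs(t(xn) - xn[i, ]))  # Manhattan distance to all
    ci <- labels[i]
    hits <- idx_by_class[[ci]]
    hits <- hits[hits != i]
    kh <- min(k, length(hits))  # anchor's own class has one fewer candidate
    hits <- hits[order(di[hits])][seq_len(kh)]
    W <- W - colSums(abs(xn[hits, , drop = FALSE] -
                           matrix(xn[i, ], kh, p, byrow = TRUE))) / (n * kh)
    for (cm in setdiff(cls, ci)) {
      miss <- idx_by_class[[cm]]
      km <- min(k, length(miss))
      miss <- miss[order(di[miss])][seq_len(km)]
      wclass <- priors[[cm]] / (1 - priors[[ci]])
      W <- W + wclass *
        colSums(abs(xn[miss, , drop = FALSE] -
                      matrix(xn[i, ], km, p, byrow = TRUE))) / (n * km)
    }
  }
  fn <- colnames(x)
  if (is.null(fn)) fn <- paste0("f", seq_len(p))
  ord <- order(W, decreasing = TRUE)
  weights <- data.frame(feature = fn, weight = W,
                        rank = match(seq_len(p), ord))
  structure(list(weights = weights, ranking = fn[ord], k = k,
                 priors = priors),
            class = "relieff_result")
}

#' Default ReliefF neighbor count
#'
#' The largest k that still provides class balance: the size of the
#' smallest class.
#'
#' @param labels Class label vector, or a named vector of class counts.
#' @return Integer k.
#' @export
#' @examples
#' relieff_default_k(c(rep("non_broken", 854), rep("broken", 23)))  # 23
relieff_default_k <- function(labels) {
  counts <- if (is.numeric(labels)) labels else table(labels)
  as.integer(min(counts))
}

#' @export
print.relieff_result <- function(x, ...) {
  cat(sprintf("<relieff_result> %d features, k = %d\n",
              nrow(x$weights), x$k))
  cat("top 5:", paste(head(x$ranking, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Select the top-ranked feature per structural category
#'
#' Walks the ReliefF ranking and keeps the first (highest-weight) feature
#' encountered in each requested registry category, emulating the selection
#' of one shape, one size and one surface descriptor for classification.
#'
#' @param relieff_result A `relieff_result`.
#' @param categories Categories to cover, in order.
#' @param registry Feature registry providing the category tags.
#' @return Named character vector (category -> feature name).
#' @export
select_top_features <- function(relieff_result,
                                categories = c("shape", "size", "surface"),
                                registry = feature_registry()) {
  stopifnot(inherits(relieff_result, "relieff_result"))
  cat_of <- setNames(registry$category, registry$name)
  out <- setNames(rep(NA_character_, length(categories)), categories)
  for (f in relieff_result$ranking) {
    cc <- cat_of[[f]]
    if (is.null(cc) || is.na(cc)) next
    if (cc %in% categories && is.na(out[[cc]])) out[[cc]] <- f
    if (!anyNA(out)) break
  }
  out
}

#' Per-feature univariate diagnostics
#'
#' Optional side rankings: Welch two-sample t-test p-values and the
#' standard F-score for binary discrimination,
#' `(m1 - m)^2 + (m2 - m)^2` over `s1^2 + s2^2` (class means/variances).
#'
#' @param x Feature matrix.
#' @param labels Binary class labels.
#' @return data.frame with `feature`, `p_value`, `f_score`.
#' @export
feature_diagnostics <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  stopifnot(length(cls) == 2)
  a <- x[labels == cls[1], , drop = FALSE]
  b <- x[labels == cls[2], , drop = FALSE]
  p <- vapply(seq_len(ncol(x)), function(j) {
    if (var(a[, j]) == 0 && var(b[, j]) == 0) return(1)
    t.test(a[, j], b[, j])$p.value
  }, numeric(1))
  m <- colMeans(x); ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, var); vb <- apply(b, 2, var)
  fs <- ((ma - m)^2 + (mb - m)^2) / (va + vb)
  fs[!is.finite(fs)] <- 0
  data.frame(feature = colnames(x), p_value = p, f_score = fs)
}
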