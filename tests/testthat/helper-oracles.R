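# Brute-force reference implementations (oracles). Deliberately naive and
# independent of the package internals; used to pin the optimized routes.

# squared EDT by exhaustive nearest-background search
oracle_edt_sq <- function(mask) {
  d <- dim(mask)
  bg <- which(!mask)
  out <- array(0, d)
  if (!length(bg)) { out[] <- Inf; return(out) }
  bco <- arrayInd(bg, d)
  fg <- which(mask)
  fco <- arrayInd(fg, d)
  for (i in seq_along(fg)) {
    dd <- (bco[, 1] - fco[i, 1])^2 + (bco[, 2] - fco[i, 2])^2 +
      (bco[, 3] - fco[i, 3])^2
    out[fg[i]] <- min(dd)
  }
  out
}

# raw and central image moments up to order 2 on 0-based voxel centers
oracle_moments <- function(mask) {
  co <- arrayInd(which(mask), dim(mask)) - 1
  n <- nrow(co)
  cen <- colMeans(co)
  cc <- sweep(co, 2, cen)
  list(n = n, centroid = cen,
       cov = crossprod(cc) / n)
}

# textbook ReliefF with m = n anchors, priors-weighted misses,
# range-normalized Manhattan diff
oracle_relieff <- function(x, labels, k) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  xn <- sweep(sweep(x, 2, apply(x, 2, min)), 2, rng, "/")
  priors <- table(labels)[cls] / n
  W <- numeric(p)
  for (i in seq_len(n)) {
    di <- colSums(abs(t(xn) - xn[i, ]))
    ci <- labels[i]
    hit_pool <- setdiff(which(labels == ci), i)
    kh <- min(k, length(hit_pool))
    hits <- hit_pool[order(di[hit_pool])][seq_len(kh)]
    for (h in hits) W <- W - abs(xn[h, ] - xn[i, ]) / (n * kh)
    for (cm in setdiff(cls, ci)) {
      miss_pool <- which(labels == cm)
      km <- min(k, length(miss_pool))
      miss <- miss_pool[order(di[miss_pool])][seq_len(km)]
      wc <- priors[[cm]] / (1 - priors[[ci]])
      for (mi in miss) W <- W + wc * abs(xn[mi, ] - xn[i, ]) / (n * km)
    }
  }
  unname(W)
}

# exhaustive 256-level threshold scan maximizing between-class variance
oracle_otsu <- function(v) {
  edges <- seq(min(v), max(v), length.out = 257)
  h <- hist(v, breaks = edges, plot = FALSE)$counts
  n <- sum(h); mids <- (edges[-1] + edges[-257]) / 2
  v2 <- rep(-Inf, 255)
  for (t in 1:255) {
    w0 <- sum(h[1:t]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:t] * mids[1:t]) / w0
    m1 <- sum(h[(t + 1):256] * mids[(t + 1):256]) / w1
    v2[t] <- w0 * w1 * (m0 - m1)^2
  }
  # center of the argmax plateau, matching threshold_histogram()
  ties <- which(v2 >= max(v2) - abs(max(v2)) * 1e-10)
  mean(edges[ties + 1])
}
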