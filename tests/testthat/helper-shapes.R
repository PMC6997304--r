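# Synthetic shape constructors shared across tests. All fixtures are
# generated in code; nothing binary ships with the package.

# digital ball: voxel centers within radius r of the center (1-based)
make_ball <- function(r, dims = rep(2L * ceiling(r) + 7L, 3L),
                      center = (dims + 1) / 2) {
  arr <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    dz2 <- (k - center[3])^2
    sl <- outer((seq_len(dims[1]) - center[1])^2,
                (seq_len(dims[2]) - center[2])^2, "+") + dz2
    arr[, , k] <- sl <= r^2
  }
  arr
}

# axis-aligned digital ellipsoid with semi-axes a >= b >= c
make_ellipsoid <- function(a, b, c,
                           dims = 2L * ceiling(c(a, b, c)) + 9L,
                           center = (dims + 1) / 2) {
  arr <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    dz2 <- ((k - center[3]) / c)^2
    sl <- outer(((seq_len(dims[1]) - center[1]) / a)^2,
                ((seq_len(dims[2]) - center[2]) / b)^2, "+") + dz2
    arr[, , k] <- sl <= 1
  }
  arr
}

# rotated digital ellipsoid: voxel center is foreground when its rotated
# coordinate lies inside the canonical ellipsoid
make_rotated_ellipsoid <- function(a, b, c, R, dims, center = (dims + 1) / 2) {
  arr <- array(FALSE, dims)
  ax <- c(a, b, c)
  for (k in seq_len(dims[3])) {
    for (j in seq_len(dims[2])) {
      v <- rbind(seq_len(dims[1]) - center[1],
                 rep(j - center[2], dims[1]),
                 rep(k - center[3], dims[1]))
      q <- crossprod(R, v) / ax  # body-frame coords scaled by semi-axes
      arr[, j, k] <- colSums(q^2) <= 1
    }
  }
  arr
}

# rotation matrix about a unit axis by angle (radians)
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# two touching digital balls along x
make_touching_balls <- function(r, gap = -1) {
  sep <- 2 * r + gap
  dims <- c(as.integer(ceiling(2 * r + sep)) + 12L,
            2L * ceiling(r) + 9L, 2L * ceiling(r) + 9L)
  c1 <- c(ceiling(r) + 6, (dims[2] + 1) / 2, (dims[3] + 1) / 2)
  c2 <- c1 + c(sep, 0, 0)
  arr <- make_ball(r, dims, c1) | make_ball(r, dims, c2)
  list(mask = arr, centers = rbind(c1, c2))
}
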