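# shared fixtures built in code

# scheme with axis-aligned and diagonal directions: convenient for
# closed-form signal checks (full-rank design)
axisScheme <- function(b = 1000, s0rows = 1) {
  s2 <- 1 / sqrt(2)
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(s2, s2, 0), c(s2, 0, s2), c(0, s2, s2))
  gradientScheme(c(rep(0, s0rows), rep(b, nrow(dirs))),
                 rbind(matrix(0, s0rows, 3), dirs))
}

# small tensor field built from a list of 3x3 matrices (in-plane grid)
fieldFromTensors <- function(tensorList, nx, ny, nz = 1) {
  stopifnot(length(tensorList) == nx * ny * nz)
  arr <- array(0, c(nx, ny, nz, 6))
  k <- 0
  for (z in seq_len(nz)) for (y in seq_len(ny)) for (x in seq_len(nx)) {
    k <- k + 1
    m <- tensorList[[k]]
    arr[x, y, z, ] <- c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
  }
  tensorField(arr)
}

# random symmetric positive-definite tensor with eigenvalues in [lo, hi]
randomTensor <- function(lo = 0.2, hi = 2.5) {
  ev <- sort(runif(3, lo, hi), decreasing = TRUE)
  a <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(a))
  m <- q %*% diag(ev) %*% t(q)
  (m + t(m)) / 2
}

# random 3D rotation matrix
randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
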