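# Shared fixtures and independent oracles for the test suite.

random_states <- function(n, seed = 1L, lim = 10) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    state_q(runif(1, -lim, lim), runif(1, -lim, lim),
            runif(1, -lim, lim), runif(1, -lim, lim))
  })
}

# central finite-difference Jacobian of a frame field, column j = d/dq_j
fd_frame_jacobian <- function(i, q, h = 1e-5) {
  v <- as.numeric(unclass(q))
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    e <- numeric(4); e[j] <- h
    J[, j] <- (frame_field(i, v + e) - frame_field(i, v - e)) / (2 * h)
  }
  J
}

# finite-difference bracket oracle: [X_i, X_j] = DX_j X_i - DX_i X_j
fd_bracket <- function(i, j, q, h = 1e-5) {
  drop(fd_frame_jacobian(j, q, h) %*% frame_field(i, q) -
       fd_frame_jacobian(i, q, h) %*% frame_field(j, q))
}

# distance from a point to a polyline (segment-projected, not vertex-only)
dist_to_polyline <- function(px, py, X, Y) {
  ax <- X[-length(X)]; ay <- Y[-length(Y)]
  bx <- X[-1L]; by <- Y[-1L]
  dx <- bx - ax; dy <- by - ay
  L2 <- dx^2 + dy^2
  t <- pmin(pmax(((px - ax) * dx + (py - ay) * dy) / pmax(L2, 1e-300), 0), 1)
  min(sqrt((ax + t * dx - px)^2 + (ay + t * dy - py)^2))
}

max_deviation_from_truth <- function(completed, truth) {
  max(vapply(seq_len(nrow(completed)), function(i) {
    dist_to_polyline(completed$x[i], completed$y[i], truth$x, truth$y)
  }, numeric(1)))
}
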