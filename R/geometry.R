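#' Construct a state of the position-orientation-curvature space M
#'
#' A point of the configuration space \eqn{M = R^2 \times SO(2) \times R}
#' records a planar position \eqn{(x, y)}, a local orientation \eqn{\theta}
#' and a signed curvature \eqn{k}.  Orientations are stored as unwrapped
#' reals; wrapping modulo \eqn{2\pi} happens only when states are compared
#' (see [state_equal()]), so that trajectories of the extremal flows stay
#' smooth in memory.
#'
#' The curvature is signed relative to the direction of travel
#' \eqn{\theta}: positive \eqn{k} bends the planar projection
#' counter-clockwise when moving forward (\eqn{\dot\theta = k u_1}).
#'
#' @param x,y planar position (length units).
#' @param theta orientation angle in radians, unwrapped.
#' @param k signed curvature (inverse length units).
#' @return A named numeric vector of class `"state_q"` with components
#'   `x`, `y`, `theta`, `k`.
#' @examples
#' q <- state_q(1, 0, pi / 4, -0.5)
#' frame_field(1, q)
#' @export
state_q <- function(x, y, theta, k) {
  q <- c(x = as.numeric(x), y = as.numeric(y),
         theta = as.numeric(theta), k = as.numeric(k))
  if (!all(is.finite(q))) stop("state components must be finite reals")
  class(q) <- "state_q"
  q
}

#' @export
print.state_q <- function(x, ...) {
  cat(sprintf("<state_q>  x = %g  y = %g  theta = %g  k = %g\n",
              x[["x"]], x[["y"]], x[["theta"]], x[["k"]]))
  invisible(x)
}

# accept either a state_q or a plain numeric of length 4 (x, y, theta, k)
as_state_vec <- function(q) {
  v <- unname(as.numeric(q))
  if (length(v) != 4L || !all(is.finite(v)))
    stop("expected a finite state (x, y, theta, k)")
  v
}

#' Compare two states, with orientation taken modulo 2*pi
#'
#' @param q1,q2 states ([state_q()] or numeric length-4 vectors).
#' @param tol absolute tolerance per component.
#' @return `TRUE` if positions, curvatures and wrapped orientations all
#'   agree within `tol`.
#' @export
state_equal <- function(q1, q2, tol = 1e-9) {
  a <- as_state_vec(q1); b <- as_state_vec(q2)
  dth <- angle_diff(a[3], b[3])
  all(abs(a[c(1, 2, 4)] - b[c(1, 2, 4)]) <= tol) && abs(dth) <= tol
}

# signed angular difference wrapped to (-pi, pi]
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Frame vector fields of the contour-lifting control system
#'
#' The control system \eqn{\dot q = u_1 X_1 + u_2 X_2} on \eqn{M} has
#' \deqn{X_1 = (\cos\theta, \sin\theta, k, 0), \quad X_2 = (0, 0, 0, 1),}
#' and the iterated Lie brackets
#' \deqn{X_3 = [X_1, X_2] = (0, 0, -1, 0), \quad
#'       X_4 = [X_1, X_3] = (-\sin\theta, \cos\theta, 0, 0)}
#' complete them to a global frame of the tangent bundle.
#'
#' @param i field index in 1..4.
#' @param q state at which to evaluate.
#' @return Numeric length-4 vector: components in the coordinate basis
#'   \eqn{(\partial_x, \partial_y, \partial_\theta, \partial_k)}.
#' @seealso [lie_bracket()], [frame_determinant()], [growth_vector()]
#' @export
frame_field <- function(i, q) {
  v <- as_state_vec(q)
  th <- v[3]; k <- v[4]
  if (!(length(i) == 1L && i %in% 1:4))
    stop("frame field index must be a single integer in 1..4")
  switch(i,
         c(cos(th), sin(th), k, 0),
         c(0, 0, 0, 1),
         c(0, 0, -1, 0),
         c(-sin(th), cos(th), 0, 0))
}

# analytic Jacobian d X_i / d(x, y, theta, k), 4 x 4
frame_jacobian <- function(i, q) {
  v <- as_state_vec(q)
  th <- v[3]
  J <- matrix(0, 4, 4)
  if (i == 1L) {
    J[, 3] <- c(-sin(th), cos(th), 0, 0)  # d X1 / d theta
    J[, 4] <- c(0, 0, 1, 0)               # d X1 / d k
  } else if (i == 4L) {
    J[, 3] <- c(-cos(th), -sin(th), 0, 0) # d X4 / d theta
  }
  J
}

#' Lie bracket of two frame fields, evaluated analytically
#'
#' Computes the Jacobi--Lie bracket \eqn{[X_i, X_j] = DX_j\,X_i - DX_i\,X_j}
#' from the closed-form coordinate expressions of the frame (analytic
#' differentiation, no finite differences).
#'
#' @param i,j field indices in 1..4.
#' @param q state at which to evaluate.
#' @return Numeric length-4 vector.
#' @examples
#' lie_bracket(1, 2, state_q(0, 0, 0.3, 2))  # equals frame_field(3, .)
#' @export
lie_bracket <- function(i, j, q) {
  if (!(length(i) == 1L && i %in% 1:4) || !(length(j) == 1L && j %in% 1:4))
    stop("bracket indices must be single integers in 1..4")
  Xi <- frame_field(i, q)
  Xj <- frame_field(j, q)
  drop(frame_jacobian(j, q) %*% Xi - frame_jacobian(i, q) %*% Xj)
}

# the 4x4 matrix with columns X1..X4 at q
frame_matrix <- function(q) {
  vapply(1:4, frame_field, numeric(4), q = q)
}

#' Determinant of the frame matrix
#'
#' The determinant of the \eqn{4 \times 4} matrix with columns
#' \eqn{X_1, X_2, X_3, X_4} is identically 1, so the frame trivializes the
#' tangent bundle of \eqn{M} and the distribution
#' \eqn{\Delta = \mathrm{span}(X_1, X_2)} is bracket-generating everywhere.
#'
#' @param q state.
#' @return The determinant (equal to 1 for every state, up to rounding).
#' @export
frame_determinant <- function(q) {
  det(frame_matrix(q))
}

#' Growth vector of the contour-lifting distribution
#'
#' Numerical ranks of the nested spans
#' \eqn{\mathrm{span}(X_1, X_2) \subset \mathrm{span}(X_1, X_2, X_3)
#' \subset \mathrm{span}(X_1, \ldots, X_4)} at a state.  The distribution
#' is of Engel type: the growth vector is \eqn{(2, 3, 4)} at every point.
#'
#' @param q state.
#' @param tol relative singular-value threshold for the numerical rank
#'   (singular values below `tol` times the largest are treated as zero).
#' @return Integer vector of length 3.
#' @export
growth_vector <- function(q, tol = 1e-9) {
  stopifnot(tol > 0)
  M <- frame_matrix(q)
  vapply(2:4, function(m) num_rank(M[, seq_len(m), drop = FALSE], tol),
         integer(1))
}

num_rank <- function(A, tol = 1e-9) {
  s <- svd(A, nu = 0, nv = 0)$d
  if (s[1] == 0) return(0L)
  sum(s > tol * s[1])
}

## ---- SE(2) symmetry ------------------------------------------------------

#' Roto-translations of the plane acting on M
#'
#' The control system is invariant under the group SE(2) of planar
#' rotations and translations acting on \eqn{(x, y, \theta)} and fixing
#' \eqn{k}.  An element is stored as `(tx, ty, phi)` and acts by rotating
#' about the origin by `phi` first, then translating by `(tx, ty)`.
#'
#' @param tx,ty translation components.
#' @param phi rotation angle in radians.
#' @return A named numeric vector of class `"se2"`.
#' @seealso [apply_se2()], [se2_compose()], [normalizing_transform()]
#' @export
se2 <- function(tx = 0, ty = 0, phi = 0) {
  g <- c(tx = as.numeric(tx), ty = as.numeric(ty), phi = as.numeric(phi))
  if (!all(is.finite(g))) stop("group element components must be finite")
  class(g) <- "se2"
  g
}

#' @rdname se2
#' @export
se2_identity <- function() se2(0, 0, 0)

#' Compose two roto-translations
#'
#' `se2_compose(g2, g1)` is the element acting as `g2` after `g1`.
#'
#' @param g2,g1 elements created by [se2()].
#' @return An `"se2"` element.
#' @export
se2_compose <- function(g2, g1) {
  c2 <- cos(g2[["phi"]]); s2 <- sin(g2[["phi"]])
  se2(c2 * g1[["tx"]] - s2 * g1[["ty"]] + g2[["tx"]],
      s2 * g1[["tx"]] + c2 * g1[["ty"]] + g2[["ty"]],
      g1[["phi"]] + g2[["phi"]])
}

#' Inverse of a roto-translation
#' @param g an element created by [se2()].
#' @return The element undoing `g`.
#' @export
se2_inverse <- function(g) {
  cphi <- cos(g[["phi"]]); sphi <- sin(g[["phi"]])
  se2(-(cphi * g[["tx"]] + sphi * g[["ty"]]),
      -(-sphi * g[["tx"]] + cphi * g[["ty"]]),
      -g[["phi"]])
}

#' Apply a roto-translation to a state of M
#'
#' Rotates the position by `phi` about the origin, translates it by
#' `(tx, ty)`, increments the orientation by `phi` and leaves the
#' curvature unchanged.
#'
#' @param g an [se2()] element.
#' @param q a state.
#' @return A [state_q()].
#' @export
apply_se2 <- function(g, q) {
  v <- as_state_vec(q)
  cphi <- cos(g[["phi"]]); sphi <- sin(g[["phi"]])
  state_q(cphi * v[1] - sphi * v[2] + g[["tx"]],
          sphi * v[1] + cphi * v[2] + g[["ty"]],
          v[3] + g[["phi"]],
          v[4])
}

#' Roto-translation carrying a state to the normalized frame
#'
#' Returns the unique SE(2) element `g` with
#' `apply_se2(g, q0) = (0, 0, 0, k0)` (orientation compared modulo
#' \eqn{2\pi}).  Two-point boundary-value problems are solved in this
#' normalized frame and mapped back, exploiting the roto-translation
#' invariance of the model.
#'
#' @param q0 state to normalize.
#' @return An `"se2"` element.
#' @export
normalizing_transform <- function(q0) {
  v <- as_state_vec(q0)
  phi <- -v[3]
  se2(-(cos(phi) * v[1] - sin(phi) * v[2]),
      -(sin(phi) * v[1] + cos(phi) * v[2]),
      phi)
}
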