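#' Momenta along the frame from canonical covector components
#'
#' The Pontryagin covector can be written either in canonical Darboux
#' coordinates \eqn{(a, b, c, d)} (momenta conjugate to
#' \eqn{x, y, \theta, k}) or as the bracket-adapted momenta
#' \eqn{h_i = \langle p, X_i\rangle}.  The conversion at a state with
#' orientation \eqn{\theta} and curvature \eqn{k} is
#' \deqn{h_1 = a\cos\theta + b\sin\theta + ck,\; h_2 = d,\;
#'       h_3 = -c,\; h_4 = -a\sin\theta + b\cos\theta.}
#'
#' @param q state ([state_q()] or numeric length 4).
#' @param p canonical covector, numeric `(a, b, c, d)`.
#' @return Named numeric vector `(h1, h2, h3, h4)`.
#' @seealso [h_to_costate()] for the inverse map.
#' @export
costate_to_h <- function(q, p) {
  v <- as_state_vec(q)
  p <- unname(as.numeric(p))
  stopifnot(length(p) == 4L, all(is.finite(p)))
  th <- v[3]; k <- v[4]
  c(h1 = p[1] * cos(th) + p[2] * sin(th) + p[3] * k,
    h2 = p[4],
    h3 = -p[3],
    h4 = -p[1] * sin(th) + p[2] * cos(th))
}

#' Canonical covector components from frame momenta
#'
#' Exact inverse of [costate_to_h()] at the same state:
#' \deqn{a = (h_1 + kh_3)\cos\theta - h_4\sin\theta,\;
#'       b = h_4\cos\theta + (h_1 + kh_3)\sin\theta,\;
#'       c = -h_3,\; d = h_2.}
#'
#' @param q state.
#' @param h frame momenta, numeric `(h1, h2, h3, h4)`.
#' @return Named numeric vector `(a, b, c, d)`.
#' @export
h_to_costate <- function(q, h) {
  v <- as_state_vec(q)
  h <- unname(as.numeric(h))
  stopifnot(length(h) == 4L, all(is.finite(h)))
  th <- v[3]; k <- v[4]
  c(a = (h[1] + k * h[3]) * cos(th) - h[4] * sin(th),
    b = h[4] * cos(th) + (h[1] + k * h[3]) * sin(th),
    c = -h[3],
    d = h[2])
}

check_finite_state <- function(s, n, what) {
  s <- unname(as.numeric(s))
  if (length(s) != n || !all(is.finite(s)))
    stop(sprintf("expected a finite %d-component %s state", n, what))
  s
}

#' Normal extremal flow in frame momenta (8 equations)
#'
#' Right-hand side of the normal Hamiltonian system of the maximum
#' principle written in the momenta \eqn{h_i = \langle p, X_i\rangle}:
#' \deqn{\dot x = h_1\cos\theta,\; \dot y = h_1\sin\theta,\;
#'       \dot\theta = h_1 k,\; \dot k = h_2,}
#' \deqn{\dot h_1 = -h_2 h_3,\; \dot h_2 = h_1 h_3,\;
#'       \dot h_3 = h_1 h_4,\; \dot h_4 = -k h_1 (k h_3 + h_1).}
#' The Hamiltonian \eqn{H = (h_1^2 + h_2^2)/2} and the canonical momenta
#' \eqn{a, b} are conserved (see [first_integrals()]).
#'
#' @param s numeric state `(x, y, theta, k, h1, h2, h3, h4)`.
#' @return The 8 time derivatives, same ordering.
#' @export
normal_rhs <- function(s) {
  s <- check_finite_state(s, 8L, "normal")
  th <- s[3]; k <- s[4]; h1 <- s[5]; h2 <- s[6]; h3 <- s[7]; h4 <- s[8]
  c(h1 * cos(th), h1 * sin(th), h1 * k, h2,
    -h2 * h3, h1 * h3, h1 * h4, -k * h1 * (k * h3 + h1))
}

#' Naturally parameterized normal flow (7 equations)
#'
#' On the level set \eqn{H = 1/2} (unit-speed curves,
#' \eqn{u_1^2 + u_2^2 = 1}) the momenta \eqn{(h_1, h_2)} live on the unit
#' circle and are replaced by a polar angle \eqn{\alpha} with
#' \eqn{h_1 = \cos\alpha}, \eqn{h_2 = \sin\alpha}:
#' \deqn{\dot x = \cos\alpha\cos\theta,\; \dot y = \cos\alpha\sin\theta,\;
#'       \dot\theta = k\cos\alpha,\; \dot k = \sin\alpha,}
#' \deqn{\dot\alpha = h_3,\; \dot h_3 = h_4\cos\alpha,\;
#'       \dot h_4 = -k\cos\alpha(k h_3 + \cos\alpha).}
#' Time equals sub-Riemannian arc length along these trajectories.
#'
#' @param s numeric state `(x, y, theta, k, alpha, h3, h4)`.
#' @return The 7 time derivatives, same ordering.
#' @export
natural_rhs <- function(s) {
  s <- check_finite_state(s, 7L, "natural")
  th <- s[3]; k <- s[4]; al <- s[5]; h3 <- s[6]; h4 <- s[7]
  ca <- cos(al)
  c(ca * cos(th), ca * sin(th), k * ca, sin(al),
    h3, h4 * ca, -k * ca * (k * h3 + ca))
}

#' Reduced vertical flow (4 equations)
#'
#' The block \eqn{(\alpha, h_3, h_4, k)} of the naturally parameterized
#' flow decouples from the planar variables:
#' \deqn{\dot\alpha = h_3,\; \dot h_3 = h_4\cos\alpha,\;
#'       \dot h_4 = -k\cos\alpha(k h_3 + \cos\alpha),\;
#'       \dot k = \sin\alpha.}
#' This is the system probed by the Poincare-map experiment.
#'
#' @param s numeric state `(alpha, h3, h4, k)`.
#' @return The 4 time derivatives, same ordering.
#' @export
reduced_rhs <- function(s) {
  s <- check_finite_state(s, 4L, "reduced")
  al <- s[1]; h3 <- s[2]; h4 <- s[3]; k <- s[4]
  ca <- cos(al)
  c(h3, h4 * ca, -k * ca * (k * h3 + ca), sin(al))
}

#' Hamiltonian of the normal flow
#'
#' @param h frame momenta `(h1, h2, h3, h4)` (only the first two enter).
#' @return \eqn{(h_1^2 + h_2^2)/2}.
#' @export
hamiltonian <- function(h) {
  h <- unname(as.numeric(h))
  (h[1]^2 + h[2]^2) / 2
}

#' First integrals H, a, b of the normal flow
#'
#' The Hamiltonian \eqn{H} and the canonical momenta \eqn{a, b}
#' (conserved because the system is invariant under planar translations)
#' are three functionally independent first integrals in involution.  A
#' fourth independent integral is supported by the Poincare experiments of
#' this package but no closed form is claimed for it.
#'
#' @param s numeric normal state `(x, y, theta, k, h1, h2, h3, h4)`.
#' @return Named numeric vector `(H, a, b)`.
#' @export
first_integrals <- function(s) {
  s <- check_finite_state(s, 8L, "normal")
  ab <- h_to_costate(s[1:4], s[5:8])
  c(H = hamiltonian(s[5:8]), a = unname(ab["a"]), b = unname(ab["b"]))
}

#' Closed-form abnormal extremal trajectory
#'
#' Abnormal extremals of the model are pure curvature motions: the planar
#' position and orientation freeze and only the curvature moves,
#' \eqn{\gamma(t) = (0, 0, 0, k_0 \pm t)} under natural parameterization
#' (controls \eqn{(u_1, u_2) = (0, \pm 1)}).
#'
#' @param k0 initial curvature.
#' @param sgn direction of curvature motion, `+1` or `-1`.
#' @param t time (arc length), `t >= 0`; may be a vector.
#' @return For scalar `t` a [state_q()]; for vector `t` a matrix with one
#'   row per time and columns `x, y, theta, k`.
#' @export
abnormal_state <- function(k0, sgn = 1, t) {
  stopifnot(sgn %in% c(-1, 1), all(t >= 0))
  if (length(t) == 1L) return(state_q(0, 0, 0, k0 + sgn * t))
  cbind(x = 0, y = 0, theta = 0, k = k0 + sgn * t)
}

check_control_grid <- function(times, u1, u2) {
  stopifnot(length(times) >= 2L, all(diff(times) > 0))
  n <- length(times)
  u1 <- rep_len(as.numeric(u1), n)
  u2 <- rep_len(as.numeric(u2), n)
  list(times = as.numeric(times), u1 = u1, u2 = u2)
}

#' Sub-Riemannian length of a control trajectory
#'
#' Trapezoidal quadrature of \eqn{\sqrt{u_1^2 + u_2^2}} over the time
#' grid.  For naturally parameterized arcs (\eqn{u_1^2 + u_2^2 = 1}) the
#' length equals the elapsed time.
#'
#' @param times strictly increasing time grid.
#' @param u1,u2 control samples on the grid (scalars are recycled).
#' @return The length (a scalar).
#' @export
sr_length <- function(times, u1, u2) {
  g <- check_control_grid(times, u1, u2)
  pracma::trapz(g$times, sqrt(g$u1^2 + g$u2^2))
}

#' Action functional of a control trajectory
#'
#' Trapezoidal quadrature of \eqn{(u_1^2 + u_2^2)/2}; minimizing the
#' action with fixed horizon is equivalent to minimizing length by the
#' Cauchy--Schwarz inequality, and a naturally parameterized arc of
#' duration `T` has action `T/2`.
#'
#' @inheritParams sr_length
#' @return The action (a scalar).
#' @export
sr_action <- function(times, u1, u2) {
  g <- check_control_grid(times, u1, u2)
  pracma::trapz(g$times, (g$u1^2 + g$u2^2) / 2)
}

#' Extremal controls along a normal arc
#'
#' The maximum condition of the maximum principle gives
#' \eqn{u_i = h_i}, so the controls are read off the first two momenta.
#'
#' @param s numeric normal state `(x, y, theta, k, h1, h2, h3, h4)`.
#' @return Named numeric vector `(u1, u2)`.
#' @export
controls_from_normal <- function(s) {
  s <- check_finite_state(s, 8L, "normal")
  c(u1 = s[5], u2 = s[6])
}
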