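ngeo_systems <- list(
  normal  = list(n = 8L, cols = c("x", "y", "theta", "k", "h1", "h2", "h3", "h4"),
                 cfun = "ngeo_normal"),
  natural = list(n = 7L, cols = c("x", "y", "theta", "k", "alpha", "h3", "h4"),
                 cfun = "ngeo_natural"),
  reduced = list(n = 4L, cols = c("alpha", "h3", "h4", "k"),
                 cfun = "ngeo_reduced")
)

ngeo_r_rhs <- function(system) {
  switch(system,
         normal  = function(t, y, p) list(normal_rhs(y)),
         natural = function(t, y, p) list(natural_rhs(y)),
         reduced = function(t, y, p) list(reduced_rhs(y)))
}

BLOWUP_LIMIT <- 1e8

#' Integrate an extremal arc
#'
#' Adaptive integration (deSolve's `lsoda`, variable order with error
#' control per component) of one of the three extremal systems, with the
#' right-hand sides evaluated in compiled code by default.  For the
#' normal and natural systems the drift of the first integrals
#' \eqn{H, a, b} over the sample grid is computed and the arc is flagged
#' if the Hamiltonian drifts by more than `flag_tol`.
#'
#' @param system `"normal"` (8 equations), `"natural"` (7) or
#'   `"reduced"` (4); see [normal_rhs()], [natural_rhs()], [reduced_rhs()]
#'   for the state layouts.  Closed-form abnormal arcs are built by
#'   [abnormal_arc()].
#' @param init numeric initial state matching the system.
#' @param t_final integration horizon; time equals arc length for
#'   naturally parameterized arcs.  A negative value integrates the flow
#'   backward from the initial state.
#' @param rtol,atol relative and absolute integration tolerances.
#' @param n_out number of equally spaced sample times (default: about 50
#'   per unit time, at least 201).
#' @param engine `"compiled"` (C right-hand sides) or `"R"` (the exported
#'   `*_rhs()` functions); both evaluate the same formulas.
#' @param flag_tol Hamiltonian-drift threshold above which the arc is
#'   flagged.
#' @return An object of class `"extremal_arc"`: a list with elements
#'   `system`, `times`, `states` (matrix, one row per time), `drift`
#'   (named vector, where applicable), `rtol`, `atol`, `flagged`.
#' @examples
#' arc <- integrate_arc("natural", c(0, 0, 0, 0, pi / 2, 1, 0), 2 * pi)
#' tail(arc$states, 1)
#' @export
integrate_arc <- function(system = c("natural", "normal", "reduced"),
                          init, t_final, rtol = 1e-10, atol = 1e-12,
                          n_out = NULL, engine = c("compiled", "R"),
                          flag_tol = 1e-6) {
  system <- match.arg(system)
  engine <- match.arg(engine)
  info <- ngeo_systems[[system]]
  init <- check_finite_state(init, info$n, system)
  stopifnot(t_final != 0, rtol > 0, atol > 0)
  if (is.null(n_out)) n_out <- max(201L, ceiling(50 * abs(t_final)) + 1L)
  times <- seq(0, t_final, length.out = n_out)

  out <- ode_raw(system, init, times, rtol, atol, engine)
  states <- out[, -1L, drop = FALSE]
  colnames(states) <- info$cols

  arc <- structure(list(system = system, times = out[, 1L], states = states,
                        drift = NULL, rtol = rtol, atol = atol,
                        flagged = FALSE),
                   class = "extremal_arc")
  if (system %in% c("normal", "natural")) {
    arc$drift <- invariant_drift(arc)
    arc$flagged <- arc$drift[["H"]] > flag_tol
  }
  arc
}

# one deSolve call with blow-up and completion checks
ode_raw <- function(system, init, times, rtol, atol, engine = "compiled",
                    method = "lsoda", ...) {
  info <- ngeo_systems[[system]]
  out <- if (engine == "compiled") {
    deSolve::ode(y = init, times = times, func = info$cfun, parms = NULL,
                 dllname = "neurogeo", initfunc = "ngeo_init",
                 method = method, rtol = rtol, atol = atol, ...)
  } else {
    deSolve::ode(y = init, times = times, func = ngeo_r_rhs(system),
                 parms = NULL, method = method, rtol = rtol, atol = atol, ...)
  }
  ok <- stats::complete.cases(out)
  stopped_at_root <- length(attr(out, "troot")) > 0L
  if (!all(ok) || (!stopped_at_root && nrow(out) < length(times))) {
    t_last <- if (any(ok)) max(out[ok, 1L]) else times[1L]
    stop(sprintf("integration of the %s system failed near t = %g",
                 system, t_last))
  }
  if (max(abs(out[, -1L])) > BLOWUP_LIMIT) {
    t_bad <- out[which(apply(abs(out[, -1L, drop = FALSE]), 1L, max) >
                         BLOWUP_LIMIT)[1L], 1L]
    stop(sprintf("state blow-up (|state| > %g) in the %s system at t = %g",
                 BLOWUP_LIMIT, system, t_bad))
  }
  out
}

#' Closed-form abnormal arc
#'
#' Builds an [integrate_arc()]-compatible arc for the abnormal extremal
#' \eqn{\gamma(t) = (0, 0, 0, k_0 + \mathrm{sgn}\, t)}: a pure curvature
#' motion whose planar projection is a single point.
#'
#' @param k0 initial curvature.
#' @param sgn `+1` or `-1`.
#' @param t_final duration (equals sub-Riemannian length).
#' @param n_out number of sample times.
#' @return An `"extremal_arc"` with `system = "abnormal"` and columns
#'   `x, y, theta, k`.
#' @export
abnormal_arc <- function(k0, sgn = 1, t_final, n_out = 201L) {
  stopifnot(t_final > 0, sgn %in% c(-1, 1))
  times <- seq(0, t_final, length.out = n_out)
  structure(list(system = "abnormal", times = times,
                 states = abnormal_state(k0, sgn, times),
                 drift = NULL, rtol = 0, atol = 0, flagged = FALSE),
            class = "extremal_arc")
}

#' @export
print.extremal_arc <- function(x, ...) {
  cat(sprintf("<extremal_arc> system = %s, t in [0, %g], %d samples\n",
              x$system, max(x$times), length(x$times)))
  if (!is.null(x$drift)) {
    cat(sprintf("  max |I(t) - I(0)|:  H %.3g   a %.3g   b %.3g%s\n",
                x$drift[["H"]], x$drift[["a"]], x$drift[["b"]],
                if (x$flagged) "   [FLAGGED]" else ""))
  }
  invisible(x)
}

#' Drift of the first integrals along an arc
#'
#' Evaluates \eqn{H, a, b} at every stored sample of a normal or natural
#' arc and returns the maximum absolute deviation of each from its
#' initial value.  Deviations are reported absolutely because `a` or `b`
#' may vanish identically on particular arcs.
#'
#' @param arc an `"extremal_arc"` from the normal or natural system.
#' @return Named numeric vector with components `H`, `a`, `b`.
#' @export
invariant_drift <- function(arc) {
  stopifnot(inherits(arc, "extremal_arc"))
  if (!arc$system %in% c("normal", "natural"))
    stop("first integrals H, a, b are defined for normal/natural arcs only")
  S <- arc$states
  if (arc$system == "natural") {
    h <- cbind(cos(S[, "alpha"]), sin(S[, "alpha"]), S[, "h3"], S[, "h4"])
  } else {
    h <- S[, c("h1", "h2", "h3", "h4"), drop = FALSE]
  }
  H <- (h[, 1]^2 + h[, 2]^2) / 2
  th <- S[, "theta"]; k <- S[, "k"]
  a <- (h[, 1] + k * h[, 3]) * cos(th) - h[, 4] * sin(th)
  b <- h[, 4] * cos(th) + (h[, 1] + k * h[, 3]) * sin(th)
  c(H = max(abs(H - H[1])), a = max(abs(a - a[1])), b = max(abs(b - b[1])))
}

#' Interpolate an arc at arbitrary times
#'
#' Cubic-spline interpolation of the stored samples (the default sample
#' density of about 50 per unit time keeps the interpolation error far
#' below the integration tolerance for these smooth flows).
#'
#' @param arc an `"extremal_arc"`.
#' @param t times inside the arc's range.
#' @return Matrix with one row per requested time.
#' @export
arc_interpolate <- function(arc, t) {
  stopifnot(inherits(arc, "extremal_arc"),
            all(t >= min(arc$times) - 1e-12), all(t <= max(arc$times) + 1e-12))
  out <- vapply(seq_len(ncol(arc$states)), function(j) {
    stats::spline(arc$times, arc$states[, j], xout = t)$y
  }, numeric(length(t)))
  out <- matrix(out, nrow = length(t))
  colnames(out) <- colnames(arc$states)
  out
}

#' Apply a roto-translation to a whole arc
#'
#' Transforms the `x`, `y`, `theta` columns of an arc by an SE(2) element
#' (curvature and momenta are invariant).
#'
#' @param g an [se2()] element.
#' @param arc an `"extremal_arc"` whose state includes `x, y, theta`.
#' @return The transformed arc.
#' @export
apply_se2_arc <- function(g, arc) {
  stopifnot(inherits(arc, "extremal_arc"),
            all(c("x", "y", "theta") %in% colnames(arc$states)))
  S <- arc$states
  cphi <- cos(g[["phi"]]); sphi <- sin(g[["phi"]])
  xn <- cphi * S[, "x"] - sphi * S[, "y"] + g[["tx"]]
  yn <- sphi * S[, "x"] + cphi * S[, "y"] + g[["ty"]]
  S[, "x"] <- xn
  S[, "y"] <- yn
  S[, "theta"] <- S[, "theta"] + g[["phi"]]
  arc$states <- S
  arc
}

## ---- section crossings ---------------------------------------------------

#' Crossings of a reduced trajectory with the section k = 0
#'
#' Integrates the reduced system with root detection (deSolve's `lsodar`)
#' and returns the first `n` times `t > 0` at which the curvature
#' vanishes with the requested crossing direction.  Each event is polished
#' by Newton steps on the flow until \eqn{|k| < 10^{-10}}.
#'
#' @param init reduced state `(alpha, h3, h4, k)`; must not be an
#'   equilibrium of the reduced flow.
#' @param n number of crossings wanted.
#' @param direction `+1` for upward crossings (\eqn{\dot k > 0}, the
#'   default, under which the closed-form periodic orbit returns once per
#'   period), `-1` for downward, `0` for both.
#' @param rtol,atol integration tolerances.
#' @param max_time horizon after which the search is abandoned and a
#'   partial, flagged result is returned.
#' @return A data frame with columns `t, alpha, h3, h4, k, direction`,
#'   one row per crossing in increasing time.  Attribute `flagged` is
#'   `TRUE` if fewer than `n` crossings were found before `max_time`.
#' @export
section_crossings <- function(init, n, direction = 1, rtol = 1e-10,
                              atol = 1e-12, max_time = 100 * n + 100) {
  init <- check_finite_state(init, 4L, "reduced")
  stopifnot(n >= 1, direction %in% c(-1, 0, 1))
  if (sqrt(sum(reduced_rhs(init)^2)) < 1e-13)
    stop("initial point is an equilibrium of the reduced flow")

  nudge <- 0.05
  events <- matrix(NA_real_, nrow = n, ncol = 6L)
  found <- 0L
  t_cur <- 0
  y <- init

  # if starting on the section, step off it before arming root detection
  if (abs(y[4]) < 1e-8) {
    step <- ode_raw("reduced", y, c(t_cur, t_cur + nudge), rtol, atol)
    y <- step[nrow(step), -1L]
    t_cur <- t_cur + nudge
  }

  while (found < n && t_cur < max_time) {
    chunk_end <- min(t_cur + 50, max_time)
    out <- ode_raw("reduced", y, c(t_cur, chunk_end), rtol, atol,
                   method = "lsodar", rootfunc = "ngeo_root_k", nroot = 1L)
    troot <- attr(out, "troot")
    if (length(troot) == 0L) {
      y <- out[nrow(out), -1L]
      t_cur <- chunk_end
      next
    }
    ev <- polish_crossing(out[nrow(out), -1L], troot[1L], rtol, atol)
    kdot <- reduced_rhs(ev$state)[4]
    dir_ev <- sign(kdot)
    if (direction == 0 || dir_ev == direction) {
      found <- found + 1L
      events[found, ] <- c(ev$t, ev$state, dir_ev)
    }
    # step past the root before searching again
    step <- ode_raw("reduced", ev$state, c(ev$t, ev$t + nudge), rtol, atol)
    y <- step[nrow(step), -1L]
    t_cur <- ev$t + nudge
  }

  events <- events[seq_len(found), , drop = FALSE]
  res <- as.data.frame(events)
  names(res) <- c("t", "alpha", "h3", "h4", "k", "direction")
  attr(res, "flagged") <- found < n
  if (found < n)
    warning(sprintf("found %d of %d crossings before max_time = %g",
                    found, n, max_time))
  res
}

# Newton refinement of a root of k(t) along the reduced flow
polish_crossing <- function(state, t_event, rtol, atol) {
  for (iter in 1:5) {
    k <- state[4]
    if (abs(k) < 1e-10) break
    kdot <- reduced_rhs(state)[4]
    dt <- -k / kdot
    if (!is.finite(dt) || abs(dt) < 1e-15) break
    step <- ode_raw("reduced", state, c(0, dt), rtol, atol)
    state <- step[nrow(step), -1L]
    t_event <- t_event + dt
  }
  list(t = t_event, state = unname(state))
}

## ---- serialization -------------------------------------------------------

#' Write an arc to CSV
#'
#' Header `t` followed by the state columns of the system
#' (`x,y,theta,k,h1,h2,h3,h4` for normal arcs, subsets for the others);
#' angles in radians, unwrapped.
#'
#' @param arc an `"extremal_arc"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_arc <- function(arc, path) {
  stopifnot(inherits(arc, "extremal_arc"))
  df <- data.frame(t = arc$times, arc$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write section crossings to CSV
#'
#' Columns `t,alpha,h3,h4,k,direction`.
#'
#' @param events data frame from [section_crossings()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_crossings <- function(events, path) {
  utils::write.csv(events[, c("t", "alpha", "h3", "h4", "k", "direction")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
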