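#' Endpoint of a naturally parameterized geodesic shot from the
#' normalized frame
#'
#' Integrates the naturally parameterized normal flow from the normalized
#' start \eqn{(0, 0, 0, k_0)} with initial momentum
#' \eqn{(\alpha_0, h_3(0), h_4(0))} for time `T` and returns the endpoint
#' state.
#'
#' @param k0 initial curvature.
#' @param momentum numeric `(alpha0, h30, h40)`.
#' @param T duration (> 0), equal to sub-Riemannian length.
#' @param rtol,atol integration tolerances.
#' @return The endpoint [state_q()].
#' @export
shoot <- function(k0, momentum, T, rtol = 1e-10, atol = 1e-12) {
  stopifnot(T > 0, length(momentum) == 3L, all(is.finite(momentum)),
            is.finite(k0))
  out <- ode_raw("natural", c(0, 0, 0, k0, momentum[1], momentum[2],
                              momentum[3]),
                 c(0, T), rtol, atol)
  endp <- out[nrow(out), -1L]
  state_q(endp[1], endp[2], endp[3], endp[4])
}

# weighted endpoint mismatch residual; theta enters via shortest angular
# distance so candidates differing by full turns are not penalized
endpoint_residual <- function(endp, target, weights = c(1, 1, 1, 1)) {
  d <- c(endp[1] - target[1],
         endp[2] - target[2],
         angle_diff(endp[3], target[3]),
         endp[4] - target[4])
  weights * d
}

#' Solve the two-point geodesic boundary-value problem by multi-start
#' shooting
#'
#' Finds naturally parameterized geodesic arcs connecting two states of
#' M.  The problem is first carried to the normalized frame
#' (`q0 -> (0, 0, 0, k0)`) by the roto-translation symmetry; the unknowns
#' \eqn{(\alpha_0, h_3(0), h_4(0), T)} are then solved by damped least
#' squares (Levenberg--Marquardt) on the weighted endpoint mismatch,
#' started from a deterministic coarse grid.  Grid starts are screened
#' with a cheap low-tolerance integration and only the most promising are
#' polished at full tolerance.  Converged solutions are deduplicated by
#' momentum distance and returned sorted by duration (= length), shortest
#' first, with arcs mapped back to the original frame.
#'
#' Optimality is not certified: the shortest returned extremal is the
#' numerical candidate for the minimizer.
#'
#' @param q0,q1 boundary states ([state_q()] or numeric length 4).
#' @param tol weighted endpoint mismatch below which a start counts as
#'   converged.
#' @param weights positive weights on the `(x, y, theta, k)` mismatch
#'   components (angular distance for theta).
#' @param n_polish number of screened starts to polish.
#' @param max_iter Levenberg--Marquardt iteration cap per start.
#' @param rtol,atol integration tolerances for the polished solutions
#'   (screening uses relaxed tolerances).
#' @return A list of class `"bvp_solutions"`; each element has `arc`
#'   (natural-system arc in the original frame), `duration`,
#'   `endpoint_error`, `initial_momentum` (`alpha0, h30, h40`),
#'   `converged`, and `cusps` (number of sign changes of
#'   \eqn{u_1 = \cos\alpha}, i.e. cusps of the planar projection).
#'   Attribute `diagnostics` records the screened starts.
#' @export
solve_bvp <- function(q0, q1, tol = 1e-6, weights = c(1, 1, 1, 1),
                      n_polish = 10L, max_iter = 60L,
                      rtol = 1e-10, atol = 1e-12) {
  q0 <- as_state_vec(q0); q1 <- as_state_vec(q1)
  stopifnot(all(weights > 0), tol > 0)

  g <- normalizing_transform(q0)
  tgt <- as_state_vec(apply_se2(g, q1))
  k0 <- q0[4]
  g_back <- se2_inverse(g)

  # coincident boundary states: the trivial zero-length solution
  if (state_equal(q0, q1, tol)) {
    return(structure(list(), class = "bvp_solutions",
                     trivial = TRUE, diagnostics = "coincident states"))
  }

  starts <- bvp_start_grid(tgt, k0)
  resid_fun <- function(par, srtol, satol) {
    endp <- tryCatch(
      shoot(k0, par[1:3], max(par[4], 1e-3), rtol = srtol, atol = satol),
      error = function(e) NULL)
    if (is.null(endp)) return(rep(1e6, 4))
    endpoint_residual(as_state_vec(endp), tgt, weights)
  }

  # cheap screening pass over the full grid
  score <- vapply(seq_len(nrow(starts)), function(i) {
    sqrt(sum(resid_fun(as.numeric(starts[i, ]), 1e-6, 1e-8)^2))
  }, numeric(1))
  ord <- order(score)
  polish_idx <- ord[seq_len(min(n_polish, length(ord)))]

  sols <- list()
  diag_rows <- list()
  for (i in polish_idx) {
    # non-convergent starts are expected in a multi-start sweep; their
    # iteration-cap warnings are not informative
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(
        par = as.numeric(starts[i, ]),
        fn = function(par) resid_fun(par, 1e-9, 1e-11),
        lower = c(-Inf, -Inf, -Inf, 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                             ftol = 1e-15, ptol = 1e-12))),
      error = function(e) NULL)
    if (is.null(fit)) {
      diag_rows[[length(diag_rows) + 1L]] <-
        c(as.numeric(starts[i, ]), NA, NA)
      next
    }
    par <- fit$par
    err <- sqrt(sum(resid_fun(par, rtol, atol)^2))
    diag_rows[[length(diag_rows) + 1L]] <- c(as.numeric(starts[i, ]), par[4], err)
    if (is.finite(err) && err < tol)
      sols[[length(sols) + 1L]] <- list(par = par, err = err)
  }

  # deduplicate by distance in (momentum, T)
  keep <- list()
  for (s in sols) {
    dup <- any(vapply(keep, function(kp) {
      sqrt(sum((kp$par - s$par)^2)) < 1e-3
    }, logical(1)))
    if (!dup) keep[[length(keep) + 1L]] <- s
  }
  keep <- keep[order(vapply(keep, function(s) s$par[4], numeric(1)))]

  out <- lapply(keep, function(s) {
    arc <- integrate_arc("natural",
                         c(0, 0, 0, k0, s$par[1], s$par[2], s$par[3]),
                         s$par[4], rtol = rtol, atol = atol)
    cusps <- sum(abs(diff(sign(cos(arc$states[, "alpha"])))) > 0)
    list(arc = apply_se2_arc(g_back, arc),
         duration = s$par[4],
         endpoint_error = s$err,
         initial_momentum = c(alpha0 = s$par[1], h30 = s$par[2],
                              h40 = s$par[3]),
         converged = TRUE,
         cusps = cusps)
  })
  structure(out, class = "bvp_solutions",
            diagnostics = do.call(rbind, diag_rows))
}

#' @export
print.bvp_solutions <- function(x, ...) {
  if (isTRUE(attr(x, "trivial"))) {
    cat("<bvp_solutions> coincident boundary states (zero-length solution)\n")
    return(invisible(x))
  }
  cat(sprintf("<bvp_solutions> %d converged arc(s)\n", length(x)))
  for (i in seq_along(x)) {
    s <- x[[i]]
    cat(sprintf("  [%d] length %.6f, endpoint error %.2e, cusps %d\n",
                i, s$duration, s$endpoint_error, s$cusps))
  }
  invisible(x)
}

# deterministic multi-start grid over (alpha0, h30, h40, T)
bvp_start_grid <- function(tgt, k0) {
  d <- max(sqrt(tgt[1]^2 + tgt[2]^2) + abs(tgt[4] - k0), 0.1)
  expand.grid(alpha0 = seq(-3 * pi / 4, 3 * pi / 4, length.out = 8),
              h30 = c(-2, -0.5, 0, 0.5, 2),
              h40 = c(-2, -0.5, 0, 0.5, 2),
              T = d * c(0.5, 1, 2, 4))
}

#' Complete an occluded contour between two boundary states
#'
#' Solves the geodesic boundary-value problem between the two boundary
#' states and returns the planar projection of the shortest converged
#' arc, densely resampled: the completed contour of the
#' position-orientation-curvature model of amodal completion.
#'
#' @param q0,q1 boundary states (position, tangent orientation, signed
#'   curvature) at the two edges of the occluded gap.
#' @param n_points number of output samples.
#' @param ... passed to [solve_bvp()].
#' @return A data frame with columns `x, y`; attributes `solution` (the
#'   full [solve_bvp()] element) and `duration`.
#' @export
complete_contour <- function(q0, q1, n_points = 200L, ...) {
  sols <- solve_bvp(q0, q1, ...)
  if (isTRUE(attr(sols, "trivial"))) {
    v <- as_state_vec(q0)
    return(data.frame(x = rep(v[1], 2L), y = rep(v[2], 2L)))
  }
  if (length(sols) == 0L)
    stop("no converged geodesic between the boundary states")
  best <- sols[[1L]]
  tt <- seq(0, best$duration, length.out = n_points)
  S <- arc_interpolate(best$arc, tt)
  out <- data.frame(x = S[, "x"], y = S[, "y"])
  attr(out, "solution") <- best
  attr(out, "duration") <- best$duration
  out
}
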