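#' Specification of a synthetic occluded contour
#'
#' Describes a smooth planar test contour with a hidden (occluded)
#' parameter interval, from which [synth_occluded()] builds the visible
#' polyline, the exact boundary states at the gap edges and the hidden
#' ground-truth segment.
#'
#' Shapes and their parameters (`params`):
#' \describe{
#'   \item{`circle`}{`radius`, optional `center` (length 2); parameter is
#'     the counter-clockwise polar angle in `[0, 2*pi)`.}
#'   \item{`ellipse`}{`a`, `b` semi-axes, optional `center`; parameter is
#'     the standard ellipse parameter `t` in `[0, 2*pi)`.}
#'   \item{`spline`}{smooth random closed curve
#'     \eqn{r(\varphi) = R(1 + \sum_m \epsilon_m\cos(m\varphi + \psi_m))}
#'     with seeded amplitudes; `radius` (base `R`), optional `wobble`
#'     (relative amplitude, default 0.1) and `center`.}
#'   \item{`line`}{straight segment from `p0` to `p1` (degenerate case,
#'     zero curvature); parameter in `[0, 1]`.}
#' }
#'
#' @param shape `"circle"`, `"ellipse"`, `"spline"` or `"line"`.
#' @param params named list of shape parameters, see Details.
#' @param gap numeric `(lo, hi)`: the hidden parameter interval, strictly
#'   inside the parameter range (for closed shapes, of width `< 2*pi`).
#' @param step target arc-length sampling step of the polylines.
#' @param seed integer seed for the spline coefficients (unused by the
#'   deterministic shapes).
#' @return A list of class `"occlusion_spec"`.
#' @export
occlusion_spec <- function(shape = c("circle", "ellipse", "spline", "line"),
                           params = list(), gap, step = 0.05,
                           seed = 20211217L) {
  shape <- match.arg(shape)
  stopifnot(step > 0, length(gap) == 2L, gap[2] > gap[1])
  range_hi <- if (shape == "line") 1 else 2 * pi
  if (gap[1] < 0 || gap[2] > range_hi || (gap[2] - gap[1]) >= range_hi)
    stop(sprintf("gap must lie strictly inside [0, %g]", range_hi))
  defaults <- switch(shape,
                     circle  = list(radius = 1, center = c(0, 0)),
                     ellipse = list(a = 2, b = 1, center = c(0, 0)),
                     spline  = list(radius = 1, wobble = 0.1,
                                    center = c(0, 0)),
                     line    = list(p0 = c(0, 0), p1 = c(1, 0)))
  params <- utils::modifyList(defaults, params)
  structure(list(shape = shape, params = params, gap = as.numeric(gap),
                 step = step, seed = as.integer(seed)),
            class = "occlusion_spec")
}

# closed-form point / tangent angle / signed curvature at parameter u
shape_eval <- function(spec, u) {
  p <- spec$params
  switch(spec$shape,
    circle = {
      R <- p$radius
      list(x = p$center[1] + R * cos(u), y = p$center[2] + R * sin(u),
           theta = u + pi / 2, k = rep(1 / R, length(u)))
    },
    ellipse = {
      a <- p$a; b <- p$b
      list(x = p$center[1] + a * cos(u), y = p$center[2] + b * sin(u),
           theta = atan2(b * cos(u), -a * sin(u)),
           k = a * b / (a^2 * sin(u)^2 + b^2 * cos(u)^2)^(3 / 2))
    },
    spline = {
      co <- spline_coefs(spec)
      r   <- co$R * (1 + colSums(co$eps * cos(outer(co$m, u) + co$psi)))
      rp  <- co$R * colSums(-co$eps * co$m * sin(outer(co$m, u) + co$psi))
      rpp <- co$R * colSums(-co$eps * co$m^2 * cos(outer(co$m, u) + co$psi))
      dx <- rp * cos(u) - r * sin(u)
      dy <- rp * sin(u) + r * cos(u)
      list(x = p$center[1] + r * cos(u), y = p$center[2] + r * sin(u),
           theta = atan2(dy, dx),
           k = (r^2 + 2 * rp^2 - r * rpp) / (r^2 + rp^2)^(3 / 2))
    },
    line = {
      d <- p$p1 - p$p0
      list(x = p$p0[1] + u * d[1], y = p$p0[2] + u * d[2],
           theta = rep(atan2(d[2], d[1]), length(u)),
           k = rep(0, length(u)))
    })
}

# seeded Fourier coefficients; the caller's RNG stream is left untouched
spline_coefs <- function(spec) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had_seed) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(spec$seed)
  m <- 2:4
  list(m = m,
       eps = spec$params$wobble * stats::runif(length(m), 0.3, 1) / m,
       psi = stats::runif(length(m), 0, 2 * pi),
       R = spec$params$radius)
}

# approximate arc length per unit parameter, for step -> parameter step
shape_speed <- function(spec) {
  u <- seq(0, if (spec$shape == "line") 1 else 2 * pi, length.out = 512L)
  pt <- shape_eval(spec, u)
  seg <- sqrt(diff(pt$x)^2 + diff(pt$y)^2)
  sum(seg) / (utils::tail(u, 1) - u[1])
}

#' Generate a synthetic occluded contour with exact ground truth
#'
#' Samples the visible part of the contour (the complement of the gap,
#' traversed so that the polyline ends where the gap begins), the exact
#' boundary states at the two gap edges — position, tangent orientation
#' and signed curvature, all evaluated from the closed-form shape — and
#' the hidden ground-truth segment inside the gap.
#'
#' The two boundary states are oriented along the traversal, so
#' `complete_contour(q0, q1)` bridges the gap: `q0` sits at the end of
#' the visible polyline (pointing into the gap) and `q1` at its start
#' (pointing out of the gap).
#'
#' @param spec an [occlusion_spec()].
#' @return A list of class `"ngeo_contour"`: `points` (visible polyline,
#'   data frame `x, y`), `closed = FALSE`, `boundary_data` (list of
#'   states `q0`, `q1`), `truth` (hidden segment, data frame `x, y`) and
#'   the `spec`.
#' @export
synth_occluded <- function(spec) {
  stopifnot(inherits(spec, "occlusion_spec"))
  closed <- spec$shape != "line"
  range_hi <- if (closed) 2 * pi else 1
  du <- spec$step / shape_speed(spec)

  # visible parameter interval: from gap end around to gap start
  if (closed) {
    u_vis <- seq(spec$gap[2], spec$gap[1] + range_hi,
                 length.out = max(8L, ceiling((spec$gap[1] + range_hi -
                                                 spec$gap[2]) / du) + 1L))
  } else {
    u_vis <- c(seq(spec$gap[2], range_hi,
                   length.out = max(4L, ceiling((range_hi - spec$gap[2]) / du) + 1L)),
               NA,  # break between the two visible pieces of an open shape
               seq(0, spec$gap[1],
                   length.out = max(4L, ceiling(spec$gap[1] / du) + 1L)))
  }
  u_truth <- seq(spec$gap[1], spec$gap[2],
                 length.out = max(8L, ceiling((spec$gap[2] - spec$gap[1]) / du) + 1L))

  vis_ok <- !is.na(u_vis)
  pv <- shape_eval(spec, u_vis[vis_ok])
  pt <- shape_eval(spec, u_truth)
  b0 <- shape_eval(spec, spec$gap[1])  # gap start: end of traversal
  b1 <- shape_eval(spec, spec$gap[2])  # gap end: start of traversal

  structure(list(
    points = data.frame(x = pv$x, y = pv$y),
    closed = FALSE,
    boundary_data = list(q0 = state_q(b0$x, b0$y, b0$theta, b0$k),
                         q1 = state_q(b1$x, b1$y, b1$theta, b1$k)),
    truth = data.frame(x = pt$x, y = pt$y),
    spec = spec), class = "ngeo_contour")
}

#' @export
print.ngeo_contour <- function(x, ...) {
  cat(sprintf("<ngeo_contour> %d visible points%s%s\n", nrow(x$points),
              if (!is.null(x$boundary_data)) ", with boundary states" else "",
              if (!is.null(x$truth)) sprintf(", %d truth points",
                                             nrow(x$truth)) else ""))
  invisible(x)
}

#' Estimate a boundary state from a sampled polyline
#'
#' Estimates the state (position, tangent orientation, signed curvature)
#' at one end of a polyline.  The position is the endpoint itself; the
#' curvature comes from an algebraic (Kasa) circle fit on the last
#' `window` samples, signed positive when the curve bends left of the
#' traversal direction; the orientation is the tangent of the fitted
#' circle at the endpoint (falling back to a total-least-squares line
#' when the window is straight).  Fitting a circle rather than a line
#' removes the one-sided chord bias from the orientation, which
#' converges at O(step^2); the curvature is exact on circular arcs and
#' straight segments, while on curves of varying curvature the
#' one-sided window leaves an O(step) endpoint bias (the fit reports
#' something close to the mean curvature over the window).
#'
#' @param points polyline, matrix or data frame with columns `x, y`.
#' @param end `"last"` (default) or `"first"`: which endpoint.
#' @param window number of samples used in the local fits (>= 5).
#' @return A [state_q()].
#' @export
estimate_boundary_data <- function(points, end = c("last", "first"),
                                   window = 9L) {
  end <- match.arg(end)
  P <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(P) <- "double"
  stopifnot(window >= 5L, nrow(P) >= window)
  idx <- if (end == "last") (nrow(P) - window + 1L):nrow(P) else 1:window
  W <- P[idx, , drop = FALSE]
  tip <- if (end == "last") W[window, ] else W[1L, ]

  ctr <- colMeans(W)
  Wc <- sweep(W, 2, ctr)
  if (max(abs(Wc)) == 0) stop("degenerate window: zero extent")
  sv <- svd(Wc)
  tang <- sv$v[, 1]
  # orient along the traversal direction (increasing index)
  travel <- W[window, ] - W[1L, ]
  if (sum(tang * travel) < 0) tang <- -tang

  fit <- kasa_circle(W, tip, tang)
  if (fit$k != 0) {
    # tangent of the fitted circle at the endpoint: rotate the radial
    # direction by +-90 degrees according to the bending sign
    radial <- tip - fit$center
    s <- sign(fit$k)
    tang <- c(-s * radial[2], s * radial[1]) / sqrt(sum(radial^2))
  }
  state_q(tip[1], tip[2], atan2(tang[2], tang[1]), fit$k)
}

# algebraic circle fit; signed curvature is 0 for collinear windows
kasa_circle <- function(W, tip, tang) {
  A <- cbind(2 * W[, 1], 2 * W[, 2], 1)
  rhs <- W[, 1]^2 + W[, 2]^2
  qrA <- qr(A)
  span <- max(stats::dist(W[c(1, ceiling(nrow(W) / 2), nrow(W)), ]))
  if (qrA$rank < 3L) return(list(k = 0, center = c(NA_real_, NA_real_)))
  cf <- qr.coef(qrA, rhs)
  cx <- cf[1]; cy <- cf[2]
  R <- sqrt(max(cf[3] + cx^2 + cy^2, 0))
  if (!is.finite(R) || R <= 0 || R > 1e6 * span)
    return(list(k = 0, center = c(NA_real_, NA_real_)))
  cross <- tang[1] * (cy - tip[2]) - tang[2] * (cx - tip[1])
  list(k = sign(cross) / R, center = c(cx, cy))
}

## ---- file I/O ------------------------------------------------------------

#' Read a contour from CSV or JSON
#'
#' CSV files hold a bare polyline (`x,y` header, one point per row,
#' decimal dot, UTF-8).  JSON files carry the full contour record
#' including boundary states and ground truth, as written by
#' [write_contour()].
#'
#' @param path input file; dialect chosen by the `.json` extension.
#' @return An `"ngeo_contour"`.
#' @export
read_contour <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::read_json(path, simplifyVector = TRUE)
    bd <- NULL
    if (!is.null(rec$boundary_data)) {
      bd <- lapply(rec$boundary_data, function(q)
        state_q(q[["x"]], q[["y"]], q[["theta"]], q[["k"]]))
    }
    return(structure(list(points = as.data.frame(rec$points),
                          closed = isTRUE(rec$closed),
                          boundary_data = bd,
                          truth = if (is.null(rec$truth)) NULL
                                  else as.data.frame(rec$truth),
                          spec = NULL), class = "ngeo_contour"))
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L)
    stop(sprintf("%s: a contour needs a header and at least 2 points", path))
  if (trimws(lines[1L]) != "x,y")
    stop(sprintf("%s: line 1: expected header 'x,y', got '%s'",
                 path, lines[1L]))
  pts <- matrix(NA_real_, length(lines) - 1L, 2L)
  for (i in 2:length(lines)) {
    f <- suppressWarnings(as.numeric(strsplit(lines[i], ",", fixed = TRUE)[[1L]]))
    if (length(f) != 2L || anyNA(f))
      stop(sprintf("%s: line %d: expected two numeric fields, got '%s'",
                   path, i, lines[i]))
    pts[i - 1L, ] <- f
  }
  structure(list(points = data.frame(x = pts[, 1], y = pts[, 2]),
                 closed = FALSE, boundary_data = NULL, truth = NULL,
                 spec = NULL), class = "ngeo_contour")
}

#' Write a contour to CSV or JSON
#'
#' @param contour an `"ngeo_contour"` (or anything with `x, y` columns,
#'   for the CSV dialect).
#' @param path output file; `.json` writes the full record (boundary
#'   states and truth included), anything else writes the bare `x,y`
#'   polyline CSV.
#' @return `path`, invisibly.
#' @export
write_contour <- function(contour, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    stopifnot(inherits(contour, "ngeo_contour"))
    bd <- NULL
    if (!is.null(contour$boundary_data)) {
      bd <- lapply(contour$boundary_data, function(q) as.list(unclass(q)))
    }
    rec <- list(points = contour$points, closed = contour$closed,
                boundary_data = bd, truth = contour$truth)
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(path))
  }
  pts <- if (inherits(contour, "ngeo_contour")) contour$points
         else as.data.frame(contour)
  utils::write.csv(pts[, c("x", "y")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

## ---- rendering -----------------------------------------------------------

#' Render contours and completed segments to a PNG
#'
#' Deterministic raster of the visible contours (solid), completed
#' segments (distinct color), hidden ground truth (dotted, when present)
#' and optional osculating-circle glyphs of radius \eqn{1/|k|} at the
#' boundary states.  Axes are mathematical (y grows upward) with unit
#' aspect ratio.
#'
#' @param contours a single `"ngeo_contour"` or list of them.
#' @param completed optional list of completed polylines (data frames
#'   with `x, y`), e.g. from [complete_contour()].
#' @param path output PNG path.
#' @param size image width and height in pixels.
#' @param osculating draw osculating-circle glyphs at boundary states.
#' @return `path`, invisibly.
#' @export
render_contours <- function(contours, completed = list(), path,
                            size = 600L, osculating = FALSE) {
  if (inherits(contours, "ngeo_contour")) contours <- list(contours)
  stopifnot(length(contours) >= 1L)
  if (inherits(completed, "data.frame")) completed <- list(completed)

  allx <- unlist(c(lapply(contours, function(ct) ct$points$x),
                   lapply(completed, function(p) p$x)))
  ally <- unlist(c(lapply(contours, function(ct) ct$points$y),
                   lapply(completed, function(p) p$y)))
  grDevices::png(path, width = size, height = size)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(2, 2, 1, 1))
  graphics::plot(NA, xlim = range(allx), ylim = range(ally), asp = 1,
                 xlab = "", ylab = "", las = 1)
  for (ct in contours) {
    graphics::lines(ct$points$x, ct$points$y, lwd = 2)
    if (!is.null(ct$truth))
      graphics::lines(ct$truth$x, ct$truth$y, lty = 3, col = "grey50")
    if (osculating && !is.null(ct$boundary_data)) {
      for (q in ct$boundary_data) {
        if (abs(q[["k"]]) > 1e-12) {
          r <- 1 / abs(q[["k"]])
          nrm <- c(-sin(q[["theta"]]), cos(q[["theta"]])) * sign(q[["k"]])
          cc <- c(q[["x"]], q[["y"]]) + r * nrm
          tt <- seq(0, 2 * pi, length.out = 181L)
          graphics::lines(cc[1] + r * cos(tt), cc[2] + r * sin(tt),
                          col = "grey70", lty = 2)
        }
      }
    }
  }
  for (p in completed)
    graphics::lines(p$x, p$y, col = "red3", lwd = 2)
  invisible(path)
}
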