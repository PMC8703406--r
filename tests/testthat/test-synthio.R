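test_that("occlusion specs validate their gap and step", {
  expect_s3_class(occlusion_spec("circle", list(radius = 2), gap = c(0, 1)),
                  "occlusion_spec")
  expect_error(occlusion_spec("circle", gap = c(1, 7)), "gap")
  expect_error(occlusion_spec("circle", gap = c(2, 1)))
  expect_error(occlusion_spec("circle", gap = c(0, 1), step = 0))
  expect_error(occlusion_spec("line", gap = c(0.2, 1.4)), "gap")
})

test_that("synthetic fixtures carry exact boundary states", {
  # circle of radius 2: curvature 1/2 at both gap edges
  ct <- synth_occluded(occlusion_spec("circle", list(radius = 2),
                                      gap = c(0.3, 1.1)))
  expect_equal(ct$boundary_data$q0[["k"]], 0.5)
  expect_equal(ct$boundary_data$q1[["k"]], 0.5)
  # boundary positions sit on the circle, orientations are tangent
  q0 <- ct$boundary_data$q0
  expect_equal(q0[["x"]]^2 + q0[["y"]]^2, 4, tolerance = 1e-12)
  expect_equal(q0[["theta"]], atan2(q0[["y"]], q0[["x"]]) + pi / 2,
               tolerance = 1e-12)
  # degenerate straight shape: zero curvature
  ln <- synth_occluded(occlusion_spec("line",
                                      list(p0 = c(0, 0), p1 = c(3, 1)),
                                      gap = c(0.4, 0.6)))
  expect_equal(ln$boundary_data$q0[["k"]], 0)
  expect_equal(ln$boundary_data$q0[["theta"]], atan2(1, 3))
  # ellipse a = 2, b = 1 at the semi-major vertex: k = a/b^2 = 2
  sp <- occlusion_spec("ellipse", list(a = 2, b = 1), gap = c(0.5, 1))
  v <- neurogeo:::shape_eval(sp, 0)
  expect_equal(v$k, 2)
  expect_equal(neurogeo:::shape_eval(sp, pi / 2)$k, 1 / 4)  # b/a^2
})

test_that("fixtures are deterministic in (spec, seed) and truth fills the gap", {
  sp <- occlusion_spec("spline", list(radius = 1.5, wobble = 0.12),
                       gap = c(1, 2), seed = 99L)
  a <- synth_occluded(sp); b <- synth_occluded(sp)
  expect_identical(a$points, b$points)
  expect_identical(a$truth, b$truth)
  dif <- synth_occluded(occlusion_spec("spline", list(radius = 1.5,
                                                      wobble = 0.12),
                                       gap = c(1, 2), seed = 100L))
  expect_false(isTRUE(all.equal(a$points, dif$points)))
  # truth endpoints coincide with the boundary states
  expect_equal(c(a$truth$x[1], a$truth$y[1]),
               c(a$boundary_data$q0[["x"]], a$boundary_data$q0[["y"]]))
  # consecutive polyline points are distinct
  expect_true(all(diff(a$points$x)^2 + diff(a$points$y)^2 > 0))
})

test_that("boundary estimation is exact on circles and lines", {
  ct <- synth_occluded(occlusion_spec("circle", list(radius = 1),
                                      gap = c(0, pi / 3), step = 0.02))
  q_hat <- estimate_boundary_data(ct$points, "last")
  q_true <- ct$boundary_data$q0
  expect_lt(abs(q_hat[["k"]] - 1), 1e-3)
  expect_lt(abs(neurogeo:::angle_diff(q_hat[["theta"]], q_true[["theta"]])),
            1e-6)
  expect_equal(q_hat[["x"]], q_true[["x"]], tolerance = 1e-12)
  P <- cbind(x = seq(0, 1, 0.01), y = 0.5 * seq(0, 1, 0.01))
  q_line <- estimate_boundary_data(P, "last")
  expect_lt(abs(q_line[["k"]]), 1e-8)
  expect_equal(q_line[["theta"]], atan2(0.5, 1))
})

test_that("estimated circle curvature stays exact across step halvings", {
  errs <- vapply(c(0.08, 0.04, 0.02), function(st) {
    ct <- synth_occluded(occlusion_spec("circle", list(radius = 1),
                                        gap = c(0, pi / 3), step = st))
    abs(estimate_boundary_data(ct$points, "last")[["k"]] - 1)
  }, numeric(1))
  # the circle fit is exact on circular data; far below the O(step^2) bound
  expect_true(all(errs < 1e-10))
  expect_true(all(errs <= c(0.08, 0.04, 0.02)^2))
})

test_that("reversing the polyline flips the orientation and curvature sign", {
  ct <- synth_occluded(occlusion_spec("circle", list(radius = 1.5),
                                      gap = c(0, 1), step = 0.03))
  P <- as.matrix(ct$points)
  fwd <- estimate_boundary_data(P, "last")
  rev <- estimate_boundary_data(P[nrow(P):1, ], "first")
  expect_lt(abs(abs(neurogeo:::angle_diff(fwd[["theta"]], rev[["theta"]])) - pi),
            1e-9)
  expect_equal(rev[["k"]], -fwd[["k"]], tolerance = 1e-9)
})

test_that("contours round-trip through CSV and JSON", {
  set.seed(20)
  ct <- synth_occluded(occlusion_spec("spline", list(radius = 1),
                                      gap = c(0.5, 1.5)))
  fc <- tempfile(fileext = ".csv")
  write_contour(ct, fc)
  back <- read_contour(fc)
  expect_equal(back$points, ct$points, tolerance = 1e-12)
  fj <- tempfile(fileext = ".json")
  write_contour(ct, fj)
  backj <- read_contour(fj)
  expect_equal(backj$points, ct$points, tolerance = 1e-12)
  expect_equal(unclass(backj$boundary_data$q0), unclass(ct$boundary_data$q0),
               tolerance = 1e-12)
  expect_equal(backj$truth, ct$truth, tolerance = 1e-12)
  unlink(c(fc, fj))
})

test_that("malformed contour files fail with the offending line", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "0,0", "1,1"), f)
  expect_error(read_contour(f), "line 1")
  writeLines(c("x,y", "0,0", "oops,1"), f)
  expect_error(read_contour(f), "line 3")
  unlink(f)
})

test_that("rendering is deterministic and handles empty completions", {
  ct <- synth_occluded(occlusion_spec("circle", list(radius = 1),
                                      gap = c(0, 1)))
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  render_contours(ct, path = f1, osculating = TRUE)
  render_contours(ct, path = f2, osculating = TRUE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  f3 <- tempfile(fileext = ".png")
  cc <- data.frame(x = c(1, 0.8), y = c(0, 0.5))
  render_contours(ct, completed = list(cc), path = f3)
  expect_true(file.size(f3) > 0)
  unlink(c(f1, f2, f3))
})

test_that("the full pipeline completes an occluded circle from samples", {
  R <- 2
  ct <- synth_occluded(occlusion_spec("circle", list(radius = R),
                                      gap = c(0, pi / 2), step = 0.02))
  q0 <- estimate_boundary_data(ct$points, "last")
  q1 <- estimate_boundary_data(ct$points, "first")
  cc <- complete_contour(q0, q1)
  expect_lt(max_deviation_from_truth(cc, ct$truth), 0.05 * R)
  # exact boundary data does even better
  cc2 <- complete_contour(ct$boundary_data$q0, ct$boundary_data$q1)
  expect_lt(max_deviation_from_truth(cc2, ct$truth), 0.02 * R)
})
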