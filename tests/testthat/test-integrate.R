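test_that("trivial arcs integrate to their closed forms", {
  arc <- integrate_arc("natural", c(0, 0, 0, 0, 0, 0, 0), 5)
  expect_equal(unname(arc$states[nrow(arc$states), ]),
               c(5, 0, 0, 0, 0, 0, 0), tolerance = 1e-9)
  expect_false(arc$flagged)
  # periodic member of the reduced flow returns to itself, alpha shifted 2*pi
  arc2 <- integrate_arc("reduced", c(pi / 2, 1, 0, 0), 2 * pi)
  endp <- unname(arc2$states[nrow(arc2$states), ])
  expect_equal(endp, c(pi / 2 + 2 * pi, 1, 0, 0), tolerance = 1e-8)
})

test_that("normal and natural parameterizations trace the same geodesics", {
  set.seed(12)
  for (i in 1:5) {
    al0 <- runif(1, -pi, pi); h30 <- runif(1, -1.5, 1.5)
    h40 <- runif(1, -1.5, 1.5); k0 <- runif(1, -1, 1)
    a8 <- integrate_arc("normal",
                        c(0, 0, 0, k0, cos(al0), sin(al0), h30, h40), 20)
    a7 <- integrate_arc("natural", c(0, 0, 0, k0, al0, h30, h40), 20)
    expect_lt(max(abs(a8$states[, 1:4] - a7$states[, 1:4])), 1e-6)
  }
})

test_that("the vertical block of the natural flow equals the reduced flow", {
  set.seed(13)
  for (i in 1:5) {
    r0 <- c(runif(1, -pi, pi), runif(3, -1.5, 1.5))
    a7 <- integrate_arc("natural", c(0, 0, 0, r0[4], r0[1], r0[2], r0[3]), 15)
    a4 <- integrate_arc("reduced", r0, 15)
    expect_lt(max(abs(a7$states[, c("alpha", "h3", "h4", "k")] -
                        a4$states[, c("alpha", "h3", "h4", "k")])), 1e-7)
  }
})

test_that("H, a, b are conserved along long normal arcs", {
  # conservation is checked at tolerances tight enough that the
  # integrator's own phase error (amplified by |k h3| on escaping arcs)
  # stays below the drift bound
  set.seed(14)
  for (i in 1:20) {
    al0 <- runif(1, -pi, pi)
    init <- c(0, 0, runif(1, -pi, pi), runif(1, -1, 1),
              cos(al0), sin(al0), runif(1, -1.5, 1.5), runif(1, -1.5, 1.5))
    arc <- integrate_arc("normal", init, 100, rtol = 1e-13, atol = 1e-15)
    expect_lt(arc$drift[["H"]], 1e-8)
    expect_lt(arc$drift[["a"]], 1e-8)
    expect_lt(arc$drift[["b"]], 1e-8)
  }
})

test_that("drift of a straight arc is at rounding level and the detector
           flags corrupted states", {
  arc <- integrate_arc("natural", c(0, 0, 0, 0, 0, 0, 0), 5)
  expect_lt(max(invariant_drift(arc)), 1e-12)
  # corrupt the stored states: recomputed drift must light up
  noisy <- arc
  set.seed(15)
  noisy$states <- arc$states + matrix(rnorm(length(arc$states), sd = 1e-3),
                                      nrow(arc$states))
  expect_gt(max(invariant_drift(noisy)), 1e-4)
  expect_error(invariant_drift(integrate_arc("reduced", c(1, 1, 0, 0), 1)),
               "normal/natural")
})

test_that("integration errors are reported, not silently returned", {
  expect_error(integrate_arc("natural", c(0, 0, 0, NaN, 0, 0, 0), 1),
               "finite")
  expect_error(integrate_arc("natural", c(0, 0, 0, 0, 0, 0, 0), 0))
  # the cubic momentum terms send h4 past the blow-up guard immediately
  # for extreme curvature data
  expect_error(suppressWarnings(integrate_arc("reduced", c(0, 1e7, 0, 1e7), 1)),
               "blow-up|failed")
})

test_that("halving tolerances moves endpoints less than the tolerance scale", {
  init <- c(0, 0, 0, 0.3, 0.9, 0.8, -0.4)
  loose <- integrate_arc("natural", init, 10, rtol = 1e-8, atol = 1e-10)
  tight <- integrate_arc("natural", init, 10, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(loose$states[nrow(loose$states), ] -
                      tight$states[nrow(tight$states), ])), 1e-6)
})

test_that("integrating forward then backward returns to the initial state", {
  init <- c(0, 0, 0, 0.5, 1.1, 0.6, -0.3)
  fwd <- integrate_arc("natural", init, 12)
  endp <- unname(fwd$states[nrow(fwd$states), ])
  back <- integrate_arc("natural", endp, -12)
  expect_lt(max(abs(unname(back$states[nrow(back$states), ]) - init)), 1e-7)
})

test_that("the flow commutes with roto-translations of the plane", {
  g <- se2(2, -1, 0.8)
  init_q <- state_q(0.5, 0.2, 0.4, 0.7)
  mom <- c(0.9, 0.6, -0.2)
  pushed <- apply_se2(g, init_q)
  a1 <- integrate_arc("natural", c(as.numeric(unclass(pushed)), mom), 8)
  a2 <- apply_se2_arc(g, integrate_arc("natural",
                                       c(as.numeric(unclass(init_q)), mom), 8))
  expect_lt(max(abs(a1$states[, c("x", "y", "theta")] -
                      a2$states[, c("x", "y", "theta")])), 1e-8)
})

test_that("compiled and R right-hand sides integrate identically", {
  init <- c(0, 0, 0, 0.2, 0.5, 1.2, -0.7)
  a_c <- integrate_arc("natural", init, 5, engine = "compiled")
  a_r <- integrate_arc("natural", init, 5, engine = "R")
  expect_lt(max(abs(a_c$states - a_r$states)), 1e-9)
})

test_that("section crossings are found, refined and direction-filtered", {
  ev <- section_crossings(c(pi / 2, 1, 0, 0), n = 1, direction = 1)
  expect_equal(ev$t[1], 2 * pi, tolerance = 1e-6)
  expect_equal(ev$alpha[1], pi / 2 + 2 * pi, tolerance = 1e-6)
  expect_equal(ev$h3[1], 1, tolerance = 1e-6)
  expect_equal(ev$h4[1], 0, tolerance = 1e-6)
  expect_false(attr(ev, "flagged"))

  both <- section_crossings(c(pi / 2, 1, 0, 0), n = 2, direction = 0)
  expect_equal(both$t[1], pi, tolerance = 1e-6)
  expect_identical(both$direction[1], -1)
  expect_identical(both$direction[2], 1)

  # every reported event sits on the section to the stated refinement
  long <- section_crossings(c(1.56, 0.94, 0.02, 0), n = 20, direction = 1)
  expect_true(all(abs(long$k) < 1e-10))
  expect_true(all(diff(long$t) > 0))
  dirs <- vapply(seq_len(nrow(long)), function(i) {
    sign(reduced_rhs(as.numeric(long[i, c("alpha", "h3", "h4", "k")]))[4])
  }, numeric(1))
  expect_true(all(dirs == 1))

  expect_error(section_crossings(c(0, 0, 0, 0), n = 1), "equilibrium")
})

test_that("arc and crossing serialization round-trips through CSV", {
  arc <- integrate_arc("normal", c(0, 0, 0, 0, 1, 0, 0.5, 0.5), 2)
  f <- tempfile(fileext = ".csv")
  write_arc(arc, f)
  back <- utils::read.csv(f)
  expect_identical(names(back),
                   c("t", "x", "y", "theta", "k", "h1", "h2", "h3", "h4"))
  expect_equal(back$k, unname(arc$states[, "k"]), tolerance = 1e-10)
  ev <- section_crossings(c(pi / 2, 1, 0, 0), n = 1)
  f2 <- tempfile(fileext = ".csv")
  write_crossings(ev, f2)
  back2 <- utils::read.csv(f2)
  expect_identical(names(back2),
                   c("t", "alpha", "h3", "h4", "k", "direction"))
  unlink(c(f, f2))
})

test_that("arc interpolation matches stored samples and refines between them", {
  arc <- integrate_arc("reduced", c(pi / 2, 1, 0, 0), 2 * pi)
  S <- arc_interpolate(arc, arc$times[c(10, 50)])
  expect_equal(unname(S), unname(arc$states[c(10, 50), ]), tolerance = 1e-12)
  mid <- arc_interpolate(arc, pi / 2)
  expect_equal(unname(mid[1, "k"]), 1, tolerance = 1e-6)  # closed form sin(t)
})
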