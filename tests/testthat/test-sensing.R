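test_that("capacity is exactly linear in MOF mass", {
  expect_equal(capacity(1), 0.33)
  expect_equal(capacity(0), 0)
  expect_equal(capacity(10), 3.3)
  expect_error(capacity(-1), ">= 0")
  set.seed(5)
  m <- stats::runif(10, 0, 50)
  expect_equal(capacity(3 * m), 3 * capacity(m))
})

test_that("window accessibility follows the two-smallest-axes rule", {
  b12 <- c(1.41, 1.83, 1.14)
  expect_true(window_accessibility(b12, 1.7))
  expect_false(window_accessibility(b12, 1.3))
  # boundary case is inclusive
  expect_true(window_accessibility(c(1, 1, 1), 1))
  expect_error(window_accessibility(c(1, -1, 1), 1), "positive")
})

test_that("accessibility is monotone in window diameter", {
  set.seed(8)
  for (k in 1:20) {
    dims <- sort(stats::runif(3, 0.5, 2.5), decreasing = TRUE)
    d1 <- stats::runif(1, 0.5, 3)
    d2 <- d1 + stats::runif(1, 0, 2)
    if (window_accessibility(dims, d1)) expect_true(window_accessibility(dims, d2))
  }
})

test_that("shipped constants carry the cited values and provenance notes", {
  sc <- sensing_constants()
  expect_equal(sc$max_load_ratio$value, 0.33)
  expect_equal(sc$initial_uptake_rate$value, 0.112)
  expect_equal(sc$detection_limit$value, 10)
  expect_equal(sort(sc$window_diameters$value), c(1.3, 1.7))
  expect_equal(sort(sc$cage_diameters$value), c(3.9, 4.7))
  expect_equal(sort(sc$molecule_dims$value), c(1.14, 1.41, 1.83))
  expect_true(all(vapply(sc[-(1:2)], function(x) nzchar(x$note[1]), logical(1))))
})

test_that("a perfectly linear trace yields its exact fractional rate", {
  t <- seq(0, 60, by = 5)
  sat <- 200
  tr <- data.frame(time_min = t, mean_intensity = sat * 0.10 * t / 60,
                   mask_area = 1)
  class(tr) <- c("intensity_trace", "data.frame")
  expect_equal(initial_uptake_rate(tr, 60, saturation = sat), 0.10)
  expect_error(initial_uptake_rate(tr[1:2, ], 60, saturation = sat), "at least 3")
  expect_error(initial_uptake_rate(tr, 120, saturation = sat), "beyond")
})

test_that("simulated initial uptake matches the Dirichlet-cube series solution", {
  a <- 100; h <- 2
  g <- crystal_geometry(a, h)
  D_um <- 0.03                                 # 3e-14 m^2/s
  ts <- seq(5, 60, by = 5)
  tr <- uptake_fraction_trace(g, 3e-14, ts)
  r_meas <- initial_uptake_rate(tr, 60, saturation = 100)
  frac_an <- vapply(ts * 60, cube_fraction, numeric(1), D_um = D_um, L = a - h)
  tr_an <- data.frame(time_min = c(0, ts), mean_intensity = c(0, frac_an) * 100,
                      mask_area = 1)
  class(tr_an) <- c("intensity_trace", "data.frame")
  r_an <- initial_uptake_rate(tr_an, 60, saturation = 100)
  expect_equal(r_meas, r_an, tolerance = 0.15)
})

test_that("longer windows see the sqrt-law concavity (lower rate)", {
  g <- crystal_geometry(100, 2)
  ts <- seq(5, 240, by = 5)
  tr <- uptake_fraction_trace(g, 3e-14, ts)
  r_short <- initial_uptake_rate(tr, 60, saturation = 100)
  r_long <- initial_uptake_rate(tr, 240, saturation = 100)
  expect_lt(r_long, r_short)
})

test_that("bigger crystals load more slowly per unit capacity", {
  ts <- seq(5, 60, by = 5)
  r60 <- initial_uptake_rate(uptake_fraction_trace(crystal_geometry(60, 2), 3e-14, ts),
                             60, saturation = 100)
  r100 <- initial_uptake_rate(uptake_fraction_trace(crystal_geometry(100, 2), 3e-14, ts),
                              60, saturation = 100)
  expect_gt(r60, r100)
})

test_that("half-saturation times order corner < edge < face < centre", {
  g <- crystal_geometry(64, 2)                  # 32^3, all faces exposed
  st <- c(seq(0.25, 20, by = 0.25), seq(21, 120, by = 1), seq(125, 400, by = 5))
  fl <- simulate_diffusion(g, diffusion_params(3e-14), "uptake", st)
  so <- saturation_ordering(fl, g)
  expect_true(so$ordered)
  expect_equal(names(so$t50),
               c("corner", "edge_midpoint", "face_center", "body_center"))
  expect_true(all(diff(so$t50) > 0))
})

test_that("sealed faces exclude their probes but keep corner-vs-centre ordering", {
  g <- crystal_geometry(40, 2, exposed_faces = "x-")
  st <- c(seq(1, 60, by = 1), seq(65, 2500, by = 15))
  fl <- simulate_diffusion(g, diffusion_params(3e-14), "uptake", st)
  so <- saturation_ordering(fl, g)
  expect_setequal(names(so$t50), c("face_center", "body_center"))
  expect_lt(so$t50["face_center"], so$t50["body_center"])
})

test_that("an already-saturated run makes the ordering vacuous", {
  g <- crystal_geometry(20, 2)
  fields <- list(build_field(g, 1), build_field(g, 1))
  fields[[2]]$time <- 10
  so <- saturation_ordering(fields, g)
  expect_true(all(so$t50 == 0))
  expect_true(is.na(so$ordered))
})
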