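test_that("empty field with empty bath is a fixed point", {
  g <- crystal_geometry(20, 2)
  p <- diffusion_params(1e-13, boundary_occupancy = 0)
  f <- step_diffusion(build_field(g, 0), g, p, n_steps = 50)
  expect_true(all(f$occupancy == 0))
})

test_that("sealed crystal conserves total occupancy over 1000 steps", {
  g <- crystal_geometry(24, 2, exposed_faces = character(0))
  p <- diffusion_params(1e-13, dt = 0.9 * stability_dt(crystal_geometry(24, 2),
                                                       diffusion_params(1e-13)))
  f <- build_field(g, 0)
  f$occupancy[] <- with_seed_test(1, stats::runif(length(f$occupancy)))
  s0 <- sum(f$occupancy)
  f2 <- step_diffusion(f, g, p, n_steps = 1000)
  expect_lt(abs(sum(f2$occupancy) - s0) / s0, 1e-9)
  expect_true(all(f2$occupancy >= 0 & f2$occupancy <= 1))
})

test_that("the solver refuses unstable time steps", {
  g <- crystal_geometry(20, 2)
  bound <- stability_dt(g, diffusion_params(1e-13))
  expect_error(
    step_diffusion(build_field(g, 0), g,
                   diffusion_params(1e-13, dt = bound * 1.5)),
    "stability")
  # just inside the bound is accepted
  f <- step_diffusion(build_field(g, 0), g,
                      diffusion_params(1e-13, dt = bound * 0.999))
  expect_s3_class(f, "concentration_field")
})

test_that("occupancy stays within [0, 1] during uptake at the stability limit", {
  g <- crystal_geometry(20, 2)
  p <- diffusion_params(1e-13, dt = stability_dt(g, diffusion_params(1e-13)))
  f <- step_diffusion(build_field(g, 0), g, p, n_steps = 200)
  expect_gte(min(f$occupancy), 0)
  expect_lte(max(f$occupancy), 1)
})

test_that("one-face uptake matches the 1D half-space erfc profile within 2% RMS", {
  g <- crystal_geometry(c(120, 12, 12), 1.2, exposed_faces = "x-")
  D_um <- 0.1                       # 1e-13 m^2/s
  t_end <- 1000                     # s; front ~ sqrt(D t) = 10 um, far wall untouched
  n_steps <- ceiling(t_end / (0.99 * g$voxel_pitch^2 / (6 * D_um)))
  p <- diffusion_params(1e-13, dt = t_end / n_steps)
  f <- step_diffusion(build_field(g, 0), g, p, n_steps = n_steps)
  prof <- apply(f$occupancy, 1, mean)
  x <- (seq_along(prof) - 0.5) * g$voxel_pitch
  x0 <- 0.5 * g$voxel_pitch         # Dirichlet layer voxel centre
  oracle <- pracma::erfc((x - x0) / (2 * sqrt(D_um * t_end)))
  expect_lt(sqrt(mean((prof - oracle)^2)), 0.02)
})

test_that("short-time interior uptake grows like sqrt(t)", {
  g <- crystal_geometry(c(120, 3.6, 3.6), 0.6, exposed_faces = "x-")
  tau_sat <- 120^2 / 0.1            # L^2 / D in seconds
  ts_s <- exp(seq(log(0.001 * tau_sat), log(0.01 * tau_sat), length.out = 8))
  fl <- simulate_diffusion(g, diffusion_params(1e-13), "uptake", ts_s / 60)
  U <- vapply(fl, function(f) total_occupancy(f, g, exclude_clamped = TRUE),
              numeric(1))
  slope <- unname(stats::coef(stats::lm(log(U) ~ log(ts_s)))[2])
  expect_gt(slope, 0.45)
  expect_lt(slope, 0.55)
})

test_that("release runs are monotone non-increasing in total occupancy", {
  g <- crystal_geometry(30, 2)
  fl <- simulate_diffusion(g, diffusion_params(2e-14), "release",
                           c(5, 20, 60, 150, 400, 1000))
  tot <- vapply(fl, total_occupancy, numeric(1))
  expect_true(all(diff(tot) < 0))
})

test_that("defect voxels act as extra bath-held surface", {
  g0 <- crystal_geometry(12, 1, exposed_faces = "x-")
  gd <- crystal_geometry(12, 1, exposed_faces = "x-",
                         defects = list(rbind(c(12, 6, 6))))
  fl0 <- simulate_diffusion(g0, diffusion_params(1e-13), "uptake", 5)[[1]]
  fld <- simulate_diffusion(gd, diffusion_params(1e-13), "uptake", 5)[[1]]
  expect_equal(fld$occupancy[12, 6, 6], 1)
  # uptake near the defect outruns the defect-free control
  expect_gt(fld$occupancy[11, 6, 6], fl0$occupancy[11, 6, 6])
})

test_that("sample times must be strictly increasing", {
  g <- crystal_geometry(10, 1)
  expect_error(simulate_diffusion(g, diffusion_params(1e-13), "uptake",
                                  c(10, 10, 20)), "strictly increasing")
})

test_that("simulation snapshots are deterministic and land on sample times", {
  g <- crystal_geometry(16, 2)
  a <- simulate_diffusion(g, diffusion_params(5e-14), "uptake", c(3, 9, 27))
  b <- simulate_diffusion(g, diffusion_params(5e-14), "uptake", c(3, 9, 27))
  expect_identical(lapply(a, `[[`, "occupancy"), lapply(b, `[[`, "occupancy"))
  expect_equal(vapply(a, `[[`, numeric(1), "time"), c(3, 9, 27))
})

test_that("face-dependent diffusivity builds slow layers under slow faces", {
  g <- crystal_geometry(12, 1)
  D <- stats::setNames(rep(2e-13, 6), mofdiff:::ALL_FACES)
  D["x-"] <- 5e-14
  dv <- mofdiff:::diffusivity_field(g, diffusion_params(D))
  expect_equal(dv[1, 6, 6], 0.05)   # um^2/s under the slow face
  expect_equal(dv[2, 6, 6], 0.05)   # two-voxel layer
  expect_equal(dv[6, 6, 6], 0.2)    # interior uses max(D_face)
  expect_equal(dv[12, 6, 6], 0.2)   # fast face keeps its own value
})
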