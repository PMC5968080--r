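test_that("area and volume of reference solids match closed forms", {
  cube <- mesh_cube(10)
  expect_equal(mesh_surface_area(cube), 6)
  expect_equal(mesh_volume(cube), 1)
  ico <- mesh_icosphere(10, 4)
  expect_lt(abs(mesh_surface_area(ico) - 4 * pi) / (4 * pi), 0.005)
  expect_lt(abs(mesh_volume(ico) - 4 * pi / 3) / (4 * pi / 3), 0.01)
})

test_that("degenerate faces, orientation and watertightness are handled", {
  cube <- mesh_cube(10)
  # an extra zero-area triangle leaves the total unchanged
  degen <- tri_mesh(cube$vertices, rbind(cube$faces, c(1, 1, 2)))
  expect_equal(mesh_surface_area(degen), mesh_surface_area(cube))
  # inside-out cube: volume is orientation-independent by contract
  flipped <- tri_mesh(cube$vertices, cube$faces[, c(1, 3, 2)])
  expect_equal(mesh_volume(flipped), 1)
  # open mesh is rejected with the boundary-edge count
  open <- tri_mesh(cube$vertices, cube$faces[-1, , drop = FALSE])
  expect_error(mesh_volume(open), "not watertight: 3")
  expect_false(is_watertight(open))
})

test_that("area and volume are rigid-motion invariant and scale as k^2 / k^3", {
  mesh <- mesh_icosphere(7, 2)
  a0 <- mesh_surface_area(mesh); v0 <- mesh_volume(mesh)
  set.seed(21)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  moved <- transform_mesh(mesh, rotation = q, translation = c(12, -5, 3))
  expect_equal(mesh_surface_area(moved), a0, tolerance = 1e-9)
  expect_equal(mesh_volume(moved), v0, tolerance = 1e-9)
  for (k in c(0.5, 2.4)) {
    sc <- transform_mesh(mesh, scale = k)
    expect_equal(mesh_surface_area(sc), a0 * k^2, tolerance = 1e-9)
    expect_equal(mesh_volume(sc), v0 * k^3, tolerance = 1e-9)
  }
})

test_that("reliability statistics reproduce hand-computed values", {
  r <- reliability(measurement_set("toy", c(1, 3)))
  expect_equal(r$mean_mm, 2)
  expect_equal(r$sd_mm, sqrt(2))
  expect_equal(r$cv_percent, 100 * sqrt(2) / 2)
  expect_equal(r$max_rel_dev_percent, 50)
  expect_equal(r$range_mm, c(1, 3))
  same <- reliability(measurement_set("same", rep(4.2, 5)))
  expect_equal(same$cv_percent, 0)
  expect_equal(same$max_rel_dev_percent, 0)
  expect_error(measurement_set("x", 5), "at least 2")
  expect_error(measurement_set("x", c(1, -1)), "positive")
})

test_that("summary-based CV and deviation reproduce the observer study table", {
  tab <- read.csv(system.file("extdata", "observer_measurement_summary.csv",
                              package = "disc3d"))
  row <- function(m, meth) tab[tab$measurement == m & tab$method == meth, ]
  expect_equal(round(cv_from_summary(row("sc", "2D")$mean_mm,
                                     row("sc", "2D")$sd_mm), 1), 8.0)
  expect_equal(round(cv_from_summary(row("ti", "2D")$mean_mm,
                                     row("ti", "2D")$sd_mm), 1), 8.3)
  expect_equal(round(cv_from_summary(row("ti", "3D")$mean_mm,
                                     row("ti", "3D")$sd_mm), 1), 1.1)
  r3 <- row("sc", "3D")
  expect_equal(round(max_rel_dev_from_summary(r3$mean_mm, r3$min_mm,
                                              r3$max_mm), 1), 5.5)
  t3 <- row("ti", "3D")
  expect_equal(round(max_rel_dev_from_summary(t3$mean_mm, t3$min_mm,
                                              t3$max_mm), 1), 2.4)
})

test_that("variance-ratio test matches hand arithmetic and the F distribution", {
  a <- measurement_set("a", c(0, 2, 4) + 1)  # variance 4 (shifted positive)
  b <- measurement_set("b", c(1, 2, 3))      # variance 1
  vr <- variance_ratio_test(a, b)
  expect_equal(vr$F, 4)
  expect_equal(vr$df, c(2, 2))
  expect_equal(vr$p_value, 2 * pf(4, 2, 2, lower.tail = FALSE))
  # identical sets: F = 1, p = 1
  same <- variance_ratio_test(b, b)
  expect_equal(same$F, 1)
  expect_equal(same$p_value, 1)
  # at the study's sample size, F = 9.87 is far beyond the 1e-4 tail
  expect_lt(2 * pf(9.87, 21, 21, lower.tail = FALSE), 1e-4)
  expect_error(variance_ratio_test(b, measurement_set("c", c(2, 2))),
               "zero variance")
})

test_that("measurement CSV tables load into sets and reports", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(label = rep(c("sc", "ti"), each = 3),
                       observer = rep(1:3, 2),
                       value_mm = c(2.6, 2.7, 2.8, 6.5, 6.6, 6.7)),
            f, row.names = FALSE)
  sets <- read_measurement_csv(f)
  expect_setequal(names(sets), c("sc", "ti"))
  expect_equal(reliability(sets$sc)$mean_mm, 2.7)
  expect_equal(reliability(sets$ti)$n, 3)
})
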