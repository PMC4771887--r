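test_that("closed-form thickness inverts Beer's law", {
  i0 <- 1e4
  mu <- 0.0229
  expect_equal(estimate_thickness(matrix(i0), i0, mu)[1, 1], 0)
  expect_equal(estimate_thickness(matrix(i0 * exp(-mu * 50)), i0, mu)[1, 1],
               50)
  # above-flat-field pixels clamp to zero thickness
  expect_equal(estimate_thickness(matrix(1.2 * i0), i0, mu)[1, 1], 0)
  # near-zero intensities are floored, map stays finite
  tmap <- estimate_thickness(matrix(c(0, 1e-9)), i0, mu)
  expect_true(all(is.finite(tmap)))
  expect_equal(tmap[1, 1], log(1 / 1e-6) / mu)
  expect_error(estimate_thickness(matrix(1), i0, mu = -1), "mu_pmma")
  expect_error(estimate_thickness(matrix(1), i0 = 0), "i0")
})

test_that("log-signal LUT matches the closed form on Beer's-law samples", {
  i0 <- 1e4
  mu <- 0.0229
  tcal <- seq(10, 200, by = 10)
  lut <- build_log_signal_lut(tcal, i0 * exp(-mu * tcal), i0)
  probe <- matrix(seq(5, 195, by = 5) * mu, nrow = 1)  # log-signal values
  got <- cbctscatter:::eval_log_signal_lut(lut, probe)
  expect_equal(as.numeric(got), seq(5, 195, by = 5), tolerance = 1e-8)
  # querying exactly at a sample returns its thickness
  expect_equal(cbctscatter:::eval_log_signal_lut(lut, matrix(mu * 10))[1, 1],
               10)
  # signal above the zero-thickness flat field -> thickness 0
  expect_equal(cbctscatter:::eval_log_signal_lut(lut, matrix(-0.3))[1, 1], 0)
  # LUT route through estimate_thickness agrees with the closed form
  img <- matrix(i0 * exp(-mu * c(25, 80, 140)), nrow = 1)
  expect_equal(estimate_thickness(img, i0, mu, lut = lut),
               estimate_thickness(img, i0, mu), tolerance = 1e-8)
})

test_that("LUT construction rejects non-monotone samples, naming the pair", {
  expect_error(build_log_signal_lut(c(10, 20, 15), c(900, 800, 850), 1e3),
               "thicknesses not strictly increasing at pair 2 -> 3")
  expect_error(build_log_signal_lut(c(10, 20, 30), c(900, 950, 800), 1e3),
               "signals not strictly decreasing at pair 1 -> 2")
  expect_error(build_log_signal_lut(10, 900, 1e3), ">= 2")
})

test_that("thickness partition is complete, disjoint, and matches per-pixel binning", {
  set.seed(42)
  edges <- default_group_edges()
  img <- matrix(runif(64 * 64, 1, 100), 64, 64)
  tmap <- matrix(runif(64 * 64, 0, 220), 64, 64)
  tmap[sample(64 * 64, 200)] <- 0
  tmap[sample(64 * 64, 17)] <- 40  # pixels exactly on a group edge
  subs <- partition_by_thickness(img, tmap, edges)
  masks <- attr(subs, "masks")
  # disjoint and complete on the t > 0 support
  cover <- Reduce(`+`, masks)
  expect_true(all(cover[tmap > 0] == 1))
  expect_true(all(cover[tmap == 0] == 0))
  # reassembly is exact
  expect_identical(Reduce(`+`, subs)[tmap > 0], img[tmap > 0])
  # brute-force per-pixel membership check
  upper <- c(edges[-1], Inf)
  for (g in seq_along(edges)) {
    ref <- tmap > edges[g] & tmap <= upper[g]
    expect_identical(masks[[g]], ref)
  }
  # representative thicknesses are the bin centres
  expect_equal(attr(subs, "centers"), c(20, 60, 100, 140, 180))
})

test_that("uniform-thickness image occupies exactly one group", {
  img <- matrix(5, 8, 8)
  tmap <- matrix(97, 8, 8)
  subs <- partition_by_thickness(img, tmap)
  nonempty <- vapply(subs, function(s) any(s != 0), logical(1))
  expect_equal(which(nonempty), 3L)
  expect_identical(subs[[3]], img)
})

test_that("emission floor removes near-air pixels from the first group only", {
  img <- matrix(1, 4, 4)
  tmap <- matrix(c(1, 3, 6, 50), 4, 4, byrow = TRUE)
  subs <- partition_by_thickness(img, tmap, t_floor = 5)
  expect_equal(sum(attr(subs, "masks")[[1]]), sum(tmap > 5 & tmap <= 40))
  expect_equal(sum(attr(subs, "masks")[[2]]), sum(tmap == 50))
})

test_that("thickness map of a simulated slab recovers the true thickness", {
  mu <- material_attenuation()[["pmma"]]
  ph <- generate_slab_phantom(50, width_mm = 360, voxel_mm = 2, mu = mu)
  geom <- acquisition_geometry(dso = 500, dsd = 786, pitch = 2.4,
                               det_rows = 65L, det_cols = 65L, n_views = 1L)
  pr <- forward_project(ph, geom, i0 = 1e4, check_fov = FALSE)
  tmap <- estimate_thickness(pr)[, , 1]
  # interior region (small incidence angles): within 1 mm of the truth
  interior <- tmap[28:38, 28:38]
  expect_true(all(abs(interior - 50) < 1))
})
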