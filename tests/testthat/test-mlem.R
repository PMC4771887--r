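test_that("frequency-domain convolution matches the direct spatial oracle", {
  set.seed(7)
  for (rep in 1:5) {
    img <- matrix(runif(16 * 16, 0, 100), 16, 16)
    ker <- matrix(runif(5 * 5), 5, 5)
    got <- scatter_convolve(list(img), list(ker))
    ref <- direct_convolve_same(img, ker)
    expect_lt(max(abs(got - ref)), 1e-10)
  }
  # multi-group linearity against the oracle
  img2 <- matrix(runif(16 * 16, 0, 50), 16, 16)
  k2 <- matrix(runif(5 * 5), 5, 5)
  got <- scatter_convolve(list(img, img2), list(ker, k2))
  ref <- direct_convolve_same(img, ker) + direct_convolve_same(img2, k2)
  expect_lt(max(abs(got - ref)), 1e-10)
})

test_that("convolving a delta image reproduces the kernel at the delta", {
  img <- matrix(0, 21, 21)
  img[11, 11] <- 1
  ker <- make_parametric_psf(60, pitch = 2, grid_size = 7L)
  out <- scatter_convolve(list(img), list(unclass(ker)))
  expect_equal(out[8:14, 8:14], unclass(ker), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(out), 1, tolerance = 1e-12)
})

test_that("all-zero subprojections give a zero scatter image", {
  z <- matrix(0, 8, 8)
  k <- matrix(1 / 9, 3, 3)
  expect_identical(scatter_convolve(list(z, z), list(k, k)), z)
})

test_that("convolution rejects mismatched shapes and even kernels", {
  expect_error(scatter_convolve(list(matrix(0, 4, 4), matrix(0, 5, 5)),
                                list(matrix(1, 3, 3), matrix(1, 3, 3))),
               "shapes differ")
  expect_error(scatter_convolve(list(matrix(0, 4, 4)),
                                list(matrix(1, 2, 2))), "odd")
  expect_error(scatter_convolve(list(matrix(0, 4, 4)), list()),
               "one kernel per")
})

test_that("log-likelihood has the Poisson form and maximum", {
  ones <- matrix(1, 5, 5)
  expect_equal(log_likelihood(ones, ones), -25)
  m <- matrix(c(3, 7, 0, 2), 2, 2)
  expect_gt(log_likelihood(m, pmax(m, 1e-12)),
            log_likelihood(m, pmax(0.5 * m, 1e-12)))
  expect_error(log_likelihood(m, matrix(0, 2, 2)), "> 0")
})

test_that("one update with zero kernels returns the measurement bit-exactly", {
  geom <- tiny_geometry(n_views = 2L)
  ph <- generate_qrm_like_phantom(160, NULL, voxel_mm = 4, nz = 16L)
  db0 <- build_kernel_database(
    t_max = 200L, pitch = 4.8, grid_size = 21L,
    amp_table = list(upper = c(40, 80, 120, 160),
                     values = rep(0, 5)))
  sim <- simulate_projections(ph, geom, i0 = 1e4, db = db0)
  expect_identical(sim$measured$intensity, sim$primary$intensity)
  im <- sim$measured$intensity[, , 1]
  upd <- mlem_update(im, im, 1e4, db0)
  expect_identical(upd, im)
})

test_that("measured signal dominates the primary after adding scatter", {
  geom <- tiny_geometry(n_views = 2L)
  ph <- generate_qrm_like_phantom(160, NULL, voxel_mm = 4, nz = 16L)
  db <- tiny_kernel_db(grid_size = 51L)
  sim <- simulate_projections(ph, geom, i0 = 1e4, db = db)
  expect_true(all(sim$measured$intensity >= sim$primary$intensity))
  expect_gt(max(sim$measured$intensity - sim$primary$intensity), 0)
})

test_that("grouped scatter addition conserves the emitted energy per group", {
  # uniform-thickness slab: one group, kernel of mass A * SF; apart from
  # boundary truncation the total scatter equals that mass times the
  # total primary energy, and padding the image recovers the identity
  mu <- material_attenuation()[["pmma"]]
  t_slab <- 100
  i0 <- 1e4
  ip <- matrix(i0 * exp(-mu * t_slab), 40, 40)
  db <- tiny_kernel_db(grid_size = 31L)
  tmap <- estimate_thickness(ip, i0)
  expect_equal(tmap[1, 1], t_slab, tolerance = 1e-9)
  subs <- partition_by_thickness(ip, tmap)
  sc <- scatter_convolve(subs, cbctscatter:::group_kernels(
    db, default_group_edges()))
  mass <- amplitude_of_thickness(100) * sf_of_thickness(100)
  # interior pixels see nearly the full kernel mass; the border loses tail
  expect_lt(sum(sc), mass * sum(ip) + 1e-9)
  expect_gt(sum(sc), 0.5 * mass * sum(ip))
  # embed in a padded frame: the centre then collects the whole mass
  pad <- matrix(0, 120, 120)
  pad[41:80, 41:80] <- ip
  tpad <- matrix(0, 120, 120)
  tpad[41:80, 41:80] <- t_slab
  scp <- scatter_convolve(partition_by_thickness(pad, tpad),
                          cbctscatter:::group_kernels(
                            db, default_group_edges()))
  expect_equal(sum(scp), mass * sum(ip), tolerance = 1e-6)
})

test_that("disjoint thickness groups correct independently (linearity)", {
  db <- tiny_kernel_db(grid_size = 21L)
  kern <- cbctscatter:::group_kernels(db, default_group_edges())
  imgA <- matrix(0, 30, 30); imgA[5:10, 5:10] <- 50
  imgB <- matrix(0, 30, 30); imgB[20:25, 20:25] <- 80
  tmap <- matrix(0, 30, 30)
  tmap[imgA > 0] <- 30   # group 1
  tmap[imgB > 0] <- 110  # group 3
  both <- scatter_convolve(partition_by_thickness(imgA + imgB, tmap), kern)
  onlyA <- scatter_convolve(partition_by_thickness(imgA, tmap * (imgA > 0)),
                            kern)
  onlyB <- scatter_convolve(partition_by_thickness(imgB, tmap * (imgB > 0)),
                            kern)
  expect_equal(both, onlyA + onlyB, tolerance = 1e-12)
})

test_that("scatter-free correction is the identity after one iteration", {
  geom <- tiny_geometry(n_views = 3L)
  ph <- generate_qrm_like_phantom(160, NULL, voxel_mm = 4, nz = 16L)
  db0 <- build_kernel_database(
    t_max = 200L, pitch = 4.8, grid_size = 21L,
    amp_table = list(upper = c(40, 80, 120, 160), values = rep(0, 5)))
  sim <- simulate_projections(ph, geom, i0 = 1e4, db = db0)
  res <- run_scatter_correction(sim$measured, db0, max_iter = 5L)
  expect_identical(res$corrected$intensity, sim$measured$intensity)
  expect_true(all(res$iterations == 1L))
  expect_true(all(res$converged))
})

test_that("correction is stable under extra iterations once converged", {
  geom <- tiny_geometry(n_views = 1L)
  ph <- generate_qrm_like_phantom(160, NULL, voxel_mm = 4, nz = 16L)
  db <- tiny_kernel_db(grid_size = 51L)
  sim <- simulate_projections(ph, geom, i0 = 1e4, db = db)
  r1 <- run_scatter_correction(sim$measured, db, max_iter = 12L,
                               tol = 1e-6, warn_nonconverged = FALSE)
  r2 <- run_scatter_correction(sim$measured, db, max_iter = 24L,
                               tol = 1e-6, warn_nonconverged = FALSE)
  expect_true(all(r1$converged))
  expect_equal(r1$corrected$intensity, r2$corrected$intensity,
               tolerance = 1e-6)
  # feeding the converged estimate back changes it below tolerance
  est <- r1$corrected$intensity[, , 1]
  upd <- mlem_update(est, sim$measured$intensity[, , 1], 1e4, db)
  expect_lt(max(abs(upd - est) / 1e4), 1e-3)
})

test_that("iterates stay strictly positive where the measurement is positive", {
  geom <- tiny_geometry(n_views = 1L)
  ph <- generate_qrm_like_phantom(160, NULL, voxel_mm = 4, nz = 16L)
  db <- tiny_kernel_db(grid_size = 51L)
  sim <- simulate_projections(ph, geom, i0 = 1e4, db = db)
  res <- run_scatter_correction(sim$measured, db, max_iter = 5L,
                                warn_nonconverged = FALSE)
  pos <- sim$measured$intensity > 0
  expect_true(all(res$corrected$intensity[pos] > 0))
})

test_that("non-convergence at max_iter warns and is flagged", {
  geom <- tiny_geometry(n_views = 1L)
  ph <- generate_qrm_like_phantom(160, NULL, voxel_mm = 4, nz = 16L)
  db <- tiny_kernel_db(grid_size = 51L)
  sim <- simulate_projections(ph, geom, i0 = 1e4, db = db)
  expect_warning(res <- run_scatter_correction(sim$measured, db,
                                               max_iter = 1L, tol = 1e-12),
                 "without meeting")
  expect_false(any(res$converged))
})
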