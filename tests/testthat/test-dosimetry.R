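test_that("bundled kernels respect support, normalization, and monotonicity", {
  ka <- build_kernel("Ac225", pixel_size_um = 4)
  # alpha support <= 50 um -> at most 13-voxel diameter at 4 um
  expect_lte(nrow(ka$S), 2 * 13 + 1)
  expect_lte(max(which(ka$S > 0, arr.ind = TRUE) - ka$center[1]), 13)

  kb <- build_kernel("Lu177", pixel_size_um = 8)
  # beta support ~1.6 mm -> 200-voxel radius at 8 um
  expect_equal((nrow(kb$S) - 1) / 2, 200)

  for (k in list(ka, kb)) {
    # normalization: kernel sum x voxel mass = energy per decay
    expect_lt(abs(sum(k$S) * k$voxel_mass_kg - k$energy_per_decay_J) /
                k$energy_per_decay_J, 1e-6)
    # center is the maximum; radially non-increasing along the axis
    expect_equal(which.max(k$S), (k$center[2] - 1) * nrow(k$S) + k$center[1])
    row_from_center <- k$S[k$center[1], k$center[2]:ncol(k$S)]
    expect_true(all(diff(row_from_center) <= 1e-15))
  }

  # support below one voxel: single-voxel kernel with all energy local
  k1 <- build_kernel("Ac225", pixel_size_um = 120)
  expect_equal(dim(k1$S), c(1L, 1L))
  expect_equal(k1$S[1, 1] * k1$voxel_mass_kg, k1$energy_per_decay_J)
})

test_that("S-value kernels load from CSV", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(d_offset_i = c(0, 1, -1), d_offset_j = c(0, 0, 0),
                       S_Gy_per_decay = c(5, 1, 1)), f, row.names = FALSE)
  k <- build_kernel("Lu177", pixel_size_um = 10, source = f)
  expect_equal(k$S[k$center[1], k$center[2]], 5)
  expect_equal(k$S[k$center[1] + 1, k$center[2]], 1)
  unlink(f)
  expect_error(build_kernel("Lu177", 10, source = {
    f2 <- tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1), f2); f2
  }), "columns")
})

test_that("dose convolution: point source, FFT-vs-brute-force, zero field", {
  k <- build_kernel("Ac225", pixel_size_um = 10)
  z <- compute_dose(matrix(0, 20, 20), k)
  expect_equal(max(z$D), 0)

  # single nonzero voxel reproduces the kernel
  a <- matrix(0, 21, 21); a[11, 11] <- 2
  d <- compute_dose(a, k, method = "direct")
  r <- (nrow(k$S) - 1) / 2
  expect_equal(d$D[(11 - r):(11 + r), (11 - r):(11 + r)], 2 * k$S,
               tolerance = 1e-12)

  # FFT equals the brute-force sum to 1e-8 relative on random activity
  set.seed(3)
  a32 <- matrix(rexp(32 * 32), 32, 32)
  kk <- build_kernel("Ac225", pixel_size_um = 6)
  dfft <- compute_dose(a32, kk, method = "fft")$D
  ddir <- compute_dose(a32, kk, method = "direct")$D
  dref <- brute_conv(a32, kk$S)
  expect_lt(max(abs(dfft - dref)) / max(dref), 1e-8)
  expect_lt(max(abs(ddir - dref)) / max(dref), 1e-12)
})

test_that("uniform activity on a large interior gives mean dose = A * sum(S)", {
  k <- build_kernel("Ac225", pixel_size_um = 12)
  r <- (nrow(k$S) - 1) / 2
  n <- 8 * r
  a <- matrix(1.5, n, n)
  d <- compute_dose(a, k)
  interior <- d$D[(r + 1):(n - r), (r + 1):(n - r)]
  expect_lt(max(abs(interior - 1.5 * sum(k$S))) / (1.5 * sum(k$S)), 0.005)
})

test_that("DTH curves are cumulative, monotone, and enumerate correctly", {
  vm <- vessel_map(matrix(c(TRUE, rep(FALSE, 8)), 3, 3), 10)
  ox <- solve_oxygen(vm, oxygen_params(M0 = 0), criterion = 1e-6)
  ox$P[!vm$mask] <- c(20, 20, 20, 1, 1, 1, 1, 1)[seq_len(8)]
  seg <- segment_tissue(ox, vm)
  d <- structure(list(D = matrix(10, 3, 3), radionuclide = "Lu177",
                      pixel_size_um = 10), class = "dose_map")
  # empty classes (this crafted field has only two) warn and are omitted
  expect_warning(expect_warning(dth <- compute_dth(d, seg, n_bins = 50),
                                "no pixels"), "no pixels")
  # uniform 10 Gy: fraction 1 at thresholds <= 10
  expect_true(all(dth$table$fraction == 1))
  # identical dose fields give identical DTHs across classes
  ph <- dth$table[dth$table$class == "physoxia", "fraction"]
  rb <- dth$table[dth$table$class == "radiobiological_hypoxia", "fraction"]
  expect_equal(ph, rb)

  # enumerated fractions: doses {2, 6, 10} at threshold 5 -> 2/3
  d$D[!vm$mask] <- c(2, 6, 10, 2, 6, 10, 2, 6)
  expect_equal(
    fraction_receiving(d, seg, "physoxia", 5), 2 / 3)
  dth2 <- suppressWarnings(compute_dth(d, seg, n_bins = 101))
  for (cl in unique(dth2$table$class)) {
    fr <- dth2$table[dth2$table$class == cl, "fraction"]
    expect_equal(fr[1], 1)
    expect_true(all(diff(fr) <= 0))
    expect_true(all(fr >= 0 & fr <= 1))
  }
})

test_that("dose-oxygen regression recovers exact and noisy slopes", {
  x <- c(0.5, 1, 2, 4, 8)
  rec <- data.frame(median_po2 = x, mean_dose = 1.24 * log10(x) + 3)
  fit <- suppressWarnings(dose_oxygen_regression(rec))  # exact fit
  expect_equal(fit$slope, 1.24, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  expect_error(dose_oxygen_regression(rec[1:2, ]), "at least 3")
  rec$median_po2[1] <- -1
  expect_error(dose_oxygen_regression(rec), "positive")

  # noisy points: OLS matches the closed-form normal equations
  set.seed(8)
  x <- 10^runif(10, -0.5, 1)
  y <- 0.86 * log10(x) + 5 + rnorm(10, 0, 0.3)
  rec <- data.frame(median_po2 = x, mean_dose = y)
  fit <- dose_oxygen_regression(rec)
  X <- cbind(1, log10(x))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
})
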