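test_that("huang threshold separates two-level and bimodal images", {
  img <- matrix(c(rep(10, 30), rep(200, 70)), 10, 10)
  thr <- huang_threshold(img)
  expect_gt(thr, 10)
  expect_lt(thr, 200)

  # constant image has no threshold
  expect_error(huang_threshold(matrix(7, 5, 5)), "no threshold")

  # bimodal 8-bit image: agree with the exhaustive-search oracle
  set.seed(42)
  g <- c(rnorm(1e4, 50, 10), rnorm(1e4, 180, 10))
  g <- pmin(pmax(round(g), 0), 255)
  img <- matrix(g, 200, 100)
  thr <- huang_threshold(img)
  expect_gt(thr, 80)
  expect_lt(thr, 150)
  # the package threshold must attain the oracle's minimal fuzziness
  # (the valley between well-separated modes is flat, so compare by value)
  orc <- huang_oracle(img)
  expect_lt(orc$entropy[floor(thr) + 1],
            min(orc$entropy, na.rm = TRUE) * (1 + 1e-9))

  # inverted image: complementary threshold, classes swap exactly
  thr_inv <- huang_threshold(255 - img)
  expect_lt(abs((255 - thr_inv) - thr), 2)
  expect_identical(img > thr, !((255 - img) > thr_inv))
})

test_that("clean_mask removes specks, fills lumina, and is idempotent", {
  m <- matrix(FALSE, 60, 60)
  m[10:32, 10:32] <- TRUE            # one ~500 px blob
  set.seed(1)
  for (k in 1:20) {                  # twenty <=3 px specks
    i <- sample(36:58, 1); j <- sample(2:58, 1)
    m[i, j] <- TRUE
    if (k %% 2 == 0) m[i, j + 1] <- TRUE
  }
  cleaned <- clean_mask(m, min_object_px = 10)
  expect_true(all(cleaned[10:32, 10:32]))
  expect_false(any(cleaned[36:60, ]))

  # empty mask is preserved
  empty <- matrix(FALSE, 8, 8)
  expect_identical(clean_mask(empty, 10), empty)

  # an annulus is filled to a disk (flood-fill oracle from the border)
  ann <- outer(1:41, 1:41, function(i, j) {
    d2 <- (i - 21)^2 + (j - 21)^2; d2 <= 15^2 & d2 >= 10^2
  })
  filled <- clean_mask(ann, 10)
  disk <- outer(1:41, 1:41, function(i, j) (i - 21)^2 + (j - 21)^2 <= 15^2)
  expect_true(all(filled[disk]))

  # idempotence
  expect_identical(clean_mask(filled, 10), filled)
})

test_that("synthetic maps hit target fractions, reproduce under seed, and cluster", {
  vm <- generate_synthetic_map(synthetic_vessel_spec(0.01, seed = 7),
                               shape = c(400, 400), pixel_size_um = 4)
  expect_gte(vascular_fraction(vm), 0.009)
  expect_lte(vascular_fraction(vm), 0.011)

  vm2 <- generate_synthetic_map(synthetic_vessel_spec(0.01, seed = 7),
                                shape = c(400, 400), pixel_size_um = 4)
  expect_identical(vm$mask, vm2$mask)

  # fraction error <= 10% relative across targets and seeds
  for (vf in c(0.005, 0.02, 0.05)) {
    for (seed in 1:4) {
      m <- generate_synthetic_map(synthetic_vessel_spec(vf, seed = seed),
                                  shape = c(128, 128), pixel_size_um = 12.5)
      expect_lte(abs(vascular_fraction(m) - vf) / vf, 0.10)
    }
  }

  # clustering increases the 95th percentile distance-to-vessel
  un <- generate_synthetic_map(
    synthetic_vessel_spec(0.032, clustering = 0, seed = 3),
    shape = c(200, 200), pixel_size_um = 8)
  cl <- generate_synthetic_map(
    synthetic_vessel_spec(0.032, clustering = 2, seed = 3),
    shape = c(200, 200), pixel_size_um = 8)
  q95 <- function(m) quantile(distance_to_vessel(m)[!m$mask], 0.95)
  expect_gt(q95(cl), q95(un))
})

test_that("vascular fraction and distance transform match first principles", {
  m <- matrix(FALSE, 10, 10); m[3, 7] <- TRUE
  vm <- vessel_map(m, 4)
  expect_equal(vascular_fraction(vm), 0.01)
  expect_equal(vascular_fraction(vessel_map(matrix(FALSE, 5, 5), 4)), 0)

  vm3 <- tiny_map(n = 3, pixel_um = 4, ci = 2, cj = 2, r = 0.5)
  d <- distance_to_vessel(vm3)
  expect_equal(d[2, 2], 0)
  expect_equal(d[1, 2], 4)
  expect_equal(d[1, 1], 4 * sqrt(2), tolerance = 1e-12)

  expect_error(distance_to_vessel(vessel_map(matrix(FALSE, 4, 4), 4)),
               "vessel-free")

  # randomized property: equals brute force exactly on small grids
  set.seed(11)
  for (rep in 1:5) {
    mk <- matrix(runif(48 * 48) < 0.02, 48, 48)
    if (!any(mk)) mk[17, 31] <- TRUE
    vm <- vessel_map(mk, 10)
    expect_equal(distance_to_vessel(vm), brute_distance(mk, 10),
                 tolerance = 1e-9)
  }
})

test_that("vessel masks round-trip through PNG and TIFF", {
  vm <- test_synth_map(0.02, seed = 5, n = 64, pixel_um = 25)
  for (ext in c("png", "tiff")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_vessel_mask(vm, f)
    back <- read_vessel_mask(f, pixel_size_um = 25)
    expect_identical(back$mask, vm$mask)
    unlink(f)
  }
})
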