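# Voxel homogenization: volumes, apparent moduli, angular dependence.

test_that("volume decomposition matches hand arithmetic and conserves the voxel box", {
  v <- voxel_spec(w1 = 0.84, w2 = 0.84, h1 = 0.42, h2 = 0.42,
                  L1 = 1.14, L2 = 1.14, E1 = 100, E2 = 100)
  vf <- volume_fractions(v)
  expect_equal(vf$VB, 1.14 * 1.14 * 0.84)  # 1.091664 mm^3
  expect_equal(vf$VL1 + vf$VS1 + vf$VL2 + vf$VS2, vf$VB)
  expect_equal(vf$VL1, 0.84 * 0.42 * 1.14)
  expect_equal(vf$VS1, 1.14 * 0.42 * (1.14 - 0.84))

  # no gaps: spacing volumes vanish
  v2 <- voxel_spec(1.14, 1.14, 0.42, 0.42, 1.14, 1.14, 100, 100)
  vf2 <- volume_fractions(v2)
  expect_equal(vf2$VS1, 0)
  expect_equal(vf2$VS2, 0)

  # homogeneity: scaling lengths by k scales volumes by k^3
  k <- 2.5
  v3 <- voxel_spec(v$w1 * k, v$w2 * k, v$h1 * k, v$h2 * k,
                   v$L1 * k, v$L2 * k, v$E1, v$E2)
  vf3 <- volume_fractions(v3)
  for (f in c("VL1", "VL2", "VS1", "VS2", "VB"))
    expect_equal(vf3[[f]], vf[[f]] * k^3)
})

test_that("volume conservation holds across 1000 random voxels", {
  set.seed(11)
  for (i in 1:1000) {
    vf <- volume_fractions(random_voxel())
    expect_lt(abs(vf$VL1 + vf$VS1 + vf$VL2 + vf$VS2 - vf$VB) / vf$VB, 1e-12)
  }
})

test_that("voxel_spec rejects invalid parameters by name", {
  expect_error(voxel_spec(-1, 0.84, 0.42, 0.42, 1.14, 1.14, 100, 100),
               "w1.*positive")
  expect_error(voxel_spec(1.2, 0.84, 0.42, 0.42, 1.14, 1.14, 100, 100),
               "w1 <= L2")
  expect_error(voxel_spec(0.84, 1.2, 0.42, 0.42, 1.14, 1.14, 100, 100),
               "w2 <= L1")
})

test_that("apparent moduli match the independently evaluated closed form", {
  # frozen oracle: exact rational evaluation of the homogenization
  # formulas at w = d = 0.84, h1 = 0.84, h2 = 0.42, L = 1.14, E = 100
  v <- voxel_spec(0.84, 0.84, 0.84, 0.42, 1.14, 1.14, 100, 100)
  a <- predict_anisotropy(v)
  expect_equal(a$EL, 69.96278575225944, tolerance = 1e-12)
  expect_equal(a$ET, 53.21637426900585, tolerance = 1e-12)
  expect_equal(a$gamma, 1.3146853146853146, tolerance = 1e-12)
})

test_that("full symmetry gives gamma = 1 and zero spacing gives the Voigt bound", {
  v <- voxel_spec(0.84, 0.84, 0.6, 0.6, 1.14, 1.14, 150, 150)
  expect_equal(predict_anisotropy(v)$gamma, 1)

  # Voigt: no gaps -> rule of mixtures in both directions
  v2 <- voxel_spec(1.2, 1.2, 0.5, 0.3, 1.2, 1.2, 200, 50)
  vf <- volume_fractions(v2)
  a <- predict_anisotropy(v2)
  voigt <- (vf$VL1 * 200 + vf$VL2 * 50) / vf$VB
  expect_equal(a$EL, voigt)
  expect_equal(a$ET, voigt)
  expect_equal(a$gamma, 1)
})

test_that("swapping layer indices maps EL <-> ET and gamma -> 1/gamma", {
  set.seed(21)
  for (i in 1:50) {
    v <- random_voxel()
    a <- predict_anisotropy(v)
    b <- predict_anisotropy(swap_voxel(v))
    expect_equal(b$EL, a$ET, tolerance = 1e-12)
    expect_equal(b$ET, a$EL, tolerance = 1e-12)
    expect_equal(b$gamma, 1 / a$gamma, tolerance = 1e-12)
  }
})

test_that("single-material anisotropy grows with height ratio and spacing", {
  gam <- function(h1, s) {
    predict_anisotropy(voxel_spec(0.84, 0.84, h1, 0.42,
                                  0.84 + s, 0.84 + s, 100, 100))$gamma
  }
  h1s <- seq(0.42, 1.2, length.out = 12)
  expect_true(all(diff(vapply(h1s, gam, numeric(1), s = 0.3)) >= 0))
  ss <- seq(0.05, 0.9, length.out = 12)
  expect_true(all(diff(vapply(ss, gam, numeric(1), h1 = 0.84)) >= 0))
})

test_that("off-axis anisotropy has the required fixed points and reciprocity", {
  v <- voxel_spec(0.84, 0.84, 0.84, 0.42, 1.14, 1.14, 100, 100)
  a <- predict_anisotropy(v)
  for (form in c("ellipse_sqrt", "linear_mix")) {
    expect_equal(anisotropy_at_angle(a, 0, form), a$gamma)
    expect_equal(anisotropy_at_angle(a, 45, form), 1)
    expect_equal(anisotropy_at_angle(a, 90, form), 1 / a$gamma)
    for (phi in c(10, 30, 70)) {
      expect_equal(anisotropy_at_angle(a, phi, form) *
                     anisotropy_at_angle(a, phi + 90, form), 1,
                   tolerance = 1e-12)
    }
  }
  # angles reduce modulo 180 and gamma stays positive
  expect_equal(anisotropy_at_angle(a, 190), anisotropy_at_angle(a, 10))
  expect_true(all(anisotropy_at_angle(a, seq(-180, 360, by = 7.5)) > 0))
})

test_that("voxel specs round-trip through JSON", {
  v <- voxel_spec(0.84, 0.84, 0.84, 0.42, 1.14, 1.14, 100, 55)
  p <- withr::local_tempfile(fileext = ".json")
  write_voxel_spec(v, p)
  expect_equal(read_voxel_spec(p), v)
})
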