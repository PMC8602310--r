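test_that("Yeoh strain energy matches direct polynomial evaluation", {
  expect_equal(yeoh_strain_energy(3, 5.64, 1812, 162), 0)
  # artery constants at I1_dev = 3.01, computed by hand from the polynomial
  x <- 0.01
  expect_equal(yeoh_strain_energy(3.01, 5.64, 1812, 162),
               5.64 * x + 1812 * x^2 + 162 * x^3)
  expect_error(yeoh_strain_energy(2.9, 5.64, 1812, 162), "not attainable")
  # non-decreasing in each coefficient at fixed I1_dev > 3
  w0 <- yeoh_strain_energy(3.05, 10, 100, 50)
  expect_gte(yeoh_strain_energy(3.05, 11, 100, 50), w0)
  expect_gte(yeoh_strain_energy(3.05, 10, 110, 50), w0)
  expect_gte(yeoh_strain_energy(3.05, 10, 100, 60), w0)
})

test_that("uniaxial closed form has the right limits and C30 sensitivity", {
  expect_equal(yeoh_uniaxial_stress(1, 54, 2200, 42.5), 0)
  expect_error(yeoh_uniaxial_stress(-1, 54, 2200, 42.5), "positive")
  # small-strain slope equals 3 mu0 = 6 C10 (incompressible Young's modulus)
  h <- 1e-6
  slope <- yeoh_uniaxial_stress(1 + h, 54, 0, 0) / h
  expect_equal(slope, 6 * 54, tolerance = 1e-4)
  # C30 moves the response only at high strain: doubling C30 barely changes
  # the stress at 10% strain but changes it substantially at 30%
  rel_change <- function(lam) {
    s1 <- yeoh_uniaxial_stress(lam, 5.64, 1812, 162)
    s2 <- yeoh_uniaxial_stress(lam, 5.64, 1812, 324)
    abs(s2 - s1) / s1
  }
  expect_lt(rel_change(1.1), 0.01)
  expect_gt(rel_change(1.3), 5 * rel_change(1.1))
})

test_that("initial shear modulus is 2 C10", {
  expect_equal(initial_shear_modulus(5.64), 11.28)
  expect_equal(initial_shear_modulus(0), 0)
  expect_equal(initial_shear_modulus(1270), 2540)  # calcium ground truth
})

test_that("small-strain Yeoh response matches a linear solid with E = 6 C10", {
  # moderate C20/C10 ratio (lipid-like); the agreement window shrinks as
  # C20/C10 grows
  C10 <- 18; C20 <- 207; C30 <- 422
  for (eps in c(0.002, 0.005, 0.01)) {
    sig <- yeoh_uniaxial_stress(1 + eps, C10, C20, C30)
    expect_equal(sig, 6 * C10 * eps, tolerance = 0.02)
  }
})

test_that("energy slope dW/dI1 stays positive across the search bounds", {
  tab <- material_bounds()
  grid <- expand.grid(C10 = c(1, 10, 100), C20 = c(100, 1000, 10000),
                      C30 = c(0, 42.5, 422), x = c(0, 0.05, 0.2, 0.5))
  dW <- with(grid, C10 + 2 * C20 * x + 3 * C30 * x^2)
  expect_true(all(dW > 0))
  expect_true(all(tab$assigned[is.finite(tab$lower)] >=
                    tab$lower[is.finite(tab$lower)]))
})

test_that("parameter packing yields 4, 8 and 9 free entries by mode", {
  pv_lin <- pack_parameters("linear")
  expect_length(free_values(pv_lin), 4L)
  expect_setequal(names(free_values(pv_lin)),
                  c("artery.E", "mixed.E", "fibrous.E", "lipid.E"))

  pv_y <- pack_parameters("yeoh")
  expect_length(free_values(pv_y), 8L)
  expect_false(any(grepl("C30", names(free_values(pv_y)))))
  expect_false(any(grepl("calcium", names(free_values(pv_y)))))

  pv_9 <- pack_parameters("yeoh9")
  expect_length(free_values(pv_9), 9L)
  expect_true("calcium.C10" %in% names(free_values(pv_9)))
})

test_that("pack/unpack is the identity on free entries and enforces bounds", {
  pv <- pack_parameters("yeoh")
  v <- free_values(pv) * 1.1
  pv2 <- set_free_values(pv, v)
  expect_equal(unname(free_values(pv2)), unname(v))
  # fixed entries untouched
  expect_identical(pv2$value[!pv2$free], pv$value[!pv$free])
  expect_error(set_free_values(pv, rep(1e6, 8)), "bounds")
  # log10 scaling round-trips
  x <- seq(0.05, 0.95, length.out = 8)
  vals <- plaquefe:::values_from_scaled(pv, x)
  expect_equal(plaquefe:::scaled_from_values(pv, vals), x, tolerance = 1e-12)
})

test_that("bounds table edits are validated", {
  ov <- data.frame(tissue = "lipid", param = "E", assigned = 20)
  tab <- material_bounds(ov)
  expect_equal(tab$assigned[tab$tissue == "lipid" & tab$param == "E"], 20)
  expect_error(material_bounds(data.frame(tissue = "lipid", param = "E",
                                          assigned = 1000)),
               "outside its search range")
  expect_error(material_bounds(data.frame(tissue = "bone", param = "E",
                                          assigned = 1)),
               "does not match")
})
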