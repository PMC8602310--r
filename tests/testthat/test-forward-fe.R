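test_that("pressure unit bridge is exact", {
  expect_identical(mmhg_to_kpa(0), 0)
  expect_equal(mmhg_to_kpa(60), 7.99932)
  expect_equal(mmhg_to_kpa(1), 0.133322)
  ld <- load_case(60, 120)
  expect_equal(ld$dp_mmhg, 60)
  expect_equal(ld$dp_kpa, 7.99932)
})

test_that("apply_displacement is additive and zero-safe", {
  mesh <- tiny_vessel()
  U0 <- matrix(0, nrow(mesh$nodes), 2)
  expect_identical(apply_displacement(mesh, U0)$nodes, mesh$nodes)
  set.seed(1)
  U1 <- matrix(rnorm(length(U0), 0, 0.01), nrow(U0), 2)
  U2 <- matrix(rnorm(length(U0), 0, 0.01), nrow(U0), 2)
  expect_equal(apply_displacement(apply_displacement(mesh, U1), U2)$nodes,
               apply_displacement(mesh, U1 + U2)$nodes)
  expect_error(apply_displacement(mesh, U1[-1, ]), "shape")
})

test_that("zero pressure differential leaves the mesh unchanged", {
  mesh <- tiny_vessel()
  for (mode in c("linear", "yeoh")) {
    res <- fe_simulate(mesh, load_case(80, 80), pack_parameters(mode))
    expect_equal(max(abs(res$U)), 0)
    expect_identical(res$deformed$nodes, mesh$nodes)
  }
})

test_that("linear solve reproduces the Lame thick-walled cylinder solution", {
  mesh <- generate_synthetic_vessel(
    synth_vessel_spec(n_circ = 64, n_rad = 8, lumen_offset = c(0, 0),
                      inclusions = list()))
  ld <- load_case(60, 120)
  res <- fe_simulate(mesh, ld, pack_parameters("linear"))
  r0 <- sqrt(rowSums(mesh$nodes^2))
  for (ring in c(1.5, 2.5)) {
    idx <- which(abs(r0 - ring) < 1e-9)
    u_fe <- ring_radial_displacement(mesh, res$deformed, idx)
    u_ex <- lame_u_r(ring, ld$dp_kpa, 300, 0.49, 1.5, 2.5)
    expect_lt(abs(u_fe - u_ex) / u_ex, 0.02)
  }
})

test_that("Lame error decreases monotonically under mesh refinement", {
  ld <- load_case(60, 120)
  errs <- vapply(list(c(16, 2), c(32, 4), c(64, 8)), function(nn) {
    mesh <- generate_synthetic_vessel(
      synth_vessel_spec(n_circ = nn[1], n_rad = nn[2], lumen_offset = c(0, 0),
                        inclusions = list()))
    res <- fe_simulate(mesh, ld, pack_parameters("linear"))
    r0 <- sqrt(rowSums(mesh$nodes^2))
    idx <- which(abs(r0 - 1.5) < 1e-9)
    u_ex <- lame_u_r(1.5, ld$dp_kpa, 300, 0.49, 1.5, 2.5)
    abs(ring_radial_displacement(mesh, res$deformed, idx) - u_ex) / u_ex
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("linear response scales linearly in moduli and pressure", {
  mesh <- tiny_vessel()
  ld <- load_case(60, 120)
  base <- fe_simulate(mesh, ld, pack_parameters("linear"))
  # doubling every E halves U
  ov <- material_bounds()
  ov$assigned[ov$param == "E"] <- ov$assigned[ov$param == "E"] * 2
  pv2 <- pack_parameters("linear", ov)
  twice <- fe_simulate(mesh, ld, pv2)
  expect_equal(twice$U, base$U / 2, tolerance = 1e-9)
  # doubling the pressure differential doubles U
  ld2 <- load_case(60, 180)
  expect_equal(fe_simulate(mesh, ld2, pack_parameters("linear"))$U,
               base$U * 2, tolerance = 1e-9)
})

test_that("the luminal pressure load is self-equilibrated", {
  mesh <- default_vessel()
  ctx <- plaquefe:::fe_context(mesh)
  f <- plaquefe:::cpp_pressure_force(mesh$nodes, ctx$inner_facets, 7.99932)
  fm <- matrix(f, ncol = 2, byrow = TRUE)
  total <- colSums(fm)
  moment <- sum(mesh$nodes[, 1] * fm[, 2] - mesh$nodes[, 2] * fm[, 1])
  scale <- sum(abs(fm))
  expect_lt(max(abs(total)) / scale, 1e-12)
  expect_lt(abs(moment) / scale, 1e-10)
  # and the pressure pushes away from the lumen
  expect_gt(sum(rowSums(fm * mesh$nodes)), 0)
})

test_that("rotating the geometry rotates the displacement field", {
  mesh <- default_vessel()
  ld <- load_case(60, 120)
  pv <- pack_parameters("linear")
  res1 <- fe_simulate(mesh, ld, pv)
  th <- 2 * pi * 5 / 48  # five circumferential spacings
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- mesh
  rot$nodes <- mesh$nodes %*% t(R)
  res2 <- fe_simulate(rot, ld, pv)
  # solutions under minimal point constraints differ by a rigid motion
  U1 <- remove_rigid_2d(res1$U %*% t(R), rot$nodes)
  U2 <- remove_rigid_2d(res2$U, rot$nodes)
  expect_lt(max(abs(U1 - U2)), 1e-8)
})

test_that("3D tube with fixed ends matches plane-strain Lame at mid-section", {
  mesh <- generate_synthetic_vessel(
    synth_vessel_spec(dim = 3, n_circ = 16, n_rad = 2, n_axial = 2,
                      length = 2, lumen_offset = c(0, 0),
                      inclusions = list()))
  ld <- load_case(60, 120)
  res <- fe_simulate(mesh, ld, pack_parameters("linear"))
  # end caps stay axially fixed
  ns <- extract_node_sets(mesh)
  caps <- c(attr(ns, "cap_lo"), attr(ns, "cap_hi"))
  expect_lt(max(abs(res$U[caps, 3])), 1e-12)
  r0 <- sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2)
  mid <- which(abs(mesh$nodes[, 3] - 1) < 1e-9 & abs(r0 - 1.5) < 1e-9)
  u_fe <- ring_radial_displacement(mesh, res$deformed, mid)
  u_ex <- lame_u_r(1.5, ld$dp_kpa, 300, 0.49, 1.5, 2.5)
  expect_lt(abs(u_fe - u_ex) / u_ex, 0.05)
})

test_that("one-element Yeoh uniaxial FE matches the closed form within 1%", {
  for (p in list(c(5.64, 1812, 162), c(18, 207, 422))) {
    for (lam in c(1.1, 1.3)) {
      fe <- yeoh_uniaxial_fe(lam, p[1], p[2], p[3])
      cf <- yeoh_uniaxial_stress(lam, p[1], p[2], p[3], nominal = TRUE)
      expect_lt(abs(fe - cf) / abs(cf), 0.01)
    }
  }
})

test_that("finite-strain vessel solve converges and reports strain state", {
  mesh <- tiny_vessel()
  res <- fe_simulate(mesh, load_case(60, 120), pack_parameters("yeoh"))
  expect_true(res$converged)
  expect_gt(res$max_strain, 0.01)
  expect_lt(res$max_strain, 0.2)  # below the C30 sensitivity threshold
  # warm restart from the converged state reproduces the same solution
  ctx <- plaquefe:::fe_context(mesh)
  res2 <- fe_simulate(mesh, load_case(60, 120), pack_parameters("yeoh"),
                      ctx = ctx, warm_start = res$U)
  expect_equal(res2$U, res$U, tolerance = 1e-7)
})
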