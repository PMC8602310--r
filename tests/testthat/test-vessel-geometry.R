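test_that("homogeneous spec produces an all-artery annulus with exact area", {
  spec <- synth_vessel_spec(n_circ = 24, n_rad = 3, inclusions = list())
  mesh <- generate_synthetic_vessel(spec)
  fr <- tissue_volume_fractions(mesh)
  expect_equal(unname(fr["artery"]), 100)
  expect_equal(unname(sum(fr)), 100, tolerance = 1e-12)
  # curved isoparametric elements reproduce the analytic annulus area closely
  area <- pi * (2.5^2 - 1.5^2)
  expect_lt(abs(sum(element_measures(mesh)) - area) / area, 1e-4)
})

test_that("default inclusion layout approximates the reference lesion phenotype", {
  fr <- tissue_volume_fractions(default_vessel())
  expect_lt(abs(fr[["artery"]] - 64.6), 2.5)
  expect_lt(abs(fr[["fibrous"]] - 19.3), 1.5)
  expect_lt(abs(fr[["lipid"]] - 13.0), 1.5)
  expect_lt(abs(fr[["mixed"]] - 2.9), 1.0)
  expect_gt(fr[["calcium"]], 0)
  expect_lt(fr[["calcium"]], 1)  # triggers the calcium-exclusion rule
  expect_equal(unname(sum(fr)), 100, tolerance = 1e-9)
})

test_that("generation is deterministic and validates its spec", {
  s <- synth_vessel_spec(n_circ = 16, n_rad = 3)
  m1 <- generate_synthetic_vessel(s)
  m2 <- generate_synthetic_vessel(s)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elements, m2$elements)
  expect_identical(m1$labels, m2$labels)

  expect_error(synth_vessel_spec(wall_thickness = 0), "positive")
  expect_error(
    synth_vessel_spec(inclusions = list(
      list(tissue = "lipid", theta = c(0, 90), r = c(2.4, 2.7)))),
    "outside the wall annulus")
  expect_error(synth_vessel_spec(n_circ = 4), "too coarse")
  expect_error(
    synth_vessel_spec(inclusions = list(
      list(tissue = "blob", theta = c(0, 90), r = c(1.6, 1.8)))),
    "unknown tissue")
})

test_that("3D tube meshes are valid, labeled and volume-consistent", {
  spec <- synth_vessel_spec(dim = 3, n_circ = 12, n_rad = 2, n_axial = 2,
                            length = 4)
  mesh <- generate_synthetic_vessel(spec)
  expect_equal(mesh$dim, 3L)
  expect_true(all(element_measures(mesh) > 0))
  vol <- pi * (2.5^2 - 1.5^2) * 4
  expect_lt(abs(sum(element_measures(mesh)) - vol) / vol, 5e-4)
  fr <- tissue_volume_fractions(mesh)
  expect_equal(unname(sum(fr)), 100, tolerance = 1e-9)
  expect_true(all(c("fibrous", "lipid") %in%
                    names(fr)[fr > 0]))
  ns <- extract_node_sets(mesh)
  expect_gt(length(attr(ns, "cap_lo")), 0)
  expect_gt(length(attr(ns, "cap_hi")), 0)
})

test_that("point-cloud labeling assigns the nearest annotation per centroid", {
  mesh <- tiny_vessel()
  # single point: everything inherits its label
  m1 <- label_elements(mesh, matrix(c(0, 0), 1, 2), "lipid")
  expect_true(all(m1$labels == "lipid"))
  # two half-space-separated points split labels by the bisecting plane
  cloud <- rbind(c(-5, 0), c(5, 0))
  m2 <- label_elements(mesh, cloud, c("fibrous", "calcium"))
  ctr <- element_centroids(mesh)
  expect_identical(as.character(m2$labels),
                   ifelse(ctr[, 1] < 0, "fibrous", "calcium"))
  # brute-force nearest-point oracle on a random cloud
  set.seed(42)
  cloud <- matrix(rnorm(20), 10, 2)
  labs <- sample(names(tissue_classes()), 10, replace = TRUE)
  m3 <- label_elements(mesh, cloud, labs)
  expect_identical(as.character(m3$labels), labs[brute_nn(cloud, ctr)$index])
  # exact tie: the lowest point index wins
  m4 <- label_elements(tiny_vessel(), rbind(c(0, 0), c(0, 0)),
                       c("mixed", "lipid"))
  expect_true(all(m4$labels == "mixed"))
  expect_error(label_elements(mesh, matrix(numeric(0), 0, 2), character(0)),
               "empty")
})

test_that("node sets satisfy their membership invariants", {
  mesh <- default_vessel()
  ns <- extract_node_sets(mesh)
  expect_true(length(ns$inner) > 0 && length(ns$outer) > 0)
  expect_length(intersect(ns$inner, ns$outer), 0)
  for (tis in c("artery", "fibrous", "lipid", "mixed", "calcium")) {
    expected <- sort(unique(as.vector(mesh$elements[mesh$labels == tis, ])))
    expect_identical(ns[[tis]], expected)
  }
})

test_that("a region touching two tissues and both surfaces has exactly 4 interfaces", {
  ns <- extract_node_sets(fig2_vessel())
  ifc <- extract_interfaces(ns)
  pairs <- vapply(ifc, function(i) paste(sort(i$pair), collapse = "|"),
                  character(1))
  c_ifc <- grep("mixed", pairs, value = TRUE)
  expect_setequal(c_ifc, c("artery|mixed", "fibrous|mixed", "inner|mixed",
                           "mixed|outer"))
  # each interface is the exact intersection of its two member sets
  for (i in ifc) {
    expect_identical(i$nodes, sort(intersect(ns[[i$pair[1]]], ns[[i$pair[2]]])))
    expect_gte(length(i$nodes), 3L)
  }
})

test_that("interfaces are stable under node renumbering", {
  mesh <- fig2_vessel()
  set.seed(3)
  perm <- sample(nrow(mesh$nodes))  # new index of each old node
  m2 <- labeled_mesh(mesh$nodes[order(perm), ],
                     matrix(perm[mesh$elements], nrow(mesh$elements)),
                     mesh$labels)
  i1 <- extract_interfaces(extract_node_sets(mesh))
  i2 <- extract_interfaces(extract_node_sets(m2))
  key <- function(ifc) {
    k <- vapply(ifc, function(i) paste(sort(i$pair), collapse = "|"),
                character(1))
    n <- vapply(ifc, function(i) length(i$nodes), integer(1))
    setNames(n, k)[order(k)]
  }
  expect_identical(key(i1), key(i2))
  # node sets map through the permutation
  n1 <- extract_node_sets(mesh)
  n2 <- extract_node_sets(m2)
  expect_identical(sort(perm[n1$inner]), n2$inner)
  expect_identical(sort(perm[n1$mixed]), n2$mixed)
})

test_that("volume fractions split 50/50 on a symmetric two-label mesh", {
  mesh <- generate_synthetic_vessel(
    synth_vessel_spec(n_circ = 16, n_rad = 2, lumen_offset = c(0, 0),
                      inclusions = list(
      list(tissue = "fibrous", theta = c(0, 180), r = c(1.5, 2.5)))))
  fr <- tissue_volume_fractions(mesh)
  expect_equal(unname(fr[["artery"]]), 50, tolerance = 1e-9)
  expect_equal(unname(fr[["fibrous"]]), 50, tolerance = 1e-9)
})
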