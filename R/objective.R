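# The difference operator between a simulated deformed geometry and the
# target geometry. Three modes:
#   * interface - one error per tissue/surface interface (the full
#     micro-morphological objective);
#   * surface   - inner and outer wall surfaces only;
#   * diameter  - min/max lumen caliper diameters on cross-sectional slices.
#
# The interface error is directional: for every interface node of the
# *target*, the Euclidean distance to the nearest node of the corresponding
# interface in the *deformed* geometry, averaged over the target nodes. It is
# implemented exactly in that direction (not symmetrized): adding far-away
# extra nodes to the deformed interface leaves the error unchanged.

#' Interface error between two point sets
#'
#' Mean, over the target nodes, of the Euclidean distance to the nearest
#' deformed node. Nearest-neighbour lookup uses a kd-tree whose result equals
#' exhaustive search (ties resolve to the lowest index; the distance is
#' identical either way).
#'
#' @param target_nodes,deformed_nodes numeric matrices of node positions
#'   (same number of columns).
#' @return list with `value` (mm), `n_target`, `n_def`.
#' @export
interface_error <- function(target_nodes, deformed_nodes) {
  target_nodes <- as.matrix(target_nodes)
  deformed_nodes <- as.matrix(deformed_nodes)
  if (nrow(target_nodes) == 0L || nrow(deformed_nodes) == 0L) {
    stop("interface error needs non-empty node sets on both sides")
  }
  nn <- cpp_nn(deformed_nodes, target_nodes)
  list(value = mean(nn$dist), n_target = nrow(target_nodes),
       n_def = nrow(deformed_nodes))
}

#' Objective specification for a base topology
#'
#' Precomputes the node sets and interfaces of the base mesh once; deformed
#' and target geometries share this topology, so their interface node
#' positions are simple row subsets.
#'
#' @param base_mesh the base `labeled_mesh`.
#' @param mode `"interface"`, `"surface"` or `"diameter"`.
#' @param n_slices number of cross-sectional slices for the diameter mode.
#' @return an `objective_spec` list.
#' @export
objective_spec <- function(base_mesh, mode = c("interface", "surface", "diameter"),
                           n_slices = 10L) {
  mode <- match.arg(mode)
  nsets <- extract_node_sets(base_mesh)
  interfaces <- extract_interfaces(nsets)
  structure(list(mode = mode, nsets = nsets, interfaces = interfaces,
                 n_slices = as.integer(n_slices), dim = base_mesh$dim),
            class = "objective_spec")
}

#' Evaluate the objective between a deformed and a target geometry
#'
#' @param deformed,target `labeled_mesh` objects sharing the base topology of
#'   `spec`.
#' @param spec an [objective_spec()].
#' @return object of class `objective_value`: list with `errors` (named
#'   vector, mm: the multi-objective vector), `total` (their sum, mm: the
#'   single-objective value) and `mode`.
#' @export
evaluate_objective <- function(deformed, target, spec) {
  stopifnot(inherits(spec, "objective_spec"))
  if (nrow(deformed$nodes) != nrow(target$nodes)) {
    stop("deformed and target geometries do not share a topology")
  }
  errors <- switch(
    spec$mode,
    interface = {
      vals <- vapply(spec$interfaces, function(ifc) {
        interface_error(target$nodes[ifc$nodes, , drop = FALSE],
                        deformed$nodes[ifc$nodes, , drop = FALSE])$value
      }, numeric(1))
      names(vals) <- vapply(spec$interfaces,
                            function(ifc) paste(ifc$pair, collapse = "|"),
                            character(1))
      vals
    },
    surface = {
      vals <- vapply(c("inner", "outer"), function(s) {
        idx <- spec$nsets[[s]]
        interface_error(target$nodes[idx, , drop = FALSE],
                        deformed$nodes[idx, , drop = FALSE])$value
      }, numeric(1))
      vals
    },
    diameter = diameter_discrepancy(deformed, target, spec)
  )
  structure(list(errors = errors, total = sum(errors), mode = spec$mode),
            class = "objective_value")
}

#' @export
print.objective_value <- function(x, ...) {
  cat(sprintf("objective_value (%s mode): total %.6g mm\n", x$mode, x$total))
  print(round(x$errors, 6))
  invisible(x)
}

# ---- diameter baseline -----------------------------------------------------

# caliper (Feret) diameter extrema of a planar point set
caliper_diameters <- function(xy, n_dir = 90L) {
  ang <- seq(0, pi, length.out = n_dir + 1L)[-(n_dir + 1L)]
  proj <- xy %*% rbind(cos(ang), sin(ang))
  ext <- apply(proj, 2, function(p) diff(range(p)))
  c(min = min(ext), max = max(ext))
}

# per-slice lumen contours: inner-surface nodes within half an axial element
# spacing of each of n evenly spaced slice planes (all nodes in 2D)
slice_contours <- function(mesh, spec) {
  inner <- spec$nsets[["inner"]]
  if (spec$dim == 2L) return(list(inner))
  z <- mesh$nodes[inner, 3]
  zu <- sort(unique(round(z, 9)))
  node_dz <- if (length(zu) > 1L) median(diff(zu)) else diff(range(z)) + 1
  stations <- seq(min(z), max(z), length.out = spec$n_slices)
  lapply(stations, function(zs) inner[abs(z - zs) <= node_dz + 1e-12])
}

diameter_discrepancy <- function(deformed, target, spec) {
  contours <- slice_contours(target, spec)
  per_slice <- vapply(contours, function(idx) {
    if (length(idx) < 3L) return(c(0, 0))
    dd <- caliper_diameters(deformed$nodes[idx, 1:2, drop = FALSE])
    dt <- caliper_diameters(target$nodes[idx, 1:2, drop = FALSE])
    abs(dd - dt)
  }, numeric(2))
  c(d_min = mean(per_slice[1, ]), d_max = mean(per_slice[2, ]))
}
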