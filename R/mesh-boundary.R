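# Boundary topology: facet extraction, inner/outer surface classification,
# node sets and tissue interfaces.

# Quadratic facet tables (local indices). 2D: edges of the 6-node triangle;
# 3D: faces of the 10-node tetrahedron (corners then mid-sides, VTK order).
facet_table <- function(dim) {
  if (dim == 2L) {
    list(c(1L, 2L, 4L), c(2L, 3L, 5L), c(3L, 1L, 6L))
  } else {
    list(c(1L, 2L, 3L, 5L, 6L, 7L),
         c(1L, 2L, 4L, 5L, 9L, 8L),
         c(2L, 3L, 4L, 6L, 10L, 9L),
         c(1L, 3L, 4L, 7L, 10L, 8L))
  }
}

# all element facets with a canonical corner key; boundary = seen exactly once
boundary_facets <- function(mesh) {
  ft <- facet_table(mesh$dim)
  ncorner <- if (mesh$dim == 2L) 2L else 3L
  fac <- do.call(rbind, lapply(ft, function(loc) mesh$elements[, loc, drop = FALSE]))
  keys <- apply(fac[, seq_len(ncorner), drop = FALSE], 1, function(v) {
    paste(sort(v), collapse = "-")
  })
  cnt <- table(keys)
  if (any(cnt > 2L)) {
    bad <- names(cnt)[cnt > 2L]
    stop("mesh is not a valid manifold: facet(s) shared by >2 elements: ",
         paste(head(bad, 5L), collapse = "; "))
  }
  fac[keys %in% names(cnt)[cnt == 1L], , drop = FALSE]
}

# split boundary facets into end caps (3D, axial extremes) and lateral walls,
# then classify lateral connected components into inner/outer by mean radius
classify_boundary <- function(mesh) {
  bf <- boundary_facets(mesh)
  nodes <- mesh$nodes
  caps_lo <- integer(0)
  caps_hi <- integer(0)
  lateral <- bf
  if (mesh$dim == 3L) {
    z <- nodes[, 3]
    zr <- range(z)
    tol <- 1e-6 * max(diff(zr), 1)
    fz <- matrix(z[bf], nrow(bf), ncol(bf))
    on_lo <- apply(abs(fz - zr[1]) < tol, 1, all)
    on_hi <- apply(abs(fz - zr[2]) < tol, 1, all)
    caps_lo <- sort(unique(as.vector(bf[on_lo, ])))
    caps_hi <- sort(unique(as.vector(bf[on_hi, ])))
    lateral <- bf[!(on_lo | on_hi), , drop = FALSE]
  }
  if (nrow(lateral) == 0L) stop("mesh has no lateral boundary surface")
  comp <- facet_components(lateral)
  ctr <- colMeans(nodes)
  rad <- vapply(seq_len(nrow(lateral)), function(i) {
    p <- nodes[lateral[i, ], , drop = FALSE]
    mean(sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2))
  }, numeric(1))
  mean_rad <- tapply(rad, comp, mean)
  if (length(mean_rad) < 2L) {
    stop("expected two lateral boundary components (inner and outer surface), found ",
         length(mean_rad))
  }
  inner_comp <- as.integer(names(mean_rad)[which.min(mean_rad)])
  outer_comp <- as.integer(names(mean_rad)[which.max(mean_rad)])
  list(inner_facets = lateral[comp == inner_comp, , drop = FALSE],
       outer_facets = lateral[comp == outer_comp, , drop = FALSE],
       cap_lo = caps_lo, cap_hi = caps_hi)
}

# connected components of facets linked by shared nodes (union-find)
facet_components <- function(fac) {
  n <- nrow(fac)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  owner <- integer(max(fac))
  for (i in seq_len(n)) {
    for (v in fac[i, ]) {
      if (owner[v] == 0L) {
        owner[v] <- i
      } else {
        ri <- find(i)
        rj <- find(owner[v])
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Node sets of a labeled mesh
#'
#' Extracts the array of node sets used by the interface-matching objective:
#' one set per tissue class present in the mesh (every node of every element
#' carrying that label) plus the inner and outer wall surfaces, and the end
#' caps in 3D. Each set is a sorted integer vector of node indices.
#'
#' @param mesh a `labeled_mesh`.
#' @return an object of class `node_set_array`: a named list of node index
#'   vectors with names drawn from the tissue classes plus `"inner"` and
#'   `"outer"`, and attributes `inner_facets`/`outer_facets`/`cap_lo`/`cap_hi`
#'   carrying the facet connectivity of the surfaces.
#' @export
extract_node_sets <- function(mesh) {
  bd <- classify_boundary(mesh)
  sets <- list()
  for (tis in levels(mesh$labels)) {
    sel <- mesh$labels == tis
    if (any(sel)) {
      sets[[tis]] <- sort(unique(as.vector(mesh$elements[sel, , drop = FALSE])))
    }
  }
  sets[["inner"]] <- sort(unique(as.vector(bd$inner_facets)))
  sets[["outer"]] <- sort(unique(as.vector(bd$outer_facets)))
  structure(sets, class = "node_set_array",
            inner_facets = bd$inner_facets, outer_facets = bd$outer_facets,
            cap_lo = bd$cap_lo, cap_hi = bd$cap_hi)
}

#' Tissue and surface interfaces
#'
#' An interface is the set of nodes common to two node sets (tissue-tissue or
#' tissue-surface). All unordered pairs with a non-empty intersection are
#' returned; pairs with fewer than `min_nodes` shared nodes are dropped with a
#' warning since a one- or two-node "interface" makes the mean interface
#' error degenerate.
#'
#' @param nsets a `node_set_array` from [extract_node_sets()].
#' @param min_nodes smallest admissible interface size (default 3).
#' @return a list of interfaces, each a list with fields `pair`
#'   (character(2)) and `nodes` (integer vector).
#' @export
extract_interfaces <- function(nsets, min_nodes = 3L) {
  stopifnot(inherits(nsets, "node_set_array"))
  nm <- names(nsets)
  out <- list()
  dropped <- character(0)
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (j <= i) next
      common <- intersect(nsets[[i]], nsets[[j]])
      if (length(common) == 0L) next
      if (length(common) < min_nodes) {
        dropped <- c(dropped, paste(nm[i], nm[j], sep = "-"))
        next
      }
      out[[length(out) + 1L]] <- list(pair = c(nm[i], nm[j]),
                                      nodes = sort(common))
    }
  }
  if (length(dropped)) {
    warning("dropped degenerate interface(s) with < ", min_nodes, " nodes: ",
            paste(dropped, collapse = ", "))
  }
  out
}

#' Label elements from an annotated point cloud
#'
#' Assigns to each element the tissue label of the cloud point nearest to its
#' centroid (the rule used to transfer image annotations onto a volume mesh).
#' Exact distance ties resolve to the lowest point index.
#'
#' @param mesh a `labeled_mesh` (labels are overwritten).
#' @param cloud numeric matrix of point coordinates, same dimension as the
#'   mesh.
#' @param cloud_labels tissue label per cloud point.
#' @return the relabeled `labeled_mesh`.
#' @export
label_elements <- function(mesh, cloud, cloud_labels) {
  cloud <- as.matrix(cloud)
  if (nrow(cloud) == 0L) stop("annotated point cloud is empty")
  if (ncol(cloud) != mesh$dim) stop("cloud dimension does not match the mesh")
  cloud_labels <- as_tissue(cloud_labels)
  if (length(cloud_labels) != nrow(cloud)) stop("need one label per cloud point")
  ctr <- element_centroids(mesh)
  nn <- cpp_nn(cloud, ctr)
  mesh$labels <- cloud_labels[nn$index]
  mesh
}
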