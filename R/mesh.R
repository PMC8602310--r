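#' Labeled vessel mesh
#'
#' Container for a volumetric (or plane-strain cross-sectional) vessel mesh
#' with one tissue class per element. Elements are quadratic simplices:
#' 6-node triangles in 2D plane-strain mode, 10-node tetrahedra in 3D
#' (VTK mid-side ordering). Coordinates are mm.
#'
#' @param nodes numeric matrix, one row per node (2 or 3 columns).
#' @param elements integer matrix, one row per element (6 or 10 columns,
#'   1-based node indices).
#' @param labels tissue class per element (names or codes, see
#'   [tissue_classes()]).
#' @param validate check connectivity and element Jacobians.
#' @return an object of class `labeled_mesh` with fields `nodes`, `elements`,
#'   `labels` and `dim`.
#' @export
labeled_mesh <- function(nodes, elements, labels, validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  dim <- ncol(nodes)
  if (!dim %in% c(2L, 3L)) stop("nodes must have 2 or 3 columns")
  nen_ok <- if (dim == 2L) 6L else 10L
  if (ncol(elements) != nen_ok) {
    stop(sprintf("expected %d-node elements for %dD meshes, got %d nodes",
                 nen_ok, dim, ncol(elements)))
  }
  labels <- as_tissue(labels)
  if (length(labels) != nrow(elements)) {
    stop("need exactly one tissue label per element")
  }
  m <- structure(list(nodes = nodes, elements = elements, labels = labels,
                      dim = dim),
                 class = "labeled_mesh")
  if (validate) validate_mesh(m)
  m
}

#' @rdname labeled_mesh
#' @param mesh a `labeled_mesh`.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  el <- mesh$elements
  if (any(is.na(el)) || any(el < 1L) || any(el > nrow(mesh$nodes))) {
    stop("element connectivity refers to nodes outside the mesh")
  }
  ms <- cpp_measures(mesh$nodes, mesh$elements)
  if (any(ms$min_jacobian <= 0)) {
    bad <- which(ms$min_jacobian <= 0)
    stop("non-positive element measure in element(s): ",
         paste(head(bad, 5L), collapse = ", "))
  }
  invisible(mesh)
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("labeled_mesh: %dD, %d nodes, %d elements\n",
              x$dim, nrow(x$nodes), nrow(x$elements)))
  fr <- tissue_volume_fractions(x)
  cat("tissue fractions (%):\n")
  print(round(fr, 2))
  invisible(x)
}

#' Element areas or volumes
#'
#' @param mesh a `labeled_mesh`.
#' @return numeric vector of element measures (mm^2 in 2D, mm^3 in 3D).
#' @export
element_measures <- function(mesh) {
  cpp_measures(mesh$nodes, mesh$elements)$measure
}

#' Element centroids (mean of corner nodes)
#'
#' @param mesh a `labeled_mesh`.
#' @return numeric matrix, one row per element.
#' @export
element_centroids <- function(mesh) {
  ncorner <- if (mesh$dim == 2L) 3L else 4L
  el <- mesh$elements[, seq_len(ncorner), drop = FALSE]
  ctr <- matrix(0, nrow(el), mesh$dim)
  for (k in seq_len(ncorner)) ctr <- ctr + mesh$nodes[el[, k], , drop = FALSE]
  ctr / ncorner
}

#' Tissue volume fractions
#'
#' Percentage of the wall volume (area in 2D) occupied by each tissue class.
#' Classes below 1% are the ones excluded from parameter recovery in sparse
#' lesions (the calcium-exclusion rule).
#'
#' @param mesh a `labeled_mesh`.
#' @return named numeric vector over the five classes, summing to 100.
#' @export
tissue_volume_fractions <- function(mesh) {
  v <- element_measures(mesh)
  tot <- sum(v)
  out <- setNames(numeric(5L), names(tissue_classes()))
  agg <- tapply(v, mesh$labels, sum)
  out[names(agg)[!is.na(agg)]] <- agg[!is.na(agg)] / tot * 100
  out[is.na(out)] <- 0
  out
}

#' Displace a mesh by a nodal displacement field
#'
#' Forms the deformed configuration by adding the per-node displacement to the
#' nodal coordinates; connectivity and labels are untouched.
#'
#' @param mesh a `labeled_mesh`.
#' @param U numeric matrix of per-node displacements (mm), same shape as
#'   `mesh$nodes`.
#' @return the displaced `labeled_mesh`.
#' @export
apply_displacement <- function(mesh, U) {
  U <- as.matrix(U)
  if (!identical(dim(U), dim(mesh$nodes))) {
    stop("displacement field shape does not match the mesh nodes")
  }
  out <- mesh
  out$nodes <- mesh$nodes + U
  out
}
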