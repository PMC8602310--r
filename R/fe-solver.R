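# Forward finite-element operator: deform a labeled vessel mesh under a
# luminal pressure differential with longitudinal end constraints.
#
# Kinematics by constitutive model:
#   * linear  - infinitesimal strain, pressure applied on the *reference*
#     inner surface, one sparse solve; near-incompressibility via a fixed
#     Poisson ratio (default 0.49);
#   * yeoh    - total-Lagrangian finite strain, follower pressure on the
#     deformed inner surface, Newton-Raphson with load stepping.
#
# Boundary conditions: axial displacement fixed on both end caps (3D); two
# in-plane point constraints remove the remaining rigid-body modes (the
# luminal pressure load is self-equilibrated, so these carry no load).

#' Luminal pressure load case
#'
#' @param p_base,p_target intraluminal pressures of the two imaged states
#'   (mmHg).
#' @return object of class `load_case` with the pressure differential in
#'   mmHg and kPa.
#' @examples
#' load_case(60, 120) # dP = 60 mmHg = 7.99932 kPa
#' @export
load_case <- function(p_base = 60, p_target = 120) {
  structure(list(p_base = p_base, p_target = p_target,
                 dp_mmhg = p_target - p_base,
                 dp_kpa = mmhg_to_kpa(p_target - p_base)),
            class = "load_case")
}

#' Scale the pressure differential of a load case
#'
#' Used by the pressure-perturbation study: the target geometry is generated
#' at a perturbed pressure while recovery assumes the nominal one.
#'
#' @param load a [load_case()].
#' @param fraction relative perturbation (e.g. `0.05` for +5%).
#' @return the perturbed `load_case`.
#' @export
perturb_pressure <- function(load, fraction) {
  stopifnot(inherits(load, "load_case"))
  load$p_target <- load$p_base + (load$p_target - load$p_base) * (1 + fraction)
  load$dp_mmhg <- load$dp_mmhg * (1 + fraction)
  load$dp_kpa <- load$dp_kpa * (1 + fraction)
  load
}

#' Forward-solver settings
#'
#' @param load_steps pressure increments for the finite-strain solve.
#' @param newton_tol relative residual tolerance of the Newton loop.
#' @param max_newton maximum Newton iterations per load step.
#' @param poisson Poisson ratio of the nearly incompressible linear model.
#' @return a `solver_settings` list.
#' @export
solver_settings <- function(load_steps = 4L, newton_tol = 1e-8,
                            max_newton = 20L, poisson = 0.49) {
  stopifnot(newton_tol > 0, load_steps >= 1L, max_newton >= 1L,
            poisson > 0, poisson < 0.5)
  structure(list(load_steps = as.integer(load_steps), newton_tol = newton_tol,
                 max_newton = as.integer(max_newton), poisson = poisson),
            class = "solver_settings")
}

solver_error <- function(msg, step = NA, residual = NA) {
  stop(structure(class = c("plaquefe_solver_error", "error", "condition"),
                 list(message = sprintf("%s (load step %s, residual %s)",
                                        msg, step, format(residual)),
                      call = NULL)))
}

# Precomputed solve context for one mesh: boundary facets (inner surface
# oriented so the pressure pushes into the wall), constrained dofs, and the
# unit-modulus stiffness triplets for the linear model (built lazily).
fe_context <- function(mesh, settings = solver_settings(), nsets = NULL) {
  if (is.null(nsets)) nsets <- extract_node_sets(mesh)
  d <- mesh$dim
  inner <- orient_facets(mesh, attr(nsets, "inner_facets"))
  fixed <- rigid_constraints(mesh, nsets)
  env <- new.env(parent = emptyenv())
  env$mesh <- mesh
  env$settings <- settings
  env$nsets <- nsets
  env$inner_facets <- inner
  env$fixed_dofs <- fixed
  env$free_dofs <- setdiff(seq_len(nrow(mesh$nodes) * d), fixed)
  env$lab_int <- as.integer(mesh$labels)
  env$linear_trip <- NULL
  env
}

# orient every boundary facet so that a positive pressure pushes away from
# the lumen; facets inherited from the volume subdivision carry mixed
# orientations, so each is checked individually against the reference
# geometry (the wall centroid lies inside the lumen)
orient_facets <- function(mesh, facets) {
  d <- mesh$dim
  nodes <- mesh$nodes
  ctr <- colMeans(nodes)
  flip <- logical(nrow(facets))
  for (k in seq_len(nrow(facets))) {
    p <- nodes[facets[k, ], , drop = FALSE]
    fc <- colMeans(p)
    if (d == 2L) {
      t <- p[2, ] - p[1, ]
      nrm <- c(t[2], -t[1])          # the kernel's perpendicular convention
      ref <- fc - ctr
    } else {
      nrm <- cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
      ref <- fc - c(ctr[1], ctr[2], fc[3])
    }
    flip[k] <- sum(nrm * ref) < 0
  }
  if (any(flip)) {
    sel <- if (d == 2L) c(2L, 1L, 3L) else c(1L, 3L, 2L, 6L, 5L, 4L)
    facets[flip, ] <- facets[flip, sel, drop = FALSE]
  }
  facets
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# end-cap axial fixities plus minimal in-plane point constraints
rigid_constraints <- function(mesh, nsets) {
  d <- mesh$dim
  fixed <- integer(0)
  if (d == 3L) {
    caps <- c(attr(nsets, "cap_lo"), attr(nsets, "cap_hi"))
    fixed <- c(fixed, (caps - 1L) * 3L + 3L)
  }
  x <- mesh$nodes[, 1]
  pin <- which(x == max(x))[1]          # full in-plane pin
  anti <- which(x == min(x))[1]         # tangential fix kills rotation
  fixed <- c(fixed, (pin - 1L) * d + 1L, (pin - 1L) * d + 2L,
             (anti - 1L) * d + 2L)
  sort(unique(fixed))
}

linear_triplets <- function(ctx) {
  if (is.null(ctx$linear_trip)) {
    tr <- cpp_stiffness_unit(ctx$mesh$nodes, ctx$mesh$elements,
                             ctx$settings$poisson)
    tr$lab <- ctx$lab_int[tr$elem]
    ctx$linear_trip <- tr
  }
  ctx$linear_trip
}

#' Forward simulation of a pressurized labeled vessel
#'
#' Deforms the base mesh under the pressure differential of `load` using the
#' material parameters in `pv` (see [pack_parameters()]). This is the forward
#' operator whose output geometry the inverse method matches against the
#' target.
#'
#' @param mesh the base `labeled_mesh` (treated as stress-free).
#' @param load a [load_case()].
#' @param pv a `parameter_vector` (its `model` attribute selects the
#'   kinematic regime).
#' @param settings a [solver_settings()].
#' @param ctx optional precomputed context (internal reuse across many
#'   solves); pass `NULL` normally.
#' @param warm_start optional displacement matrix from a nearby solve, used
#'   as the Newton initial guess for the finite-strain model.
#' @return list with elements `deformed` (the displaced mesh), `U` (per-node
#'   displacement matrix, mm), `max_strain` (an equivalent tensile-strain
#'   estimate from the largest deviatoric invariant; finite-strain model
#'   only) and `converged`.
#' @export
fe_simulate <- function(mesh, load, pv, settings = solver_settings(),
                        ctx = NULL, warm_start = NULL) {
  stopifnot(inherits(load, "load_case"), inherits(pv, "parameter_vector"))
  if (is.null(ctx)) ctx <- fe_context(mesh, settings)
  mats <- materials_of(pv)
  missing <- setdiff(levels(droplevels(mesh$labels)), names(mats))
  if (length(missing)) {
    stop("parameter vector lacks materials for tissue(s): ",
         paste(missing, collapse = ", "))
  }
  if (attr(pv, "model") == "linear") {
    res <- solve_linear(ctx, load$dp_kpa, mats)
  } else {
    res <- solve_yeoh(ctx, load$dp_kpa, mats, warm_start)
  }
  U <- matrix(res$u, ncol = mesh$dim, byrow = TRUE)
  list(deformed = apply_displacement(mesh, U), U = U,
       max_strain = res$max_strain, converged = TRUE)
}

# Free-DOF reduction cache. Element assembly emits triplets in a fixed
# order for a given mesh (identical for the linear and Yeoh kernels), so the
# restriction to free DOFs, the mapping from triplets to the compressed
# sparse layout, and the Cholesky symbolic analysis are all computed once
# and reused across every solve on this mesh.
reduced_system <- function(ctx, i, j) {
  if (!is.null(ctx$redsys)) return(ctx$redsys)
  ndof <- nrow(ctx$mesh$nodes) * ctx$mesh$dim
  free <- ctx$free_dofs
  isfree <- logical(ndof)
  isfree[free] <- TRUE
  keep <- which(isfree[i] & isfree[j])
  remap <- integer(ndof)
  remap[free] <- seq_along(free)
  i2 <- remap[i[keep]]
  j2 <- remap[j[keep]]
  nf <- length(free)
  key <- (as.numeric(j2) - 1) * nf + i2   # CSC (column-major) ordering
  uk <- sort(unique(key))
  iu <- as.integer((uk - 1) %% nf) + 1L
  ju <- as.integer((uk - 1) %/% nf) + 1L
  sel_ut <- which(iu <= ju)
  rs <- list(
    keep = keep, pos = match(key, uk), nf = nf, sel_ut = sel_ut,
    n_slots = length(uk),
    tpl = Matrix::sparseMatrix(i = iu, j = ju, x = numeric(length(uk)),
                               dims = c(nf, nf)),
    tpl_sym = Matrix::sparseMatrix(i = iu[sel_ut], j = ju[sel_ut],
                                   x = numeric(length(sel_ut)),
                                   dims = c(nf, nf), symmetric = TRUE))
  ctx$redsys <- rs
  rs
}

# solve K_ff du = b with K given as aggregated triplet values; Cholesky with
# a cached symbolic factor, LU fallback for indefinite tangents
solve_reduced <- function(ctx, rs, xagg, b) {
  Ks <- rs$tpl_sym
  Ks@x <- xagg[rs$sel_ut]
  du <- tryCatch({
    if (is.null(ctx$chol)) {
      ctx$chol <- Matrix::Cholesky(Ks, LDL = FALSE, super = TRUE)
    } else {
      ctx$chol <- Matrix::update(ctx$chol, Ks)
    }
    as.numeric(Matrix::solve(ctx$chol, b))
  }, error = function(e) NULL)
  if (is.null(du)) {
    K <- rs$tpl
    K@x <- xagg
    du <- tryCatch(as.numeric(Matrix::solve(K, b)), error = function(e) NULL)
  }
  du
}

solve_linear <- function(ctx, dp_kpa, mats) {
  mesh <- ctx$mesh
  d <- mesh$dim
  ndof <- nrow(mesh$nodes) * d
  u <- numeric(ndof)
  if (dp_kpa != 0) {
    tr <- linear_triplets(ctx)
    rs <- reduced_system(ctx, tr$i, tr$j)
    Evec <- vapply(names(tissue_classes()), function(t) {
      if (!is.null(mats[[t]])) mats[[t]]$E else NA_real_
    }, numeric(1))
    xagg <- cpp_scatter_add(tr$x[rs$keep] * Evec[tr$lab[rs$keep]], rs$pos,
                            rs$n_slots)
    f <- cpp_pressure_force(mesh$nodes, ctx$inner_facets, dp_kpa)
    sol <- solve_reduced(ctx, rs, xagg, f[ctx$free_dofs])
    if (is.null(sol)) {
      solver_error("singular linear system (insufficient constraints?)", 1, NA)
    }
    u[ctx$free_dofs] <- sol
  }
  list(u = u, max_strain = NA_real_)
}

solve_yeoh <- function(ctx, dp_kpa, mats, warm_start = NULL) {
  mesh <- ctx$mesh
  st <- ctx$settings
  d <- mesh$dim
  ndof <- nrow(mesh$nodes) * d
  matpar <- t(vapply(as.character(mesh$labels), function(t) {
    m <- mats[[t]]
    c(m$C10, m$C20, m$C30, m$kappa)
  }, numeric(4)))
  free <- ctx$free_dofs
  max_strain <- 0

  newton_at <- function(u, lambda) {
    # returns list(u, iters) or NULL on failure; bails out early when the
    # backtracked steps stall (stiffening from the C20/C30 terms makes the
    # full Newton step overshoot far from the solution)
    f_ref <- NULL
    res_norm <- Inf
    stalls <- 0L
    for (it in seq_len(st$max_newton)) {
      umat <- matrix(u, ncol = d, byrow = TRUE)
      fext <- cpp_pressure_force(mesh$nodes + umat, ctx$inner_facets,
                                 lambda * dp_kpa)
      asm <- cpp_assemble_yeoh(mesh$nodes, mesh$elements, umat, matpar, TRUE)
      if (!asm$ok || asm$minJ <= 0) return(NULL)
      r <- asm$fint - fext
      if (is.null(f_ref)) f_ref <- max(sqrt(sum(fext^2)), 1e-8)
      res_norm <- sqrt(sum(r[free]^2)) / f_ref
      max_strain <<- max(max_strain, sqrt(max(asm$maxI1dev, 0) / 3))
      if (res_norm < st$newton_tol) return(list(u = u, iters = it))
      rs <- reduced_system(ctx, asm$i, asm$j)
      xagg <- cpp_scatter_add(asm$x[rs$keep], rs$pos, rs$n_slots)
      du <- solve_reduced(ctx, rs, xagg, -r[free])
      if (is.null(du)) return(NULL)
      step <- numeric(ndof)
      step[free] <- du
      # backtracking on the residual norm (monotone decrease required; the
      # Newton direction is a descent direction for |r| with the exact
      # tangent, so a small enough step always qualifies)
      alpha <- 1
      ok_step <- FALSE
      r2 <- Inf
      for (k in 1:10) {
        u_try <- u + alpha * step
        umat_try <- matrix(u_try, ncol = d, byrow = TRUE)
        a2 <- cpp_assemble_yeoh(mesh$nodes, mesh$elements, umat_try, matpar,
                                FALSE)
        if (a2$ok && a2$minJ > 0) {
          f2 <- cpp_pressure_force(mesh$nodes + umat_try, ctx$inner_facets,
                                   lambda * dp_kpa)
          r2 <- sqrt(sum((a2$fint - f2)[free]^2)) / f_ref
          if (r2 < res_norm) {
            ok_step <- TRUE
            break
          }
        }
        alpha <- alpha / 2
      }
      if (!ok_step) return(NULL)
      stalls <- if (r2 > 0.9 * res_norm) stalls + 1L else 0L
      if (stalls >= 3L) return(NULL)  # barely moving: refine the load step
      u <- u + alpha * step
    }
    NULL  # out of iterations
  }

  if (dp_kpa == 0) return(list(u = numeric(ndof), max_strain = 0))

  # warm start: single full-load Newton from a nearby solution
  if (!is.null(warm_start)) {
    u0 <- as.numeric(t(warm_start))
    sol <- newton_at(u0, 1)
    if (!is.null(sol)) return(list(u = sol$u, max_strain = max_strain))
  }
  # load continuation with a secant predictor and adaptive step control
  u <- numeric(ndof)
  u_prev <- NULL
  l_prev <- NULL
  lambda_done <- 0
  dl <- 1 / st$load_steps
  while (lambda_done < 1 - 1e-12) {
    dl <- min(dl, 1 - lambda_done)
    lambda <- lambda_done + dl
    u0 <- u
    if (!is.null(u_prev) && lambda_done > l_prev) {
      u0 <- u + (u - u_prev) * dl / (lambda_done - l_prev)
    }
    sol <- newton_at(u0, lambda)
    if (is.null(sol) && !identical(u0, u)) sol <- newton_at(u, lambda)
    if (is.null(sol)) {
      dl <- dl / 2
      if (dl < 2^-10) solver_error("Newton failed to converge", lambda, NA)
    } else {
      u_prev <- u
      l_prev <- lambda_done
      u <- sol$u
      lambda_done <- lambda
      if (sol$iters <= 5L) dl <- dl * 1.6
    }
  }
  list(u = u, max_strain = max_strain)
}

# ---- material-test harness -------------------------------------------------

# unit cube meshed into 6 quadratic tetrahedra (Freudenthal subdivision on a
# doubled 3x3x3 node grid); used by the uniaxial material verification
unit_cube_mesh <- function() {
  gid <- function(g) (g[3] * 3L + g[2]) * 3L + g[1] + 1L
  nodes <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2)) / 2
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  eye <- diag(3) * 2
  elems <- matrix(0L, 6L, 10L)
  for (k in seq_along(perms)) {
    p <- perms[[k]]
    cs <- rbind(c(0, 0, 0), eye[p[1], ], eye[p[1], ] + eye[p[2], ], c(2, 2, 2))
    pc <- nodes[apply(cs, 1, gid), ]
    v <- det(rbind(pc[2, ] - pc[1, ], pc[3, ] - pc[1, ], pc[4, ] - pc[1, ]))
    if (v < 0) cs <- cs[c(1L, 2L, 4L, 3L), ]
    mids <- rbind((cs[1, ] + cs[2, ]) / 2, (cs[2, ] + cs[3, ]) / 2,
                  (cs[1, ] + cs[3, ]) / 2, (cs[1, ] + cs[4, ]) / 2,
                  (cs[2, ] + cs[4, ]) / 2, (cs[3, ] + cs[4, ]) / 2)
    elems[k, ] <- c(apply(cs, 1, gid), apply(mids, 1, gid))
  }
  labeled_mesh(nodes, elems, rep("artery", 6L))
}

#' Uniaxial tension of a Yeoh solid by finite elements
#'
#' Displacement-controlled uniaxial tensile test on a single-cube mesh of
#' quadratic tetrahedra: symmetry conditions on three faces, a prescribed
#' stretch on the top face, free lateral contraction. Returns the nominal
#' (first Piola-Kirchhoff) stress from the face reaction, for comparison
#' against the incompressible closed form [yeoh_uniaxial_stress()]. Also the
#' basis of the C30 sensitivity check: the response departs from the
#' C30-free curve only beyond ~20% strain.
#'
#' @inheritParams yeoh_strain_energy
#' @param lambda target stretch (> 0).
#' @param kappa volumetric penalty modulus (kPa); the default scales with
#'   the full polynomial so the solid stays nearly incompressible at the
#'   hydrostatic stress levels reached near `lambda` = 1.3.
#' @param n_steps displacement increments.
#' @param tol Newton tolerance on the relative residual.
#' @return nominal stress (kPa, force per undeformed area).
#' @export
yeoh_uniaxial_fe <- function(lambda, C10, C20 = 0, C30 = 0,
                             kappa = 1000 * (C10 + C20 + C30),
                             n_steps = 8L, tol = 1e-10) {
  stopifnot(lambda > 0)
  mesh <- unit_cube_mesh()
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  matpar <- matrix(rep(c(C10, C20, C30, kappa), each = 6L), ncol = 4L)
  xyz <- mesh$nodes
  face <- function(axis, value) which(abs(xyz[, axis] - value) < 1e-12)
  dofs_of <- function(nodes, comp) (nodes - 1L) * 3L + comp
  fixed0 <- c(dofs_of(face(1, 0), 1L), dofs_of(face(2, 0), 2L),
              dofs_of(face(3, 0), 3L))
  top <- face(3, 1)
  top_dofs <- dofs_of(top, 3L)
  fixed <- sort(unique(c(fixed0, top_dofs)))
  free <- setdiff(seq_len(ndof), fixed)
  u <- numeric(ndof)

  residual_of <- function(u) {
    umat <- matrix(u, ncol = 3L, byrow = TRUE)
    asm <- cpp_assemble_yeoh(mesh$nodes, mesh$elements, umat, matpar, FALSE)
    if (!asm$ok || asm$minJ <= 0) return(Inf)
    sqrt(sum(asm$fint[free]^2))
  }
  newton_stretch <- function(u, lam) {
    # incompressible affine predictor: the solution is a homogeneous
    # deformation, so this starts inside the Newton basin even for a stiff
    # volumetric penalty
    ls <- lam^(-0.5)
    u <- as.numeric(t(cbind(xyz[, 1] * (ls - 1), xyz[, 2] * (ls - 1),
                            xyz[, 3] * (lam - 1))))
    for (it in 1:200) {
      umat <- matrix(u, ncol = 3L, byrow = TRUE)
      asm <- cpp_assemble_yeoh(mesh$nodes, mesh$elements, umat, matpar, TRUE)
      if (!asm$ok || asm$minJ <= 0) return(NULL)
      r <- asm$fint
      scale <- max(sqrt(sum(r[top_dofs]^2)), 1e-8)
      rn <- sqrt(sum(r[free]^2))
      # the absolute floor reflects the round-off level of assembling
      # kappa-scaled volumetric terms
      if (rn < tol * scale + 1e-10 * kappa) return(u)
      K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$x,
                                dims = c(ndof, ndof))
      du <- Matrix::solve(K[free, free, drop = FALSE], -r[free])
      step <- numeric(ndof)
      step[free] <- as.numeric(du)
      alpha <- 1
      ok <- FALSE
      for (k in 1:20) {
        if (residual_of(u + alpha * step) < rn) {
          ok <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (!ok) return(NULL)
      u <- u + alpha * step
    }
    NULL
  }

  lam_done <- 1
  dl <- (lambda - 1) / n_steps
  while (lam_done < lambda - 1e-12) {
    dl <- min(dl, lambda - lam_done)
    u_new <- newton_stretch(u, lam_done + dl)
    if (is.null(u_new)) {
      dl <- dl / 2
      if (dl < (lambda - 1) * 2^-12) {
        solver_error("uniaxial Newton did not converge", lam_done + dl, NA)
      }
    } else {
      u <- u_new
      lam_done <- lam_done + dl
    }
  }
  umat <- matrix(u, ncol = 3L, byrow = TRUE)
  asm <- cpp_assemble_yeoh(mesh$nodes, mesh$elements, umat, matpar, FALSE)
  sum(asm$fint[top_dofs])  # reference area is 1, so force = nominal stress
}
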