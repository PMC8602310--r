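# Constitutive models and the material parameter vector.
#
# Two models are supported:
#   * linear elastic (Hooke), one free modulus E per tissue, treated as
#     nearly incompressible with a fixed Poisson ratio;
#   * Yeoh hyperelastic, W = C10 (I1b - 3) + C20 (I1b - 3)^2 + C30 (I1b - 3)^3
#     with I1b the first *deviatoric* invariant (J^{-2/3} tr(F'F)), plus a
#     volumetric penalty kappa/2 (J - 1)^2 enforcing near-incompressibility.

#' Yeoh strain-energy density
#'
#' Cubic polynomial in the excess of the first deviatoric invariant over its
#' undeformed value of 3. `I1_dev = 3` (undeformed) gives zero energy.
#'
#' @param I1_dev first deviatoric strain invariant (dimensionless, >= 3).
#' @param C10,C20,C30 material constants (kPa).
#' @return strain-energy density (kPa).
#' @export
yeoh_strain_energy <- function(I1_dev, C10, C20, C30) {
  if (any(I1_dev < 3 - 1e-12)) {
    stop("I1_dev < 3 is not attainable for the deviatoric invariant")
  }
  x <- pmax(I1_dev - 3, 0)
  C10 * x + C20 * x^2 + C30 * x^3
}

#' Incompressible uniaxial Cauchy stress of a Yeoh solid
#'
#' Closed form for a uniaxial stretch `lambda` under incompressible
#' kinematics (`I1 = lambda^2 + 2/lambda`):
#' `sigma = 2 (lambda^2 - 1/lambda) dW/dI1`. The C30 term contributes only at
#' large strains (> ~20%), which is why C30 is held fixed during recovery.
#'
#' @param lambda uniaxial stretch (> 0).
#' @inheritParams yeoh_strain_energy
#' @param nominal return the nominal (first Piola-Kirchhoff) stress
#'   `sigma / lambda` instead of the Cauchy stress.
#' @return stress (kPa).
#' @export
yeoh_uniaxial_stress <- function(lambda, C10, C20, C30, nominal = FALSE) {
  if (any(lambda <= 0)) stop("stretch must be positive")
  I1 <- lambda^2 + 2 / lambda
  x <- I1 - 3
  dW <- C10 + 2 * C20 * x + 3 * C30 * x^2
  sig <- 2 * (lambda^2 - 1 / lambda) * dW
  if (nominal) sig / lambda else sig
}

#' Initial shear modulus of a Yeoh solid
#'
#' Small-strain limit `mu0 = 2 C10`; the small-strain Young's modulus of the
#' incompressible solid is `3 mu0 = 6 C10`.
#'
#' @param C10 first Yeoh constant (kPa).
#' @return `mu0` in kPa.
#' @export
initial_shear_modulus <- function(C10) 2 * C10

#' Volumetric penalty modulus for the nearly incompressible Yeoh solid
#'
#' The default penalty is 1000 times the initial shear modulus
#' (`kappa = 1000 * 2 * C10`), which keeps volume changes at the 1e-3 level
#' for the luminal pressure range of the vessel problem while leaving the
#' Newton landscape tractable. Displacement-controlled material tests at
#' large stretch (see [yeoh_uniaxial_fe()]) use a stiffer penalty scaled to
#' the full polynomial, since the hydrostatic stress there is dominated by
#' the C20/C30 terms.
#'
#' @param C10 first Yeoh constant (kPa).
#' @param factor multiple of the initial shear modulus.
#' @return penalty modulus (kPa).
#' @export
yeoh_kappa <- function(C10, factor = 1000) {
  factor * initial_shear_modulus(C10)
}

#' Ground-truth material parameters and search bounds
#'
#' Assigned (ground-truth) values and one-order-of-magnitude search ranges
#' for every tissue class and parameter, in kPa: linear elastic moduli `E`
#' and Yeoh constants `C10`, `C20`, `C30`. Calcium has no published search
#' range; for the 9-parameter recovery mode a symmetric one-order-of-magnitude
#' range around its assigned `C10` is used. `C30` is never given a range:
#' the objective is insensitive to it below ~20% strain, so it is held at its
#' assigned value.
#'
#' @param overrides optional data frame with columns `tissue`, `param` and any
#'   of `assigned`, `lower`, `upper` to replace individual entries.
#' @return data frame with columns `tissue`, `param`, `assigned`, `lower`,
#'   `upper` (`NA` bounds mean "never free").
#' @export
material_bounds <- function(overrides = NULL) {
  tab <- rbind(
    data.frame(tissue = c("artery", "mixed", "fibrous", "lipid", "calcium"),
               param = "E",
               assigned = c(300, 500, 1200, 15, 5000),
               lower = c(100, 100, 100, 5, NA),
               upper = c(3000, 3000, 3000, 200, NA)),
    data.frame(tissue = c("artery", "mixed", "fibrous", "lipid", "calcium"),
               param = "C10",
               assigned = c(5.64, 25, 54, 18, 1270),
               lower = c(1, 10, 10, 10, 127),
               upper = c(10, 100, 100, 100, 12700)),
    data.frame(tissue = c("artery", "mixed", "fibrous", "lipid"),
               param = "C20",
               assigned = c(1812, 850, 2200, 207),
               lower = c(1000, 100, 1000, 100),
               upper = c(10000, 1000, 10000, 1000)),
    data.frame(tissue = c("artery", "mixed", "fibrous", "lipid"),
               param = "C30",
               assigned = c(162, 300, 42.5, 422),
               lower = NA_real_, upper = NA_real_)
  )
  if (!is.null(overrides)) {
    for (k in seq_len(nrow(overrides))) {
      i <- which(tab$tissue == overrides$tissue[k] &
                   tab$param == overrides$param[k])
      if (length(i) != 1L) {
        stop("override does not match a bounds-table row: ",
             overrides$tissue[k], "/", overrides$param[k])
      }
      for (col in intersect(names(overrides), c("assigned", "lower", "upper"))) {
        tab[[col]][i] <- overrides[[col]][k]
      }
    }
  }
  free <- is.finite(tab$lower) & is.finite(tab$upper)
  bad <- free & (tab$assigned < tab$lower | tab$assigned > tab$upper)
  if (any(bad)) stop("assigned value outside its search range")
  rownames(tab) <- NULL
  tab
}

#' Pack material parameters into an optimization vector
#'
#' Builds the ordered parameter vector with bounds and fixed-value masks for
#' one of three recovery modes:
#' \describe{
#'   \item{`linear`}{4 free parameters: `E` for artery, mixed, fibrous,
#'     lipid; calcium `E` fixed.}
#'   \item{`yeoh`}{8 free parameters: `C10` and `C20` for the four soft
#'     classes; all `C30` and every calcium parameter fixed.}
#'   \item{`yeoh9`}{as `yeoh` plus calcium `C10` free (9 parameters), the
#'     mode used when the lesion's calcium volume exceeds 1%.}
#' }
#' Free entries are optimized in a log10 scaling of their search range
#' (ranges span 1-2 orders of magnitude), mapped onto the unit interval.
#'
#' @param mode recovery mode.
#' @param bounds bounds table from [material_bounds()].
#' @return object of class `parameter_vector`: a data frame of all (tissue,
#'   param) entries with columns `assigned`, `lower`, `upper`, `free`,
#'   `value`, plus the constitutive model as attribute `model`.
#' @export
pack_parameters <- function(mode = c("linear", "yeoh", "yeoh9"),
                            bounds = material_bounds()) {
  mode <- match.arg(mode)
  model <- if (mode == "linear") "linear" else "yeoh"
  tab <- bounds[bounds$param %in% (if (model == "linear") "E" else c("C10", "C20", "C30")), ]
  soft <- c("artery", "mixed", "fibrous", "lipid")
  tab$free <- is.finite(tab$lower) & is.finite(tab$upper) &
    tab$param %in% c("E", "C10", "C20")
  if (mode != "yeoh9") tab$free <- tab$free & tab$tissue %in% soft
  tab$value <- tab$assigned
  # free entries first in (tissue, param) table order for a stable vector order
  rownames(tab) <- NULL
  structure(tab, class = c("parameter_vector", "data.frame"), model = model,
            mode = mode)
}

#' @rdname pack_parameters
#' @param pv a `parameter_vector`.
#' @return `free_values()` returns the named numeric vector of free entries
#'   (kPa).
#' @export
free_values <- function(pv) {
  stopifnot(inherits(pv, "parameter_vector"))
  setNames(pv$value[pv$free], paste(pv$tissue[pv$free], pv$param[pv$free],
                                    sep = "."))
}

#' @rdname pack_parameters
#' @param values numeric vector of free parameter values (kPa), in the order
#'   of `free_values(pv)`.
#' @return `set_free_values()` returns the updated `parameter_vector`;
#'   out-of-bounds values are an error.
#' @export
set_free_values <- function(pv, values) {
  stopifnot(inherits(pv, "parameter_vector"))
  idx <- which(pv$free)
  if (length(values) != length(idx)) stop("wrong number of free values")
  tol <- 1e-9
  if (any(values < pv$lower[idx] * (1 - tol) - tol) ||
      any(values > pv$upper[idx] * (1 + tol) + tol)) {
    stop("free parameter value outside its search bounds")
  }
  pv$value[idx] <- values
  pv
}

# log10 scaling between free values (kPa) and the unit cube
scaled_from_values <- function(pv, values = free_values(pv)) {
  idx <- which(pv$free)
  lo <- log10(pv$lower[idx])
  hi <- log10(pv$upper[idx])
  (log10(values) - lo) / (hi - lo)
}

values_from_scaled <- function(pv, x) {
  idx <- which(pv$free)
  lo <- log10(pv$lower[idx])
  hi <- log10(pv$upper[idx])
  10^(lo + pmin(pmax(x, 0), 1) * (hi - lo))
}

#' Materials of a parameter vector, per tissue class
#'
#' @param pv a `parameter_vector`.
#' @return named list per tissue: either `list(E = ...)` or
#'   `list(C10 =, C20 =, C30 =, kappa =)` depending on the model.
#' @export
materials_of <- function(pv) {
  model <- attr(pv, "model")
  out <- list()
  for (tis in unique(pv$tissue)) {
    sub <- pv[pv$tissue == tis, ]
    if (model == "linear") {
      out[[tis]] <- list(E = sub$value[sub$param == "E"])
    } else {
      C10 <- sub$value[sub$param == "C10"]
      C20 <- if ("C20" %in% sub$param) sub$value[sub$param == "C20"] else 0
      C30 <- if ("C30" %in% sub$param) sub$value[sub$param == "C30"] else 0
      out[[tis]] <- list(C10 = C10, C20 = C20, C30 = C30,
                         kappa = yeoh_kappa(C10))
    }
  }
  out
}

#' @export
print.parameter_vector <- function(x, ...) {
  cat(sprintf("parameter_vector (%s model, %d free of %d entries)\n",
              attr(x, "model"), sum(x$free), nrow(x)))
  print(as.data.frame(x))
  invisible(x)
}
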