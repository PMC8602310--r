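# The inverse method driver: build the evaluator (forward solve + objective),
# run the NSGA-II global stage, pick the incumbent by summed interface error,
# refine it with the SQP stage, and report the recovered parameter vector.

#' Build a forward-simulation evaluator
#'
#' Wraps [fe_simulate()] and [evaluate_objective()] into the evaluator
#' contract consumed by the optimizer stages: a function from a scaled
#' parameter vector to `list(errors =, total =)` (or `NULL` when the forward
#' solve fails). The FE context and objective topology are precomputed once;
#' for the finite-strain model the previous converged displacement warm-starts
#' the next Newton solve.
#'
#' @param base,target `labeled_mesh` pair sharing one topology.
#' @param load a [load_case()].
#' @param pv a `parameter_vector` template from [pack_parameters()].
#' @param settings a [solver_settings()].
#' @param objective `"interface"`, `"surface"` or `"diameter"`.
#' @param n_slices slice count for the diameter mode.
#' @return evaluator function with attribute `"pv"` (the template).
#' @export
make_evaluator <- function(base, target, load, pv,
                           settings = solver_settings(),
                           objective = "interface", n_slices = 10L) {
  nsets <- extract_node_sets(base)
  ctx <- fe_context(base, settings, nsets)
  ospec <- objective_spec_from_sets(base, nsets, objective, n_slices)
  cache <- new.env(parent = emptyenv())
  cache$U <- NULL
  is_yeoh <- attr(pv, "model") == "yeoh"
  fn <- function(x) {
    vals <- values_from_scaled(pv, x)
    pvx <- set_free_values(pv, vals)
    res <- tryCatch(
      fe_simulate(base, load, pvx, settings, ctx = ctx,
                  warm_start = if (is_yeoh) cache$U else NULL),
      plaquefe_solver_error = function(e) NULL)
    if (is.null(res)) return(NULL)
    if (is_yeoh) cache$U <- res$U
    ov <- evaluate_objective(res$deformed, target, ospec)
    list(errors = ov$errors, total = ov$total)
  }
  attr(fn, "pv") <- pv
  fn
}

# objective_spec variant reusing already-extracted node sets
objective_spec_from_sets <- function(base_mesh, nsets, mode, n_slices = 10L) {
  mode <- match.arg(mode, c("interface", "surface", "diameter"))
  interfaces <- extract_interfaces(nsets)
  structure(list(mode = mode, nsets = nsets, interfaces = interfaces,
                 n_slices = as.integer(n_slices), dim = base_mesh$dim),
            class = "objective_spec")
}

#' Recover material parameters from two vessel states
#'
#' The full inverse method: a Latin-hypercube-initialized NSGA-II search on
#' the vector of interface errors, incumbent selection by the summed error
#' across all generations, then SQP refinement within the search bounds.
#'
#' @inheritParams make_evaluator
#' @param mode recovery mode passed to [pack_parameters()] (`"linear"`,
#'   `"yeoh"` or `"yeoh9"`).
#' @param bounds bounds table ([material_bounds()]).
#' @param config an [optimizer_config()].
#' @param objective objective mode.
#' @return list of class `recovery_result`: `pv` (the recovered
#'   `parameter_vector`), `values` (named free values, kPa), `incumbent`,
#'   `sqp` (local-stage report), `trace`, and `config`.
#' @export
recover_materials <- function(base, target, load,
                              mode = c("linear", "yeoh", "yeoh9"),
                              bounds = material_bounds(),
                              config = optimizer_config(),
                              settings = solver_settings(),
                              objective = "interface", n_slices = 10L) {
  mode <- match.arg(mode)
  pv <- pack_parameters(mode, bounds)
  evaluator <- make_evaluator(base, target, load, pv, settings, objective,
                              n_slices)
  n_par <- sum(pv$free)
  global <- nsga2_stage(evaluator, n_par, config)
  tr <- global$trace
  inc <- select_incumbent(tr)
  sfun <- function(x) {
    res <- evaluator(x)
    total <- if (is.null(res)) Inf else res$total
    errors <- if (is.null(res)) rep(Inf, length(tr$rows[[1]]$errors)) else res$errors
    trace_record(tr, x, errors, total, "sqp")
    res
  }
  ref <- sqp_refine(sfun, inc$x, config)
  pv_star <- set_free_values(pv, values_from_scaled(pv, ref$x))
  structure(list(pv = pv_star, values = free_values(pv_star),
                 x_scaled = ref$x, incumbent = inc, sqp = ref, trace = tr,
                 config = config, mode = mode, objective = objective),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("recovery_result: %s model, %s objective\n", x$mode, x$objective))
  cat(sprintf("  incumbent delta_SO %.6g mm -> refined %.6g mm (%s, %d sims)\n",
              x$incumbent$total, x$sqp$value, x$sqp$stop_reason, x$sqp$sims))
  print(round(x$values, 4))
  invisible(x)
}

#' Percent errors of a recovery against assigned values
#'
#' `100 * |recovered - assigned| / assigned` per free parameter.
#'
#' @param result a `recovery_result` (or a `parameter_vector`).
#' @return named numeric vector of percent errors.
#' @export
percent_errors <- function(result) {
  pv <- if (inherits(result, "recovery_result")) result$pv else result
  stopifnot(inherits(pv, "parameter_vector"))
  idx <- which(pv$free)
  setNames(100 * abs(pv$value[idx] - pv$assigned[idx]) / pv$assigned[idx],
           paste(pv$tissue[idx], pv$param[idx], sep = "."))
}
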