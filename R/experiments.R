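# Verification harness: in-silico target generation (the inverse-crime
# setting with a known exact optimum), Gaussian displacement noise, pressure
# perturbation, repeated seeded recoveries, and objective-mode comparison.

#' Simulate a target geometry for verification
#'
#' Forward-simulates the base mesh at the assigned (ground-truth) material
#' values, producing the target geometry that a second image acquisition
#' would supply in practice, plus the displacement field used by the noise
#' studies.
#'
#' @param base the base `labeled_mesh`.
#' @param load a [load_case()] (default pressure differential 60 mmHg).
#' @param pv parameter vector at its assigned values
#'   (see [pack_parameters()]).
#' @param settings a [solver_settings()].
#' @return list with `target` (a `labeled_mesh`) and `U` (nodal displacement
#'   matrix, mm).
#' @export
make_target <- function(base, load = load_case(), pv = pack_parameters(),
                        settings = solver_settings()) {
  res <- fe_simulate(base, load, pv, settings)
  list(target = res$deformed, U = res$U, max_strain = res$max_strain)
}

#' Add multiplicative Gaussian noise to a displacement field
#'
#' Each displacement component `u` is replaced by `u * (1 + z)` with `z`
#' drawn independently per component from a zero-mean Gaussian whose standard
#' deviation is `n` times the maximum absolute displacement component in the
#' field. The noisy target is then `base + U_noisy`.
#'
#' @param U displacement matrix (mm).
#' @param n noise fraction (e.g. 0.05 or 0.20).
#' @param seed RNG seed (deterministic noise per seed).
#' @return the noisy displacement matrix.
#' @export
add_noise <- function(U, n, seed = NULL) {
  stopifnot(n >= 0)
  if (n == 0) return(U)
  if (max(abs(U)) == 0) stop("displacement field is identically zero; noise fraction has no scale")
  if (!is.null(seed)) set.seed(seed)
  sdev <- n * max(abs(U))
  U * (1 + matrix(rnorm(length(U), 0, sdev), nrow(U), ncol(U)))
}

#' Run a repeated-seed recovery study
#'
#' One full two-stage recovery per seed against a common in-silico target
#' (optionally noise-contaminated per run, or generated at a perturbed
#' pressure), consolidated into a per-parameter error table with run-level
#' and aggregate statistics.
#'
#' @param base the base `labeled_mesh`.
#' @param seeds integer vector; one recovery per seed (the seed drives the
#'   NSGA-II stage and, when `noise > 0`, the noise realization).
#' @param mode recovery mode (see [pack_parameters()]).
#' @param load nominal [load_case()] assumed during recovery.
#' @param noise displacement noise fraction applied to the target per run.
#' @param pressure_perturbation relative perturbation of the pressure used
#'   to *generate* the target (recovery still assumes the nominal load).
#' @param bounds,config,settings,objective,n_slices forwarded to
#'   [recover_materials()].
#' @param out_dir optional directory; when given, the base/target meshes
#'   (VTU), per-run traces (CSV) and the report (JSON) are written there.
#' @return object of class `recovery_report`; see [summary.recovery_report()].
#' @export
run_study <- function(base, seeds = 1:8,
                      mode = c("linear", "yeoh", "yeoh9"),
                      load = load_case(), noise = 0,
                      pressure_perturbation = 0,
                      bounds = material_bounds(),
                      config = optimizer_config(),
                      settings = solver_settings(),
                      objective = "interface", n_slices = 10L,
                      out_dir = NULL) {
  mode <- match.arg(mode)
  pv0 <- pack_parameters(mode, bounds)
  gen_load <- if (pressure_perturbation != 0) {
    perturb_pressure(load, pressure_perturbation)
  } else {
    load
  }
  tgt <- make_target(base, gen_load, pv0, settings)
  rows <- list()
  runs <- list()
  failures <- character(0)
  for (s in seeds) {
    target_s <- tgt$target
    if (noise > 0) {
      Un <- add_noise(tgt$U, noise, seed = s + 990000L)
      target_s <- apply_displacement(base, Un)
    }
    cfg <- config
    cfg$seed <- as.integer(s)
    rec <- tryCatch(
      recover_materials(base, target_s, load, mode = mode, bounds = bounds,
                        config = cfg, settings = settings,
                        objective = objective, n_slices = n_slices),
      error = function(e) e)
    if (inherits(rec, "error")) {
      warning("recovery for seed ", s, " failed and is excluded: ",
              conditionMessage(rec))
      failures <- c(failures, as.character(s))
      next
    }
    runs[[as.character(s)]] <- rec
    pe <- percent_errors(rec)
    idx <- which(rec$pv$free)
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s, tissue = rec$pv$tissue[idx], param = rec$pv$param[idx],
      assigned = rec$pv$assigned[idx], recovered = rec$pv$value[idx],
      pct_error = as.numeric(pe))
  }
  if (!length(rows)) stop("all recovery runs failed")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  rep <- structure(list(errors = tab, runs = runs, seeds = seeds,
                        failed_seeds = failures, mode = mode,
                        objective = objective, noise = noise,
                        pressure_perturbation = pressure_perturbation,
                        config = config, target = tgt),
                   class = "recovery_report")
  if (!is.null(out_dir)) write_study(rep, base, out_dir)
  rep
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("recovery_report: %s model, %s objective, noise %g, %d run(s)\n",
              x$mode, x$objective, x$noise, length(x$runs)))
  cat(sprintf("  mean %.3g%% +/- %.3g%%, median %.3g%%\n",
              s$mean, s$sd, s$median))
  invisible(x)
}

#' Aggregate statistics of a recovery report
#'
#' Reported as in the verification studies: "mean +/- SD" percent error over
#' all free parameters and runs, with the median alongside; per-run and
#' per-parameter breakdowns for finer questions.
#'
#' @param object a `recovery_report`.
#' @param ... unused.
#' @return list with `mean`, `sd`, `median`, `per_run` (data frame of
#'   run-level mean/median/sd) and `per_param` (data frame of parameter-level
#'   mean/median over runs).
#' @export
summary.recovery_report <- function(object, ...) {
  e <- object$errors
  per_run <- do.call(rbind, lapply(split(e, e$seed), function(d) {
    data.frame(seed = d$seed[1], mean = mean(d$pct_error),
               median = median(d$pct_error), sd = sd(d$pct_error))
  }))
  key <- paste(e$tissue, e$param, sep = ".")
  per_param <- do.call(rbind, lapply(split(e, key), function(d) {
    data.frame(tissue = d$tissue[1], param = d$param[1],
               mean = mean(d$pct_error), median = median(d$pct_error))
  }))
  rownames(per_run) <- rownames(per_param) <- NULL
  list(mean = mean(e$pct_error), sd = sd(e$pct_error),
       median = median(e$pct_error), per_run = per_run,
       per_param = per_param)
}

write_study <- function(rep, base, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_mesh(base, file.path(out_dir, "base.vtu"))
  write_mesh(rep$target$target, file.path(out_dir, "target.vtu"))
  for (s in names(rep$runs)) {
    write.csv(trace_as_data_frame(rep$runs[[s]]$trace),
              file.path(out_dir, sprintf("trace_seed%s.csv", s)),
              row.names = FALSE)
  }
  s <- summary(rep)
  jsonlite::write_json(
    list(mode = rep$mode, objective = rep$objective, noise = rep$noise,
         pressure_perturbation = rep$pressure_perturbation,
         seeds = rep$seeds, failed_seeds = rep$failed_seeds,
         aggregate = list(mean = s$mean, sd = s$sd, median = s$median),
         per_run = s$per_run, errors = rep$errors),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Compare objective modes on identical targets and seeds
#'
#' Runs the same recovery study under each objective definition (full
#' interface matching vs. the inner/outer-surface and slice-diameter
#' baselines) with identical geometry, targets and seed list, so per-parameter
#' errors are paired across modes.
#'
#' @inheritParams run_study
#' @param modes objective modes to compare.
#' @return named list of `recovery_report`, one per mode, with a combined
#'   paired error table in attribute `"paired"`.
#' @export
compare_objective_modes <- function(base, seeds = 1:8,
                                    mode = c("linear", "yeoh", "yeoh9"),
                                    modes = c("interface", "surface", "diameter"),
                                    load = load_case(), noise = 0,
                                    bounds = material_bounds(),
                                    config = optimizer_config(),
                                    settings = solver_settings(),
                                    n_slices = 10L) {
  mode <- match.arg(mode)
  out <- list()
  for (m in modes) {
    out[[m]] <- run_study(base, seeds = seeds, mode = mode, load = load,
                          noise = noise, bounds = bounds, config = config,
                          settings = settings, objective = m,
                          n_slices = n_slices)
  }
  paired <- do.call(rbind, lapply(names(out), function(m) {
    e <- out[[m]]$errors
    e$objective <- m
    e
  }))
  attr(out, "paired") <- paired
  out
}
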