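# NSGA-II global stage (Deb et al. 2002) over the scaled unit cube, with the
# vector of interface errors as the multi-objective fitness. Operators are the
# canonical defaults: simulated binary crossover and polynomial mutation.
# Failed forward solves (non-convergence at extreme parameter combinations)
# receive +Inf on all objectives, so they are dominated by every viable
# individual.

#' Optimizer configuration
#'
#' Defaults follow the two-stage protocol: an NSGA-II population of 24
#' propagated over 7 generations for the linear model (24 for the nonlinear
#' model), then an SQP refinement limited to 40 function evaluations with a
#' successive-objective termination residual of 1e-9.
#'
#' @param pop_size NSGA-II population size.
#' @param generations NSGA-II generations.
#' @param sqp_max_evals local-stage budget: one function evaluation costs
#'   `n + 1` forward simulations (the point plus its forward-difference
#'   gradient).
#' @param sqp_tol termination residual on the difference between successive
#'   objective values (mm).
#' @param fd_step initial forward-difference relative step in scaled space
#'   (shrinks adaptively as the step size contracts).
#' @param sbx_eta,sbx_prob simulated-binary-crossover distribution index and
#'   probability.
#' @param mut_eta polynomial-mutation distribution index (per-variable
#'   probability is `1/n`).
#' @param seed RNG seed for the stochastic stage.
#' @return an `optimizer_config` list.
#' @export
optimizer_config <- function(pop_size = 24L, generations = 7L,
                             sqp_max_evals = 40L, sqp_tol = 1e-9,
                             fd_step = 1e-3, sbx_eta = 15, sbx_prob = 0.9,
                             mut_eta = 20, seed = 1L) {
  stopifnot(pop_size >= 2L, generations >= 1L, sqp_max_evals >= 1L,
            sqp_tol > 0, fd_step > 0)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 sqp_max_evals = as.integer(sqp_max_evals),
                 sqp_tol = sqp_tol, fd_step = fd_step, sbx_eta = sbx_eta,
                 sbx_prob = sbx_prob, mut_eta = mut_eta,
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Latin hypercube sample of the scaled parameter space
#'
#' Space-filling initial population: one sample in each of the `n` equal
#' probability strata of every dimension (in the log10-scaled unit cube).
#'
#' @param n_par number of free parameters.
#' @param n number of samples.
#' @param seed RNG seed.
#' @return `n` x `n_par` matrix of scaled coordinates in `[0, 1]`.
#' @export
lhs_sample <- function(n_par, n, seed = NULL) {
  stopifnot(n >= 1L, n_par >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lhs::randomLHS(n, n_par)
}

# ---- run trace -------------------------------------------------------------

new_trace <- function(n_par) {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env
}

trace_record <- function(tr, x, errors, total, stage) {
  tr$rows[[length(tr$rows) + 1L]] <-
    list(x = x, errors = errors, total = total, stage = stage)
  invisible(tr)
}

#' Flatten a run trace
#'
#' Every evaluated parameter vector with its objective, stage tag and
#' evaluation index; the incumbent is reconstructible from this table alone.
#'
#' @param tr trace object from [recover_materials()].
#' @return data frame with columns `eval`, `stage`, `total`, `x.*` (scaled
#'   parameters) and `err.*` (objective entries).
#' @export
trace_as_data_frame <- function(tr) {
  rows <- tr$rows
  n <- length(rows)
  nerr <- max(vapply(rows, function(r) length(r$errors), integer(1)))
  X <- t(vapply(rows, function(r) r$x, numeric(length(rows[[1]]$x))))
  E <- t(vapply(rows, function(r) {
    e <- r$errors
    length(e) <- nerr
    as.numeric(e)
  }, numeric(nerr)))
  out <- data.frame(eval = seq_len(n),
                    stage = vapply(rows, function(r) r$stage, character(1)),
                    total = vapply(rows, function(r) r$total, numeric(1)))
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  colnames(E) <- paste0("err", seq_len(nerr))
  cbind(out, X, E)
}

#' Incumbent of a trace
#'
#' The evaluation with the minimum single-objective value (sum of interface
#' errors) across the whole global stage - all generations, not just the
#' final front. Ties resolve to the earliest evaluation.
#'
#' @param tr trace object.
#' @param stages restrict to stage tags matching this regular expression.
#' @return list with `x` (scaled parameters), `total` and `eval` index.
#' @export
select_incumbent <- function(tr, stages = "^(lhs|gen)") {
  sel <- grepl(stages, vapply(tr$rows, function(r) r$stage, character(1)))
  if (!any(sel)) stop("trace has no evaluations in the requested stages")
  idx <- which(sel)
  totals <- vapply(tr$rows[idx], function(r) r$total, numeric(1))
  best <- idx[which.min(totals)]
  list(x = tr$rows[[best]]$x, total = tr$rows[[best]]$total, eval = best)
}

# ---- non-dominated sorting and crowding ------------------------------------

dominates <- function(a, b) all(a <= b) && any(a < b)

nondominated_sort <- function(OBJ) {
  n <- nrow(OBJ)
  rank <- integer(n)
  dom_count <- integer(n)
  dominated_by <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(OBJ[i, ], OBJ[j, ])) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (dominates(OBJ[j, ], OBJ[i, ])) {
        dom_count[i] <- dom_count[i] + 1L
      }
    }
  }
  front <- which(dom_count == 0L)
  r <- 1L
  while (length(front)) {
    rank[front] <- r
    nxt <- integer(0)
    for (i in front) {
      for (j in dominated_by[[i]]) {
        dom_count[j] <- dom_count[j] - 1L
        if (dom_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    front <- sort(unique(nxt))
    r <- r + 1L
  }
  rank
}

crowding_distance <- function(OBJ) {
  n <- nrow(OBJ)
  d <- numeric(n)
  for (k in seq_len(ncol(OBJ))) {
    v <- OBJ[, k]
    o <- order(v)
    rng <- v[o[n]] - v[o[1]]
    d[o[c(1, n)]] <- Inf
    if (n > 2 && is.finite(rng) && rng > 0) {
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] + (v[o[3:n]] - v[o[1:(n - 2)]]) / rng
    }
  }
  d
}

# binary tournament on (rank, crowding)
tournament_pick <- function(rank, crowd) {
  n <- length(rank)
  a <- sample.int(n, 1L)
  b <- sample.int(n, 1L)
  if (rank[a] < rank[b]) return(a)
  if (rank[b] < rank[a]) return(b)
  if (crowd[a] >= crowd[b]) a else b
}

sbx_crossover <- function(p1, p2, eta, prob) {
  c1 <- p1
  c2 <- p2
  if (runif(1) <= prob) {
    for (i in seq_along(p1)) {
      if (runif(1) > 0.5) next
      u <- runif(1)
      beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1)) else
        (1 / (2 * (1 - u)))^(1 / (eta + 1))
      c1[i] <- 0.5 * ((1 + beta) * p1[i] + (1 - beta) * p2[i])
      c2[i] <- 0.5 * ((1 - beta) * p1[i] + (1 + beta) * p2[i])
    }
  }
  list(pmin(pmax(c1, 0), 1), pmin(pmax(c2, 0), 1))
}

poly_mutation <- function(x, eta, prob) {
  for (i in seq_along(x)) {
    if (runif(1) > prob) next
    u <- runif(1)
    delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1 else
      1 - (2 * (1 - u))^(1 / (eta + 1))
    x[i] <- x[i] + delta
  }
  pmin(pmax(x, 0), 1)
}

# ---- the global stage ------------------------------------------------------

eval_with_trace <- function(evaluator, x, tr, stage, n_obj_hint) {
  res <- evaluator(x)
  if (is.null(res) || !all(is.finite(res$errors))) {
    errors <- rep(Inf, n_obj_hint)
    total <- Inf
  } else {
    errors <- res$errors
    total <- res$total
  }
  trace_record(tr, x, errors, total, stage)
  errors
}

#' NSGA-II global search stage
#'
#' Runs the multi-objective genetic stage on the vector of interface errors,
#' starting from a Latin hypercube population. Every evaluation is appended
#' to the trace; [select_incumbent()] then picks the starting point of the
#' local stage.
#'
#' @param evaluator function mapping a scaled parameter vector to
#'   `list(errors =, total =)` (or `NULL` on forward-solve failure).
#' @param n_par number of free parameters.
#' @param config an [optimizer_config()].
#' @param tr optional existing trace to append to.
#' @return list with the trace, the final population (`X`, `OBJ`) and the
#'   indices of its non-dominated front.
#' @export
nsga2_stage <- function(evaluator, n_par, config = optimizer_config(),
                        tr = NULL) {
  if (is.null(tr)) tr <- new_trace(n_par)
  set.seed(config$seed)
  pop <- config$pop_size
  X <- lhs_sample(n_par, pop)
  # evaluate the initial population; the objective-vector length comes from
  # the first individual whose forward solve succeeds
  vals <- vector("list", pop)
  n_obj <- NULL
  for (i in seq_len(pop)) {
    vals[i] <- list(evaluator(X[i, ]))
    if (is.null(n_obj) && !is.null(vals[[i]]) &&
        all(is.finite(vals[[i]]$errors))) {
      n_obj <- length(vals[[i]]$errors)
    }
  }
  if (is.null(n_obj)) {
    stop("every individual in the initial population failed to evaluate")
  }
  OBJ <- matrix(NA_real_, pop, n_obj)
  for (i in seq_len(pop)) {
    v <- vals[[i]]
    bad <- is.null(v) || length(v$errors) != n_obj || !all(is.finite(v$errors))
    OBJ[i, ] <- if (bad) rep(Inf, n_obj) else v$errors
    trace_record(tr, X[i, ], OBJ[i, ],
                 if (bad) Inf else v$total, "lhs")
  }
  rank <- nondominated_sort(OBJ)
  crowd <- crowding_distance(OBJ)
  mut_prob <- 1 / n_par
  for (g in seq_len(config$generations)) {
    CX <- matrix(NA_real_, pop, n_par)
    for (k in seq_len(pop / 2)) {
      p1 <- tournament_pick(rank, crowd)
      p2 <- tournament_pick(rank, crowd)
      ch <- sbx_crossover(X[p1, ], X[p2, ], config$sbx_eta, config$sbx_prob)
      CX[2 * k - 1, ] <- poly_mutation(ch[[1]], config$mut_eta, mut_prob)
      CX[2 * k, ] <- poly_mutation(ch[[2]], config$mut_eta, mut_prob)
    }
    if (pop %% 2 == 1) {
      CX[pop, ] <- poly_mutation(X[tournament_pick(rank, crowd), ],
                                 config$mut_eta, mut_prob)
    }
    COBJ <- matrix(NA_real_, pop, n_obj)
    for (i in seq_len(pop)) {
      COBJ[i, ] <- eval_with_trace(evaluator, CX[i, ], tr,
                                   sprintf("gen%02d", g), n_obj)
    }
    # elitist environmental selection on the combined population
    AX <- rbind(X, CX)
    AOBJ <- rbind(OBJ, COBJ)
    arank <- nondominated_sort(AOBJ)
    keep <- integer(0)
    r <- 1L
    while (length(keep) < pop) {
      fr <- which(arank == r)
      if (length(keep) + length(fr) <= pop) {
        keep <- c(keep, fr)
      } else {
        cd <- crowding_distance(AOBJ[fr, , drop = FALSE])
        fr <- fr[order(cd, decreasing = TRUE)]
        keep <- c(keep, fr[seq_len(pop - length(keep))])
      }
      r <- r + 1L
    }
    X <- AX[keep, , drop = FALSE]
    OBJ <- AOBJ[keep, , drop = FALSE]
    rank <- nondominated_sort(OBJ)
    crowd <- crowding_distance(OBJ)
  }
  list(trace = tr, X = X, OBJ = OBJ, front = which(rank == 1L))
}
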