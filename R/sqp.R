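# Local refinement stage: a bound-constrained SQP-type polisher in the
# spirit of NLPQLP (which is proprietary). Contract honoured:
#   * derivatives by forward finite differences - each function evaluation
#     costs n + 1 forward simulations (the point plus n perturbed points),
#     and the total simulation budget is sqp_max_evals * (n + 1);
#   * iterates stay within bounds and the objective decreases monotonically;
#   * stops when the difference between successive objective values falls
#     below the termination residual (at full derivative resolution), or
#     when the budget is spent.
#
# Step model. The n perturbed simulations estimate the Jacobian of the
# interface-error *vector* (not just the gradient of the sum); steps solve
# the damped linearized root problem with Marquardt scaling, so
# low-sensitivity directions still move. An accepted step is extended by
# doubling while the objective keeps dropping. The summed interface error
# is a sum of per-node distance magnitudes, so near well-matched
# configurations it is a cone complex: finite-difference gradients taken
# across cone faces can cancel along the valley floor and strand the
# damped step. When that happens the previous accepted direction is
# retried with backtracking (valley momentum) - landscape probes show
# long, exactly-linear descent valleys whose direction recent steps
# already found - before the derivative resolution is refined.

#' SQP-style local refinement
#'
#' Polishes the incumbent of the global stage within the search bounds,
#' using forward-finite-difference derivatives of the objective vector and
#' damped Gauss-Newton steps with a valley-following line search.
#'
#' @param fun objective on the scaled unit cube. May return either a single
#'   numeric value or a `list(errors =, total =)` as produced by the
#'   recovery evaluator; `NULL` or non-finite values mark a failed forward
#'   solve (the step is rejected and the damping increased).
#' @param x0 start point (from [select_incumbent()]); must lie in bounds.
#' @param config an [optimizer_config()] (fields `sqp_max_evals`, `sqp_tol`,
#'   `fd_step`).
#' @return list with `x`, `value`, `evals` (accepted steps), `sims`
#'   (forward simulations used, `<= sqp_max_evals * (n + 1)`),
#'   `stop_reason` (`"residual"` or `"budget"`), and the monotone `history`
#'   of accepted objective values.
#' @export
sqp_refine <- function(fun, x0, config = optimizer_config()) {
  n <- length(x0)
  if (any(x0 < -1e-12) || any(x0 > 1 + 1e-12)) stop("start point out of bounds")
  x <- pmin(pmax(x0, 0), 1)
  sims <- 0L
  evaluate <- function(xt) {
    sims <<- sims + 1L
    res <- fun(xt)
    if (is.null(res)) return(NULL)
    if (is.numeric(res)) res <- list(errors = res, total = sum(res))
    if (!all(is.finite(res$errors)) || !is.finite(res$total)) return(NULL)
    res
  }
  budget <- config$sqp_max_evals * (n + 1L)
  r0 <- evaluate(x)
  if (is.null(r0)) stop("objective not evaluable at the start point")
  fx <- r0$total
  ex <- r0$errors
  m <- length(ex)
  history <- fx
  h <- config$fd_step
  evals <- 1L
  stop_reason <- "budget"
  mu <- 0         # Levenberg damping, raised on rejected steps
  tol_hits <- 0L  # consecutive sub-tolerance drops at full resolution
  recycles <- 0L  # fruitless full-resolution cycles since the last accept
  h_floor <- 1e-6 # below this, forward-solver noise corrupts derivatives
  d_last <- NULL  # last accepted stride (valley momentum)
  done <- FALSE

  # accept an improving candidate: extend it by doubling while the
  # objective keeps dropping, update the iterate and the stop-rule state
  accept_step <- function(xt, rt) {
    x_from <- x
    best_x <- xt
    best_r <- rt
    stride <- xt - x
    while (sims < budget) {
      x2 <- pmin(pmax(x_from + 2 * stride, 0), 1)
      if (max(abs(x2 - best_x)) < 1e-15) break
      r2 <- evaluate(x2)
      if (is.null(r2) || r2$total >= best_r$total) break
      best_x <- x2
      best_r <- r2
      stride <- x2 - x_from
    }
    s_vec <- best_x - x
    drop <- fx - best_r$total
    x <<- best_x
    fx <<- best_r$total
    ex <<- best_r$errors
    history <<- c(history, fx)
    evals <<- evals + 1L
    recycles <<- 0L
    d_last <<- s_vec
    mu <<- mu / 4
    h <<- min(config$fd_step, max(0.5 * max(abs(s_vec)), h_floor))
    if (drop < config$sqp_tol) {
      if (h > 1.5 * h_floor) {
        h <<- max(h / 10, h_floor)
      } else if (mu < 1e-3) {
        tol_hits <<- tol_hits + 1L
        if (tol_hits >= 2L) {
          stop_reason <<- "residual"
          done <<- TRUE
        }
      }
    } else {
      tol_hits <<- 0L
    }
    invisible(TRUE)
  }

  fd_jacobian <- function(x, ex) {
    J <- matrix(NA_real_, m, n)
    for (i in seq_len(n)) {
      if (sims >= budget) return(NULL)
      hi <- if (x[i] + h > 1) -h else h  # backward difference at the bound
      xt <- x
      xt[i] <- xt[i] + hi
      ri <- evaluate(xt)
      if (is.null(ri)) return(NULL)
      J[, i] <- (ri$errors - ex) / hi
    }
    J
  }

  # scalar objectives (toy problems) get a BFGS curvature model on the
  # finite-difference gradient instead of the Gauss-Newton normal matrix: a
  # scalar residual with a nonzero minimum is not a root-finding problem
  B <- diag(n)
  bfgs_prev <- NULL

  while (!done && sims + n < budget) {
    J <- fd_jacobian(x, ex)
    if (is.null(J)) {
      h <- h / 4
      if (h < h_floor) break
      next
    }
    if (m == 1L) {
      g <- as.numeric(J)
      if (!is.null(bfgs_prev)) {
        s <- x - bfgs_prev$x
        y <- g - bfgs_prev$g
        sy <- sum(s * y)
        if (is.finite(sy) && sy > 1e-12 * sqrt(sum(s^2) * sum(y^2))) {
          Bs <- B %*% s
          B <- B + tcrossprod(y) / sy -
            tcrossprod(Bs) / as.numeric(crossprod(s, Bs))
        }
      }
      bfgs_prev <- list(x = x, g = g)
      JtJ <- B
    } else {
      g <- as.numeric(crossprod(J, ex))
      JtJ <- crossprod(J)
    }
    # Marquardt scaling: damping proportional to each direction's own
    # curvature, so low-sensitivity (sloppy) directions still take long
    # steps at moderate damping
    Dscale <- diag(pmax(diag(JtJ), 1e-6 * max(diag(JtJ), 1e-300)), n)
    accepted <- FALSE
    for (damp in 1:10) {
      if (sims >= budget) break
      d <- tryCatch(
        -as.numeric(solve(JtJ + (mu + 1e-10) * Dscale, g)),
        error = function(e) NULL)
      if (is.null(d)) {
        mu <- max(mu * 8, 1e-4)
        next
      }
      xt <- pmin(pmax(x + d, 0), 1)
      if (max(abs(xt - x)) < 1e-15) break
      rt <- evaluate(xt)
      if (!is.null(rt) && rt$total < fx) {
        accept_step(xt, rt)
        accepted <- TRUE
        break
      }
      mu <- max(mu * 8, 1e-4)
    }
    if (!accepted && !is.null(d_last) && max(abs(d_last)) > 1e-15) {
      # valley momentum: retry the last accepted direction with backtracking
      alpha <- 1
      for (k in 1:4) {
        if (sims >= budget) break
        xt <- pmin(pmax(x + alpha * d_last, 0), 1)
        if (max(abs(xt - x)) < 1e-15) break
        rt <- evaluate(xt)
        if (!is.null(rt) && rt$total < fx) {
          accept_step(xt, rt)
          accepted <- TRUE
          break
        }
        alpha <- alpha / 2
      }
    }
    if (!accepted && sims + 2 * n < budget) {
      # coordinate fallback: on a cone-complex valley whose floor aligns
      # with a parameter axis, a pure basis stride descends where the mixed
      # Gauss-Newton direction is contaminated by uphill components; the
      # accepted stride is then extended by the doubling expansion
      delta <- max(8 * h, 1e-3)
      for (i in seq_len(n)) {
        for (sgn in c(1, -1)) {
          if (sims >= budget || accepted) break
          xt <- x
          xt[i] <- min(max(xt[i] + sgn * delta, 0), 1)
          if (abs(xt[i] - x[i]) < 1e-15) next
          rt <- evaluate(xt)
          if (!is.null(rt) && rt$total < fx) {
            accept_step(xt, rt)
            accepted <- TRUE
          }
        }
        if (accepted) break
      }
    }
    if (!accepted) {
      if (h > h_floor + 1e-15) {
        # no decrease at this derivative resolution: sharpen it
        h <- max(h / 10, h_floor)
        mu <- max(mu, 1e-4)
      } else {
        # already at the finest resolution: re-coarsen and try once more
        # from a fresh local model before declaring stationarity
        recycles <- recycles + 1L
        if (recycles >= 2L) {
          stop_reason <- "residual"
          break
        }
        h <- config$fd_step
        mu <- 1e-2
      }
    }
    if (sims >= budget) break
  }
  list(x = x, value = fx, evals = evals, sims = sims,
       stop_reason = stop_reason, history = history)
}
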