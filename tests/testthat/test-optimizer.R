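# Toy evaluators exercise the optimizer stages without FE solves.

quad_toy <- function(center) {
  function(x) {
    e <- (x - center)^2
    list(errors = e, total = sum(e))
  }
}

test_that("Latin hypercube samples stratify every dimension", {
  x1 <- lhs_sample(3, 1, seed = 5)
  expect_true(all(x1 >= 0 & x1 <= 1))
  X <- lhs_sample(4, 24, seed = 5)
  expect_equal(dim(X), c(24L, 4L))
  for (k in 1:4) {
    strata <- floor(X[, k] * 24)
    expect_setequal(strata, 0:23)  # exactly one sample per 1/24 stratum
  }
  expect_identical(lhs_sample(4, 24, seed = 5), X)
})

test_that("NSGA-II evaluates the expected budget and returns a clean front", {
  cfg <- optimizer_config(pop_size = 12, generations = 5, seed = 3)
  out <- nsga2_stage(quad_toy(c(0.3, 0.7)), 2, cfg)
  df <- trace_as_data_frame(out$trace)
  expect_equal(nrow(df), 12 * (5 + 1))  # initial population plus offspring
  expect_true(all(df$stage[1:12] == "lhs"))
  # exhaustive pairwise non-domination check of the final front
  front_obj <- out$OBJ[out$front, , drop = FALSE]
  for (i in seq_len(nrow(front_obj))) {
    for (j in seq_len(nrow(front_obj))) {
      if (i != j) {
        expect_false(all(front_obj[i, ] <= front_obj[j, ]) &&
                       any(front_obj[i, ] < front_obj[j, ]))
      }
    }
  }
  # best-so-far single objective is non-increasing across generations
  best <- cummin(df$total)
  expect_true(all(diff(best) <= 0))
  # determinism under a fixed seed
  out2 <- nsga2_stage(quad_toy(c(0.3, 0.7)), 2, cfg)
  expect_identical(trace_as_data_frame(out2$trace), df)
})

test_that("failed evaluations receive infinite fitness and are dominated", {
  flaky <- function(x) {
    if (x[1] > 0.8) return(NULL)
    list(errors = abs(x - 0.2), total = sum(abs(x - 0.2)))
  }
  out <- nsga2_stage(flaky, 2, optimizer_config(pop_size = 8,
                                                generations = 3, seed = 1))
  df <- trace_as_data_frame(out$trace)
  expect_true(any(!is.finite(df$total)))
  expect_true(all(is.finite(out$OBJ[out$front, ])))
})

test_that("the incumbent is the trace-wide minimum with earliest tie-break", {
  tr <- plaquefe:::new_trace(2)
  vals <- c(0.5, 0.2, 0.9, 0.2, 0.4)
  for (i in seq_along(vals)) {
    plaquefe:::trace_record(tr, c(i / 10, 0), vals[i], vals[i],
                            if (i <= 2) "lhs" else "gen01")
  }
  inc <- select_incumbent(tr)
  expect_equal(inc$eval, 2L)  # first of the two 0.2 ties
  expect_equal(inc$total, 0.2)
  # incumbent is at least as good as any front member by construction
  out <- nsga2_stage(quad_toy(c(0.5, 0.5)), 2,
                     optimizer_config(pop_size = 8, generations = 4, seed = 2))
  inc2 <- select_incumbent(out$trace)
  expect_lte(inc2$total, min(rowSums(out$OBJ[out$front, , drop = FALSE])))
})

test_that("the SQP stage solves quadratic toys within its contract", {
  cfg <- optimizer_config(sqp_max_evals = 40, sqp_tol = 1e-9)
  # start at the optimum: immediate residual-based stop
  at_opt <- sqp_refine(function(x) sum((x - 0.4)^2), rep(0.4, 2), cfg)
  expect_equal(at_opt$stop_reason, "residual")
  expect_lt(at_opt$value, 1e-12)
  # 2-parameter bowl: recovers the minimizer precisely
  # the termination residual of 1e-9 on a quadratic bowl localizes the
  # minimizer to ~sqrt(tol) in each coordinate
  bowl <- sqp_refine(function(x) (x[1] - 0.3)^2 + 2 * (x[2] - 0.6)^2 + 0.5,
                     c(0.9, 0.1), cfg)
  expect_equal(bowl$x, c(0.3, 0.6), tolerance = 1e-4)
  expect_true(all(diff(bowl$history) < 0))  # monotone decrease
  expect_lte(bowl$sims, 40 * 3)             # n + 1 simulations per evaluation
  # bound-active problem: the minimizer outside [0,1] maps to the bound
  edge <- sqp_refine(function(x) sum((x - c(1.4, 0.5))^2), c(0.2, 0.2), cfg)
  expect_equal(edge$x[1], 1, tolerance = 1e-8)
  expect_equal(edge$x[2], 0.5, tolerance = 1e-5)
  expect_true(all(edge$x >= 0 & edge$x <= 1))
  expect_error(sqp_refine(function(x) sum(x), c(2, 0), cfg), "out of bounds")
})

test_that("vector-valued objectives get Gauss-Newton treatment", {
  cfg <- optimizer_config(sqp_max_evals = 30, sqp_tol = 1e-12)
  target <- c(0.25, 0.65, 0.45)
  res <- sqp_refine(quad_toy(target), c(0.9, 0.1, 0.8), cfg)
  expect_equal(res$x, target, tolerance = 1e-4)
  expect_lt(res$value, 1e-8)
})

test_that("a mock evaluator with a known optimum is recovered end to end", {
  center <- c(0.35, 0.55, 0.75)
  ev <- quad_toy(center)
  cfg <- optimizer_config(pop_size = 12, generations = 6, seed = 4)
  out <- nsga2_stage(ev, 3, cfg)
  inc <- select_incumbent(out$trace)
  ref <- sqp_refine(ev, inc$x, cfg)
  expect_equal(ref$x, center, tolerance = 1e-3)
  expect_lte(ref$value, inc$total)
  # stochastic global stage: different seeds, different incumbents
  incs <- vapply(1:8, function(s) {
    o <- nsga2_stage(ev, 3, optimizer_config(pop_size = 8, generations = 2,
                                             seed = s))
    select_incumbent(o$trace)$total
  }, numeric(1))
  expect_gt(length(unique(incs)), 4)
  # the local stage is deterministic from a fixed start
  ref2 <- sqp_refine(ev, inc$x, cfg)
  expect_identical(ref$x, ref2$x)
})

test_that("all evaluated points lie within the scaled bounds", {
  ev <- quad_toy(c(0.2, 0.8))
  out <- nsga2_stage(ev, 2, optimizer_config(pop_size = 10, generations = 4,
                                             seed = 6))
  df <- trace_as_data_frame(out$trace)
  X <- as.matrix(df[, c("x1", "x2")])
  expect_true(all(X >= 0 & X <= 1))
})
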