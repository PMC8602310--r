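# Independent oracles and shared fixtures for the test suite.

# exhaustive nearest-neighbour search; ties resolve to the lowest index
brute_nn <- function(ref, query) {
  idx <- integer(nrow(query))
  dist <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    d2 <- rowSums(sweep(ref, 2, query[i, ])^2)
    idx[i] <- which.min(d2)  # which.min returns the first minimum
    dist[i] <- sqrt(d2[idx[i]])
  }
  list(index = idx, dist = dist)
}

# plane-strain Lame solution for a thick-walled cylinder under internal
# pressure p: radial displacement at radius r
lame_u_r <- function(r, p, E, nu, Ri, Ro) {
  A <- p * Ri^2 / (Ro^2 - Ri^2)
  A * (1 + nu) / E * ((1 - 2 * nu) * r + Ro^2 / r)
}

# mean radial displacement of a node ring, measured about the ring's own
# centroid so that rigid translations cancel
ring_radial_displacement <- function(base, deformed, idx) {
  b <- base$nodes[idx, 1:2, drop = FALSE]
  d <- deformed$nodes[idx, 1:2, drop = FALSE]
  rb <- sqrt(rowSums(sweep(b, 2, colMeans(b))^2))
  rd <- sqrt(rowSums(sweep(d, 2, colMeans(d))^2))
  mean(rd) - mean(rb)
}

# remove the best-fit in-plane rigid motion (translation + infinitesimal
# rotation) from a 2D displacement field
remove_rigid_2d <- function(U, X) {
  A <- cbind(1, 0, -X[, 2])
  B <- cbind(0, 1, X[, 1])
  M <- rbind(A, B)
  rhs <- c(U[, 1], U[, 2])
  beta <- qr.solve(M, rhs)
  U - cbind(beta[1] - beta[3] * X[, 2], beta[2] + beta[3] * X[, 1])
}

# small meshes shared across tests (memoized; generation is deterministic)
.fixture_env <- new.env()

tiny_vessel <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <-
      generate_synthetic_vessel(synth_vessel_spec(n_circ = 16, n_rad = 3))
  }
  .fixture_env$tiny
}

default_vessel <- function() {
  if (is.null(.fixture_env$default)) {
    .fixture_env$default <- generate_synthetic_vessel(synth_vessel_spec())
  }
  .fixture_env$default
}

# annulus with three tissue arcs where region C (mixed) spans the boundary
# between regions A (artery) and B (fibrous) and runs the full wall depth,
# touching both surfaces: C has exactly four interfaces
fig2_vessel <- function() {
  if (is.null(.fixture_env$fig2)) {
    incl <- list(
      list(tissue = "fibrous", theta = c(180, 360), r = c(1.5, 2.5)),
      list(tissue = "mixed", theta = c(170, 190), r = c(1.5, 2.5))
    )
    .fixture_env$fig2 <- generate_synthetic_vessel(
      synth_vessel_spec(n_circ = 36, n_rad = 3, lumen_offset = c(0, 0),
                        inclusions = incl))
  }
  .fixture_env$fig2
}
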