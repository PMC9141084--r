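# Shared fixtures and independent oracles for the test suite.

baseline <- game_parameters()

# Central finite-difference Jacobian of the replicator field: the
# independent oracle against which the analytic Jacobian is checked.
fd_jacobian <- function(params, state, variant = "as_printed", h = 1e-7) {
  s0 <- as.numeric(unclass(as_strategy_state(state)))
  J <- matrix(NA_real_, 3, 3)
  for (j in 1:3) {
    up <- s0; up[j] <- up[j] + h
    dn <- s0; dn[j] <- dn[j] - h
    J[, j] <- (replicator_field(params, up, variant) -
                 replicator_field(params, dn, variant)) / (2 * h)
  }
  J
}

# Random interior state away from the faces, so s(1-s) factors are live.
random_interior_state <- function() {
  strategy_state(runif(1, 0.05, 0.95), runif(1, 0.05, 0.95),
                 runif(1, 0.05, 0.95))
}

corner_states <- lapply(1:8, function(i) {
  g <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  strategy_state(g$x[i], g$y[i], g$z[i])
})

# Eigenvalue triples and attributes of the published equilibrium table,
# in O1..O8 corner order.
published_table4 <- data.frame(
  point = paste0("O", 1:8),
  e1 = c(1.85, -1.85, -0.15, 1.55, 0.15, -1.55, -0.45, 0.45),
  e2 = c(-0.05, 1.95, 0.05, 1.25, -1.95, 3.25, -1.25, -3.25),
  e3 = c(0.25, 0.55, 0.45, -0.25, 0.75, -0.55, -0.45, -0.75),
  attribute = c(rep("saddle", 6), "stable", "saddle")
)

write_baseline_json <- function(dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  path <- file.path(dir, "params.json")
  write_parameters(baseline, path)
  path
}
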