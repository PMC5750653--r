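# Independent oracles used across tests; these never call the package's
# analytic superposition path.

# two-compartment IV bolus model integrated numerically (stiff ODE solver
# with bolus events into the central compartment)
ode_profile_oracle <- function(params, doses, baseline, times) {
  k10 <- params$cl / params$v1
  k12 <- params$q / params$v1
  k21 <- params$q / params$v2
  rhs <- function(t, y, parms) {
    list(c(-(k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  }
  ev <- data.frame(var = "A1", time = doses$time_h, value = doses$amount_iu,
                   method = "add")
  out <- deSolve::lsoda(c(A1 = 0, A2 = 0), times, rhs, NULL,
                        events = list(data = ev),
                        rtol = 1e-10, atol = 1e-8)
  baseline + out[, "A1"] / params$v1
}

# closed-form steady-state pre-dose trough for equal boluses every tau h:
# geometric-series sum of the bi-exponential unit response
ss_trough_q48h_oracle <- function(params, amount_iu, baseline, tau = 48) {
  k10 <- params$cl / params$v1
  k12 <- params$q / params$v1
  k21 <- params$q / params$v2
  s <- k10 + k12 + k21
  p <- k10 * k21
  alpha <- (s + sqrt(s^2 - 4 * p)) / 2
  beta <- p / alpha
  A <- (alpha - k21) / (params$v1 * (alpha - beta))
  B <- (k21 - beta) / (params$v1 * (alpha - beta))
  ea <- exp(-alpha * tau)
  eb <- exp(-beta * tau)
  baseline + amount_iu * (A * ea / (1 - ea) + B * eb / (1 - eb))
}

# small test cohort with sampled PK, reused by regimen/dose-search tests
make_test_cohort <- function(n = 60, seed = 101, group = "both") {
  spec <- population_spec(n_per_group = n, seed = seed)
  pop <- generate_population(spec)
  if (group != "both") pop <- pop[pop$group == group, ]
  pk <- sample_pk_parameters(pk_model_spec(), pop$lbw_kg, seed = seed + 1)
  list(pop = pop, pk = pk)
}
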