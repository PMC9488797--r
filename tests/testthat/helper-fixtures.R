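# Small in-code fixtures shared across test files.

fixture_start <- as.POSIXct("2022-03-01 07:00:00", tz = "UTC")

# a minimal well-formed trace tibble on the 24-min grid starting at ZT 0
make_traces <- function(n = 10, mouse_id = "m1", start_zt = 0,
                        d_o2 = 0.003, d_co2 = 0.0024, d_h2 = 0,
                        food_g = 0.2, water_g = 0.3, flow_lpm = 0.4) {
  t_h <- start_zt + (seq_len(n) - 1) * 0.4
  tibble::tibble(
    mouse_id = mouse_id,
    cage_id = "cage_1",
    timestamp = fixture_start + t_h * 3600,
    zt = t_h %% 24,
    d_o2 = rep_len(d_o2, n), d_co2 = rep_len(d_co2, n),
    d_h2 = rep_len(d_h2, n),
    food_g = rep_len(food_g, n), water_g = rep_len(water_g, n),
    flow_lpm = rep_len(flow_lpm, n), qc_flags = ""
  )
}

default_dialect <- function(...) study_dialect(lights_on = "07:00", ...)

# independent mass-balance oracle for gas exchange: solves the two species
# balances with the *total* volume balance F_in = F_out + VO2 - VCO2 as a
# numeric 2x2 linear system in (vo2, vco2) -- a different derivation route
# than the inert-gas elimination used by haldane_volumes()
oracle_gas_volumes <- function(d_o2, d_co2, flow, ref_o2 = 0.2095,
                               ref_co2 = 0.0004) {
  fe_o2 <- ref_o2 - d_o2
  fe_co2 <- ref_co2 + d_co2
  # (flow + vo2 - vco2) ref_o2  - vo2  = flow fe_o2
  # flow fe_co2 - (flow + vo2 - vco2) ref_co2 = vco2
  a <- matrix(c(ref_o2 - 1, -ref_o2,
                -ref_co2, ref_co2 - 1), nrow = 2, byrow = TRUE)
  b <- c(flow * (fe_o2 - ref_o2), flow * (ref_co2 - fe_co2))
  x <- solve(a, b)
  list(vo2 = x[1], vco2 = x[2])
}

# Monte-Carlo oracle for first-order uncertainty propagation
mc_sd <- function(f, means, us, n = 1e5, seed = 99) {
  set.seed(seed)
  draws <- mapply(function(m, u) rnorm(n, m, u), means, us)
  stats::sd(do.call(f, unname(as.list(as.data.frame(draws)))))
}
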