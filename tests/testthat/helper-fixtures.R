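# shared fixtures: short protocols and a fixed replica pore geometry so
# individual tests stay fast

quick_protocol <- function(...) {
  defaults <- list(durations = c(300, 900, 900), sampling_s = 5,
                   noise_sd = 0.03)
  do.call(eb_protocol, utils::modifyList(defaults, list(...)))
}

paper_geometry <- function() {
  pore_geometry(diameter = 0.5e-3, depth = 40e-6,
                density = per_inch2_to_per_m2(160))
}

std_air <- function(t_c = 20, rh = 0.5, p = 101325) {
  air_state(t_c + 273.15, rh, p)
}

# fixed-step classical Runge-Kutta integrator: the brute-force oracle the
# adaptive stiff solver is checked against
rk4 <- function(rhs, y0, times, dt) {
  grid <- seq(times[1], times[length(times)], by = dt)
  y <- numeric(length(grid))
  y[1] <- y0
  for (i in seq_len(length(grid) - 1)) {
    t <- grid[i]; h <- grid[i + 1] - t; yi <- y[i]
    k1 <- rhs(yi, t)
    k2 <- rhs(yi + h / 2 * k1, t + h / 2)
    k3 <- rhs(yi + h / 2 * k2, t + h / 2)
    k4 <- rhs(yi + h * k3, t + h)
    y[i + 1] <- yi + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  stats::approx(grid, y, xout = times)$y
}
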