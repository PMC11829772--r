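# Shared fixtures and independent oracles.

# Naive O(N^4) double-sum 2D DFT, the independent oracle for dft2().
naive_dft2 <- function(x) {
  N <- nrow(x); M <- ncol(x)
  out <- matrix(0i, N, M)
  for (u in 0:(N - 1)) {
    for (v in 0:(M - 1)) {
      s <- 0i
      for (j in 0:(N - 1)) {
        for (k in 0:(M - 1)) {
          s <- s + x[j + 1, k + 1] * exp(-2i * pi * (j * u / N + k * v / M))
        }
      }
      out[u + 1, v + 1] <- s
    }
  }
  out
}

# Noiseless synthetic approach curve with contact at piezo extension zc
# (height frame origin 0, so the surface height is -zc + deflection terms).
make_curve <- function(E_kPa, zc = 150, z_max = 500, z_step = 2,
                       probe = probe_params(), noise_sd = 0, z_ref = 0,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- hertz_coefficient(E_kPa, probe)
  k <- probe$spring_constant * 1000
  z <- seq(0, z_max, by = z_step)
  u <- z - zc
  delta <- ifelse(u > 0, 2 * u / (1 + sqrt(pmax(1 + 4 * (C / k) * u, 1))), 0)
  f <- C * delta^2
  keep <- f <= probe$setpoint_force * 1000
  f <- f[keep] + if (noise_sd > 0) rnorm(sum(keep), 0, noise_sd) else 0
  force_curve(z[keep], f, probe, z_ref = z_ref)
}

# Orientation distribution with all mass exactly at `angle`.
delta_distribution <- function(angle) {
  list(bin_centers = angle, frequency = 1)
}

uniform_distribution <- function(bin_width = 2) {
  centers <- seq(bin_width / 2, 180 - bin_width / 2, by = bin_width)
  list(bin_centers = centers, frequency = rep(1 / length(centers),
                                              length(centers)))
}
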