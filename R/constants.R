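# Physical constants and decay data defaults.

KEV_TO_J <- 1.602176634e-16

# Published physical half-lives; overridable through calibration_config().
HALF_LIFE_GA68_MIN <- 67.71
HALF_LIFE_LU177_D <- 6.647

# mean lognormal factor == 1 for a given coefficient of variation
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# closed-form absorbed dose per injected activity (Gy/GBq) for a
# mono-exponential concentration curve under local energy deposition
ad_per_ia_monoexp <- function(c0_per_ml, t_eff_h, energy_kev = 147.9,
                              density = 1.04) {
  lambda_h <- log(2) / t_eff_h
  c0_per_ml * (energy_kev * KEV_TO_J) / (density * 1e-3) * 3600 / lambda_h * 1e9
}
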