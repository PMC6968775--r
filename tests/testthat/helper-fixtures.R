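# Shared builders for synthetic profiles and packaged reference tables.

# mono-exponential decay profile
exp_profile <- function(c0 = 100, k = 0.3, times = c(1, 2, 4, 8),
                        route = "iv", site = "systemic", dose = 1) {
  conc_profile("testdrug", "WT", route, site, times, c0 * exp(-k * times),
               dose)
}

# Bateman oral systemic profile, optionally noisy
bateman_profile <- function(s = 100, ka = 2, ke = 0.5,
                            times = default_schedule(), cv = 0, dose = 1) {
  d <- ka - ke
  c_true <- if (abs(d) < 1e-12) s * ka * times * exp(-ka * times)
            else s * ka / d * (exp(-ke * times) - exp(-ka * times))
  if (cv > 0)
    c_true <- c_true * exp(stats::rnorm(length(times), 0,
                                        sqrt(log(1 + cv^2))))
  conc_profile("testdrug", "WT", "oral", "systemic", times, c_true, dose)
}

read_fixture <- function(name) utils::read.csv(psdiff_example(name))

sim_specs <- function() list(simdrug = compound_spec("simdrug", 400, 1, 1, 1))
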