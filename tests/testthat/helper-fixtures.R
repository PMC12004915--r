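# Shared fixtures: the standard demicellization protocols used throughout
# (32 x 8 uL into 1.4 mL every 300 s; 0.04 M stock for the sulfobetaine
# run, 0.02 M for the phosphocholine run).

dps_protocol <- function(temperature = 298.15)
  titration_protocol(cell_volume = 1.4e-3, injection_volume = 8e-6,
                     n_injections = 32L, syringe_conc = 0.04,
                     spacing = 300, temperature = temperature)

dpc_protocol <- function(temperature = 298.15)
  titration_protocol(cell_volume = 1.4e-3, injection_volume = 8e-6,
                     n_injections = 32L, syringe_conc = 0.02,
                     spacing = 300, temperature = temperature)

dps_model <- function(kind = "mass_action", cmc = 3.6e-3, dH = 4000, n = 55,
                      offset = -200)
  micellization_model(kind, cmc = cmc, dH_demic = dH, agg_number = n,
                      dilution_offset = offset)

# two-condition study emulating the salt series (water vs perchlorate)
demo_config <- function(seed = 11L) {
  protocol <- list(cell_volume = 1.4e-3, injection_volume = 8e-6,
                   n_injections = 32L, syringe_conc = 0.04, spacing = 300)
  list(
    seed = seed,
    conditions = list(
      list(label = "DPS water", temperatures_C = c(10, 25, 35),
           protocol = protocol,
           model = list(kind = "mass_action", agg_number = 55,
                        cmc = 3.6e-3, dCp = -450, T_H = 300,
                        dilution_offset = -150)),
      list(label = "DPS NaClO4", temperatures_C = c(10, 25, 35),
           protocol = protocol,
           model = list(kind = "mass_action", agg_number = 55,
                        cmc = 1.0e-3, dCp = -400, T_H = 276,
                        dilution_offset = -150))))
}

# independent bisection oracle for x + n*K*x^n = C (linear scale)
bisect_monomer <- function(C, K, n, iter = 200L) {
  if (C == 0) return(0)
  f <- function(x) x + n * K * x^n - C
  lo <- 0; hi <- C
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# random sigmoid parameter draws with the transition inside the data span
# and every parameter bounded away from zero (identifiable draws)
random_sigmoid_params <- function(span = 7e-3) {
  sgn <- function() sample(c(-1, 1), 1)
  c(a1 = stats::runif(1, 500, 6000),
    a2 = sgn() * stats::runif(1, 1e4, 2e5),
    a3 = sgn() * stats::runif(1, 100, 500),
    a4 = sgn() * stats::runif(1, 1e4, 2e5),
    a5 = stats::runif(1, 0.3 * span, 0.7 * span),
    a6 = stats::runif(1, 0.012 * span, 0.06 * span))
}
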