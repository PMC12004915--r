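#' Forward-simulate a demicellization enthalpogram
#'
#' Emulates the ITC demicellization experiment: concentrated (micellar)
#' surfactant stock is injected stepwise into the cell; while the cell is
#' below the CMC the injected micelles dissolve and release/absorb
#' `dH_demic` per mole demicellized, and above the CMC they persist, leaving
#' only the dilution heat.
#'
#' Bookkeeping per injection (overfilled cell, plug-flow displacement): a
#' volume `v` of cell solution at the pre-injection composition is expelled,
#' `v` of syringe solution is added, and the cell re-equilibrates to the
#' monomer/micelle partition of the model at the new total concentration
#' `C_i = C_syr * (1 - (1 - v/V0)^i)`. The demicellized amount is the drop in
#' micellar material between the freshly mixed and the re-equilibrated state;
#' the molar heat is
#' `q_i = dH_demic * dn_demic_i / (C_syr * v) + dilution_offset + baselines`.
#' The syringe content is partitioned as monomer = `cmc`, micellar =
#' `C_syr - cmc` (the stock is ~12x CMC, micelle-dominated).
#'
#' Noise-free pseudophase output is step-like; mass-action output is a smooth
#' sigmoid that approaches the pseudophase curve as the aggregation number
#' grows.
#'
#' @param protocol A [titration_protocol()]; `syringe_conc` must exceed the
#'   model CMC (demicellization design).
#' @param model A [micellization_model()].
#' @param noise A [noise_spec()], or `NULL` for noise-free output.
#' @param bookkeeping Concentration convention passed to
#'   [cell_concentration()].
#' @param conc_assignment Concentration assigned to each point: `"mid"`
#'   (default; midpoint of the pre/post-injection cell concentrations — the
#'   second-order-accurate pairing for an interval-averaged heat) or
#'   `"post"` (cell concentration after the addition, the convention most
#'   instrument software prints; it shifts the apparent transition right by
#'   about half an injection).
#' @return An [enthalpogram()] with attribute `truth` recording the
#'   generating parameters.
#' @export
simulate_enthalpogram <- function(protocol, model, noise = NULL,
                                  bookkeeping = c("displacement", "additive"),
                                  conc_assignment = c("mid", "post")) {
  validate_protocol(protocol)
  stopifnot(inherits(model, "micelle_model"))
  bookkeeping <- match.arg(bookkeeping)
  conc_assignment <- match.arg(conc_assignment)
  if (protocol$syringe_conc <= model$cmc)
    stop("syringe_conc must exceed the model CMC for a demicellization run",
         call. = FALSE)

  n <- protocol$n_injections
  v <- protocol$injection_volume
  V0 <- protocol$cell_volume
  f <- v / V0
  C <- cell_concentration(protocol, 0:n, bookkeeping = "displacement")
  if (C[n + 1L] <= model$cmc)
    warning("final cell concentration never exceeds the CMC; ",
            "no transition will be observed", call. = FALSE)

  monomer <- model_monomer(model, C)
  micellar <- C - monomer
  mono_syr <- min(model$cmc, protocol$syringe_conc)
  mic_syr <- protocol$syringe_conc - mono_syr

  # micellar concentration just after mixing, before re-equilibration
  mic_mix <- micellar[1:n] * (1 - f) + mic_syr * f
  dn_demic <- (mic_mix - micellar[2:(n + 1L)]) * V0
  n_inj <- moles_per_injection(protocol)

  w <- if (mic_syr > 0) pmin(pmax(dn_demic / (mic_syr * v), 0), 1) else 0
  conc_post <- cell_concentration(protocol, 1:n, bookkeeping = bookkeeping)
  conc_pre <- cell_concentration(protocol, 0:(n - 1L), bookkeeping = bookkeeping)
  q <- model$dH_demic * dn_demic / n_inj + model$dilution_offset +
    w * model$baseline_slopes[1] * conc_post +
    (1 - w) * model$baseline_slopes[2] * conc_post

  if (!is.null(noise)) {
    stopifnot(inherits(noise, "itc_noise"))
    if (noise$sigma_heat > 0) {
      q <- q + with_local_seed(noise$seed, stats::rnorm(
        n, sd = noise$sigma_heat * abs(model$dH_demic)))
    }
  }

  conc <- if (conc_assignment == "post") conc_post else (conc_pre + conc_post) / 2
  e <- enthalpogram(conc, q, temperature = protocol$temperature)
  attr(e, "truth") <- list(model = model, protocol = protocol,
                           bookkeeping = bookkeeping,
                           conc_assignment = conc_assignment)
  e
}

# Evaluate an expression under a given RNG seed without disturbing the
# caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render an enthalpogram as a raw heat-flow trace
#'
#' Produces the synthetic analogue of the instrument record: each injection's
#' heat appears as a Gaussian power pulse whose time integral equals that
#' injection's heat (in joules), superimposed on a linear baseline. Pulses
#' decay to baseline well before the next injection, as in a well-spaced
#' demicellization run.
#'
#' @param e An [enthalpogram()] (molar heats are converted to joules with the
#'   protocol's moles-per-injection).
#' @param protocol The generating [titration_protocol()].
#' @param peak_width Pulse duration in seconds (rendered as a Gaussian with
#'   `sd = peak_width/8`); must be smaller than the injection spacing.
#' @param baseline_drift Linear baseline drift, W/s.
#' @param baseline_power Baseline power at t = 0, W.
#' @param dt Sampling interval, s.
#' @param lead_in Quiet time before the first injection, s.
#' @return An object of class `itc_thermogram` (see [thermogram()]).
#' @export
simulate_power_trace <- function(e, protocol, peak_width = 40,
                                 baseline_drift = 0, baseline_power = 0,
                                 dt = 1, lead_in = 60) {
  stopifnot(inherits(e, "itc_enthalpogram"))
  validate_protocol(protocol)
  if (peak_width >= protocol$spacing)
    stop("peak_width must be smaller than the injection spacing",
         call. = FALSE)
  n <- nrow(e)
  t_inj <- lead_in + (seq_len(n) - 1) * protocol$spacing
  t_end <- lead_in + n * protocol$spacing
  times <- seq(0, t_end, by = dt)
  Q <- e$q_J_per_mol * moles_per_injection(protocol)  # joules per injection
  sigma <- peak_width / 8
  centre <- t_inj + peak_width / 2
  power <- baseline_power + baseline_drift * times
  for (k in seq_len(n)) {
    power <- power + Q[k] * stats::dnorm(times, mean = centre[k], sd = sigma)
  }
  sched <- data.frame(injection = seq_len(n), time_s = t_inj,
                      volume_L = protocol$injection_volume)
  thermogram(times, power, sched)
}

#' Generate a linear enthalpy-vs-temperature series
#'
#' Under a constant heat capacity of micellization the enthalpy is exactly
#' linear in temperature, `dH_mic(T) = dCp * (T - T_H)`, crossing zero at the
#' compensation temperature `T_H`.
#'
#' @param dCp Heat capacity change of micellization, J mol^-1 K^-1.
#' @param T_H Temperature at which the micellization enthalpy is zero, K.
#' @param temperatures Vector of at least two distinct temperatures, K.
#' @return A data frame with columns `temperature_K` and `dH_mic_J_per_mol`.
#' @examples
#' simulate_temperature_series(-400, 290.65, c(283.15, 298.15, 308.15))
#' @export
simulate_temperature_series <- function(dCp, T_H, temperatures) {
  stopifnot(is.numeric(dCp), is.numeric(T_H), is.numeric(temperatures))
  if (anyDuplicated(temperatures)) {
    warning("duplicate temperatures collapsed to the unique set",
            call. = FALSE)
    temperatures <- unique(temperatures)
  }
  if (length(temperatures) < 2L)
    stop("need at least 2 distinct temperatures", call. = FALSE)
  data.frame(temperature_K = temperatures,
             dH_mic_J_per_mol = dCp * (temperatures - T_H))
}
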