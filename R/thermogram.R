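#' Raw heat-flow thermogram
#'
#' Differential power versus time, with injection markers. This is the raw
#' instrument record; [integrate_peaks()] turns it into an enthalpogram.
#'
#' @param times Strictly increasing times, s.
#' @param powers Differential power, W; same length as `times`.
#' @param injections Data frame with columns `injection`, `time_s`,
#'   `volume_L`, sorted by time; every injection time must fall inside the
#'   record.
#' @return An object of class `itc_thermogram`.
#' @export
thermogram <- function(times, powers, injections) {
  times <- as.numeric(times)
  powers <- as.numeric(powers)
  if (length(times) != length(powers))
    stop("times and powers must have equal length", call. = FALSE)
  bad <- which(diff(times) <= 0)
  if (length(bad))
    stop(sprintf("times must be strictly increasing (row %d)", bad[1] + 1L),
         call. = FALSE)
  need <- c("injection", "time_s", "volume_L")
  if (!all(need %in% names(injections)))
    stop("injection schedule needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(injections$time_s, strictly = TRUE))
    stop("injections must be sorted by time", call. = FALSE)
  if (any(injections$time_s < times[1]) ||
      any(injections$time_s > times[length(times)]))
    stop("every injection time must lie within the record", call. = FALSE)
  structure(list(times = times, powers = powers,
                 injections = as.data.frame(injections)),
            class = "itc_thermogram")
}

#' @export
print.itc_thermogram <- function(x, ...) {
  cat(sprintf("ITC thermogram: %d samples over %.0f s, %d injections\n",
              length(x$times), diff(range(x$times)), nrow(x$injections)))
  invisible(x)
}

#' Read / write thermogram and injection-schedule CSVs
#'
#' Thermogram files carry columns `time_s,power_W`; the injection schedule is
#' a separate CSV with `injection,time_s,volume_L`.
#'
#' @param path,schedule_path File paths.
#' @return `read_thermogram` returns an [thermogram()] object.
#' @export
read_thermogram <- function(path, schedule_path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "power_W")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in need) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (any(is.na(v)))
      stop(sprintf("non-numeric value in column '%s' (row %d)", col,
                   which(is.na(v))[1]), call. = FALSE)
    d[[col]] <- v
  }
  s <- utils::read.csv(schedule_path)
  thermogram(d$time_s, d$power_W, s)
}

#' @rdname read_thermogram
#' @param tg An [thermogram()] object.
#' @export
write_thermogram <- function(tg, path, schedule_path) {
  stopifnot(inherits(tg, "itc_thermogram"))
  utils::write.csv(data.frame(time_s = tg$times, power_W = tg$powers),
                   path, row.names = FALSE, quote = FALSE)
  utils::write.csv(tg$injections, schedule_path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Integrate injection peaks into per-injection molar heats
#'
#' The raw-trace-to-enthalpogram transformation. Each injection's window runs
#' from its injection time to the next injection (or to `spacing` seconds
#' after the last). The local baseline under each peak is the linear
#' interpolant between two quiet segments — the last `quiet_fraction` of the
#' interval preceding the window and the last `quiet_fraction` of the window
#' itself — which is well defined because the signal returns to baseline
#' between injections. The heat is the trapezoidal integral of
#' (power - baseline) over the window; molar heat divides by the moles
#' injected, `C_syr * v`; the concentration for each point follows the
#' protocol bookkeeping.
#'
#' @param tg An [thermogram()] object.
#' @param protocol The [titration_protocol()] describing the run.
#' @param quiet_fraction Fraction of each inter-injection interval treated as
#'   baseline-representative (default 0.1).
#' @param drop_first Discard the first injection (common calorimetric
#'   practice for an under-filled first delivery); kept by default.
#' @param conc_assignment `"mid"` (default) or `"post"`, as in
#'   [simulate_enthalpogram()].
#' @param bookkeeping Concentration convention, see [cell_concentration()].
#' @return An [enthalpogram()].
#' @export
integrate_peaks <- function(tg, protocol, quiet_fraction = 0.1,
                            drop_first = FALSE,
                            conc_assignment = c("mid", "post"),
                            bookkeeping = c("displacement", "additive")) {
  stopifnot(inherits(tg, "itc_thermogram"))
  validate_protocol(protocol)
  conc_assignment <- match.arg(conc_assignment)
  bookkeeping <- match.arg(bookkeeping)
  if (quiet_fraction <= 0 || quiet_fraction >= 0.5)
    stop("quiet_fraction must lie in (0, 0.5)", call. = FALSE)
  t_inj <- tg$injections$time_s
  n <- length(t_inj)
  t_end <- tg$times[length(tg$times)]
  windows_end <- c(t_inj[-1], min(t_end, t_inj[n] + protocol$spacing))
  if (t_inj[n] + protocol$spacing > t_end + 1e-9)
    warning("last integration window truncated at the end of the record",
            call. = FALSE)

  # quiet segment ending at time tq: mean power and mean time over the last
  # quiet_fraction of the interval [t_prev, tq]
  quiet_point <- function(t_from, t_to) {
    lo <- t_to - quiet_fraction * (t_to - t_from)
    sel <- tg$times >= lo & tg$times <= t_to
    if (!any(sel))
      stop("no samples in quiet segment before t = ", t_to, call. = FALSE)
    c(t = mean(tg$times[sel]), p = mean(tg$powers[sel]))
  }

  heats <- numeric(n)
  for (k in seq_len(n)) {
    w_from <- t_inj[k]
    w_to <- windows_end[k]
    pre <- quiet_point(if (k == 1L) tg$times[1] else t_inj[k - 1L], w_from)
    post <- quiet_point(w_from, w_to)
    sel <- tg$times >= w_from & tg$times <= w_to
    tt <- tg$times[sel]
    if (length(tt) < 3L)
      stop("integration window ", k, " contains fewer than 3 samples",
           call. = FALSE)
    baseline <- pre["p"] + (post["p"] - pre["p"]) *
      (tt - pre["t"]) / (post["t"] - pre["t"])
    heats[k] <- pracma::trapz(tt, tg$powers[sel] - baseline)
  }
  q_molar <- heats / moles_per_injection(protocol)
  idx <- seq_len(n)
  conc_post <- cell_concentration(protocol, idx, bookkeeping = bookkeeping)
  conc_pre <- cell_concentration(protocol, idx - 1L, bookkeeping = bookkeeping)
  conc <- if (conc_assignment == "post") conc_post else (conc_pre + conc_post) / 2
  keep <- if (drop_first) -1L else idx
  enthalpogram(conc[keep], q_molar[keep],
               temperature = protocol$temperature)
}
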