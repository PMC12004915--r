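#' Read a study configuration
#'
#' YAML file mirroring the constructor arguments: a top-level `seed`,
#' `output_dir`, `plot`, and a list of `conditions`, each with a unique
#' `label`, `temperatures_K` (or `temperatures_C`, converted with 273.15), a
#' `protocol` block ([titration_protocol()] fields) and either a `model`
#' block (simulation: [micellization_model()] fields plus `dCp`/`T_H` giving
#' the temperature dependence of the enthalpy, and optional `noise_sigma`)
#' or `enthalpograms` (paths of per-temperature enthalpogram CSVs).
#'
#' @param path YAML file path.
#' @return A validated study configuration list.
#' @export
read_study_config <- function(path) {
  validate_study_config(yaml::read_yaml(path))
}

validate_study_config <- function(cfg) {
  if (is.null(cfg$conditions) || !length(cfg$conditions))
    stop("study config needs at least one condition", call. = FALSE)
  labels <- vapply(cfg$conditions, function(cnd) as.character(cnd$label),
                   character(1))
  if (anyDuplicated(labels))
    stop("condition labels must be unique", call. = FALSE)
  for (cnd in cfg$conditions) {
    tK <- condition_temperatures(cnd)
    if (!length(tK))
      stop("condition '", cnd$label, "' has no temperatures", call. = FALSE)
    if (is.null(cnd$model) && is.null(cnd$enthalpograms))
      stop("condition '", cnd$label,
           "' needs a model block or enthalpogram paths", call. = FALSE)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

condition_temperatures <- function(cnd) {
  if (!is.null(cnd$temperatures_K)) as.numeric(cnd$temperatures_K)
  else if (!is.null(cnd$temperatures_C)) as.numeric(cnd$temperatures_C) + 273.15
  else numeric(0)
}

#' Run a batch demicellization study
#'
#' End-to-end driver: for every (condition, temperature) pair, obtain an
#' enthalpogram (forward-simulated from the condition's model, or read from
#' disk), fit the sigmoid, extract CMC and demicellization enthalpy, and
#' build a [thermo_record()]; then fit [heat_capacity()] per condition with
#' at least two temperatures. Simulation seeds are derived deterministically
#' from the study seed, so reruns are bit-identical. A condition whose fit
#' fails is recorded in `errors` and does not disturb the others.
#'
#' @param config A configuration list (see [read_study_config()]) or a path
#'   to a YAML file.
#' @param c_std Standard concentration for [gibbs_energy()], mol/L.
#' @return An object of class `itc_study`: `records` (one row per condition
#'   and temperature), `heat_capacity` (one row per eligible condition),
#'   `fits`, `enthalpograms`, `errors` and the `config`.
#' @export
run_study <- function(config, c_std = 1) {
  if (is.character(config)) config <- read_study_config(config)
  config <- validate_study_config(config)
  seed0 <- as.integer(config$seed)

  records <- list()
  hc_rows <- list()
  fits <- list()
  enths <- list()
  errors <- list()

  for (ci in seq_along(config$conditions)) {
    cnd <- config$conditions[[ci]]
    label <- as.character(cnd$label)
    temps <- condition_temperatures(cnd)
    res <- tryCatch({
      rows <- vector("list", length(temps))
      for (ti in seq_along(temps)) {
        Tk <- temps[ti]
        e <- condition_enthalpogram(cnd, ti, Tk,
                                    seed = seed0 + 1009L * ci + ti)
        fit <- fit_sigmoid(e)
        key <- sprintf("%s@%.2fK", label, Tk)
        fits[[key]] <- fit
        enths[[key]] <- e
        rows[[ti]] <- thermo_record(label, Tk, cmc_from_fit(fit),
                                    micellization_enthalpy(dH_from_fit(fit)),
                                    c_std = c_std)
      }
      do.call(rbind, rows)
    }, error = function(err) err)
    if (inherits(res, "error")) {
      errors[[label]] <- conditionMessage(res)
      next
    }
    records[[label]] <- res
    if (nrow(res) >= 2L) {
      hc <- heat_capacity(data.frame(temperature_K = res$T_K,
                                     dH_mic_J_per_mol = res$dH_mic_J_per_mol))
      hc_rows[[label]] <- data.frame(
        condition = label, dCp_J_per_mol_K = hc$dCp, T_H_K = hc$T_H,
        slope_stderr_J_per_mol_K = hc$slope_stderr,
        n_points = hc$n_points, extrapolated = hc$extrapolated)
    }
  }

  structure(list(
    records = if (length(records)) do.call(rbind, unname(records)) else NULL,
    heat_capacity = if (length(hc_rows)) do.call(rbind, unname(hc_rows))
                    else NULL,
    fits = fits, enthalpograms = enths, errors = errors, config = config),
    class = "itc_study")
}

# Build one enthalpogram for a condition at temperature Tk: simulate from the
# model block, or read the ti-th enthalpogram path.
condition_enthalpogram <- function(cnd, ti, Tk, seed) {
  if (!is.null(cnd$enthalpograms)) {
    e <- read_enthalpogram(cnd$enthalpograms[[ti]], temperature = Tk,
                           condition_label = as.character(cnd$label))
    return(e)
  }
  mb <- cnd$model
  pb <- if (is.null(cnd$protocol)) list() else cnd$protocol
  protocol <- do.call(titration_protocol,
                      c(pb[setdiff(names(pb), "temperature")],
                        list(temperature = Tk)))
  cmc <- as.numeric(mb$cmc)
  cmc_T <- if (length(cmc) > 1L) cmc[ti] else cmc
  dH_mic <- if (!is.null(mb$dCp) && !is.null(mb$T_H))
    as.numeric(mb$dCp) * (Tk - as.numeric(mb$T_H))
  else as.numeric(mb$dH_mic %||% -4000)
  model <- micellization_model(
    kind = mb$kind %||% "mass_action",
    cmc = cmc_T,
    dH_demic = -dH_mic,
    agg_number = mb$agg_number %||% 55,
    dilution_offset = as.numeric(mb$dilution_offset %||% 0))
  noise <- noise_spec(sigma_heat = as.numeric(cnd$noise_sigma %||% 0),
                      seed = seed)
  e <- simulate_enthalpogram(protocol, model, noise)
  attr(e, "condition_label") <- as.character(cnd$label)
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.itc_study <- function(x, ...) {
  nrec <- if (is.null(x$records)) 0L else nrow(x$records)
  cat(sprintf("ITC study: %d thermodynamic records, %d heat-capacity fits",
              nrec,
              if (is.null(x$heat_capacity)) 0L else nrow(x$heat_capacity)))
  if (length(x$errors))
    cat(sprintf(", %d failed condition(s): %s",
                length(x$errors), paste(names(x$errors), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Write consolidated study outputs
#'
#' Writes `thermo_records.csv` (condition, T_K, cmc_M, dG_J_per_mol,
#' dH_mic_J_per_mol, minus_TdS_J_per_mol, dS_J_per_mol_K),
#' `heat_capacity.csv` (condition, dCp_J_per_mol_K, T_H_K,
#' slope_stderr_J_per_mol_K, n_points, extrapolated) and
#' `study_summary.json` into `output_dir`. With `plot = TRUE` (requires
#' ggplot2) it adds one enthalpogram+fit figure per record
#' (`fit_<condition>_<T>.png`) and a bar chart of the thermodynamic
#' decomposition (`decomposition.png`). Reruns overwrite with identical
#' content.
#'
#' @param study An [run_study()] result.
#' @param output_dir Output directory (created if absent).
#' @param plot Render figures (off by default; headless-safe).
#' @return Invisibly, the vector of files written.
#' @export
render_report <- function(study, output_dir, plot = FALSE) {
  stopifnot(inherits(study, "itc_study"))
  if (is.null(study$records) || nrow(study$records) == 0L)
    stop("nothing to report: study contains no records", call. = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(output_dir, mode = 2) != 0L)
    stop("output directory is not writable: ", output_dir, call. = FALSE)

  files <- character(0)
  f <- file.path(output_dir, "thermo_records.csv")
  utils::write.csv(format_num_df(study$records), f, row.names = FALSE,
                   quote = FALSE)
  files <- c(files, f)
  f <- file.path(output_dir, "heat_capacity.csv")
  hc <- study$heat_capacity
  if (is.null(hc))
    hc <- data.frame(condition = character(0), dCp_J_per_mol_K = numeric(0),
                     T_H_K = numeric(0),
                     slope_stderr_J_per_mol_K = numeric(0),
                     n_points = integer(0), extrapolated = logical(0))
  utils::write.csv(format_num_df(hc), f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  f <- file.path(output_dir, "study_summary.json")
  jsonlite::write_json(list(
    n_records = nrow(study$records),
    n_heat_capacity = if (is.null(study$heat_capacity)) 0L
                      else nrow(study$heat_capacity),
    failed_conditions = as.list(study$errors)),
    f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, f)

  if (isTRUE(plot)) files <- c(files, render_plots(study, output_dir))
  invisible(files)
}

# Fixed-format numbers so identical studies produce byte-identical CSVs.
format_num_df <- function(d) {
  for (nm in names(d))
    if (is.numeric(d[[nm]])) d[[nm]] <- sprintf("%.10g", d[[nm]])
  d
}

render_plots <- function(study, output_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package", call. = FALSE)
  files <- character(0)
  for (key in names(study$enthalpograms)) {
    e <- study$enthalpograms[[key]]
    fit <- study$fits[[key]]
    grid <- seq(min(e$conc_mol_per_L), max(e$conc_mol_per_L),
                length.out = 400)
    curve <- data.frame(conc = grid,
                        q = eval_sigmoid(fit$coefficients, grid))
    gp <- ggplot2::ggplot(e, ggplot2::aes(
      x = conc_mol_per_L * 1e3, y = q_J_per_mol / 1e3)) +
      ggplot2::geom_point() +
      ggplot2::geom_line(data = curve,
                         ggplot2::aes(x = conc * 1e3, y = q / 1e3)) +
      ggplot2::geom_vline(xintercept = fit$cmc * 1e3, linetype = 2) +
      ggplot2::labs(x = "[surfactant] (mM)", y = "q (kJ/mol injectant)",
                    title = key)
    f <- file.path(output_dir,
                   paste0("fit_", gsub("[^A-Za-z0-9._-]", "_", key), ".png"))
    ggplot2::ggsave(f, gp, width = 5, height = 3.5, dpi = 120)
    files <- c(files, f)
  }
  rec <- study$records
  long <- rbind(
    data.frame(condition = rec$condition, T_K = rec$T_K,
               term = "dG", value = rec$dG_J_per_mol),
    data.frame(condition = rec$condition, T_K = rec$T_K,
               term = "dH_mic", value = rec$dH_mic_J_per_mol),
    data.frame(condition = rec$condition, T_K = rec$T_K,
               term = "-TdS", value = rec$minus_TdS_J_per_mol))
  gp <- ggplot2::ggplot(long, ggplot2::aes(
    x = condition, y = value / 1e3, fill = term)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~T_K) +
    ggplot2::labs(x = NULL, y = "kJ/mol") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  f <- file.path(output_dir, "decomposition.png")
  ggplot2::ggsave(f, gp, width = 7, height = 4, dpi = 120)
  c(files, f)
}
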