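#' Enthalpogram: per-injection molar heats vs cell concentration
#'
#' The central intermediate of the analysis: for each injection, the heat per
#' mole of injectant (J/mol) paired with the total surfactant concentration
#' in the cell after that injection (mol/L).
#'
#' @param concentrations Strictly increasing cell concentrations, mol/L.
#' @param heats Molar heats, J per mole of injectant; same length.
#' @param temperature Cell temperature, kelvin.
#' @param condition_label Free-text condition tag (e.g. salt identity).
#' @return An object of class `itc_enthalpogram` (a data frame with columns
#'   `injection`, `conc_mol_per_L`, `q_J_per_mol` and attributes
#'   `temperature`, `condition_label`).
#' @export
enthalpogram <- function(concentrations, heats, temperature = 298.15,
                         condition_label = "") {
  concentrations <- as.numeric(concentrations)
  heats <- as.numeric(heats)
  if (length(concentrations) != length(heats))
    stop("concentrations and heats must have equal length", call. = FALSE)
  if (length(concentrations) == 0L)
    stop("enthalpogram must contain at least one injection", call. = FALSE)
  bad <- which(diff(concentrations) <= 0)
  if (length(bad))
    stop(sprintf("concentrations must be strictly increasing (row %d)",
                 bad[1] + 1L), call. = FALSE)
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive", call. = FALSE)
  e <- data.frame(injection = seq_along(concentrations),
                  conc_mol_per_L = concentrations,
                  q_J_per_mol = heats)
  attr(e, "temperature") <- as.numeric(temperature)
  attr(e, "condition_label") <- as.character(condition_label)
  class(e) <- c("itc_enthalpogram", "data.frame")
  e
}

#' @export
print.itc_enthalpogram <- function(x, ...) {
  cat(sprintf("ITC enthalpogram: %d injections, %.4g-%.4g mM, T = %.2f K%s\n",
              nrow(x), min(x$conc_mol_per_L) * 1e3,
              max(x$conc_mol_per_L) * 1e3, attr(x, "temperature"),
              if (nzchar(attr(x, "condition_label")))
                paste0(" [", attr(x, "condition_label"), "]") else ""))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more injections\n", nrow(x) - 6L))
  invisible(x)
}

#' Read / write enthalpogram CSV
#'
#' Plain CSV dialect with a mandatory header
#' `injection,conc_mol_per_L,q_J_per_mol` (decimal point, no thousands
#' separators). Temperature and condition label ride along as optional
#' `# key: value` comment lines above the header so a write/read round trip
#' is lossless to 12+ significant digits.
#'
#' @param path File path.
#' @param temperature,condition_label Used when the file carries no metadata
#'   comments.
#' @return `read_enthalpogram` returns an [enthalpogram()];
#'   `write_enthalpogram` returns `path` invisibly.
#' @export
read_enthalpogram <- function(path, temperature = 298.15,
                              condition_label = "") {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  for (m in meta) {
    kv <- sub("^#\\s*", "", m)
    if (grepl("^temperature_K:", kv))
      temperature <- as.numeric(sub("^temperature_K:\\s*", "", kv))
    if (grepl("^condition:", kv))
      condition_label <- sub("^condition:\\s*", "", kv)
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L)
    stop("empty data section in ", path, call. = FALSE)
  d <- utils::read.csv(text = paste(body, collapse = "\n"),
                       colClasses = "character")
  need <- c("injection", "conc_mol_per_L", "q_J_per_mol")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (col in need) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (any(is.na(v)))
      stop(sprintf("non-numeric value in column '%s' (row %d)",
                   col, which(is.na(v))[1]), call. = FALSE)
    d[[col]] <- v
  }
  dup <- which(diff(d$conc_mol_per_L) <= 0)
  if (length(dup))
    stop(sprintf(
      "concentrations must be strictly increasing (row %d)", dup[1] + 1L),
      call. = FALSE)
  enthalpogram(d$conc_mol_per_L, d$q_J_per_mol, temperature, condition_label)
}

#' @rdname read_enthalpogram
#' @param e An [enthalpogram()].
#' @export
write_enthalpogram <- function(e, path) {
  stopifnot(inherits(e, "itc_enthalpogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature_K: %.12g", attr(e, "temperature")), con)
  if (nzchar(attr(e, "condition_label")))
    writeLines(paste0("# condition: ", attr(e, "condition_label")), con)
  writeLines("injection,conc_mol_per_L,q_J_per_mol", con)
  writeLines(sprintf("%d,%.15g,%.15g", e$injection, e$conc_mol_per_L,
                     e$q_J_per_mol), con)
  invisible(path)
}
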