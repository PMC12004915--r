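#' Boltzmann sigmoid bridging two linear baselines
#'
#' The normative enthalpogram model: two linear baselines, `a1 + a2*C` before
#' the transition and `a3 + a4*C` after it, joined by a Boltzmann switch of
#' centre `a5` and width `a6`:
#'
#' `q(C) = (a3 + a4*C) + ((a1 + a2*C) - (a3 + a4*C)) / (1 + exp((C - a5)/a6))`
#'
#' For `C << a5` the curve tends to the pre-transition line, for `C >> a5` to
#' the post-transition line; the CMC is read from the extremum of `dq/dC` and
#' the demicellization enthalpy from the baseline gap at the CMC.
#'
#' @param params Named numeric vector or list with elements `a1`..`a6`
#'   (`a6 > 0`).
#' @param conc Concentration(s), mol/L (any concentration unit works as long
#'   as `a2`, `a4`, `a5`, `a6` share it).
#' @return Molar heat(s), same units as `a1`/`a3`.
#' @examples
#' eval_sigmoid(c(a1 = 4000, a2 = 0, a3 = 0, a4 = 0, a5 = 3.6e-3, a6 = 1e-4),
#'              c(1e-3, 3.6e-3, 6e-3))
#' @export
eval_sigmoid <- function(params, conc) {
  p <- as.list(params)
  stopifnot(all(c("a1", "a2", "a3", "a4", "a5", "a6") %in% names(p)))
  if (p$a6 <= 0) stop("a6 must be positive", call. = FALSE)
  pre <- p$a1 + p$a2 * conc
  post <- p$a3 + p$a4 * conc
  post + (pre - post) / (1 + exp((conc - p$a5) / p$a6))
}

# Analytic first derivative dq/dC of the sigmoid.
sigmoid_deriv <- function(params, conc) {
  p <- as.list(params)
  z <- (conc - p$a5) / p$a6
  s <- stats::plogis(-z)             # 1 / (1 + exp(z)), overflow-safe
  sp <- -stats::dlogis(z) / p$a6     # d s / dC
  gap <- (p$a1 + p$a2 * conc) - (p$a3 + p$a4 * conc)
  p$a4 + (p$a2 - p$a4) * s + gap * sp
}

#' Fit the sigmoid model to an enthalpogram
#'
#' Least-squares fit (unit weights by default) of [eval_sigmoid()] by
#' Levenberg-Marquardt with bound constraints, with deterministic multi-start:
#' the data-driven initialisation (transition centre at the steepest data
#' slope, width 10% of the concentration span, baselines from straight lines
#' through the first and last quarter of the points) plus jittered restarts.
#' The best converged solution by residual sum of squares wins; the fit
#' refuses to return non-converged parameters silently.
#'
#' @param e An [enthalpogram()] (>= 8 points spanning the transition).
#' @param weights Optional per-point weights (default unit).
#' @param n_starts Number of jittered restarts on top of the data-driven
#'   initialisation (>= 5 used in total).
#' @param jitter_seed Seed for the deterministic restart jitter.
#' @return An object of class `sigmoid_fit` with elements `coefficients`
#'   (`a1`..`a6`), `covariance`, `rss`, `cmc`, `dH_demic`, `converged`,
#'   `boundary` (extremum at the data edge) and `data`.
#' @export
fit_sigmoid <- function(e, weights = NULL, n_starts = 6L,
                        jitter_seed = 1905L) {
  stopifnot(inherits(e, "itc_enthalpogram"))
  C <- e$conc_mol_per_L
  q <- e$q_J_per_mol
  m <- length(C)
  if (m < 8L)
    stop("need at least 8 points to fit the sigmoid", call. = FALSE)
  if (diff(range(q)) <= 3 * stats::median(abs(diff(q))))
    stop("no transition detected: heat range does not exceed the ",
         "point-to-point scatter", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, m)
  span <- diff(range(C))

  slopes <- diff(q) / diff(C)
  k_steep <- which.max(abs(slopes))
  n_edge <- max(2L, floor(m / 4))
  lm_pre <- stats::lm(q[1:n_edge] ~ C[1:n_edge])
  lm_post <- stats::lm(q[(m - n_edge + 1L):m] ~ C[(m - n_edge + 1L):m])
  init <- c(a1 = unname(stats::coef(lm_pre)[1]),
            a2 = unname(stats::coef(lm_pre)[2]),
            a3 = unname(stats::coef(lm_post)[1]),
            a4 = unname(stats::coef(lm_post)[2]),
            a5 = mean(C[k_steep + 0:1]),
            a6 = 0.1 * span)

  # keep a6 large enough that at least a few points feel the transition:
  # below ~1/5 of the median concentration step the sigmoid degenerates to a
  # step between samples and the parameters are unidentifiable
  dC_med <- stats::median(diff(sort(C)))
  lower <- c(-Inf, -Inf, -Inf, -Inf, min(C), dC_med / 5)
  upper <- c(Inf, Inf, Inf, Inf, max(C), span)
  pn <- c("a1", "a2", "a3", "a4", "a5", "a6")

  starts <- list(init)
  for (w6 in c(0.02, 0.05)) {
    st <- init
    st["a6"] <- max(w6 * span, dC_med / 5)
    starts[[length(starts) + 1L]] <- st
  }
  jit <- with_local_seed(jitter_seed, matrix(
    stats::rnorm(max(n_starts, 5L) * 2), ncol = 2))
  for (s in seq_len(max(n_starts, 5L))) {
    st <- init
    st["a5"] <- min(max(init["a5"] + 0.1 * span * jit[s, 1], min(C)), max(C))
    st["a6"] <- min(max(init["a6"] * exp(1.2 * jit[s, 2]), dC_med / 5), span)
    starts[[length(starts) + 1L]] <- st
  }

  sw <- sqrt(weights)
  resid_fn <- function(par) {
    names(par) <- pn
    sw * (q - eval_sigmoid(par, C))
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = pmin(pmax(unname(st), lower), upper), fn = resid_fn,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          maxiter = 1000, ftol = 1e-14, ptol = 1e-14, gtol = 1e-14)),
      error = function(err) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4)) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("sigmoid fit failed to converge after ", length(starts),
         " starts; check that the data bracket a transition", call. = FALSE)

  co <- stats::setNames(best$fit$par, pn)
  covmat <- sigmoid_vcov(co, C, weights, best$rss, m)
  out <- structure(list(coefficients = co, covariance = covmat,
                        rss = best$rss, converged = TRUE,
                        data = e, n = m), class = "sigmoid_fit")
  ext <- derivative_extremum(co, range(C))
  out$cmc <- ext$cmc
  out$boundary <- ext$boundary
  out$dH_demic <- dH_from_fit(out)
  if (ext$boundary)
    warning("derivative extremum at the edge of the data range: ",
            "transition not bracketed", call. = FALSE)
  out
}

# Asymptotic parameter covariance sigma^2 (J' W J)^-1 from a central
# difference Jacobian at the solution; NA matrix if the information matrix
# is numerically singular.
sigmoid_vcov <- function(co, C, weights, rss, m) {
  J <- matrix(0, length(C), 6L)
  for (j in seq_len(6L)) {
    h <- max(abs(co[j]) * 1e-6, 1e-12)
    up <- co; up[j] <- up[j] + h
    dn <- co; dn[j] <- dn[j] - h
    J[, j] <- (eval_sigmoid(up, C) - eval_sigmoid(dn, C)) / (2 * h)
  }
  JtWJ <- crossprod(J * sqrt(weights))
  sigma2 <- rss / max(m - 6L, 1L)
  # equilibrate before inverting: the parameter scales differ by many orders
  # of magnitude (intercepts in J/mol, centre/width in mol/L)
  d <- sqrt(diag(JtWJ))
  d[d == 0] <- 1
  A <- JtWJ / tcrossprod(d)
  V <- tryCatch(solve(A) / tcrossprod(d) * sigma2, error = function(err)
    matrix(NA_real_, 6L, 6L))
  (V + t(V)) / 2
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("Sigmoid enthalpogram fit\n")
  cat(sprintf("  converged : %s (rss = %.4g)\n", x$converged, x$rss))
  cat(sprintf("  CMC       : %.6g mol/L%s\n", x$cmc,
              if (isTRUE(x$boundary)) " [boundary!]" else ""))
  cat(sprintf("  dH_demic  : %.6g J/mol\n", x$dH_demic))
  cat("  parameters:\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) object$coefficients

# Locate the extremum of |dq/dC| inside `rng`. Coarse scan to bracket all
# local extrema (there can be two when the baselines slope), then local
# refinement; ties broken by largest |dq/dC|.
derivative_extremum <- function(params, rng, n_grid = 4001L) {
  p <- as.list(params)
  if (abs(p$a2 - p$a4) <= 1e-12 * (abs(p$a2) + abs(p$a4) + 1e-300) ||
      p$a2 == p$a4) {
    # equal baseline slopes: |dq/dC| is symmetric about a5, extremum exact
    cmc <- min(max(p$a5, rng[1]), rng[2])
    return(list(cmc = cmc, boundary = cmc <= rng[1] || cmc >= rng[2]))
  }
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  g <- abs(sigmoid_deriv(params, grid))
  interior <- which(diff(sign(diff(g))) < 0) + 1L
  cands <- lapply(interior, function(k) {
    o <- stats::optimize(function(x) -abs(sigmoid_deriv(params, x)),
                         lower = grid[k - 1L], upper = grid[k + 1L],
                         tol = diff(rng) * 1e-12)
    c(x = o$minimum, val = -o$objective)
  })
  cands <- c(cands, list(c(x = rng[1], val = g[1]),
                         c(x = rng[2], val = g[n_grid])))
  vals <- vapply(cands, `[[`, numeric(1), "val")
  bestc <- cands[[which.max(vals)]]
  step <- diff(rng) / (n_grid - 1)
  list(cmc = unname(bestc["x"]),
       boundary = bestc["x"] <= rng[1] + step || bestc["x"] >= rng[2] - step)
}

#' CMC from a fitted sigmoid
#'
#' The CMC is the concentration at which the first derivative of the fitted
#' curve is extremal (maximum for endothermic demicellization, minimum for
#' exothermic — the extremum of `|dq/dC|` covers both). With flat baselines
#' (`a2 = a4`) the extremum is exactly the transition centre `a5`; with
#' sloping baselines it is found from the analytic derivative with a
#' dense-grid bracket plus local refinement. An extremum at the edge of the
#' data range sets the `boundary` flag on the fit (transition not bracketed).
#'
#' @param fit A converged [fit_sigmoid()] result.
#' @return CMC, in the concentration units of the fitted data.
#' @export
cmc_from_fit <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!isTRUE(fit$converged))
    stop("cmc_from_fit requires a converged fit", call. = FALSE)
  fit$cmc
}

#' Demicellization enthalpy from a fitted sigmoid
#'
#' The gap between the two fitted baselines evaluated at the CMC:
#' `(a1 + a2*cmc) - (a3 + a4*cmc)`, i.e. pre-transition minus
#' post-transition. This is the standard demicellization enthalpy; the
#' micellization enthalpy is its negative ([micellization_enthalpy()]).
#'
#' @param fit A converged [fit_sigmoid()] result.
#' @return Demicellization enthalpy, J per mole of surfactant.
#' @export
dH_from_fit <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  p <- as.list(fit$coefficients)
  (p$a1 + p$a2 * fit$cmc) - (p$a3 + p$a4 * fit$cmc)
}
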