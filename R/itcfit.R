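#' Titration protocol for an ITC experiment
#'
#' Geometry and concentrations of a perfusion-cell titration. Units are
#' fixed throughout the module: volumes in microlitres, concentrations in
#' molar, enthalpies in kcal/mol, heats in microcalories.
#'
#' @param v0 Cell volume (uL).
#' @param n_inj Number of injections.
#' @param v_inj Volume per injection (uL).
#' @param syringe_conc Titrant (ligand) concentration in the syringe (M).
#' @param cell_conc Macromolecule concentration in the cell (M).
#' @return List of class `ITCProtocol`.
#' @export
itc_protocol <- function(v0 = 200, n_inj = 19, v_inj = 2,
                         syringe_conc = 200e-6, cell_conc = 200e-6) {
  stopifnot(v0 > 0, n_inj >= 1, v_inj > 0, syringe_conc > 0, cell_conc > 0)
  if (n_inj * v_inj >= v0)
    warning("cumulative injected volume reaches the cell volume; ",
            "displacement corrections become inaccurate")
  structure(list(v0 = v0, n_inj = as.integer(n_inj), v_inj = v_inj,
                 syringe_conc = syringe_conc, cell_conc = cell_conc),
            class = "ITCProtocol")
}

#' Active concentrations after i injections
#'
#' Standard perfusion-cell bookkeeping: each injection displaces cell
#' liquid, so after a cumulative injected volume dV the cell
#' macromolecule is diluted to `M0 (1 - dV/2v0) / (1 + dV/2v0)` and the
#' titrant in the cell reaches `Xsyr (dV/v0) / (1 + dV/2v0)`.
#'
#' @param p An [itc_protocol()].
#' @param i Injection index (0 allowed: the pre-titration state).
#' @return List with `M_t`, `X_t` (molar) and `dilution` = dV/v0.
#' @export
injection_state <- function(p, i) {
  stopifnot(i >= 0, i <= p$n_inj)
  dv <- i * p$v_inj
  half <- dv / (2 * p$v0)
  list(M_t = p$cell_conc * (1 - half) / (1 + half),
       X_t = p$syringe_conc * (dv / p$v0) / (1 + half),
       dilution = dv / p$v0)
}

# Fraction of binding sites occupied: root in [0,1] of the single-site
# quadratic  theta^2 - theta (1 + X/nM + 1/(n Ka M)) + X/nM = 0.
site_occupancy <- function(Ka, n, M_t, X_t) {
  r <- X_t / (n * M_t)
  b <- 1 + r + 1 / (n * Ka * M_t)
  disc <- b^2 - 4 * r
  if (any(disc < 0)) stop("negative discriminant in single-site quadratic")
  (b - sqrt(disc)) / 2
}

#' Simulate single-site injection heats
#'
#' Single-binding-site (Wiseman) isotherm: after injection i, the
#' cumulative heat is `Q_i = n M_t dH v0 theta_i` with theta the occupied
#' site fraction from the single-site quadratic; the heat of injection i
#' is the cumulative difference with the standard displaced-volume
#' correction `q_i = Q_i - Q_(i-1) + (v_inj/v0)(Q_i + Q_(i-1))/2`.
#'
#' @param Ka Association constant (1/M).
#' @param dH Binding enthalpy (kcal/mol).
#' @param n Stoichiometry (fraction of binding-competent macromolecule).
#' @param p An [itc_protocol()].
#' @return Numeric vector of per-injection heats (ucal), length `n_inj`.
#' @export
simulate_isotherm <- function(Ka, dH, n, p) {
  stopifnot(Ka > 0, n > 0)
  Q <- numeric(p$n_inj + 1)            # Q[1] = state before injection 1
  for (i in seq_len(p$n_inj)) {
    st <- injection_state(p, i)
    theta <- site_occupancy(Ka, n, st$M_t, st$X_t)
    # kcal/mol * M * uL -> ucal needs a factor 1e3
    Q[i + 1] <- 1e3 * n * st$M_t * dH * p$v0 * theta
  }
  dQ <- diff(Q)
  Qi <- Q[-1]; Qim1 <- Q[-length(Q)]
  dQ + (p$v_inj / p$v0) * (Qi + Qim1) / 2
}

#' Integrate a thermogram into per-injection heats
#'
#' Subtracts a constant baseline (the median power outside the injection
#' windows) and integrates the power trace over each injection window by
#' the trapezoidal rule.
#'
#' @param time Monotone time grid (s).
#' @param power Differential power (ucal/s), same length as `time`.
#' @param injection_times Start time of each injection (s).
#' @param window Integration window length per injection (s); windows
#'   must not overlap.
#' @return Numeric vector of per-injection heats (ucal).
#' @export
integrate_thermogram <- function(time, power, injection_times, window) {
  stopifnot(length(time) == length(power), !is.unsorted(time), window > 0)
  if (any(diff(injection_times) < window))
    stop("injection windows overlap")
  in_window <- rep(FALSE, length(time))
  for (t0 in injection_times)
    in_window <- in_window | (time >= t0 & time < t0 + window)
  baseline <- stats::median(power[!in_window])
  vapply(injection_times, function(t0) {
    idx <- which(time >= t0 & time <= t0 + window)
    pracma::trapz(time[idx], power[idx] - baseline)
  }, numeric(1))
}

#' Fit the single-site model to injection heats
#'
#' Nonlinear least squares (Levenberg-Marquardt) for (Ka, dH, n) against
#' [simulate_isotherm()] predictions. Ka and n are optimised on the log
#' scale to enforce positivity. Without a user-supplied start the fit is
#' multi-started from a grid of association constants (10^3..10^8 /M) and
#' stoichiometries, with the enthalpy seeded from the observed heats; the
#' best final fit is kept. Nearly-zero heat vectors leave Ka and n
#' unidentifiable: the fit returns `dH = 0` with `converged = FALSE`.
#'
#' @param heats Observed per-injection heats (ucal), length >= 5.
#' @param p An [itc_protocol()].
#' @param init Optional list with `Ka`, `dH`, `n` starting values.
#' @param drop_first Drop injection 1 (common practice for the
#'   first-injection anomaly) from the fitted residuals.
#' @return List of class `ITCFitResult`: `Ka` (1/M), `Kd` (M), `dH`
#'   (kcal/mol), `n`, `residual_sse`, `converged`.
#' @export
fit_single_site <- function(heats, p, init = NULL, drop_first = FALSE) {
  stopifnot(length(heats) == p$n_inj, p$n_inj >= 5)
  use <- if (drop_first) seq_along(heats)[-1] else seq_along(heats)
  scale <- max(abs(heats))
  if (scale < 1e-9)
    return(structure(list(Ka = NA_real_, Kd = NA_real_, dH = 0, n = NA_real_,
                          residual_sse = 0, converged = FALSE),
                     class = "ITCFitResult"))
  resid_fn <- function(par) {
    q <- simulate_isotherm(10^par[1], par[2], exp(par[3]), p)
    q[use] - heats[use]
  }
  # enthalpy scale guess: total heat over the moles that could bind
  moles_lim <- min(p$syringe_conc * p$n_inj * p$v_inj / p$v0, p$cell_conc)
  dh0 <- sum(heats) / (1e3 * moles_lim * p$v0)
  starts <- if (!is.null(init)) {
    list(c(log10(init$Ka), init$dH, log(init$n)))
  } else {
    unlist(lapply(c(3, 4, 5, 6, 7, 8), function(lka)
      lapply(c(0.8, 1.2), function(n0) c(lka, dh0, log(n0)))),
      recursive = FALSE)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = fit$par, sse = sse, info = fit$info)
  }
  if (is.null(best))
    return(structure(list(Ka = NA_real_, Kd = NA_real_, dH = NA_real_,
                          n = NA_real_, residual_sse = Inf,
                          converged = FALSE),
                     class = "ITCFitResult"))
  Ka <- 10^best$par[1]
  structure(list(Ka = Ka, Kd = 1 / Ka, dH = best$par[2],
                 n = exp(best$par[3]), residual_sse = best$sse,
                 converged = best$info %in% 1:3),
            class = "ITCFitResult")
}

#' @export
print.ITCFitResult <- function(x, ...) {
  cat(sprintf(
    "ITC single-site fit: Kd = %.3g M, dH = %.3g kcal/mol, n = %.3g (SSE %.3g%s)\n",
    x$Kd, x$dH, x$n, x$residual_sse,
    if (isTRUE(x$converged)) "" else ", NOT converged"))
  invisible(x)
}
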