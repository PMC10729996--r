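#' Soft-Heaviside logistic regulator
#'
#' One logistic "valve" controlling a rate constant:
#' `k_obs = k_reg / (1 + exp(n ([SP] - [Sen]))) + k_unreg`.
#' At `[Sen] = [SP]` the regulated term is exactly half-maximal. The sign of
#' `n` sets the direction of the response; `k_unreg` is the constitutive
#' (unregulated) part.
#'
#' @param sensor sensed component, one of the 8 model components.
#' @param n sensitivity (signed, dimensionless).
#' @param SP setpoint concentration of the sensor, uM; must satisfy
#'   `0 < SP <= 10000`.
#' @param k_reg,k_unreg regulated and constitutive terms (units of the
#'   regulated rate constant); both must be nonnegative.
#' @param mode `"feedback"` or `"feedforward"` label, established by the
#'   trending rule rather than re-inferred from `n`.
#' @return An object of class `heaviside_regulator`.
#' @export
heaviside_regulator <- function(sensor, n, SP, k_reg, k_unreg = 0,
                                mode = NA_character_) {
  if (!sensor %in% FS_COMPONENTS)
    stop("sensor must be a model component, got: ", sensor)
  if (k_reg < 0 || k_unreg < 0) stop("k_reg and k_unreg must be >= 0")
  if (SP <= 0 || SP > 10000) stop("setpoint must satisfy 0 < SP <= 10000")
  structure(list(sensor = sensor, n = n, SP = SP,
                 k_reg = k_reg, k_unreg = k_unreg, mode = mode),
            class = "heaviside_regulator")
}

#' @export
print.heaviside_regulator <- function(x, ...) {
  cat(sprintf("<heaviside_regulator> Sen=%s n=%g SP=%g k_reg=%g k_unreg=%g %s\n",
              x$sensor, x$n, x$SP, x$k_reg, x$k_unreg,
              if (is.na(x$mode)) "" else x$mode))
  invisible(x)
}

#' Effective rate constant under logistic regulation
#'
#' Overflow-safe evaluation of the logistic valve: for
#' `|n([SP]-[Sen])| > 700` the valve saturates to `k_unreg` or
#' `k_reg + k_unreg` instead of overflowing.
#'
#' @param reg a [heaviside_regulator()].
#' @param sen_conc sensor concentration(s), uM; vectorized.
#' @return Effective rate constant(s).
#' @export
regulated_k <- function(reg, sen_conc) {
  x <- reg$n * (reg$SP - sen_conc)
  out <- ifelse(x > 700, reg$k_unreg,
         ifelse(x < -700, reg$k_reg + reg$k_unreg,
                reg$k_reg / (1 + exp(pmin(pmax(x, -700), 700))) + reg$k_unreg))
  unname(out)
}

## derivative of the effective rate constant w.r.t. the sensor concentration
regulated_k_deriv <- function(reg, sen_conc) {
  x <- reg$n * (reg$SP - sen_conc)
  ifelse(abs(x) > 700, 0, {
    sig <- 1 / (1 + exp(pmin(pmax(x, -700), 700)))
    reg$k_reg * reg$n * exp(x) * sig^2
  })
}

#' Cellular regulatory mechanism (CRM)
#'
#' A complete assignment of logistic regulators to the regulatable reactions
#' (`cyt`, `mit`, `vac`, `cia`, `mp`, `O2`, `23`). Reactions may be left
#' unregulated by omitting them; `isu` (the primary-mutation reaction) and
#' `res` are never regulated.
#'
#' @param regulators named list of [heaviside_regulator()] objects keyed by
#'   reaction id.
#' @param label case label, e.g. `"case1"`.
#' @return An object of class `crm`.
#' @export
crm <- function(regulators = list(), label = "custom") {
  bad <- setdiff(names(regulators), FS_REGULATABLE)
  if (length(bad))
    stop("not regulatable reaction(s): ", paste(bad, collapse = ", "))
  ok <- vapply(regulators, inherits, logical(1), "heaviside_regulator")
  if (length(regulators) && !all(ok))
    stop("all regulators must be heaviside_regulator objects")
  structure(list(regulators = regulators, label = label), class = "crm")
}

#' @export
print.crm <- function(x, ...) {
  cat("<crm>", x$label, "-", length(x$regulators), "regulated reaction(s)\n")
  for (id in names(x$regulators)) {
    r <- x$regulators[[id]]
    cat(sprintf("  k_%-3s <- %-3s (n=%g, SP=%g, k_reg=%g, k_unreg=%g, %s)\n",
                id, r$sensor, r$n, r$SP, r$k_reg, r$k_unreg,
                if (is.na(r$mode)) "?" else r$mode))
  }
  invisible(x)
}

#' Apply a CRM at given sensor concentrations
#'
#' Replaces each regulated rate constant in `base` with the effective value
#' of its logistic valve at the current sensor concentrations; unregulated
#' reactions are untouched.
#'
#' @param crm a [crm()].
#' @param base `cell_state_params` supplying the unregulated constants.
#' @param conc concentration profile providing the sensor concentrations.
#' @return `cell_state_params` with effective rate constants.
#' @export
apply_crm <- function(crm, base, conc) {
  for (id in names(crm$regulators)) {
    reg <- crm$regulators[[id]]
    if (!reg$sensor %in% names(conc))
      stop("sensor ", reg$sensor, " not present in the concentration profile")
    base$k[[id]] <- regulated_k(reg, conc[[reg$sensor]])
  }
  base
}

#' Fit a logistic regulator to per-state (sensor, rate-constant) points
#'
#' Least-squares fit of `(n, SP, k_reg, k_unreg)` to the three
#' (sensor concentration, observed rate constant) pairs of the W/Y/D states,
#' subject to `0 < SP <= 10000` and `k_reg, k_unreg >= 0`. With four
#' parameters and three points the parameters are not unique; the contract
#' is curve-level agreement at the three abscissae. The fit uses a
#' deterministic multi-start Levenberg-Marquardt schedule; among converged
#' starts the smallest residual wins, with ties broken by smallest `|n|`
#' and then by `SP` closest to the mean sensor concentration.
#'
#' @param sen_conc numeric(3): sensor concentrations.
#' @param k_obs numeric(3): observed rate constants.
#' @param sp_max upper bound on the setpoint (default 10000 uM).
#' @param rel_tol maximum relative residual at any of the three points for
#'   the fit to be declared successful.
#' @return A [heaviside_regulator()] with attributes `residual` (sum of
#'   squares) and `ok` (logical), or `NULL` when no start converges.
#' @export
fit_regulator <- function(sen_conc, k_obs, sp_max = 10000, rel_tol = 0.01) {
  stopifnot(length(sen_conc) == 3, length(k_obs) == 3)
  if (length(unique(sen_conc)) < 3)
    stop("sensor concentrations must be distinct")
  if (diff(range(k_obs)) == 0) {
    ## three identical constants: nothing to regulate
    reg <- heaviside_regulator(FS_COMPONENTS[1], n = 0.001,
                               SP = mean(sen_conc), k_reg = 0,
                               k_unreg = k_obs[1])
    attr(reg, "residual") <- 0
    attr(reg, "ok") <- FALSE
    attr(reg, "degenerate") <- TRUE
    return(reg)
  }

  smin <- min(sen_conc); smax <- max(sen_conc); smean <- mean(sen_conc)
  span <- smax - smin
  ## direction: k increasing with sensor needs n > 0 under the
  ## exp(n(SP - Sen)) convention
  slope <- stats::coef(stats::lm(k_obs ~ sen_conc))[2]
  sgn <- if (slope >= 0) 1 else -1

  ## three relative data residuals (the success contract is relative, and the
  ## observed constants can span two orders of magnitude) plus two vanishingly
  ## weighted pulls toward small |n| and SP near the mean sensor
  ## concentration: they make the 4-parameter / 3-point problem well-posed
  ## and encode the tie-break preference continuously without perturbing the
  ## curve fit
  kscale <- pmax(abs(k_obs), .Machine$double.eps)
  resid_fn <- function(p) {
    pred <- p[3] / (1 + exp(pmin(pmax(p[1] * (p[2] - sen_conc), -700), 700))) + p[4]
    c((pred - k_obs) / kscale, 1e-6 * p[1] * span, 1e-8 * (p[2] - smean) / span)
  }
  lower <- c(-Inf, 1e-9, 0, 0)
  upper <- c(Inf, sp_max, Inf, Inf)

  ## sensitivity starts scaled both by the full sensor span and by the
  ## smallest adjacent gap (the informative scale when one state lies far
  ## from the other two)
  min_gap <- min(diff(sort(sen_conc)))
  n_starts  <- sgn * unique(c(c(0.2, 0.5, 1, 2, 5, 20) / span,
                              c(0.5, 1, 2, 5) / min_gap))
  sp_starts <- unique(c(smin, smean, smax, sqrt(smin * smax)))
  kr_starts <- c(diff(range(k_obs)), 2 * diff(range(k_obs)), max(k_obs))
  ku_starts <- c(0, min(k_obs))

  best <- NULL
  for (n0 in n_starts) for (sp0 in sp_starts)
    for (kr0 in kr_starts) for (ku0 in ku_starts) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = c(n0, sp0, kr0, ku0), lower = lower,
                           upper = upper, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
        error = function(e) NULL)
      if (is.null(fit)) next
      ss <- sum(resid_fn(fit$par)^2)
      cand <- list(par = fit$par, ss = ss)
      if (is.null(best)) { best <- cand; next }
      if (ss < best$ss - 1e-18 * (1 + best$ss)) { best <- cand; next }
      if (abs(ss - best$ss) <= 1e-12 * (1 + best$ss)) {
        if (abs(cand$par[1]) < abs(best$par[1]) - 1e-12) best <- cand
        else if (abs(abs(cand$par[1]) - abs(best$par[1])) <= 1e-12 &&
                 abs(cand$par[2] - smean) < abs(best$par[2] - smean))
          best <- cand
      }
    }
  if (is.null(best)) return(NULL)

  p <- best$par
  reg <- heaviside_regulator(FS_COMPONENTS[1], n = p[1], SP = p[2],
                             k_reg = p[3], k_unreg = p[4])
  pred <- regulated_k(reg, sen_conc)
  relerr <- abs(pred - k_obs) / pmax(abs(k_obs), .Machine$double.eps)
  attr(reg, "residual") <- best$ss
  attr(reg, "ok") <- all(relerr <= rel_tol)
  attr(reg, "degenerate") <- FALSE
  reg
}
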