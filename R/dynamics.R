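## Time integration and cell-state transitions.
##
## The stiff integrator (lsoda) drives a compiled right-hand side; the pure-R
## ode_rhs() is the readable reference implementation and the two are held
## together by tests. Steady states are defined operationally as the
## concentrations attained at t = 50,000 min.

FS_T_STEADY <- 50000

## effective rate constants along a trace (columns of sensor concentrations)
.effective_k <- function(df, params, crm) {
  out <- matrix(rep(params$k[FS_REGULATABLE], each = nrow(df)),
                nrow = nrow(df),
                dimnames = list(NULL, paste0("k_", FS_REGULATABLE)))
  if (!is.null(crm)) {
    for (id in names(crm$regulators)) {
      reg <- crm$regulators[[id]]
      out[, paste0("k_", id)] <- regulated_k(reg, df[[reg$sensor]])
    }
  }
  out
}

.as_trace <- function(df, mode = "time", params = NULL, crm = NULL,
                      with_k = TRUE, param_name = NULL) {
  if (with_k && !is.null(params))
    df <- cbind(df, as.data.frame(.effective_k(df, params, crm)))
  structure(df, class = c("transition_trace", "data.frame"),
            mode = mode, param_name = param_name)
}

#' @export
print.transition_trace <- function(x, ...) {
  cat("<transition_trace>", nrow(x), "points,",
      attr(x, "mode"), "mode\n")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

## single lsoda run against the compiled RHS; returns the deSolve matrix
.lsoda_raw <- function(params, init, times, crm = NULL,
                       rtol = 1e-8, atol = 1e-6) {
  y <- init[FS_COMPONENTS]
  out <- deSolve::lsoda(y = y, times = times, func = "ferrosim_derivs",
                        parms = pack_parms(params, crm),
                        dllname = "ferrosim", initfunc = "ferrosim_initmod",
                        rtol = rtol, atol = atol, maxsteps = 200000)
  if (nrow(out) < length(times)) {
    stop("integration failed at t = ", out[nrow(out), 1],
         " min (requested ", times[length(times)], " min)")
  }
  out
}

#' Integrate the kinetic model
#'
#' Stiff integration of the iron-trafficking ODE system, optionally under a
#' CRM whose logistic valves recompute the regulated rate constants from the
#' instantaneous sensor concentrations at every step.
#'
#' @param params `cell_state_params`.
#' @param init initial concentration profile.
#' @param t_end end time, min. `t_end = 0` returns the initial profile.
#' @param crm optional [crm()].
#' @param times output time grid; default `c(0, t_end)` (endpoint runs) or a
#'   dense grid when `n_out` is given.
#' @param n_out number of output points when `times` is `NULL`.
#' @param rtol,atol integrator tolerances.
#' @param with_k include effective rate-constant columns in the trace.
#' @return A `transition_trace` data frame: `time`, the 8 components, and
#'   (optionally) the 7 effective rate constants.
#' @export
integrate_model <- function(params, init, t_end = FS_T_STEADY, crm = NULL,
                            times = NULL, n_out = 2, rtol = 1e-8, atol = 1e-6,
                            with_k = TRUE) {
  init <- concentration_profile(init)
  if (t_end < 0) stop("t_end must be >= 0")
  if (t_end == 0) {
    df <- data.frame(time = 0, as.list(init))
    return(.as_trace(df, "time", params, crm, with_k))
  }
  if (is.null(times)) times <- seq(0, t_end, length.out = max(2, n_out))
  out <- .lsoda_raw(params, init, times, crm, rtol, atol)
  df <- as.data.frame(out)
  names(df) <- c("time", FS_COMPONENTS)
  .as_trace(df, "time", params, crm, with_k)
}

#' Steady state by long integration
#'
#' The operational steady state: the profile attained after integrating for
#' `t_end` (default 50,000 min).
#'
#' @inheritParams integrate_model
#' @return Named concentration profile.
#' @export
steady_state <- function(params, init, crm = NULL, t_end = FS_T_STEADY,
                         rtol = 1e-8, atol = 1e-6) {
  out <- .lsoda_raw(params, concentration_profile(init), c(0, t_end), crm,
                    rtol, atol)
  ## integrator noise can leave decayed components a hair below zero
  setNames(pmax(out[nrow(out), 1 + seq_along(FS_COMPONENTS)], 0),
           FS_COMPONENTS)
}

#' Growth rate along the W-to-Y transition
#'
#' Linear coupling of the growth rate to the ISC-assembly rate constant,
#' through the points (6.666, 0.003333) and (0.6666, 0.002): as the primary
#' mutation lowers `k_isu` ten-fold, the growth rate falls with it.
#'
#' @param k_isu ISC-assembly rate constant(s), 1/min.
#' @param k_W,alpha_W,k_Y,alpha_Y anchor points of the line.
#' @return Growth rate(s) alpha_cell, 1/min. Extrapolation beyond
#'   `[k_Y, k_W]` is permitted with a warning.
#' @export
alpha_of_kisu <- function(k_isu, k_W = 6.666, alpha_W = 0.003333,
                          k_Y = 0.6666, alpha_Y = 0.002) {
  if (any(k_isu > max(k_W, k_Y) + 1e-12) || any(k_isu < min(k_W, k_Y) - 1e-12))
    warning("k_isu outside [", min(k_W, k_Y), ", ", max(k_W, k_Y),
            "]; extrapolating the linear coupling")
  slope <- (alpha_W - alpha_Y) / (k_W - k_Y)
  slope * k_isu + (alpha_Y * k_W - alpha_W * k_Y) / (k_W - k_Y)
}

## apply a trigger (partial parameter override) to a state
.apply_trigger <- function(params, trigger) {
  for (nm in names(trigger)) {
    val <- trigger[[nm]]
    switch(nm,
           k_isu  = { params$k[["isu"]] <- val },
           alpha  = { params$alpha <- val },
           IRON   = { params$IRON <- val },
           OXYGEN = { params$OXYGEN <- val },
           { # any named rate constant, e.g. "k_cyt"
             id <- sub("^k_", "", nm)
             if (!id %in% FS_REACTIONS) stop("unknown trigger parameter: ", nm)
             params$k[[id]] <- val
           })
  }
  params
}

#' Time-dependent cell-state transition
#'
#' Abruptly switches the trigger parameters at `t0` (primary mutation of
#' `k_isu` with its coupled growth rate, or a change in external `IRON` or
#' `OXYGEN`) and integrates onward, optionally under a CRM. Reverse
#' transitions and hypoxia shifts use the same machinery.
#'
#' @param params starting state's `cell_state_params`.
#' @param init starting profile (normally the starting state's steady state).
#' @param trigger named list of parameter overrides applied at `t0`: any of
#'   `k_isu`, `alpha`, `IRON`, `OXYGEN`, or `k_<reaction>`.
#' @param crm optional [crm()].
#' @param t0 trigger time, min.
#' @param t_end end time, min.
#' @param n_out output points after the trigger.
#' @param with_k include effective rate-constant columns.
#' @inheritParams integrate_model
#' @return `transition_trace`.
#' @export
time_transition <- function(params, init, trigger = list(), crm = NULL,
                            t0 = 0, t_end = FS_T_STEADY, n_out = 2,
                            times = NULL, rtol = 1e-8, atol = 1e-6,
                            with_k = TRUE) {
  init <- concentration_profile(init)
  post <- .apply_trigger(params, trigger)
  pre_df <- NULL
  if (t0 > 0) {
    pre <- integrate_model(params, init, t_end = t0, crm = crm,
                           n_out = max(2, ceiling(n_out * t0 / t_end)),
                           rtol = rtol, atol = atol, with_k = FALSE)
    init <- setNames(as.numeric(pre[nrow(pre), FS_COMPONENTS]), FS_COMPONENTS)
    pre_df <- as.data.frame(pre)[-nrow(pre), ]
  }
  if (is.null(times)) times <- seq(t0, t_end, length.out = max(2, n_out))
  out <- .lsoda_raw(post, init, times, crm, rtol, atol)
  df <- as.data.frame(out)
  names(df) <- c("time", FS_COMPONENTS)
  if (!is.null(pre_df)) df <- rbind(pre_df, df)
  .as_trace(df, "time", post, crm, with_k)
}

#' Steady-state (incremental) cell-state transition
#'
#' Moves the trigger parameters linearly over `n_increments` steps and lets
#' the system settle (50,000 min) at each increment. When `k_isu` is among
#' the triggers, the growth rate follows [alpha_of_kisu()] at every increment
#' unless `alpha` is supplied explicitly. Increments are warm-started from
#' the previous increment's endpoint by default; `warm_start = FALSE`
#' restarts each increment from `init`.
#'
#' @param params starting state's `cell_state_params`.
#' @param init starting profile.
#' @param to named list of trigger targets (`k_isu`, `IRON`, `OXYGEN`, ...).
#' @param crm optional [crm()].
#' @param n_increments number of increments (>= 2), including both endpoints.
#' @param t_per settling time per increment, min.
#' @param warm_start warm-start each increment from the previous endpoint.
#' @param conv_tol relative residual `max |C'|/C` above which an increment is
#'   flagged non-converged.
#' @inheritParams integrate_model
#' @return `transition_trace` in increment mode: `increment`, the moving
#'   parameter value(s), the 8 components, effective rate constants, plus a
#'   `converged` attribute (logical per increment).
#' @export
steady_state_transition <- function(params, init, to, crm = NULL,
                                    n_increments = 100, t_per = FS_T_STEADY,
                                    warm_start = TRUE, rtol = 1e-8,
                                    atol = 1e-6, conv_tol = 1e-4,
                                    with_k = TRUE) {
  if (n_increments < 2) stop("n_increments must be >= 2")
  init <- concentration_profile(init)
  couple_alpha <- ("k_isu" %in% names(to)) && !("alpha" %in% names(to))
  start <- list(k_isu = params$k[["isu"]], alpha = params$alpha,
                IRON = params$IRON, OXYGEN = params$OXYGEN)
  grids <- lapply(names(to), function(nm)
    seq(start[[nm]], to[[nm]], length.out = n_increments))
  names(grids) <- names(to)
  prof <- init
  rows <- vector("list", n_increments)
  converged <- logical(n_increments)
  for (j in seq_len(n_increments)) {
    trig <- lapply(grids, `[[`, j)
    if (couple_alpha)
      trig$alpha <- suppressWarnings(alpha_of_kisu(trig$k_isu))
    pj <- .apply_trigger(params, trig)
    from <- if (warm_start) prof else init
    prof <- steady_state(pj, from, crm = crm, t_end = t_per,
                         rtol = rtol, atol = atol)
    rhs <- ode_rhs(prof, pj, crm)
    converged[j] <- max(abs(rhs) / pmax(prof, 1e-8)) < conv_tol
    rows[[j]] <- c(increment = j, unlist(trig), prof)
  }
  df <- as.data.frame(do.call(rbind, rows))
  tr <- .as_trace(df, "increment", params, crm, with_k,
                  param_name = names(to)[1])
  attr(tr, "converged") <- converged
  tr
}

#' Perturb one component and follow the recovery
#'
#' Multiplies a single concentration by `factor` at `t_perturb` and
#' integrates onward. Recovery time is the first time after the perturbation
#' at which every component is back within `threshold` (relative) of the
#' reference steady state.
#'
#' @param params `cell_state_params`.
#' @param init steady-state profile to perturb.
#' @param component component to perturb.
#' @param factor multiplicative perturbation (> 0).
#' @param crm optional [crm()].
#' @param t_perturb perturbation time, min.
#' @param t_end end time, min.
#' @param threshold relative recovery threshold (default 1%).
#' @param dt output grid spacing, min.
#' @inheritParams integrate_model
#' @return `transition_trace` with attribute `recovery_time` (min, `NA` if
#'   not recovered by `t_end`).
#' @export
perturb_recover <- function(params, init, component, factor, crm = NULL,
                            t_perturb = 400, t_end = FS_T_STEADY,
                            threshold = 0.01, dt = 10,
                            rtol = 1e-8, atol = 1e-6) {
  if (factor <= 0) stop("factor must be > 0")
  if (!component %in% FS_COMPONENTS) stop("unknown component: ", component)
  init <- concentration_profile(init)
  t1 <- seq(0, t_perturb, by = dt)
  if (t1[length(t1)] < t_perturb) t1 <- c(t1, t_perturb)
  out1 <- .lsoda_raw(params, init, t1, crm, rtol, atol)
  prof <- setNames(out1[nrow(out1), -1], FS_COMPONENTS)
  prof[component] <- prof[component] * factor
  t2 <- seq(t_perturb, t_end, by = dt)
  if (t2[length(t2)] < t_end) t2 <- c(t2, t_end)
  out2 <- .lsoda_raw(params, prof, t2, crm, rtol, atol)
  df <- as.data.frame(rbind(out1[-nrow(out1), ], out2))
  names(df) <- c("time", FS_COMPONENTS)
  rel <- sweep(abs(sweep(as.matrix(df[FS_COMPONENTS]), 2, init)), 2,
               pmax(init, 1e-12), "/")
  post <- df$time > t_perturb
  ok <- post & apply(rel <= threshold, 1, all)
  rec <- if (any(ok)) min(df$time[ok]) - t_perturb else NA_real_
  tr <- .as_trace(df, "time", params, crm, with_k = TRUE)
  attr(tr, "recovery_time") <- rec
  tr
}
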