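#' Analytic Jacobian of the ODE system
#'
#' Partial derivatives of the eight right-hand-side functions with respect to
#' each component, evaluated at a concentration profile. When a CRM is
#' supplied, the chain-rule terms through the logistic valves (rate constant
#' as a function of the sensor concentration) are included.
#'
#' @param params `cell_state_params`.
#' @param conc concentration profile (assumed strictly positive).
#' @param crm optional [crm()].
#' @return 8 x 8 matrix with component dimnames.
#' @export
jacobian_matrix <- function(params, conc, crm = NULL) {
  conc <- concentration_profile(conc)
  eff <- if (is.null(crm)) params else apply_crm(crm, params, conc)
  k <- eff$k; Km <- eff$Km
  sp <- eff$O2_sp
  mm  <- function(x, K) x / (K + x)
  dmm <- function(x, K) K / (K + x)^2

  ## substrate-dependent part phi of each rate law and its gradient
  phi <- c(cyt = mm(eff$IRON, Km[["cyt"]]),
           mit = mm(conc[["FC"]], Km[["mit"]]),
           vac = mm(conc[["FC"]], Km[["vac"]]),
           cia = mm(conc[["FC"]], Km[["cia"]]),
           isu = mm(conc[["FM"]], Km[["isu"]]) * sp / (sp + conc[["O2"]]),
           mp  = conc[["FM"]] * conc[["O2"]],
           O2  = eff$OXYGEN - conc[["O2"]],
           res = conc[["FS"]] * mm(conc[["O2"]], Km[["res"]]),
           `23` = mm(conc[["F2"]], Km[["23"]]) * eff$OXYGEN)

  dphi <- matrix(0, 9, 8, dimnames = list(FS_REACTIONS, FS_COMPONENTS))
  dphi["mit", "FC"] <- dmm(conc[["FC"]], Km[["mit"]])
  dphi["vac", "FC"] <- dmm(conc[["FC"]], Km[["vac"]])
  dphi["cia", "FC"] <- dmm(conc[["FC"]], Km[["cia"]])
  dphi["isu", "FM"] <- dmm(conc[["FM"]], Km[["isu"]]) * sp / (sp + conc[["O2"]])
  dphi["isu", "O2"] <- -mm(conc[["FM"]], Km[["isu"]]) * sp / (sp + conc[["O2"]])^2
  dphi["mp", "FM"]  <- conc[["O2"]]
  dphi["mp", "O2"]  <- conc[["FM"]]
  dphi["O2", "O2"]  <- -1
  dphi["res", "FS"] <- mm(conc[["O2"]], Km[["res"]])
  dphi["res", "O2"] <- conc[["FS"]] * dmm(conc[["O2"]], Km[["res"]])
  dphi["23", "F2"]  <- dmm(conc[["F2"]], Km[["23"]]) * eff$OXYGEN

  ## dR/dC = k * dphi + (dk/dSen) * phi on the sensor column
  dR <- k[FS_REACTIONS] * dphi
  if (!is.null(crm)) {
    for (id in names(crm$regulators)) {
      reg <- crm$regulators[[id]]
      dR[id, reg$sensor] <- dR[id, reg$sensor] +
        regulated_k_deriv(reg, conc[[reg$sensor]]) * phi[[id]]
    }
  }
  S <- stoichiometric_matrix(reaction_network(eff$layout))
  ## reaction columns of S, matched to the row order of dR
  Sr <- S[, c("R_cyt", "R_mit", "R_vac", "R_cia", "R_isu", "R_mp",
              "R_O2", "R_res", "R_23")]
  J <- Sr %*% dR[c("cyt", "mit", "vac", "cia", "isu", "mp", "O2", "res", "23"), ] -
    diag(eff$alpha, 8)
  dimnames(J) <- list(FS_COMPONENTS, FS_COMPONENTS)
  J
}

#' Eigenvalue stability report
#'
#' Full spectrum of a Jacobian with stability classification: the state is
#' stable to limited perturbations iff every eigenvalue has a negative real
#' part. Eigenvalues are ordered by decreasing magnitude and each is
#' associated with the component dominating its eigenvector.
#'
#' @param J square matrix, or `NULL` to build it from the remaining
#'   arguments.
#' @param params,conc,crm used when `J` is `NULL`; see [jacobian_matrix()].
#' @return An object of class `stability_report`: `jacobian`, `values`
#'   (complex, sorted by decreasing magnitude), `dominant` (component
#'   labels), `stable`, `max_re`.
#' @export
stability_report <- function(J = NULL, params = NULL, conc = NULL, crm = NULL) {
  if (is.null(J)) J <- jacobian_matrix(params, conc, crm)
  if (nrow(J) != ncol(J)) stop("J must be square")
  e <- eigen(J)
  ord <- order(Mod(e$values), decreasing = TRUE)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  dominant <- if (!is.null(rownames(J)))
    rownames(J)[apply(Mod(vecs), 2, which.max)] else rep(NA_character_, length(vals))
  structure(list(jacobian = J, values = vals, dominant = dominant,
                 stable = all(Re(vals) < 0), max_re = max(Re(vals))),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>", if (x$stable) "STABLE" else "UNSTABLE",
      sprintf("(max Re = %.6g)\n", x$max_re))
  df <- data.frame(eigenvalue = format(x$values, digits = 6),
                   dominant = x$dominant)
  print(df, row.names = FALSE)
  invisible(x)
}

## scale a rate constant (and, when regulated, its whole valve) by h
.scale_k <- function(params, crm, k_name, h) {
  id <- sub("^k_", "", k_name)
  if (!id %in% FS_REACTIONS) stop("unknown rate constant: ", k_name)
  params$k[[id]] <- params$k[[id]] * h
  if (!is.null(crm) && id %in% names(crm$regulators)) {
    crm$regulators[[id]]$k_reg <- crm$regulators[[id]]$k_reg * h
    crm$regulators[[id]]$k_unreg <- crm$regulators[[id]]$k_unreg * h
  }
  list(params = params, crm = crm)
}

#' Local sensitivity of the steady state to one rate constant
#'
#' Scales the rate constant (including its regulated term, when a CRM is
#' active) by a factor `h`, locates the steady state at each stencil node by
#' the 50,000-min settling convention, expresses each component's response as
#' the percent change `G_i(h)`, and returns the mean over components of the
#' absolute five-point-stencil derivative of `G_i` at `h = 1`:
#' `score = (1/8) sum_i |(G_i(1-2j) - 8 G_i(1-j) + 8 G_i(1+j) - G_i(1+2j)) / (12 j)|`.
#'
#' `stencil = "as_printed"` instead uses a `+G(h+2j)` final term and
#' multiplies each summand by the steady-state concentration; it is provided
#' for comparison only.
#'
#' @param params `cell_state_params` at its steady state.
#' @param conc steady-state profile.
#' @param k_name rate constant to jiggle (e.g. `"k_O2"` or `"O2"`).
#' @param crm optional [crm()].
#' @param j stencil step for the scale factor h.
#' @param t_ss settling time per stencil node, min.
#' @param stencil `"standard"` or `"as_printed"`.
#' @return Sensitivity score (percent units); `Inf` if a stencil node loses
#'   its steady state (component diverging or vanishing).
#' @export
sensitivity_of_k <- function(params, conc, k_name, crm = NULL, j = 0.01,
                             t_ss = FS_T_STEADY, stencil = c("standard", "as_printed")) {
  stencil <- match.arg(stencil)
  conc <- concentration_profile(conc)
  base <- steady_state(params, conc, crm, t_end = t_ss)
  G <- function(h) {
    sc <- .scale_k(params, crm, k_name, h)
    ss <- tryCatch(steady_state(sc$params, base, sc$crm, t_end = t_ss),
                   error = function(e) rep(NA_real_, 8))
    ## a component absent at baseline (base ~ 0) contributes no percent change
    100 * (ss - base) / pmax(base, 1e-9)
  }
  hs <- 1 + j * c(-2, -1, 1, 2)
  Gm <- vapply(hs, G, numeric(8))
  if (any(!is.finite(Gm))) return(Inf)
  d <- if (stencil == "standard")
    (Gm[, 1] - 8 * Gm[, 2] + 8 * Gm[, 3] - Gm[, 4]) / (12 * j)
  else
    (Gm[, 1] - 8 * Gm[, 2] + 8 * Gm[, 3] + Gm[, 4]) / (12 * j) * base
  mean(abs(d))
}

#' Sensitivity table over the regulatable rate constants
#'
#' @inheritParams sensitivity_of_k
#' @param k_names rate constants to score (default: the 7 regulatable ones).
#' @return Named numeric vector of sensitivity scores, sorted decreasing.
#' @export
sensitivity_table <- function(params, conc, crm = NULL,
                              k_names = paste0("k_", FS_REGULATABLE),
                              j = 0.01, t_ss = FS_T_STEADY) {
  scores <- vapply(k_names, function(kn)
    sensitivity_of_k(params, conc, kn, crm = crm, j = j, t_ss = t_ss),
    numeric(1))
  sort(scores, decreasing = TRUE)
}
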