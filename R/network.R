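#' @useDynLib ferrosim
#' @importFrom stats setNames
NULL

## Canonical orderings. Components follow the ODE system; rates follow the
## column order of the stoichiometric matrix (eight dependent reaction rates
## first, then the respiration rate and the eight dilution rates).
FS_COMPONENTS <- c("FC", "CIA", "F2", "F3", "FM", "FS", "MP", "O2")
FS_REACTIONS  <- c("cyt", "mit", "vac", "cia", "isu", "mp", "O2", "res", "23")
FS_RATE_COLS  <- c("R_cyt", "R_mit", "R_vac", "R_cia", "R_isu", "R_mp",
                   "R_O2", "R_23", "R_res",
                   paste0("D_", FS_COMPONENTS))
FS_KM_NAMES   <- c("cyt", "mit", "vac", "cia", "23", "isu", "res")
## Reactions whose rate constant may be placed under logistic control
FS_REGULATABLE <- c("cyt", "mit", "vac", "cia", "mp", "O2", "23")

#' Compartment layout of the in-silico cell
#'
#' Fractional volumes of the three cellular regions. The bundled yeast model
#' uses 0.8 (cytosol), 0.1 (mitochondria) and 0.1 (vacuole); interregional
#' reactions are scaled by the ratios `f_cyt/f_mit` and `f_cyt/f_vac` so that
#' mass is conserved when material crosses region boundaries.
#'
#' @param f_cyt,f_mit,f_vac fractional volumes; must be positive and sum to 1.
#' @return An object of class `compartment_layout`.
#' @export
compartment_layout <- function(f_cyt = 0.8, f_mit = 0.1, f_vac = 0.1) {
  f <- c(f_cyt = f_cyt, f_mit = f_mit, f_vac = f_vac)
  if (any(f <= 0)) stop("all fractional volumes must be strictly positive")
  if (abs(sum(f) - 1) > 1e-12)
    stop("fractional volumes must sum to 1 (got ", format(sum(f), digits = 15), ")")
  structure(as.list(f), class = "compartment_layout")
}

#' Local concentration profile
#'
#' A named vector of the eight component concentrations (uM, local to each
#' component's compartment), validated for completeness and nonnegativity.
#'
#' @param ... either a single named vector or named scalar arguments, one per
#'   component (`FC`, `CIA`, `F2`, `F3`, `FM`, `FS`, `MP`, `O2`).
#' @return Named numeric vector in canonical component order.
#' @export
concentration_profile <- function(...) {
  args <- list(...)
  x <- if (length(args) == 1L && length(args[[1L]]) > 1L) args[[1L]] else unlist(args)
  if (!all(FS_COMPONENTS %in% names(x)))
    stop("missing components: ",
         paste(setdiff(FS_COMPONENTS, names(x)), collapse = ", "))
  x <- as.numeric(x[FS_COMPONENTS])
  names(x) <- FS_COMPONENTS
  if (any(!is.finite(x))) stop("non-finite concentration")
  if (any(x < 0)) stop("negative concentration: ",
                       paste(FS_COMPONENTS[x < 0], collapse = ", "))
  x
}

#' Whole-cell iron concentration
#'
#' Volume-weighted sum of the seven iron-containing components:
#' `f_cyt([CIA]+[FC]) + f_vac([F2]+[F3]) + f_mit([FM]+[FS]+[MP])`.
#'
#' @param conc concentration profile (see [concentration_profile()]).
#' @param layout compartment layout.
#' @return Whole-cell iron in uM.
#' @export
fe_cell <- function(conc, layout = compartment_layout()) {
  unname(layout$f_cyt * (conc[["CIA"]] + conc[["FC"]]) +
         layout$f_vac * (conc[["F2"]] + conc[["F3"]]) +
         layout$f_mit * (conc[["FM"]] + conc[["FS"]] + conc[["MP"]]))
}

#' Kinetic parameterization of one cellular state
#'
#' Bundles everything needed to evaluate the rate laws for one cellular
#' state: nine rate constants, seven Michaelis constants, the O2-inhibition
#' setpoint of the ISC-assembly reaction, the exponential growth rate, and
#' the external nutrient concentrations.
#'
#' @param k named vector of the 9 rate constants
#'   (`cyt`, `mit`, `vac`, `cia`, `isu`, `mp`, `O2`, `res`, `23`); units are
#'   dictated by the corresponding rate law.
#' @param Km named vector of the 7 Michaelis constants
#'   (`cyt`, `mit`, `vac`, `cia`, `23`, `isu`, `res`), uM.
#' @param O2_sp O2-inhibition setpoint of the ISC assembly reaction, uM.
#' @param alpha exponential growth rate of the cell, 1/min.
#' @param IRON,OXYGEN external nutrient concentrations, uM.
#' @param label state label (e.g. `"W"`, `"Y"`, `"D"`).
#' @param layout compartment layout.
#' @return An object of class `cell_state_params`.
#' @export
cell_state_params <- function(k, Km, O2_sp = 1, alpha = 0.003333,
                              IRON = 40, OXYGEN = 100, label = "custom",
                              layout = compartment_layout()) {
  if (!all(FS_REACTIONS %in% names(k)))
    stop("missing rate constants: ",
         paste(setdiff(FS_REACTIONS, names(k)), collapse = ", "))
  if (!all(FS_KM_NAMES %in% names(Km)))
    stop("missing Km values: ",
         paste(setdiff(FS_KM_NAMES, names(Km)), collapse = ", "))
  k  <- setNames(as.numeric(k[FS_REACTIONS]), FS_REACTIONS)
  Km <- setNames(as.numeric(Km[FS_KM_NAMES]), FS_KM_NAMES)
  stopifnot(all(is.finite(k)), all(is.finite(Km)))
  if (any(k < 0) || any(Km < 0) || alpha < 0 || IRON < 0 || OXYGEN < 0)
    stop("rate constants, Km values, growth rate and externals must be >= 0")
  if (O2_sp <= 0) stop("[O2]_sp must be > 0")
  structure(list(k = k, Km = Km, O2_sp = O2_sp, alpha = alpha,
                 IRON = IRON, OXYGEN = OXYGEN, label = label,
                 layout = layout),
            class = "cell_state_params")
}

#' @export
print.cell_state_params <- function(x, ...) {
  cat("<cell_state_params> state", x$label,
      sprintf("(alpha = %g /min, IRON = %g uM, OXYGEN = %g uM)\n",
              x$alpha, x$IRON, x$OXYGEN))
  print(signif(x$k, 7))
  invisible(x)
}

#' The bundled iron-trafficking reaction network
#'
#' Nine reactions over eight components in three compartments. Rate-law kinds
#' are recorded per reaction; the stoichiometry (including the interregional
#' volume-ratio factors) is available via [stoichiometric_matrix()].
#'
#' @param layout compartment layout.
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(layout = compartment_layout()) {
  reactions <- data.frame(
    id = FS_REACTIONS,
    equation = c("IRON -> FC", "FC -> FM", "FC -> F2", "FC -> CIA",
                 "FM -> FS", "FM + O2 -> MP", "OXYGEN -> O2",
                 "O2 ->", "F2 -> F3"),
    kind = c("saturating_import", "saturating_transfer", "saturating_transfer",
             "saturating_transfer", "saturating_o2_inhibited", "bilinear",
             "linear_exchange", "saturating_catalytic", "saturating_external"),
    region = c("E,C", "C,M", "C,V", "C", "M", "M", "E,M", "M", "V"),
    stringsAsFactors = FALSE
  )
  structure(list(reactions = reactions, components = FS_COMPONENTS,
                 layout = layout),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network>", nrow(x$reactions), "reactions,",
      length(x$components), "components\n")
  print(x$reactions, row.names = FALSE)
  invisible(x)
}

#' Evaluate one reaction rate
#'
#' Evaluates the rate-law expression for a single reaction at the given
#' concentrations. Rates are local to the reaction's source region (uM/min).
#' All rates are nonnegative except the net oxygen exchange
#' `R_O2 = k_O2 (OXYGEN - [O2])`, which is signed.
#'
#' @param reaction_id one of `"cyt"`, `"mit"`, `"vac"`, `"cia"`, `"isu"`,
#'   `"mp"`, `"O2"`, `"res"`, `"23"`.
#' @param conc concentration profile.
#' @param params `cell_state_params`.
#' @return Scalar rate in uM/min.
#' @export
reaction_rate <- function(reaction_id, conc, params) {
  if (!reaction_id %in% FS_REACTIONS)
    stop("unknown reaction id: ", reaction_id)
  reaction_rates(conc, params)[[reaction_id]]
}

#' Evaluate all nine reaction rates
#'
#' @inheritParams reaction_rate
#' @param clip if `TRUE` (default), rate laws see `max(C, 0)`; the integrator
#'   is allowed transiently tiny negative concentrations.
#' @return Named vector of 9 rates in canonical reaction order.
#' @export
reaction_rates <- function(conc, params, clip = TRUE) {
  if (is.null(names(conc))) names(conc) <- FS_COMPONENTS
  if (!clip && any(conc < 0))
    stop("negative concentration: ",
         paste(names(conc)[conc < 0], collapse = ", "))
  cc <- pmax(conc, 0)
  k <- params$k; Km <- params$Km
  mm <- function(x, K) x / (K + x)
  c(cyt = k[["cyt"]] * mm(params$IRON, Km[["cyt"]]),
    mit = k[["mit"]] * mm(cc[["FC"]], Km[["mit"]]),
    vac = k[["vac"]] * mm(cc[["FC"]], Km[["vac"]]),
    cia = k[["cia"]] * mm(cc[["FC"]], Km[["cia"]]),
    isu = k[["isu"]] * mm(cc[["FM"]], Km[["isu"]]) *
            params$O2_sp / (params$O2_sp + cc[["O2"]]),
    mp  = k[["mp"]] * cc[["FM"]] * cc[["O2"]],
    O2  = k[["O2"]] * (params$OXYGEN - conc[["O2"]]),
    res = k[["res"]] * cc[["FS"]] * mm(cc[["O2"]], Km[["res"]]),
    `23` = k[["23"]] * mm(cc[["F2"]], Km[["23"]]) * params$OXYGEN)
}

#' ODE right-hand side
#'
#' Time derivative of the eight local concentrations: reaction gains/losses
#' with interregional volume-ratio factors on the `F2` and `FM` gains, and a
#' growth-dilution loss `-alpha_cell [C_i]` on every component. When a CRM is
#' supplied, the regulated rate constants are first recomputed from the
#' current sensor concentrations through the logistic valves.
#'
#' @inheritParams reaction_rate
#' @param crm optional [crm()] of logistic regulators.
#' @return Named vector of 8 derivatives, uM/min.
#' @export
ode_rhs <- function(conc, params, crm = NULL) {
  if (!is.null(crm)) params <- apply_crm(crm, params, conc)
  R <- reaction_rates(conc, params)
  lay <- params$layout
  rv <- lay$f_cyt / lay$f_vac
  rm <- lay$f_cyt / lay$f_mit
  a <- params$alpha
  c(FC  = R[["cyt"]] - R[["vac"]] - R[["mit"]] - R[["cia"]] - a * conc[["FC"]],
    CIA = R[["cia"]] - a * conc[["CIA"]],
    F2  = rv * R[["vac"]] - R[["23"]] - a * conc[["F2"]],
    F3  = R[["23"]] - a * conc[["F3"]],
    FM  = rm * R[["mit"]] - R[["isu"]] - R[["mp"]] - a * conc[["FM"]],
    FS  = R[["isu"]] - a * conc[["FS"]],
    MP  = R[["mp"]] - a * conc[["MP"]],
    O2  = R[["O2"]] - R[["mp"]] - R[["res"]] - a * conc[["O2"]])
}

#' Stoichiometric matrix of the network
#'
#' The 8 x 17 matrix S such that `S %*% R` equals the ODE right-hand side
#' when `R` stacks the nine reaction rates and the eight dilution rates.
#' Entries are integers except the interregional volume-ratio factors
#' (`f_cyt/f_vac` and `f_cyt/f_mit`, both 8 for the bundled layout) on the
#' `F2` and `FM` gain terms.
#'
#' @param network a [reaction_network()].
#' @return 8 x 17 numeric matrix with dimnames.
#' @export
stoichiometric_matrix <- function(network = reaction_network()) {
  lay <- network$layout
  rv <- lay$f_cyt / lay$f_vac
  rm <- lay$f_cyt / lay$f_mit
  S <- matrix(0, 8, 17, dimnames = list(FS_COMPONENTS, FS_RATE_COLS))
  S["FC", c("R_cyt", "R_mit", "R_vac", "R_cia")] <- c(1, -1, -1, -1)
  S["CIA", "R_cia"] <- 1
  S["F2", c("R_vac", "R_23")] <- c(rv, -1)
  S["F3", "R_23"] <- 1
  S["FM", c("R_mit", "R_isu", "R_mp")] <- c(rm, -1, -1)
  S["FS", "R_isu"] <- 1
  S["MP", "R_mp"] <- 1
  S["O2", c("R_O2", "R_mp", "R_res")] <- c(1, -1, -1)
  S[, paste0("D_", FS_COMPONENTS)] <- -diag(8)
  S
}

#' Assemble the 17-entry rate vector at a given state
#'
#' Stacks the nine reaction rates (evaluated from the rate laws) and the
#' eight dilution rates `alpha * [C_i]`, in stoichiometric column order, so
#' that `stoichiometric_matrix() %*% assemble_rate_vector(...)` reproduces
#' [ode_rhs()].
#'
#' @inheritParams reaction_rate
#' @return Named numeric vector of length 17.
#' @export
assemble_rate_vector <- function(conc, params) {
  R <- reaction_rates(conc, params)
  out <- c(R[["cyt"]], R[["mit"]], R[["vac"]], R[["cia"]], R[["isu"]],
           R[["mp"]], R[["O2"]], R[["23"]], R[["res"]],
           params$alpha * conc[FS_COMPONENTS])
  setNames(out, FS_RATE_COLS)
}

## Pack params (+ optional CRM) into the 65-entry vector consumed by the
## compiled derivative function.
pack_parms <- function(params, crm = NULL) {
  p <- numeric(65)
  p[1:9]   <- params$k[FS_REACTIONS]
  p[10:16] <- params$Km[FS_KM_NAMES]
  p[17] <- params$O2_sp
  p[18] <- params$alpha
  p[19] <- params$IRON
  p[20] <- params$OXYGEN
  p[21:23] <- c(params$layout$f_cyt, params$layout$f_mit, params$layout$f_vac)
  if (!is.null(crm)) {
    for (i in seq_along(FS_REGULATABLE)) {
      reg <- crm$regulators[[FS_REGULATABLE[i]]]
      if (!is.null(reg)) {
        off <- 23 + 6 * (i - 1)
        p[off + 1:6] <- c(1, match(reg$sensor, FS_COMPONENTS),
                          reg$n, reg$SP, reg$k_reg, reg$k_unreg)
      }
    }
  }
  p
}
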