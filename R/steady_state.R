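## Exact rational RREF of the stoichiometric matrix and the null-space
## parameterization of steady states.
##
## Pivot classification is done in exact rational arithmetic (integer
## numerator/denominator matrices) so that near-zero floating-point residues
## can never be mistaken for pivots. Floats are used only downstream.

## continued-fraction rationalization of a numeric matrix entry
.as_rational <- function(x, tol = 1e-9, max_den = 1e6) {
  if (x == round(x)) return(c(num = x, den = 1))
  # Stern-Brocot style continued fraction expansion
  sign <- if (x < 0) -1 else 1
  z <- abs(x)
  h <- c(1, 0); k <- c(0, 1)
  repeat {
    a <- floor(z)
    h <- c(a * h[1] + h[2], h[1])
    k <- c(a * k[1] + k[2], k[1])
    if (k[1] > max_den) stop("cannot rationalize entry ", x)
    if (abs(sign * h[1] / k[1] - x) < tol) break
    frac <- z - a
    if (frac < tol) break
    z <- 1 / frac
  }
  c(num = sign * h[1], den = k[1])
}

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- b; b <- a %% b; a <- t }
  max(a, 1)
}

#' Reduced row-echelon form and null-space relations of a stoichiometric matrix
#'
#' Transforms the matrix to RREF using exact rational arithmetic, classifies
#' pivot columns as *dependent* rates and non-pivot columns as *independent*
#' rates, and extracts the linear null-space relations expressing each
#' dependent rate in terms of the independent ones. For the bundled network
#' the dependent rates are the eight reaction rates
#' `R_cyt, R_mit, R_vac, R_cia, R_isu, R_mp, R_O2, R_23` and the independent
#' rates are `R_res` and the eight dilution rates.
#'
#' @param S numeric matrix, typically from [stoichiometric_matrix()]. Entries
#'   must be rational (integers or small-denominator fractions).
#' @return An object of class `stoich_system` with elements `S`, `rref`,
#'   `pivots`, `free` (column indices), and `relations`, the matrix `M` such
#'   that at steady state `R[pivots] = M %*% R[free]`.
#' @export
rref_decompose <- function(S) {
  m <- nrow(S); n <- ncol(S)
  num <- matrix(0, m, n); den <- matrix(1, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    r <- .as_rational(S[i, j])
    num[i, j] <- r[1]; den[i, j] <- r[2]
  }
  simp <- function(i, j) {
    if (num[i, j] == 0) { den[i, j] <<- 1; return(invisible()) }
    g <- .gcd(num[i, j], den[i, j])
    s <- if (den[i, j] < 0) -1 else 1
    num[i, j] <<- s * num[i, j] / g
    den[i, j] <<- s * den[i, j] / g
    invisible()
  }
  pivots <- integer(0)
  r <- 1L
  for (col in seq_len(n)) {
    if (r > m) break
    pr <- which(num[r:m, col] != 0)
    if (length(pr) == 0) next
    pr <- pr[1] + r - 1L
    if (pr != r) {
      tmp <- num[r, ]; num[r, ] <- num[pr, ]; num[pr, ] <- tmp
      tmp <- den[r, ]; den[r, ] <- den[pr, ]; den[pr, ] <- tmp
    }
    ## normalize pivot row to a leading 1
    pn <- num[r, col]; pd <- den[r, col]
    for (j in seq_len(n)) {
      num[r, j] <- num[r, j] * pd
      den[r, j] <- den[r, j] * pn
      simp(r, j)
    }
    ## eliminate the pivot column from every other row
    for (i in seq_len(m)) {
      if (i == r || num[i, col] == 0) next
      fn <- num[i, col]; fd <- den[i, col]
      for (j in seq_len(n)) {
        ## row_i <- row_i - (f) * row_r, all rational
        an <- num[i, j]; ad <- den[i, j]
        bn <- fn * num[r, j]; bd <- fd * den[r, j]
        num[i, j] <- an * bd - bn * ad
        den[i, j] <- ad * bd
        simp(i, j)
      }
    }
    pivots <- c(pivots, col)
    r <- r + 1L
  }
  if (length(pivots) < m) {
    zero_rows <- which(apply(num, 1, function(z) all(z == 0)))
    stop("rank-deficient stoichiometric matrix: rank ", length(pivots),
         " < ", m, " rows; linearly dependent rows: ",
         paste(rownames(S)[zero_rows], collapse = ", "))
  }
  rref <- num / den
  dimnames(rref) <- dimnames(S)
  free <- setdiff(seq_len(n), pivots)
  relations <- -rref[, free, drop = FALSE]
  rownames(relations) <- colnames(S)[pivots]
  structure(list(S = S, rref = rref, pivots = pivots, free = free,
                 dependent = colnames(S)[pivots],
                 independent = colnames(S)[free],
                 relations = relations),
            class = "stoich_system")
}

#' @export
print.stoich_system <- function(x, ...) {
  cat("<stoich_system>", nrow(x$S), "x", ncol(x$S),
      "| rank", length(x$pivots),
      "| null-space dimension", length(x$free), "\n")
  cat("dependent:  ", paste(x$dependent, collapse = ", "), "\n")
  cat("independent:", paste(x$independent, collapse = ", "), "\n")
  invisible(x)
}

#' Dilution rates of all components
#'
#' `D_i = alpha_cell * [C_i]`: the rate at which exponential growth dilutes
#' each component at its steady-state concentration.
#'
#' @param conc concentration profile.
#' @param alpha exponential growth rate, 1/min.
#' @return Named vector `D_FC ... D_O2`, uM/min.
#' @export
dilution_rates <- function(conc, alpha) {
  if (alpha < 0) stop("alpha must be >= 0")
  setNames(alpha * conc[FS_COMPONENTS], paste0("D_", FS_COMPONENTS))
}

#' Dependent rates from the null-space relations
#'
#' Given an assignment of the nine independent rates (`R_res` plus the eight
#' dilution rates), fills in the eight dependent reaction rates through the
#' null-space relations, e.g.
#' `R_cyt = D_FC + D_CIA + (1/8)(D_F2 + D_F3 + D_FM + D_FS + D_MP)`.
#'
#' @param independent named vector containing `R_res` and `D_FC ... D_O2`.
#' @param system a `stoich_system`; defaults to the bundled network's.
#' @return Full named rate vector of length 17 (dependent + independent).
#' @export
dependent_rates <- function(independent, system = rref_decompose(stoichiometric_matrix())) {
  need <- system$independent
  if (!all(need %in% names(independent)))
    stop("missing independent rates: ",
         paste(setdiff(need, names(independent)), collapse = ", "))
  ind <- independent[need]
  dep <- drop(system$relations %*% ind)
  out <- setNames(numeric(ncol(system$S)), colnames(system$S))
  out[system$dependent] <- dep
  out[need] <- ind
  out
}

#' Invert the rate laws for the rate constants
#'
#' Equates each steady-state rate to its rate-law expression and solves for
#' the rate constant, e.g.
#' `k_isu = R_isu (K_isu + [FM]) / [FM] * ([O2]_sp + [O2]) / [O2]_sp`.
#' A zero rate yields a zero rate constant; a zero substrate concentration
#' with a nonzero rate is an inversion error.
#'
#' @param rates full rate vector (length 17, as from [dependent_rates()]).
#' @param conc concentration profile at the steady state.
#' @param IRON,OXYGEN external nutrient concentrations, uM.
#' @param Km named Michaelis-constant vector.
#' @param O2_sp O2-inhibition setpoint, uM.
#' @return Named vector of the 9 rate constants.
#' @export
invert_rate_laws <- function(rates, conc, IRON, OXYGEN, Km, O2_sp = 1) {
  inv <- function(rate, denom, id) {
    if (rate == 0) return(0)
    if (denom <= 0)
      stop("cannot invert rate law for reaction '", id,
           "': zero substrate with nonzero rate")
    rate / denom
  }
  mm <- function(x, K) x / (K + x)
  c(cyt = inv(rates[["R_cyt"]], mm(IRON, Km[["cyt"]]), "cyt"),
    mit = inv(rates[["R_mit"]], mm(conc[["FC"]], Km[["mit"]]), "mit"),
    vac = inv(rates[["R_vac"]], mm(conc[["FC"]], Km[["vac"]]), "vac"),
    cia = inv(rates[["R_cia"]], mm(conc[["FC"]], Km[["cia"]]), "cia"),
    isu = inv(rates[["R_isu"]],
              mm(conc[["FM"]], Km[["isu"]]) * O2_sp / (O2_sp + conc[["O2"]]),
              "isu"),
    mp  = inv(rates[["R_mp"]], conc[["FM"]] * conc[["O2"]], "mp"),
    O2  = inv(rates[["R_O2"]], OXYGEN - conc[["O2"]], "O2"),
    res = inv(rates[["R_res"]],
              conc[["FS"]] * mm(conc[["O2"]], Km[["res"]]), "res"),
    `23` = inv(rates[["R_23"]], mm(conc[["F2"]], Km[["23"]]) * OXYGEN, "23"))
}

#' Default Michaelis-constant table
#'
#' Each `K_m` is set to the wild-type substrate concentration of its
#' reaction, which maximizes the sensitivity of the rate to that substrate,
#' except `K_cyt(IRON)` which is 10 uM (adjusted from 40 to avoid
#' instability).
#'
#' @return Named vector of 7 Km values, uM.
#' @export
default_km <- function() {
  c(cyt = 10, mit = 20, vac = 20, cia = 20, `23` = 200, isu = 100, res = 1)
}

#' Build a full cellular state from steady-state data
#'
#' Composes the steady-state parameterization pipeline: dilution rates from
#' the concentrations and growth rate, dependent rates from the null-space
#' relations given the one free reaction rate `R_res`, and rate constants by
#' rate-law inversion.
#'
#' @param conc steady-state concentration profile (uM, local).
#' @param alpha exponential growth rate, 1/min.
#' @param IRON,OXYGEN external nutrient concentrations, uM.
#' @param R_res respiration rate, uM/min; the single free reaction rate.
#'   Its value is constrained by stability, not by the null space (the
#'   initially assumed 10,000 uM/min satisfies the null space but yields a
#'   non-negative Jacobian eigenvalue).
#' @param Km Michaelis constants; defaults to [default_km()].
#' @param O2_sp O2-inhibition setpoint, uM.
#' @param label state label.
#' @param layout compartment layout.
#' @return A list with elements `params` (a [cell_state_params()]), `rates`
#'   (the 17-entry rate vector) and `conc`.
#' @export
build_cell_state <- function(conc, alpha, IRON, OXYGEN, R_res,
                             Km = default_km(), O2_sp = 1, label = "custom",
                             layout = compartment_layout()) {
  if (R_res <= 0) stop("R_res must be > 0")
  conc <- concentration_profile(conc)
  system <- rref_decompose(stoichiometric_matrix(reaction_network(layout)))
  ind <- c(R_res = R_res, dilution_rates(conc, alpha))
  rates <- dependent_rates(ind, system)
  k <- invert_rate_laws(rates, conc, IRON, OXYGEN, Km, O2_sp)
  params <- cell_state_params(k = k, Km = Km, O2_sp = O2_sp, alpha = alpha,
                              IRON = IRON, OXYGEN = OXYGEN, label = label,
                              layout = layout)
  list(params = params, rates = rates, conc = conc)
}
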