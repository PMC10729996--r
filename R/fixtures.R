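## The bundled yeast model: loading, validation and accessors.

#' Load a model bundle
#'
#' Reads a structured-text (YAML) model bundle: network definition, named
#' state definitions (steady-state concentrations, growth rate, externals,
#' free respiration rate), reference constants, CRM cases and prediction
#' scenarios. The packaged yeast iron-trafficking bundle is the default.
#'
#' @param path path to a bundle file; default: the packaged fixture.
#' @return An object of class `model_bundle`, with a `checksum` attribute
#'   (md5 of the file).
#' @export
load_bundle <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "yeast_iron_model.yaml",
                        package = "ferrosim", mustWork = TRUE)
  b <- yaml::read_yaml(path)
  .check_bundle(b)
  structure(b, class = "model_bundle",
            checksum = unname(tools::md5sum(path)), path = path)
}

.check_bundle <- function(b) {
  need <- c("compartments", "components", "reactions", "km", "o2_setpoint",
            "states")
  miss <- setdiff(need, names(b))
  if (length(miss))
    stop("bundle is missing field(s): ", paste(miss, collapse = ", "))
  f <- unlist(b$compartments)
  if (!all(c("f_cyt", "f_mit", "f_vac") %in% names(f)))
    stop("bundle field 'compartments' must define f_cyt, f_mit, f_vac")
  if (abs(sum(f) - 1) > 1e-12)
    stop("bundle field 'compartments': fractional volumes sum to ",
         format(sum(f), digits = 15), ", expected 1")
  ids <- vapply(b$components, function(x) as.character(x$id), character(1))
  if (!setequal(ids, FS_COMPONENTS))
    stop("bundle field 'components': expected the 8 model components")
  if (length(b$reactions) != 9)
    stop("bundle field 'reactions': expected 9 reactions, found ",
         length(b$reactions))
  for (s in names(b$states)) {
    st <- b$states[[s]]
    for (fld in c("conc", "alpha", "IRON", "OXYGEN", "R_res"))
      if (is.null(st[[fld]]))
        stop("bundle field 'states/", s, "/", fld, "' is missing")
    cc <- unlist(st$conc)
    if (!setequal(names(cc), FS_COMPONENTS))
      stop("bundle field 'states/", s, "/conc': must name all 8 components")
    if (any(cc < 0)) stop("bundle field 'states/", s, "/conc': negative value")
  }
  invisible(b)
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("<model_bundle>", x$model, "- states:",
      paste(names(x$states), collapse = ", "),
      "- CRM cases:", paste(names(x$crm_cases), collapse = ", "), "\n")
  invisible(x)
}

#' Save a model bundle
#'
#' @param bundle a `model_bundle`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  b <- unclass(bundle)
  attributes(b) <- attributes(b)["names"]
  yaml::write_yaml(b, path, precision = 12)
  invisible(path)
}

#' Compartment layout of a bundle
#' @param bundle a `model_bundle`.
#' @return [compartment_layout()].
#' @export
bundle_layout <- function(bundle = load_bundle()) {
  compartment_layout(bundle$compartments$f_cyt, bundle$compartments$f_mit,
                     bundle$compartments$f_vac)
}

#' Steady-state concentration profile of a bundled state
#'
#' @param state state label (`"W"`, `"Y"`, `"D"`).
#' @param bundle a `model_bundle`.
#' @return Named concentration profile, uM.
#' @export
state_profile <- function(state, bundle = load_bundle()) {
  st <- bundle$states[[state]]
  if (is.null(st)) stop("no such state in bundle: ", state)
  concentration_profile(unlist(st$conc))
}

#' Full kinetic parameterization of a bundled state
#'
#' Derives the state's rates and rate constants from its steady-state
#' concentrations through the null-space relations ([build_cell_state()]).
#'
#' @inheritParams state_profile
#' @return List with `params`, `rates`, `conc` (see [build_cell_state()]).
#' @export
state_parameterization <- function(state, bundle = load_bundle()) {
  st <- bundle$states[[state]]
  if (is.null(st)) stop("no such state in bundle: ", state)
  build_cell_state(conc = concentration_profile(unlist(st$conc)),
                   alpha = st$alpha, IRON = st$IRON, OXYGEN = st$OXYGEN,
                   R_res = st$R_res,
                   Km = setNames(unlist(bundle$km)[FS_KM_NAMES], FS_KM_NAMES),
                   O2_sp = bundle$o2_setpoint, label = state,
                   layout = bundle_layout(bundle))
}

#' Cell-state parameters of a bundled state
#'
#' Convenience wrapper returning just the `cell_state_params` of
#' [state_parameterization()].
#'
#' @inheritParams state_profile
#' @return `cell_state_params`.
#' @export
state_params <- function(state, bundle = load_bundle()) {
  state_parameterization(state, bundle)$params
}

#' A bundled CRM case
#'
#' The selected cellular regulatory mechanisms ship with the bundle as
#' `case1` and `case2`; the two differ only in the sensor of the cellular
#' iron-import reaction (FC vs F2).
#'
#' @param case 1, 2, or a case name.
#' @param bundle a `model_bundle`.
#' @return A [crm()].
#' @export
crm_case <- function(case = 1, bundle = load_bundle()) {
  nm <- if (is.numeric(case)) paste0("case", case) else case
  spec <- bundle$crm_cases[[nm]]
  if (is.null(spec)) stop("no such CRM case in bundle: ", nm)
  regs <- lapply(spec, function(r)
    heaviside_regulator(r$sensor, r$n, r$SP, r$k_reg, r$k_unreg, r$mode))
  crm(regs, label = nm)
}

#' Reference (published) constants of a bundled state
#'
#' @inheritParams state_profile
#' @return Named vector of full-precision reference rates and rate constants.
#' @export
reference_constants <- function(state, bundle = load_bundle()) {
  unlist(bundle$reference_constants[[state]])
}

#' Validate a bundle by re-derivation
#'
#' Re-derives every state's rates and rate constants from its concentrations
#' and compares them entry-by-entry with the bundle's reference constants.
#' The W state must agree to `tol_W` relative (default 1e-4). The Y and D
#' states are compared at `tol_other` (default 1e-3): their reference R_res
#' values are published at limited precision.
#'
#' @param bundle a `model_bundle`.
#' @param tol_W,tol_other relative tolerances.
#' @return Invisibly, a data frame of per-entry relative errors. Errors above
#'   tolerance raise.
#' @export
validate_bundle <- function(bundle = load_bundle(), tol_W = 1e-4,
                            tol_other = 1e-3) {
  rows <- list()
  for (s in names(bundle$reference_constants)) {
    ref <- reference_constants(s, bundle)
    der <- state_parameterization(s, bundle)
    got <- c(der$rates[c("R_cia", "R_23", "R_isu", "R_mp", "R_vac", "R_mit",
                         "R_cyt", "R_res", "R_O2",
                         paste0("D_", FS_COMPONENTS))],
             setNames(der$params$k[FS_REACTIONS],
                      paste0("k_", FS_REACTIONS)))
    common <- intersect(names(ref), names(got))
    rel <- abs(got[common] - ref[common]) / pmax(abs(ref[common]), 1e-12)
    tol <- if (s == "W") tol_W else tol_other
    ## reference values are printed to 6 decimals; differences within half a
    ## printed ulp are rounding, not disagreement
    rel[abs(got[common] - ref[common]) <= 5.0001e-7] <- 0
    if (any(rel > tol))
      stop("bundle validation failed for state ", s, ": ",
           paste0(common[rel > tol], " (", signif(rel[rel > tol], 3), ")",
                  collapse = ", "), " exceed tolerance ", tol)
    rows[[s]] <- data.frame(state = s, entry = common, rel_err = unname(rel))
  }
  invisible(do.call(rbind, rows))
}
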