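## Trace serialization: CSV data plus a JSON run manifest.

#' Write a transition trace to CSV with a JSON manifest
#'
#' The CSV carries the abscissa, the eight local concentrations and any
#' effective rate-constant columns. A sidecar manifest (`<path>.manifest.json`)
#' records the run conditions (parameters, CRM, tolerances, seed, fixture
#' checksum) so the run can be reproduced bit-for-bit.
#'
#' @param trace a `transition_trace`.
#' @param path output CSV path.
#' @param params optional `cell_state_params` recorded in the manifest.
#' @param crm optional [crm()] recorded in the manifest.
#' @param seed optional RNG seed recorded in the manifest.
#' @param fixture_checksum optional md5 of the model bundle used.
#' @param rtol,atol integrator tolerances recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, params = NULL, crm = NULL, seed = NULL,
                        fixture_checksum = NULL, rtol = 1e-8, atol = 1e-6) {
  df <- as.data.frame(trace)
  utils::write.csv(df, path, row.names = FALSE)
  manifest <- list(
    format = "ferrosim_trace",
    mode = attr(trace, "mode"),
    columns = names(df),
    n_points = nrow(df),
    tolerances = list(rtol = rtol, atol = atol),
    seed = seed,
    fixture_checksum = fixture_checksum)
  if (!is.null(params))
    manifest$params <- list(
      label = params$label, alpha = params$alpha, IRON = params$IRON,
      OXYGEN = params$OXYGEN, O2_sp = params$O2_sp,
      k = as.list(params$k), Km = as.list(params$Km))
  if (!is.null(crm))
    manifest$crm <- list(
      label = crm$label,
      regulators = lapply(crm$regulators, function(r)
        list(sensor = r$sensor, n = r$n, SP = r$SP,
             k_reg = r$k_reg, k_unreg = r$k_unreg, mode = r$mode)))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path CSV path.
#' @return `transition_trace` (manifest attached as attribute `manifest` when
#'   present).
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  mode <- if ("increment" %in% names(df)) "increment" else "time"
  tr <- structure(df, class = c("transition_trace", "data.frame"),
                  mode = mode)
  mf <- paste0(path, ".manifest.json")
  if (file.exists(mf)) {
    man <- jsonlite::read_json(mf)
    attr(tr, "manifest") <- man
    if (!is.null(man$mode)) attr(tr, "mode") <- man$mode
  }
  tr
}
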