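# Shared fixtures: the bundled states are derived once per test run.
# Heavy computations (the full evolutionary screen) are memoized so that
# several test blocks can interrogate a single run.

fs_bundle <- load_bundle()
fs_W <- state_parameterization("W", fs_bundle)
fs_Y <- state_parameterization("Y", fs_bundle)
fs_D <- state_parameterization("D", fs_bundle)
fs_case1 <- crm_case(1, fs_bundle)
fs_case2 <- crm_case(2, fs_bundle)

fs_states <- list(W = fs_W, Y = fs_Y, D = fs_D)

fs_conc_table <- vapply(fs_states, function(x) x$conc, numeric(8))
fs_k_table <- vapply(fs_states, function(x) x$params$k, numeric(9))

# random nonnegative concentration profile, roughly on the physiological scale
fs_random_profile <- function() {
  concentration_profile(setNames(
    stats::runif(8, 0, 1) * c(50, 150, 400, 5000, 300, 800, 1000, 2),
    c("FC", "CIA", "F2", "F3", "FM", "FS", "MP", "O2")))
}

# finite-difference Jacobian oracle, independent of jacobian_matrix()
fs_fd_jacobian <- function(params, conc, crm = NULL, h = 1e-6) {
  J <- matrix(0, 8, 8)
  for (j in 1:8) {
    up <- conc; dn <- conc
    dh <- h * max(1, conc[j])
    up[j] <- up[j] + dh; dn[j] <- dn[j] - dh
    J[, j] <- (ode_rhs(up, params, crm) - ode_rhs(dn, params, crm)) / (2 * dh)
  }
  J
}

# memoized full evolutionary screen (used by several acceptance checks)
fs_cache <- new.env(parent = emptyenv())
fs_evolve <- function() {
  if (is.null(fs_cache$evolve))
    fs_cache$evolve <- evolve_crms(fs_bundle, verbose = FALSE)
  fs_cache$evolve
}
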