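test_that("RREF classifies dependent and independent rates", {
  sys <- rref_decompose(stoichiometric_matrix())
  expect_length(sys$pivots, 8)
  expect_length(sys$free, 9)
  expect_setequal(sys$dependent,
                  c("R_cyt", "R_mit", "R_vac", "R_cia", "R_isu", "R_mp",
                    "R_O2", "R_23"))
  expect_setequal(sys$independent,
                  c("R_res", paste0("D_", names(fs_W$conc))))
  # identity padded with zero columns: pivots are the first 8 columns
  id <- cbind(diag(8), matrix(0, 8, 9))
  expect_equal(rref_decompose(id)$pivots, 1:8)
  # rank-deficient input is rejected with a structural error
  bad <- stoichiometric_matrix()
  bad[2, ] <- 2 * bad[1, ]
  bad[2, "D_CIA"] <- 0; bad[2, "D_FC"] <- -2
  expect_error(rref_decompose(bad), "rank-deficient")
})

test_that("exact RREF agrees with the floating-point elimination oracle", {
  skip_if_not_installed("pracma")
  S <- stoichiometric_matrix()
  expect_equal(unname(rref_decompose(S)$rref), unname(pracma::rref(S)),
               tolerance = 1e-12)
  expect_equal(17 - qr(S)$rank, 9)   # null-space dimension
})

test_that("null-space relations are exact for arbitrary independent rates", {
  sys <- rref_decompose(stoichiometric_matrix())
  S <- sys$S
  set.seed(11)
  for (i in 1:20) {
    ind <- setNames(stats::runif(9, 0, 100), sys$independent)
    R <- dependent_rates(ind, sys)
    expect_lt(max(abs(S %*% R[colnames(S)])), 1e-12 * max(abs(R)))
  }
  zero <- setNames(rep(0, 9), sys$independent)
  expect_equal(unname(dependent_rates(zero, sys)), rep(0, 17))
})

test_that("dilution rates scale concentrations by the growth rate", {
  d <- dilution_rates(fs_W$conc, 0.003333)
  expect_equal(unname(d[["D_F3"]]), 11.3322)
  expect_equal(unname(dilution_rates(fs_W$conc, 0)), rep(0, 8))
  expect_equal(unname(dilution_rates(fs_Y$conc, 0.002)[["D_MP"]]), 17)
})

test_that("dependent rates reproduce the tabulated wild-type values", {
  sys <- rref_decompose(stoichiometric_matrix())
  ind <- c(R_res = 9090.909091, dilution_rates(fs_W$conc, 0.003333))
  R <- dependent_rates(ind, sys)
  expect_equal(unname(R[["R_vac"]]), (0.6666 + 11.3322) / 8)
  expect_equal(unname(R[["R_mit"]]), 0.270806, tolerance = 1e-5)
  expect_equal(unname(R[["R_cyt"]]), 2.103960, tolerance = 1e-5)
})

test_that("rate-law inversion recovers the tabulated rate constants", {
  k <- invert_rate_laws(fs_W$rates, fs_W$conc, IRON = 40, OXYGEN = 100,
                        Km = default_km(), O2_sp = 1)
  expect_equal(unname(k[["isu"]]), 1.6665 * 2 * 2)
  expect_equal(unname(k[["mp"]]), 0.16665 / 100)
  expect_equal(unname(k[["res"]]), 36.363636, tolerance = 1e-7)
  # a zero rate maps to a zero constant; a zero substrate with flux errors
  r0 <- fs_W$rates; r0[["R_mp"]] <- 0
  expect_equal(unname(invert_rate_laws(r0, fs_W$conc, 40, 100,
                                       default_km())[["mp"]]), 0)
  c0 <- fs_W$conc; c0["FM"] <- 0
  expect_error(invert_rate_laws(fs_W$rates, c0, 40, 100, default_km()),
               "isu")
})

test_that("full parameterization matches the published constant table", {
  # W to 1e-4 relative; Y/D to 1e-3 (their published R_res has fewer digits)
  rel <- validate_bundle(fs_bundle)
  expect_lt(max(rel$rel_err[rel$state == "W"]), 1e-4)
  expect_lt(max(rel$rel_err), 1e-3)
  # spot values, including the iron-starved import constant
  expect_equal(unname(fs_D$params$k[["cyt"]]), 4.738685, tolerance = 1e-4)
  expect_equal(unname(fs_W$params$k[["isu"]]), 6.666, tolerance = 1e-9)
  expect_error(build_cell_state(fs_W$conc, 0.003333, 40, 100, R_res = 0),
               "R_res")
})

test_that("derive -> simulate -> re-derive is a fixed point within 1%", {
  ss <- steady_state(fs_W$params, fs_W$conc)
  re <- build_cell_state(ss, 0.003333, 40, 100, R_res = 9090.909091)
  expect_equal(unname(re$params$k), unname(fs_W$params$k), tolerance = 0.01)
})
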