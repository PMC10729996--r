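test_that("compartment layout enforces its invariants", {
  lay <- compartment_layout()
  expect_equal(lay$f_cyt + lay$f_mit + lay$f_vac, 1)
  expect_error(compartment_layout(0.9, 0.1, 0.1), "sum to 1")
  expect_error(compartment_layout(1.2, -0.1, -0.1), "positive")
})

test_that("concentration profiles validate and whole-cell iron books close", {
  expect_error(concentration_profile(FC = 1), "missing components")
  expect_error(concentration_profile(fs_W$conc - 100), "negative")
  expect_equal(fe_cell(fs_W$conc), 505)       # 0.8*100 + 0.1*3600 + 0.1*650
  expect_true(is.finite(fe_cell(fs_Y$conc)))
})

test_that("rate laws reproduce the tabulated steady-state rates", {
  w <- fs_W$params
  # saturating import at the wild-type operating point
  expect_equal(reaction_rate("cyt", fs_W$conc, w), 2.629945 * 40 / 50,
               tolerance = 1e-6)
  expect_equal(reaction_rate("cyt", fs_W$conc, w), 2.103960, tolerance = 1e-5)
  # ISC assembly with half-saturation and half O2 inhibition
  expect_equal(reaction_rate("isu", fs_W$conc, w), 6.666 * 0.5 * 0.5,
               tolerance = 1e-9)
  # vacuolar oxidation driven by external OXYGEN
  expect_equal(reaction_rate("23", fs_W$conc, w), 11.33215, tolerance = 1e-4)
  # zero substrate kills the bilinear nanoparticle reaction
  conc0 <- fs_W$conc; conc0["FM"] <- 0
  expect_equal(reaction_rate("mp", conc0, w), 0)
  expect_error(reaction_rate("nope", fs_W$conc, w), "unknown reaction")
  expect_error(reaction_rates(fs_W$conc - 100, w, clip = FALSE), "negative")
})

test_that("the derived states are steady states of the ODE right-hand side", {
  for (st in fs_states) {
    rhs <- ode_rhs(st$conc, st$params)
    rates <- reaction_rates(st$conc, st$params)
    expect_lt(max(abs(rhs)), 1e-3 * max(abs(rates)))
  }
  # hand-assembled F2 balance at the wild-type state
  R <- reaction_rates(fs_W$conc, fs_W$params)
  dF2 <- 8 * R[["vac"]] - R[["23"]] - fs_W$params$alpha * fs_W$conc[["F2"]]
  expect_equal(unname(ode_rhs(fs_W$conc, fs_W$params)[["F2"]]), unname(dF2))
  expect_lt(abs(dF2), 1e-6)
})

test_that("an empty cell only takes up oxygen", {
  p <- fs_W$params
  p$IRON <- 0
  zero <- concentration_profile(setNames(rep(0, 8), names(fs_W$conc)))
  rhs <- ode_rhs(zero, p)
  expect_equal(unname(rhs[["O2"]]), p$k[["O2"]] * p$OXYGEN)
  expect_equal(unname(rhs[setdiff(names(rhs), "O2")]), rep(0, 7))
})

test_that("stoichiometric matrix structure matches the network", {
  S <- stoichiometric_matrix()
  expect_equal(dim(S), c(8, 17))
  fc <- S["FC", ]
  expect_equal(unname(fc[c("R_cyt", "R_mit", "R_vac", "R_cia", "D_FC")]),
               c(1, -1, -1, -1, -1))
  expect_equal(sum(fc != 0), 5)
  # a dilution column touches exactly its component
  expect_equal(unname(S[, "D_MP"]), c(0, 0, 0, 0, 0, 0, -1, 0))
  # interregional volume-ratio factors
  expect_equal(S["F2", "R_vac"], 8)
  expect_equal(S["FM", "R_mit"], 8)
})

test_that("S %*% R reproduces the ODE right-hand side everywhere", {
  S <- stoichiometric_matrix()
  set.seed(421)
  for (i in 1:100) {
    conc <- fs_random_profile()
    lhs <- drop(S %*% assemble_rate_vector(conc, fs_W$params))
    rhs <- ode_rhs(conc, fs_W$params)
    expect_equal(unname(lhs), unname(rhs), tolerance = 1e-10)
  }
  # and S times the tabulated wild-type rate vector is the zero vector
  expect_lt(max(abs(S %*% fs_W$rates[colnames(S)])), 1e-4)
})

test_that("compiled and reference right-hand sides integrate identically", {
  set.seed(99)
  r_rhs <- function(t, y, p) list(ode_rhs(setNames(y, names(fs_W$conc)),
                                          fs_W$params, fs_case1))
  for (i in 1:3) {
    y0 <- fs_random_profile()
    ref <- deSolve::lsoda(y0, c(0, 100), r_rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-8)
    got <- integrate_model(fs_W$params, y0, t_end = 100, crm = fs_case1,
                           rtol = 1e-10, atol = 1e-8, with_k = FALSE)
    expect_equal(unname(as.numeric(got[2, 2:9])), unname(ref[2, 2:9]),
                 tolerance = 1e-6)
  }
})

test_that("cell iron is conserved without growth or import", {
  p <- fs_W$params
  p$alpha <- 0
  p$k[["cyt"]] <- 0
  tr <- integrate_model(p, fs_W$conc, t_end = 2000, n_out = 21,
                        with_k = FALSE)
  fe <- unname(apply(as.matrix(tr[, names(fs_W$conc)]), 1, function(row)
    fe_cell(setNames(row, names(fs_W$conc)))))
  expect_equal(fe, rep(fe[1], length(fe)), tolerance = 1e-7)
})

test_that("all rates are nonnegative except the signed oxygen exchange", {
  set.seed(7)
  for (i in 1:25) {
    R <- reaction_rates(fs_random_profile(), fs_W$params)
    expect_true(all(R[setdiff(names(R), "O2")] >= 0))
  }
  hi <- fs_W$conc; hi["O2"] <- 150           # above external OXYGEN
  expect_lt(reaction_rates(hi, fs_W$params)[["O2"]], 0)
})
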