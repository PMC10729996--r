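test_that("each state integrates back onto its tabulated profile", {
  for (st in fs_states) {
    ss <- steady_state(st$params, st$conc)
    expect_lt(max(abs(ss - st$conc) / st$conc), 0.01)
  }
  # zero-length integration returns the initial profile
  tr0 <- integrate_model(fs_W$params, fs_W$conc, t_end = 0)
  expect_equal(unname(as.numeric(tr0[1, names(fs_W$conc)])),
               unname(fs_W$conc))
})

test_that("integration endpoint matches an algebraic root of the RHS", {
  skip_if_not_installed("pracma")
  f <- function(x) unname(ode_rhs(concentration_profile(
    setNames(pmax(x, 1e-12), names(fs_Y$conc))), fs_Y$params))
  root <- pracma::fsolve(f, as.numeric(fs_Y$conc * 1.05))$x
  ss <- steady_state(fs_Y$params, fs_Y$conc * 1.05)
  expect_equal(unname(ss), root, tolerance = 1e-3)
})

test_that("growth rate is linearly coupled to the ISC rate constant", {
  expect_equal(alpha_of_kisu(6.666), 0.003333)
  expect_equal(alpha_of_kisu(0.6666), 0.002)
  expect_equal(alpha_of_kisu((6.666 + 0.6666) / 2), (0.003333 + 0.002) / 2)
  expect_warning(alpha_of_kisu(10), "extrapolat")
})

test_that("time transitions reach the target states under case-1 regulation", {
  # primary mutation: k_isu and growth rate drop abruptly at t = 0
  tr <- time_transition(fs_W$params, fs_W$conc,
                        trigger = list(k_isu = fs_Y$params$k[["isu"]],
                                       alpha = fs_Y$params$alpha),
                        crm = fs_case1)
  end <- setNames(as.numeric(tr[nrow(tr), names(fs_Y$conc)]),
                  names(fs_Y$conc))
  expect_lt(max(abs(end - fs_Y$conc) / fs_Y$conc), 0.01)
  expect_gt(end[["MP"]], 8000)  # nanoparticle accumulation is the phenotype
  # a null trigger leaves the steady state flat
  flat <- time_transition(fs_W$params, fs_W$conc, trigger = list(),
                          crm = NULL, n_out = 5)
  dev <- abs(sweep(as.matrix(flat[, names(fs_W$conc)]), 2, fs_W$conc)) /
    rep(fs_W$conc, each = nrow(flat))
  expect_lt(max(dev), 1e-5)
})

test_that("reverse transitions are not time-mirrors of forward ones", {
  times <- seq(0, 3000, by = 50)
  fwd <- time_transition(fs_W$params, fs_W$conc,
                         trigger = list(k_isu = fs_Y$params$k[["isu"]],
                                        alpha = fs_Y$params$alpha),
                         crm = fs_case1, times = times, with_k = FALSE)
  y_params <- fs_W$params
  y_params$k[["isu"]] <- fs_Y$params$k[["isu"]]
  y_params$alpha <- fs_Y$params$alpha
  rev <- time_transition(y_params, fs_Y$conc,
                         trigger = list(k_isu = fs_W$params$k[["isu"]],
                                        alpha = fs_W$params$alpha),
                         crm = fs_case1, times = times, with_k = FALSE)
  mirror <- as.matrix(fwd[rev(seq_len(nrow(fwd))), names(fs_W$conc)])
  direct <- as.matrix(rev[, names(fs_W$conc)])
  expect_gt(max(abs(direct - mirror) / (abs(mirror) + 1)), 0.1)
})

test_that("steady-state transitions land on the target and move smoothly", {
  # iron starvation: IRON 40 -> 1 over increments
  tr <- steady_state_transition(fs_W$params, fs_W$conc,
                                to = list(IRON = 1), crm = fs_case1,
                                n_increments = 30)
  expect_true(all(attr(tr, "converged")))
  end <- setNames(as.numeric(tr[nrow(tr), names(fs_D$conc)]),
                  names(fs_D$conc))
  expect_lt(max(abs(end - fs_D$conc) / fs_D$conc), 0.02)
  # two increments degenerate to the two endpoint states
  tr2 <- steady_state_transition(fs_W$params, fs_W$conc,
                                 to = list(IRON = 1), crm = fs_case1,
                                 n_increments = 2)
  expect_equal(nrow(tr2), 2)
  expect_equal(tr2$IRON, c(40, 1))
  # primary-mutation transition: FS declines monotonically (the first
  # increment settles onto the regulated system's own wild-type state)
  try <- steady_state_transition(fs_W$params, fs_W$conc,
                                 to = list(k_isu = fs_Y$params$k[["isu"]]),
                                 crm = fs_case1, n_increments = 30)
  expect_true(all(diff(try$FS[-1]) < 1e-6))
})

test_that("perturbation recovery behaves as the coupling structure dictates", {
  # without regulation, doubling FS cannot reach FC, CIA, F2 or F3
  tr <- perturb_recover(fs_W$params, fs_W$conc, "FS", 2, t_perturb = 400,
                        t_end = 20000, dt = 20)
  upstream <- c("FC", "CIA", "F2", "F3")
  dev <- abs(sweep(as.matrix(tr[, upstream]), 2, fs_W$conc[upstream])) /
    rep(fs_W$conc[upstream], each = nrow(tr))
  expect_lt(max(dev), 1e-5)
  expect_lt(attr(tr, "recovery_time"), 20000)
  # factor 1 is a null perturbation
  flat <- perturb_recover(fs_W$params, fs_W$conc, "FS", 1, t_end = 2000,
                          dt = 100)
  expect_equal(attr(flat, "recovery_time"), 100)
  # with autoregulation every component is transiently displaced
  trc <- perturb_recover(fs_W$params, fs_W$conc, "FS", 2, crm = fs_case1,
                         t_perturb = 400, t_end = 20000, dt = 20)
  devc <- abs(sweep(as.matrix(trc[, names(fs_W$conc)]), 2, fs_W$conc)) /
    rep(fs_W$conc, each = nrow(trc))
  expect_true(all(apply(devc, 2, max) > 1e-4))
  expect_lt(attr(trc, "recovery_time"), 20000)
})

test_that("severe hypoxia refills the vacuolar Fe(II) pool of diseased cells", {
  p <- fs_Y$params
  p$OXYGEN <- 1
  hy <- steady_state(p, fs_Y$conc, crm = fs_case1)
  target <- unlist(fs_bundle$predictions$H_Y$target)
  expect_equal(unname(hy[["F2"]]), 5500, tolerance = 0.05)
  expect_lt(hy[["MP"]], fs_Y$conc[["MP"]] / 5)   # nanoparticles dissolve away
  expect_gt(hy[["FS"]] / fs_Y$conc[["FS"]], 1.5) # ISC partially recovers
  expect_equal(unname(hy[["FM"]]), target[["FM"]], tolerance = 0.1)
})
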