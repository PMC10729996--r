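test_that("candidate-space combinatorics", {
  expect_equal(enumerate_count(9, 8), 134217728)
  expect_equal(enumerate_count(7, 8), 2097152)
  expect_equal(enumerate_count(1, 1), 1)
})

test_that("uniqueness keeps reactions with three distinct constants", {
  uniq <- filter_uniqueness(lapply(fs_states, `[[`, "params"))
  expect_setequal(uniq, c("cyt", "mit", "vac", "cia", "mp", "O2", "23"))
  # identical states leave nothing to regulate
  same <- fs_k_table; same[, 2] <- same[, 1]; same[, 3] <- same[, 1]
  expect_length(filter_uniqueness(same), 0)
  # near-equal values below tolerance are not distinct
  kt <- fs_k_table
  kt["vac", ] <- c(1, 1 + 1e-12, 2)
  expect_false("vac" %in% filter_uniqueness(kt))
})

test_that("trending admits exactly the order-compatible sensors", {
  uniq <- c("cyt", "mit", "vac", "cia", "mp", "O2", "23")
  tr <- filter_trending(fs_k_table[uniq, ], fs_conc_table)
  expect_equal(tr$n_crms, 576)
  expect_equal(unname(tr$counts[c("mit", "O2")]), c(1L, 1L))
  # mitochondrial import: only the ISC pool, in feedback
  expect_equal(tr$valid$mit$sensor, "FS")
  expect_equal(tr$valid$mit$mode, "feedback")
  # a sensor with a concentration tie is invalid for every reaction
  ct <- fs_conc_table
  ct["FC", 2] <- ct["FC", 1]
  tr2 <- filter_trending(fs_k_table[uniq, ], ct)
  expect_false(any(vapply(tr2$valid, function(v) "FC" %in% v$sensor,
                          logical(1))))
})

test_that("product-of-counts equals brute-force enumeration", {
  # a small constructed screen, checked by exhausting all assignments
  valid <- list(
    r1 = data.frame(sensor = c("FC", "FM"), mode = "feedforward"),
    r2 = data.frame(sensor = c("FS"), mode = "feedback"),
    r3 = data.frame(sensor = c("FC", "F2", "O2"), mode = "feedback"))
  counts <- vapply(valid, nrow, integer(1))
  expect_equal(brute_force_trending(valid, sensors = c("FC", "FM", "FS",
                                                       "F2", "O2")),
               prod(counts))
})

test_that("wandering scores vanish for straight paths and see detours", {
  # a perfectly linear steady-state transition has zero wandering error
  n <- 100
  p <- seq(6.666, 0.6666, length.out = n)
  lin <- data.frame(increment = 1:n, k_isu = p)
  for (cn in rownames(fs_conc_table))
    lin[[cn]] <- seq(fs_conc_table[cn, 1], fs_conc_table[cn, 2],
                     length.out = n)
  lin <- structure(lin, class = c("transition_trace", "data.frame"),
                   mode = "increment", param_name = "k_isu")
  ws <- wander_scores(trace_ss = lin)
  expect_equal(unname(ws$err_ss), rep(0, 8), tolerance = 1e-9)
  # a sinusoidal detour that doubles the arc length scores exactly 100
  sin_tr <- lin
  ab <- seq(0, 1, length.out = 4001)
  amp <- 40
  base_len <- sqrt(sum(c(diff(range(p)), 0)^2))
  sin_tr <- data.frame(increment = seq_along(ab),
                       k_isu = seq(6.666, 0.6666, length.out = length(ab)))
  for (cn in rownames(fs_conc_table)) sin_tr[[cn]] <- 0 * ab
  # calibrate the amplitude so the polyline is twice the straight line
  f <- function(a) {
    y <- a * sin(2 * pi * 6 * ab)
    x <- sin_tr$k_isu
    sum(sqrt(diff(x)^2 + diff(y)^2)) / base_len - 2
  }
  a2 <- stats::uniroot(f, c(0.01, 10))$root
  sin_tr$FC <- a2 * sin(2 * pi * 6 * ab)
  sin_tr$FC <- sin_tr$FC - min(sin_tr$FC)   # keep the profile nonnegative
  sin_tr <- structure(sin_tr, class = c("transition_trace", "data.frame"),
                      mode = "increment", param_name = "k_isu")
  ws2 <- wander_scores(trace_ss = sin_tr)
  expect_equal(unname(ws2$err_ss[["FC"]]), 100, tolerance = 0.01)
})

test_that("smoothness scoring sums normalized increment jumps", {
  n <- 100
  flat <- data.frame(increment = 1:n)
  for (cn in rownames(fs_conc_table)) flat[[cn]] <- rep(100, n)
  flat <- structure(flat, class = c("transition_trace", "data.frame"),
                    mode = "increment", param_name = "k_isu")
  expect_equal(smoothness_score(list(flat)), 0)
  # a single 10% spike in one component costs 100*(0.1 + 1/11)
  spike <- flat
  spike$FM[50] <- 110
  expect_equal(smoothness_score(list(spike)), 100 * (0.1 + 10 / 110),
               tolerance = 1e-10)
})

test_that("n/SP reasonableness penalties follow their branch rules", {
  mk <- function(n, SP) crm(list(mit = heaviside_regulator("FS", n, SP,
                                                           k_reg = 1)))
  expect_equal(n_sp_scores(mk(1, 300), fs_conc_table)$n_Err, 0)
  expect_equal(n_sp_scores(mk(-0.022, 300), fs_conc_table)$n_Err,
               1 / 0.022 - 1, tolerance = 1e-10)
  expect_equal(n_sp_scores(mk(3, 300), fs_conc_table)$n_Err, 2)
  # setpoint at the mean sensor concentration has zero setpoint error
  smean <- mean(fs_conc_table["FS", ])
  expect_equal(n_sp_scores(mk(1, smean), fs_conc_table)$SP_Err, 0)
})

test_that("one-dimensional mean shift separates well-separated groups", {
  x <- c(1.0, 1.1, 1.05, 9.0, 9.2, 9.1)
  cl <- mean_shift_1d(x, bandwidth = 0.5)
  expect_equal(length(unique(cl)), 2)
  expect_equal(cl[1:3], rep(cl[1], 3))
  expect_equal(cl[4:6], rep(cl[4], 3))
  expect_true(all(x[cl == 1] < x[cl == 2]))
})
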