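## Evolutionary selection of cellular regulatory mechanisms (CRMs): the six
## sequential fitness filters (uniqueness, trending, targeting, wandering,
## smoothness, n/SP-reasonableness) over the space of sensor assignments.

#' Size of the CRM candidate space
#'
#' Every regulatable reaction can be sensed by any model component, so the
#' candidate space has `n_sensors ^ n_reactions` CRMs (8^9 = 134,217,728 for
#' the full bundled model; 8^7 = 2,097,152 after the uniqueness filter).
#'
#' @param n_reactions,n_sensors positive integers.
#' @return Numeric count.
#' @export
enumerate_count <- function(n_reactions, n_sensors) {
  stopifnot(n_reactions >= 1, n_sensors >= 1)
  as.numeric(n_sensors)^n_reactions
}

#' Uniqueness filter: which reactions are regulatable
#'
#' A reaction is regulatable when its rate constant takes three pairwise
#' distinct values across the cellular states; a reaction whose constant is
#' shared between states needs no regulation. Reactions named in `lock` are
#' excluded regardless (the bundled model locks `isu`, the primary-mutation
#' reaction, whose constant is assigned rather than regulated).
#'
#' @param states list of three `cell_state_params` (or a 9 x 3 rate-constant
#'   matrix with reaction rownames).
#' @param lock reaction ids never regulated.
#' @param tol relative tolerance for "distinct": constants whose values are
#'   derived from concentrations printed at limited precision can differ by
#'   a fraction of a percent without being biologically distinct.
#' @return Character vector of regulatable reaction ids.
#' @export
filter_uniqueness <- function(states, lock = "isu", tol = 1e-2) {
  k_table <- if (is.matrix(states)) states else
    vapply(states, function(s) s$k[FS_REACTIONS], numeric(9))
  distinct <- apply(k_table, 1, function(v) {
    pairs <- utils::combn(length(v), 2)
    all(apply(pairs, 2, function(ij) {
      a <- v[ij[1]]; b <- v[ij[2]]
      abs(a - b) > tol * max(abs(a), abs(b), 1e-300)
    }))
  })
  setdiff(rownames(k_table)[distinct], lock)
}

#' Trending filter: admissible (sensor, mode) pairs per reaction
#'
#' A sensor is admissible for a reaction when its concentrations across the
#' three states are strictly monotone in the same order as the rate
#' constants (feedforward) or in the strictly opposite order (feedback). A
#' single tie or deviation disqualifies the pairing. The number of surviving
#' CRMs is the product of the per-reaction counts.
#'
#' @param k_table rate-constant matrix, regulatable reactions x states.
#' @param conc_table concentration matrix, 8 sensors x states (same column
#'   order).
#' @return List with `valid` (per-reaction data frame of sensor/mode),
#'   `counts` (per-reaction) and `n_crms` (product).
#' @export
filter_trending <- function(k_table, conc_table) {
  valid <- lapply(rownames(k_table), function(r) {
    ko <- order(k_table[r, ], decreasing = TRUE)
    out <- list()
    for (s in rownames(conc_table)) {
      cs <- conc_table[s, ]
      if (anyDuplicated(cs)) next               # ties violate both trends
      co <- order(cs, decreasing = TRUE)
      if (identical(co, ko))
        out[[length(out) + 1L]] <- data.frame(sensor = s, mode = "feedforward")
      else if (identical(co, rev(ko)))
        out[[length(out) + 1L]] <- data.frame(sensor = s, mode = "feedback")
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(sensor = character(0), mode = character(0))
  })
  names(valid) <- rownames(k_table)
  counts <- vapply(valid, nrow, integer(1))
  list(valid = valid, counts = counts, n_crms = prod(counts))
}

#' Brute-force count of trending survivors
#'
#' Enumerates every sensor assignment over the regulatable reactions and
#' counts those in which all assignments are trending-admissible. Used as an
#' oracle for the product-of-counts shortcut.
#'
#' @param valid per-reaction valid-set list from [filter_trending()].
#' @param sensors sensor labels (default: the 8 components).
#' @return Integer count.
#' @export
brute_force_trending <- function(valid, sensors = FS_COMPONENTS) {
  nr <- length(valid)
  ns <- length(sensors)
  total <- ns^nr
  if (total > 5e7) stop("assignment space too large for brute force")
  mask <- vapply(valid, function(df) sensors %in% df$sensor, logical(ns))
  idx <- seq_len(total) - 1
  acc <- rep(TRUE, total)
  for (r in seq_len(nr)) {
    digit <- (idx %/% ns^(r - 1)) %% ns
    acc <- acc & mask[digit + 1, r]
  }
  sum(acc)
}

#' Fit the pool of logistic regulators
#'
#' One regulator is fitted for every trending-admissible (reaction, sensor)
#' pair from the three (sensor concentration, rate constant) points; pool
#' entries whose fit fails to converge, violates the setpoint bounds, or
#' misses any of the three constants by more than `rel_tol` are excluded
#' with a reason. Candidate CRMs mix and match entries of this pool.
#'
#' @inheritParams filter_trending
#' @param valid per-reaction valid sets from [filter_trending()].
#' @param rel_tol maximum relative curve error at the three points.
#' @return List with `pool` (nested list `pool[[reaction]][[sensor]]` of
#'   regulators) and `table` (fit summary data frame).
#' @export
build_regulator_pool <- function(k_table, conc_table, valid, rel_tol = 0.01) {
  pool <- list()
  rows <- list()
  for (r in names(valid)) {
    pool[[r]] <- list()
    df <- valid[[r]]
    for (i in seq_len(nrow(df))) {
      s <- df$sensor[i]
      reg <- fit_regulator(conc_table[s, ], k_table[r, ])
      reason <- "ok"
      if (is.null(reg)) {
        reason <- "no converged fit"
      } else {
        reg$sensor <- s
        reg$mode <- df$mode[i]
        if (!attr(reg, "ok")) reason <- "curve error > tolerance"
      }
      if (reason == "ok") pool[[r]][[s]] <- reg
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = r, sensor = s, mode = df$mode[i],
        n = if (is.null(reg)) NA else reg$n,
        SP = if (is.null(reg)) NA else reg$SP,
        k_reg = if (is.null(reg)) NA else reg$k_reg,
        k_unreg = if (is.null(reg)) NA else reg$k_unreg,
        residual = if (is.null(reg)) NA else attr(reg, "residual"),
        status = reason)
    }
  }
  list(pool = pool, table = do.call(rbind, rows))
}

## all candidate CRMs from a pool: data frame of sensor assignments
.enumerate_candidates <- function(pool) {
  choices <- lapply(pool, names)
  if (any(lengths(choices) == 0)) return(data.frame())
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  names(grid) <- names(pool)
  grid
}

.crm_from_assignment <- function(assign, pool, label = "candidate") {
  regs <- lapply(names(assign), function(r) pool[[r]][[assign[[r]]]])
  names(regs) <- names(assign)
  crm(regs, label = label)
}

#' Targeting filter
#'
#' Simulates the time-dependent W-to-Y and W-to-D transitions to 50,000 min
#' under each candidate CRM and keeps those for which every component lands
#' within `tol` (relative) of the target state's concentrations.
#'
#' @param candidates data frame of sensor assignments (one column per
#'   regulatable reaction).
#' @param pool regulator pool from [build_regulator_pool()].
#' @param w_params,w_conc the starting (W) state and its steady state.
#' @param transitions named list; each element has `trigger` (parameter
#'   overrides) and `target` (target profile).
#' @param tol maximum relative targeting error (default 1%).
#' @param t_end settling horizon, min.
#' @return List with `errors` (matrix, candidates x transitions, max relative
#'   error; `NA` = integration failure) and `survivors` (row indices).
#' @export
filter_targeting <- function(candidates, pool, w_params, w_conc, transitions,
                             tol = 0.01, t_end = FS_T_STEADY) {
  n <- nrow(candidates)
  errs <- matrix(NA_real_, n, length(transitions),
                 dimnames = list(NULL, names(transitions)))
  for (i in seq_len(n)) {
    cr <- .crm_from_assignment(candidates[i, , drop = FALSE], pool)
    for (tn in names(transitions)) {
      tr <- transitions[[tn]]
      end <- tryCatch({
        pp <- .apply_trigger(w_params, tr$trigger)
        steady_state(pp, w_conc, crm = cr, t_end = t_end)
      }, error = function(e) NULL)
      if (!is.null(end))
        errs[i, tn] <- max(abs(end - tr$target) / tr$target)
    }
  }
  ok <- apply(errs, 1, function(e) all(is.finite(e)) && all(e <= tol))
  list(errors = errs, survivors = which(ok))
}

## polyline arc length of columns of a matrix against an abscissa
.arc_lengths <- function(abscissa, mat) {
  da <- diff(abscissa)
  apply(mat, 2, function(col) sum(sqrt(da^2 + diff(col)^2)))
}

.arc_min <- function(abscissa, mat) {
  da <- abscissa[length(abscissa)] - abscissa[1]
  apply(mat, 2, function(col) sqrt(da^2 + (col[length(col)] - col[1])^2))
}

#' Wandering scores of a transition
#'
#' Arc-length-based measure of how far a transition deviates from a straight
#' path. For a time trace the coordinates are (t, C_i) over the first 5000
#' min; for a steady-state trace they are (trigger parameter, C_i) over the
#' increments. The error per component is
#' `(AL - AL_min)/AL_min * 100` with `AL_min` the straight-line endpoint
#' distance in the same coordinates.
#'
#' @param trace_time `transition_trace` in time mode (already restricted to
#'   the wandering horizon).
#' @param trace_ss `transition_trace` in increment mode.
#' @return List with per-component `AL_t`, `AL_ss`, `err_time`, `err_ss`.
#' @export
wander_scores <- function(trace_time = NULL, trace_ss = NULL) {
  out <- list()
  if (!is.null(trace_time)) {
    m <- as.matrix(as.data.frame(trace_time)[, FS_COMPONENTS])
    al <- .arc_lengths(trace_time$time, m)
    almin <- .arc_min(trace_time$time, m)
    out$AL_t <- al
    out$err_time <- (al - almin) / almin * 100
  }
  if (!is.null(trace_ss)) {
    pn <- attr(trace_ss, "param_name")
    if (is.null(pn)) stop("trace_ss lacks a trigger-parameter column")
    m <- as.matrix(as.data.frame(trace_ss)[, FS_COMPONENTS])
    al <- .arc_lengths(trace_ss[[pn]], m)
    almin <- .arc_min(trace_ss[[pn]], m)
    if (!is.null(attr(trace_ss, "converged")) &&
        !all(attr(trace_ss, "converged")))
      al[] <- NA_real_                      # non-convergent increment: invalid
    out$AL_ss <- al
    out$err_ss <- (al - almin) / almin * 100
  }
  out
}

#' Smoothness error of a pair of steady-state transitions
#'
#' Sums the normalized increment-to-increment jumps of every component over
#' both steady-state transitions:
#' `Sm_Err = sum_i 100 sum_{j=1..99} |C_i(j) - C_i(j+1)| / C_i(j)`,
#' accumulated for the W-to-Y and W-to-D traces. Concentrations below
#' `floor_eps` are floored in the denominator.
#'
#' @param ss_traces list of increment-mode `transition_trace`s.
#' @param floor_eps denominator floor, uM.
#' @return Scalar smoothness error.
#' @export
smoothness_score <- function(ss_traces, floor_eps = 1e-6) {
  total <- 0
  for (tr in ss_traces) {
    m <- as.matrix(as.data.frame(tr)[, FS_COMPONENTS])
    steps <- abs(diff(m)) / pmax(m[-nrow(m), , drop = FALSE], floor_eps)
    total <- total + 100 * sum(steps)
  }
  total
}

#' Sensitivity and setpoint reasonableness scores of a CRM
#'
#' `n_Err` penalizes regulator sensitivities away from 1 (`|n| - 1` for
#' `|n| > 1`, `|1/n| - 1` for `|n| < 1`; `n = 0` is infinite). `SP_Err` sums
#' the relative deviations of each setpoint from the mean sensor
#' concentration across the three states.
#'
#' @param crm a fitted [crm()].
#' @param conc_table 8 x 3 concentration matrix (sensors x states).
#' @return List with `n_Err` and `SP_Err`.
#' @export
n_sp_scores <- function(crm, conc_table) {
  n_err <- 0; sp_err <- 0
  for (reg in crm$regulators) {
    an <- abs(reg$n)
    n_err <- n_err + if (an == 0) Inf else if (an > 1) an - 1 else 1 / an - 1
    smean <- mean(conc_table[reg$sensor, ])
    sp_err <- sp_err + abs(reg$SP - smean) / smean
  }
  list(n_Err = n_err, SP_Err = sp_err)
}

#' One-dimensional mean-shift clustering
#'
#' Gaussian-kernel mean shift on a numeric vector; points whose modes
#' coincide (within `bandwidth/2`) share a cluster.
#'
#' @param x numeric vector.
#' @param bandwidth kernel bandwidth; default Silverman's rule
#'   ([stats::bw.nrd0()]).
#' @param max_iter,tol iteration controls.
#' @return Integer cluster labels (1 = cluster with the smallest values).
#' @export
mean_shift_1d <- function(x, bandwidth = NULL, max_iter = 500, tol = 1e-10) {
  if (length(x) == 1) return(1L)
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(x)
  if (bandwidth <= 0) bandwidth <- diff(range(x)) / 10 + 1e-12
  modes <- vapply(x, function(y) {
    for (it in seq_len(max_iter)) {
      w <- exp(-0.5 * ((y - x) / bandwidth)^2)
      y2 <- sum(w * x) / sum(w)
      if (abs(y2 - y) < tol) break
      y <- y2
    }
    y
  }, numeric(1))
  centers <- sort(unique(round(modes / (bandwidth / 2))))
  labels <- match(round(modes / (bandwidth / 2)), centers)
  as.integer(labels)
}

#' Run the six-filter evolutionary screen
#'
#' Executes the full cascade on a model bundle: uniqueness, trending,
#' regulator fitting, targeting (time-dependent transitions to the Y and D
#' states), wandering (intersection of the lowest-error halves for time and
#' steady-state transitions), smoothness (mean-shift clustering of the
#' scores) and n/SP-reasonableness scoring.
#'
#' @param bundle a `model_bundle` (default: the packaged yeast model).
#' @param n_increments increments of the steady-state transitions.
#' @param wander_horizon time horizon of the wandering arc length, min.
#' @param targeting_tol targeting tolerance (relative).
#' @param time_grid_dt output spacing of the wandering time traces, min.
#' @param wander_grouping how the two lowest-error halves are formed before
#'   intersecting: `"mode"` (default) ranks by time-mode and steady-state-mode
#'   wandering error, each averaged over both transitions; `"transition"`
#'   ranks by per-transition error averaged over the two modes.
#' @param verbose print per-stage progress.
#' @param checkpoint_dir optional directory for per-stage CSV checkpoints.
#' @return An object of class `filter_report`: stage `counts`, the
#'   regulatable set, trending sets, pool table, per-candidate scores, and
#'   the surviving CRMs with fitted regulators.
#' @export
evolve_crms <- function(bundle = load_bundle(), n_increments = 100,
                        wander_horizon = 5000, targeting_tol = 0.01,
                        time_grid_dt = 5,
                        wander_grouping = c("mode", "transition"),
                        verbose = interactive(), checkpoint_dir = NULL) {
  wander_grouping <- match.arg(wander_grouping)
  say <- function(...) if (verbose) message(...)
  ckpt <- function(name, df) {
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(df, file.path(checkpoint_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }

  st <- lapply(c(W = "W", Y = "Y", D = "D"), state_parameterization,
               bundle = bundle)
  conc_table <- vapply(st, function(x) x$conc, numeric(8))
  rownames(conc_table) <- FS_COMPONENTS
  k_full <- vapply(st, function(x) x$params$k, numeric(9))
  rownames(k_full) <- FS_REACTIONS

  counts <- c(enumeration = enumerate_count(9, 8))
  regulatable <- filter_uniqueness(lapply(st, `[[`, "params"))
  counts["uniqueness"] <- enumerate_count(length(regulatable), 8)
  say("uniqueness: ", length(regulatable), " regulatable reactions -> ",
      counts["uniqueness"], " CRMs")

  k_table <- k_full[regulatable, , drop = FALSE]
  trend <- filter_trending(k_table, conc_table)
  counts["trending"] <- trend$n_crms
  say("trending: ", trend$n_crms, " CRMs (per-reaction counts: ",
      paste(trend$counts, collapse = ", "), ")")

  fitted <- build_regulator_pool(k_table, conc_table, trend$valid)
  ckpt("pool", fitted$table)
  say("pool: ", sum(fitted$table$status == "ok"), " of ",
      nrow(fitted$table), " regulators fitted")

  candidates <- .enumerate_candidates(fitted$pool)
  w_params <- st$W$params
  w_conc <- st$W$conc
  transitions <- list(
    WY = list(trigger = list(k_isu = st$Y$params$k[["isu"]],
                             alpha = st$Y$params$alpha),
              target = st$Y$conc,
              to = list(k_isu = st$Y$params$k[["isu"]])),
    WD = list(trigger = list(IRON = st$D$params$IRON),
              target = st$D$conc,
              to = list(IRON = st$D$params$IRON)))

  targ <- filter_targeting(candidates, fitted$pool, w_params, w_conc,
                           transitions, tol = targeting_tol)
  counts["targeting"] <- length(targ$survivors)
  scores <- cbind(candidates,
                  target_err_WY = targ$errors[, "WY"],
                  target_err_WD = targ$errors[, "WD"])
  ckpt("targeting", scores)
  say("targeting: ", counts["targeting"], " survivors")

  ## --- wandering ---------------------------------------------------------
  surv <- targ$survivors
  times <- seq(0, wander_horizon, by = time_grid_dt)
  werr <- matrix(NA_real_, nrow(candidates), 4,
                 dimnames = list(NULL, c("time.WY", "time.WD",
                                         "ss.WY", "ss.WD")))
  ss_traces <- vector("list", nrow(candidates))
  for (i in surv) {
    cr <- .crm_from_assignment(candidates[i, , drop = FALSE], fitted$pool)
    ss_i <- list()
    okc <- TRUE
    for (tn in names(transitions)) {
      tr <- transitions[[tn]]
      tt <- tryCatch(
        time_transition(w_params, w_conc, tr$trigger, crm = cr,
                        t_end = wander_horizon, times = times, with_k = FALSE),
        error = function(e) NULL)
      sst <- tryCatch(
        steady_state_transition(w_params, w_conc, tr$to, crm = cr,
                                n_increments = n_increments, with_k = FALSE),
        error = function(e) NULL)
      if (is.null(tt) || is.null(sst)) { okc <- FALSE; break }
      ws <- wander_scores(tt, sst)
      if (any(!is.finite(ws$err_ss))) { okc <- FALSE; break }
      werr[i, paste0("time.", tn)] <- mean(ws$err_time)
      werr[i, paste0("ss.", tn)] <- mean(ws$err_ss)
      ss_i[[tn]] <- sst
    }
    if (okc) ss_traces[[i]] <- ss_i else werr[i, ] <- NA_real_
  }
  ## two rankings whose lowest halves are intersected
  if (wander_grouping == "mode") {
    rank_a <- rowMeans(werr[, c("time.WY", "time.WD"), drop = FALSE])
    rank_b <- rowMeans(werr[, c("ss.WY", "ss.WD"), drop = FALSE])
  } else {
    rank_a <- rowMeans(werr[, c("time.WY", "ss.WY"), drop = FALSE])
    rank_b <- rowMeans(werr[, c("time.WD", "ss.WD"), drop = FALSE])
  }
  half <- ceiling(length(surv) / 2)
  best_a <- surv[order(rank_a[surv])][seq_len(half)]
  best_b <- surv[order(rank_b[surv])][seq_len(half)]
  wander_surv <- sort(intersect(best_a, best_b))
  wander_surv <- wander_surv[is.finite(rank_a[wander_surv]) &
                             is.finite(rank_b[wander_surv])]
  counts["wandering"] <- length(wander_surv)
  scores <- cbind(scores, wander_err = werr)
  scores$wander_err_time <- rowMeans(werr[, 1:2, drop = FALSE])
  scores$wander_err_ss <- rowMeans(werr[, 3:4, drop = FALSE])
  ckpt("wandering", scores)
  say("wandering: ", counts["wandering"],
      " CRMs in the intersection of the two best halves")

  ## --- smoothness --------------------------------------------------------
  sm <- rep(NA_real_, nrow(candidates))
  for (i in wander_surv) sm[i] <- smoothness_score(ss_traces[[i]])
  scores$smooth_err <- sm
  cl <- mean_shift_1d(log10(sm[wander_surv]))
  ## the cluster holding the smoothest (lowest-score) case wins
  top <- wander_surv[cl == cl[which.min(sm[wander_surv])]]
  counts["smoothness"] <- length(top)
  ckpt("smoothness", scores)
  say("smoothness: top cluster of ", length(top), " case(s)")

  ## --- n/SP reasonableness ------------------------------------------------
  finals <- lapply(top, function(i)
    .crm_from_assignment(candidates[i, , drop = FALSE], fitted$pool,
                         label = paste0("survivor_", i)))
  nsp <- t(vapply(finals, function(cr)
    unlist(n_sp_scores(cr, conc_table)), numeric(2)))
  scores$n_err <- scores$sp_err <- NA_real_
  scores$n_err[top] <- nsp[, "n_Err"]
  scores$sp_err[top] <- nsp[, "SP_Err"]
  ord <- order(nsp[, "n_Err"] + nsp[, "SP_Err"])
  finals <- finals[ord]
  counts["n_sp"] <- length(finals)
  ckpt("final_scores", scores)

  structure(list(counts = counts, regulatable = regulatable,
                 trending = trend, pool = fitted,
                 candidates = candidates, scores = scores,
                 targeting_survivors = surv,
                 wandering_survivors = wander_surv,
                 smoothness_survivors = top[ord],
                 survivors = finals,
                 conc_table = conc_table, k_table = k_table),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> cascade:\n")
  print(x$counts)
  cat("surviving CRMs:\n")
  for (cr in x$survivors) print(cr)
  invisible(x)
}
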