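#' Stimulus protocol for the adaptation assay
#'
#' The input is held at `I1` until the system reaches its pre-stimulus
#' steady state, then stepped to `I2` and held there. Defaults follow the
#' standard chemotaxis assay: a 0.5 to 0.6 step (a 20% relative input
#' change).
#'
#' @param I1 Pre-stimulus input level (> 0). Default 0.5.
#' @param I2 Post-stimulus input level (!= I1). Default 0.6.
#' @return A list of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(I1 = 0.5, I2 = 0.6) {
  stopifnot(I1 > 0, I2 != I1)
  structure(list(I1 = I1, I2 = I2), class = "stimulus_protocol")
}

#' Trajectory-rejection thresholds
#'
#' Parameter sets whose dynamics are pathological are discarded before
#' scoring: vanishing steady states, persistent or weakly damped
#' oscillations, and transients that do not settle within the simulation
#' budget. The category names are fixed; these thresholds decide the
#' boundaries.
#'
#' @param tiny_ss Steady-state floor: `TINY_STEADY_STATE` when any node's
#'   pre- or post-stimulus steady-state value falls below it. Default
#'   `0.01`, calibrated so the fraction of sets surviving all filters
#'   matches the ~47% acceptance rate characteristic of this screen.
#' @param tol_ss Infinity-norm derivative tolerance defining a steady state.
#'   Default `1e-9`.
#' @param t_max Transient budget in dimensionless time units; settling past
#'   it is `LONG_TRANSIENT`. Default `1e4`.
#' @param settle_tol A trajectory has settled once every state stays within
#'   this distance of its final value. Default `1e-4`.
#' @param osc_floor Peak-to-peak amplitude below which residual oscillation
#'   is ignored. Default `1e-4`.
#' @param rtol,atol Relative and absolute integrator tolerances (stiff-capable
#'   lsoda). Defaults `1e-8`, `1e-10`.
#' @param n_grid Number of output points on the logarithmic time grid used
#'   to resolve the transient. Default 300.
#' @return A list of class `rejection_thresholds`.
#' @export
rejection_thresholds <- function(tiny_ss = 0.01, tol_ss = 1e-9, t_max = 1e4,
                                 settle_tol = 1e-4, osc_floor = 1e-4,
                                 rtol = 1e-8, atol = 1e-10, n_grid = 300) {
  structure(list(tiny_ss = tiny_ss, tol_ss = tol_ss, t_max = t_max,
                 settle_tol = settle_tol, osc_floor = osc_floor,
                 rtol = rtol, atol = atol, n_grid = n_grid),
            class = "rejection_thresholds")
}

#' Criteria defining a kinetic solution
#'
#' A screened parameter set is a kinetic solution when its step response is
#' both sensitive and precise: sensitivity strictly above `sensitivity` and
#' precision strictly above `precision`. At the default 0.5 to 0.6 stimulus
#' these bounds demand a peak excursion of at least 20% of the pre-stimulus
#' output and a final return to within 2% of it.
#'
#' @param sensitivity Strict lower bound on the sensitivity score. Default 1.
#' @param precision Strict lower bound on the precision score. Default 10.
#' @return A list of class `solution_criteria`.
#' @export
solution_criteria <- function(sensitivity = 1, precision = 10) {
  structure(list(sensitivity = sensitivity, precision = precision),
            class = "solution_criteria")
}

# one deSolve integration; returns the deSolve matrix or NULL on breakdown
ode_run <- function(model, params, input, y0, times, thresholds) {
  args <- model_desolve_args(model, params, input)
  out <- tryCatch(suppressWarnings({
    if (isTRUE(model$compiled)) {
      deSolve::ode(y = unname(y0), times = times, func = args$func,
                   parms = args$parms, dllname = args$dllname,
                   initfunc = args$initfunc, method = "lsoda",
                   rtol = thresholds$rtol, atol = thresholds$atol)
    } else {
      deSolve::ode(y = unname(y0), times = times, func = args$func,
                   parms = NULL, method = "lsoda",
                   rtol = thresholds$rtol, atol = thresholds$atol)
    }
  }), error = function(e) NULL)
  if (is.null(out)) return(NULL)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) return(NULL)
  if (nrow(out) < length(times) || !all(is.finite(out))) return(NULL)
  out
}

# damped Newton iteration on the rate equations; numeric 3x3 Jacobian
newton_root <- function(model, params, input, guess, tol, max_iter = 60) {
  nodes <- model$topology$nodes
  f <- make_rate_fn(model, params, input)
  x <- unname(guess[nodes])
  for (iter in seq_len(max_iter)) {
    fx <- f(x)
    if (!all(is.finite(fx))) return(NULL)
    if (max(abs(fx)) < tol) {
      J <- numeric_jacobian(f, x)
      if (is.null(J)) return(NULL)
      stable <- all(Re(eigen(J, only.values = TRUE)$values) < 0)
      return(list(state = setNames(x, nodes), stable = stable))
    }
    J <- numeric_jacobian(f, x)
    if (is.null(J)) return(NULL)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    # damp large steps; the state space is the unit cube
    nrm <- max(abs(step))
    if (nrm > 0.5) step <- step * (0.5 / nrm)
    x <- x - step
    if (any(x < -0.05) || any(x > 1.05)) return(NULL)
    x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  }
  NULL
}

numeric_jacobian <- function(f, x, h = 1e-7) {
  n <- length(x)
  J <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h
    hi <- f(x + e); lo <- f(x - e)
    if (!all(is.finite(hi)) || !all(is.finite(lo))) return(NULL)
    J[, j] <- (hi - lo) / (2 * h)
  }
  J
}

#' Find a stable steady state of the network at a fixed input
#'
#' Tries Newton root-finding on the rate equations first (with stability
#' judged from the eigenvalues of the numeric Jacobian); when the root
#' search fails, leaves the unit cube, or lands on an unstable root, falls
#' back to long-horizon integration from the initial guess over successively
#' longer windows.
#'
#' @inheritParams rate_of_change
#' @param input_level Input held constant during relaxation (> 0).
#' @param initial_guess Starting state. Default the cube centre.
#' @param thresholds A [rejection_thresholds()]; `tol_ss` defines
#'   convergence, `t_max` scales the integration budget.
#' @return A list: `state` (named vector), `stable`, `converged`, `method`
#'   (`"newton"` or `"integration"`), `oscillating` (TRUE when the fallback
#'   integration kept oscillating above the amplitude floor instead of
#'   settling), and `trajectory` (tibble of the last integration window, or
#'   NULL when Newton succeeded).
#' @export
find_steady_state <- function(model, params, input_level,
                              initial_guess = c(A = 0.5, B = 0.5, C = 0.5),
                              thresholds = rejection_thresholds()) {
  stopifnot(input_level > 0)
  nodes <- model$topology$nodes
  root <- newton_root(model, params, input_level, initial_guess,
                      thresholds$tol_ss)
  if (!is.null(root) && root$stable) {
    return(list(state = root$state, stable = TRUE, converged = TRUE,
                method = "newton", oscillating = FALSE, trajectory = NULL))
  }
  # fall back to relaxation by integration over doubling horizons
  y <- unname(initial_guess[nodes])
  horizons <- 10^seq(2, log10(thresholds$t_max) + 2)
  traj <- NULL
  for (t_end in horizons) {
    times <- c(0, 10^seq(-2, log10(t_end), length.out = 200))
    out <- ode_run(model, params, input_level, y, times, thresholds)
    if (is.null(out)) {
      return(list(state = setNames(rep(NA_real_, length(nodes)), nodes),
                  stable = FALSE, converged = FALSE, method = "integration",
                  oscillating = FALSE, trajectory = traj))
    }
    y <- out[nrow(out), -1]
    traj <- tibble::as_tibble(as.data.frame(out))
    names(traj) <- c("time", nodes)
    fy <- rate_of_change(model, setNames(y, nodes), params,
                         input = input_level)
    if (max(abs(fy)) < thresholds$tol_ss) {
      polished <- newton_root(model, params, input_level, setNames(y, nodes),
                              thresholds$tol_ss)
      state <- if (!is.null(polished)) polished$state else setNames(y, nodes)
      stable <- if (!is.null(polished)) polished$stable else TRUE
      return(list(state = state, stable = stable, converged = TRUE,
                  method = "integration", oscillating = FALSE,
                  trajectory = traj))
    }
  }
  osc <- oscillation_amplitudes(traj$time, traj[[model$topology$output_node]])
  oscillating <- length(osc) >= 2 && max(osc) >= thresholds$osc_floor
  list(state = setNames(y, nodes), stable = FALSE, converged = FALSE,
       method = "integration", oscillating = oscillating, trajectory = traj)
}

# peak-to-peak amplitudes between successive local extrema of x(t)
oscillation_amplitudes <- function(time, x) {
  dx <- diff(x)
  s <- sign(dx)
  s <- s[s != 0]
  if (length(s) < 2) return(numeric(0))
  ext <- which(diff(sign(diff(x))) != 0) + 1
  if (length(ext) < 2) return(numeric(0))
  abs(diff(x[ext]))
}

#' Simulate the step response of the network
#'
#' Relaxes the network to its steady state at `I1`, switches the input to
#' `I2`, and integrates the transient on a logarithmically spaced time grid
#' dense enough to resolve the response peak. Summary quantities follow the
#' adaptation literature: `O1` is the pre-stimulus output (node C), `Op` the
#' output at the extremum of `|C(t) - O1|`, and `O2` the post-stimulus
#' steady state.
#'
#' @inheritParams find_steady_state
#' @param protocol A [stimulus_protocol()].
#' @return An object of class `step_response`: list with `O1`, `Op`, `O2`,
#'   `settle_time`, `trajectory` (tibble `time`, one column per node),
#'   `protocol`, plus status fields (`pre_converged`, `pre_oscillating`,
#'   `post_converged`, `numerical_failure`) consumed by
#'   [classify_outcome()].
#' @export
simulate_step_response <- function(model, params, protocol = stimulus_protocol(),
                                   thresholds = rejection_thresholds(),
                                   initial_guess = c(A = 0.5, B = 0.5, C = 0.5)) {
  nodes <- model$topology$nodes
  outn <- model$topology$output_node
  res <- list(O1 = NA_real_, Op = NA_real_, O2 = NA_real_,
              settle_time = NA_real_, trajectory = NULL, protocol = protocol,
              pre_state = NULL, post_state = NULL,
              pre_converged = FALSE, pre_oscillating = FALSE,
              post_converged = FALSE, numerical_failure = FALSE)
  class(res) <- "step_response"

  ss1 <- find_steady_state(model, params, protocol$I1, initial_guess,
                           thresholds)
  if (!ss1$converged) {
    res$pre_oscillating <- ss1$oscillating
    res$numerical_failure <- is.null(ss1$trajectory) && !ss1$oscillating &&
      any(!is.finite(ss1$state))
    return(res)
  }
  res$pre_converged <- TRUE
  res$pre_state <- ss1$state
  res$O1 <- ss1$state[[outn]]

  times <- c(0, 10^seq(-2, log10(thresholds$t_max),
                       length.out = thresholds$n_grid))
  out <- ode_run(model, params, protocol$I2, ss1$state, times, thresholds)
  if (is.null(out)) {
    res$numerical_failure <- TRUE
    return(res)
  }
  traj <- tibble::as_tibble(as.data.frame(out))
  names(traj) <- c("time", nodes)
  res$trajectory <- traj
  x <- traj[[outn]]

  # peak of |C(t) - O1| with local quadratic refinement of the sampled max
  dev <- abs(x - res$O1)
  i <- which.max(dev)
  res$Op <- x[i]
  if (i > 1 && i < length(x)) {
    fit <- tryCatch(stats::lm(y ~ poly(t, 2, raw = TRUE),
                              data = data.frame(t = traj$time[(i - 1):(i + 1)],
                                                y = x[(i - 1):(i + 1)])),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      if (is.finite(cf[3]) && cf[3] != 0) {
        tv <- -cf[2] / (2 * cf[3])
        if (tv > traj$time[i - 1] && tv < traj$time[i + 1]) {
          pv <- unname(cf[1] + cf[2] * tv + cf[3] * tv^2)
          if (abs(pv - res$O1) > dev[i]) res$Op <- pv
        }
      }
    }
  }

  # post-stimulus steady state: polish the trajectory endpoint
  yend <- setNames(as.numeric(traj[nrow(traj), nodes]), nodes)
  root <- newton_root(model, params, protocol$I2, yend, thresholds$tol_ss)
  if (!is.null(root) && root$stable) {
    res$post_converged <- TRUE
    res$post_state <- root$state
    res$O2 <- root$state[[outn]]
    ref <- root$state
  } else {
    fy <- rate_of_change(model, yend, params, input = protocol$I2)
    if (max(abs(fy)) < sqrt(thresholds$tol_ss)) {
      res$post_converged <- TRUE
      res$post_state <- yend
      res$O2 <- yend[[outn]]
    }
    ref <- yend
  }

  # settling: first grid time after which every state stays within
  # settle_tol of the post-step steady state
  devs <- apply(abs(sweep(as.matrix(traj[nodes]), 2, unname(ref[nodes]))),
                1, max)
  sup <- rev(cummax(rev(devs)))
  idx <- which(sup < thresholds$settle_tol)
  res$settle_time <- if (length(idx) > 0) traj$time[idx[1]] else Inf
  res
}

#' Classify a simulated step response
#'
#' Applies the trajectory-rejection rules in order: numerical breakdown,
#' failure to reach a pre-stimulus steady state (oscillatory or not),
#' vanishing steady states, sustained or weakly damped oscillation of the
#' output after the initial excursion, and transients that fail to settle
#' within the budget. Responses passing all filters are `OK`.
#'
#' @param summary A `step_response` (or a list with the same fields, which
#'   lets constructed trajectories be classified directly).
#' @param thresholds A [rejection_thresholds()].
#' @return A single string, one of `"OK"`, `"TINY_STEADY_STATE"`,
#'   `"PERSISTENT_OSCILLATION"`, `"WEAKLY_DAMPED_OSCILLATION"`,
#'   `"LONG_TRANSIENT"`, `"NO_CONVERGENCE"`, `"NUMERICAL_FAILURE"`.
#' @export
classify_outcome <- function(summary, thresholds = rejection_thresholds()) {
  g <- function(field, default) {
    if (!is.null(summary[[field]])) summary[[field]] else default
  }
  if (isTRUE(g("numerical_failure", FALSE))) return("NUMERICAL_FAILURE")
  if (!isTRUE(g("pre_converged", TRUE))) {
    if (isTRUE(g("pre_oscillating", FALSE))) return("PERSISTENT_OSCILLATION")
    return("NO_CONVERGENCE")
  }
  O1 <- summary$O1
  O2 <- summary$O2
  if (!isTRUE(g("post_converged", TRUE)) || !is.finite(O2)) {
    # no settled post-stimulus state: decide between oscillation and
    # a transient that simply never converged
    osc <- post_peak_oscillation(summary, thresholds)
    if (!is.na(osc)) return(osc)
    return("NO_CONVERGENCE")
  }
  # "extremely small steady-state values" is read across all nodes: a
  # network whose receptor or buffer node has collapsed is as degenerate
  # as one with a silent output
  pre_min <- if (!is.null(summary$pre_state)) min(summary$pre_state) else O1
  post_min <- if (!is.null(summary$post_state)) min(summary$post_state) else O2
  if (min(pre_min, O1) < thresholds$tiny_ss ||
      min(post_min, O2) < thresholds$tiny_ss) {
    return("TINY_STEADY_STATE")
  }
  osc <- post_peak_oscillation(summary, thresholds)
  if (!is.na(osc)) return(osc)
  st <- g("settle_time", NA_real_)
  if (!is.finite(st) || st > thresholds$t_max) return("LONG_TRANSIENT")
  "OK"
}

# oscillation call on the output trajectory restricted to times after twice
# the initial excursion; NA when no oscillatory rejection applies
post_peak_oscillation <- function(summary, thresholds) {
  traj <- summary$trajectory
  if (is.null(traj)) return(NA_character_)
  outn <- if (!is.null(summary$output_node)) summary$output_node else
    setdiff(names(traj), "time")[length(setdiff(names(traj), "time"))]
  x0 <- traj[[outn]]
  t0 <- traj$time
  O1 <- summary$O1
  t_peak <- t0[which.max(abs(x0 - O1))]
  keep <- t0 >= 2 * t_peak
  if (sum(keep) < 4) return(NA_character_)
  t <- t0[keep]; x <- x0[keep]
  amps <- oscillation_amplitudes(t, x)
  if (length(amps) < 2 || max(amps) < thresholds$osc_floor) {
    return(NA_character_)
  }
  # compare amplitude envelopes of the early and late halves of the
  # window; sparse sampling aliases fast oscillations, so single-extremum
  # comparisons are unreliable while the half-window maxima are not
  n <- length(amps)
  early <- max(amps[seq_len(ceiling(n / 2))])
  late <- max(amps[(ceiling(n / 2) + 1):n])
  if (late >= early * 0.95) return("PERSISTENT_OSCILLATION")
  if (late >= thresholds$osc_floor) return("WEAKLY_DAMPED_OSCILLATION")
  NA_character_
}

#' Sensitivity score of a step response
#'
#' Relative peak excursion of the output normalised by the relative input
#' change:
#' \deqn{S = \frac{|O_p - O_1| / O_1}{|I_2 - I_1| / I_1}.}
#' At the default 0.5 to 0.6 protocol a score of 1 corresponds to a 20%
#' relative peak excursion.
#'
#' @param O1 Pre-stimulus steady-state output (> 0).
#' @param Op Peak output of the transient.
#' @param protocol A [stimulus_protocol()].
#' @return Non-negative score; `NaN` when `O1 <= 0` (such sets must already
#'   carry the `TINY_STEADY_STATE` label).
#' @export
sensitivity_score <- function(O1, Op, protocol = stimulus_protocol()) {
  rel_in <- abs(protocol$I2 - protocol$I1) / protocol$I1
  out <- (abs(Op - O1) / O1) / rel_in
  out[O1 <= 0] <- NaN
  out
}

#' Precision score of a step response
#'
#' Inverse of the relative steady-state shift normalised by the relative
#' input change:
#' \deqn{P = \left(\frac{|O_2 - O_1| / O_1}{|I_2 - I_1| / I_1}\right)^{-1}.}
#' Perfect adaptation (`O2 == O1`) scores `+Inf`. At the default protocol a
#' score of 10 corresponds to a 2% relative steady-state shift.
#'
#' @param O1 Pre-stimulus steady-state output (> 0).
#' @param O2 Post-stimulus steady-state output.
#' @inheritParams sensitivity_score
#' @return Non-negative score, possibly `Inf`; `NaN` when `O1 <= 0`.
#' @export
precision_score <- function(O1, O2, protocol = stimulus_protocol()) {
  rel_in <- abs(protocol$I2 - protocol$I1) / protocol$I1
  rel <- (abs(O2 - O1) / O1) / rel_in
  out <- ifelse(rel == 0, Inf, 1 / rel)
  out[O1 <= 0] <- NaN
  out
}

#' Is a scored parameter set a kinetic solution?
#'
#' Strict comparisons against the solution criteria: sensitivity must exceed
#' the sensitivity bound AND precision the precision bound. An infinite
#' precision (perfect adaptation) passes.
#'
#' @param sensitivity,precision Numeric score vectors.
#' @param criteria A [solution_criteria()].
#' @return Logical vector; `NA` scores give `FALSE`.
#' @export
is_kinetic_solution <- function(sensitivity, precision,
                                criteria = solution_criteria()) {
  ok <- sensitivity > criteria$sensitivity & precision > criteria$precision
  ok[is.na(ok)] <- FALSE
  ok
}

#' @export
print.step_response <- function(x, ...) {
  cat("<step_response> O1 =", format(x$O1), " Op =", format(x$Op),
      " O2 =", format(x$O2), " settle_time =", format(x$settle_time), "\n")
  invisible(x)
}

#' @export
tidy.step_response <- function(x, ...) {
  x$trajectory
}

#' @export
glance.step_response <- function(x, ...) {
  tibble(O1 = x$O1, Op = x$Op, O2 = x$O2, settle_time = x$settle_time,
         sensitivity = sensitivity_score(x$O1, x$Op, x$protocol),
         precision = precision_score(x$O1, x$O2, x$protocol))
}
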