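test_that("steady-state finder recovers the symmetric equilibrium", {
  p <- all_ones_params()
  ss <- find_steady_state(nfblb, p, 0.5)
  expect_true(ss$converged)
  expect_true(ss$stable)
  expect_equal(ss$state, c(A = 0.5, B = 0.5, C = 0.5), tolerance = 1e-8)
  # basin convergence: a distant initial guess reaches the same state
  ss2 <- find_steady_state(nfblb, p, 0.5,
                           initial_guess = c(A = 0.9, B = 0.9, C = 0.9))
  expect_equal(ss2$state, ss$state, tolerance = 1e-6)
})

test_that("root-finding and long-horizon integration agree on random sets", {
  set.seed(23)
  checked <- 0
  while (checked < 100) {
    p <- random_params()
    ss_n <- find_steady_state(nfblb, p, 0.5)
    if (!(ss_n$converged && ss_n$method == "newton")) next
    # independent route: pure relaxation by integration from the guess
    th <- rejection_thresholds()
    y <- c(A = 0.5, B = 0.5, C = 0.5)
    out <- kinmotif:::ode_run(nfblb, p, 0.5, y,
                              c(0, 10^seq(-2, 6, length.out = 300)), th)
    if (is.null(out)) next
    yend <- setNames(out[nrow(out), 2:4], c("A", "B", "C"))
    f <- rate_of_change(nfblb, yend, p, input = 0.5)
    if (max(abs(f)) > 1e-9) next # did not settle (oscillatory/slow): skip
    expect_equal(unname(yend), unname(ss_n$state), tolerance = 1e-5)
    checked <- checked + 1
  }
  expect_equal(checked, 100)
})

test_that("step response of the symmetric system behaves as derived", {
  p <- all_ones_params()
  sr <- simulate_step_response(nfblb, p)
  expect_s3_class(sr, "step_response")
  expect_equal(sr$O1, 0.5, tolerance = 1e-8)
  expect_identical(sr$protocol$I1, 0.5)
  expect_identical(sr$protocol$I2, 0.6)
  # the response overshoots slightly before settling; expected values from
  # a dense fixed-grid integration oracle (dt = 1e-3, rtol 1e-10)
  expect_equal(sr$Op, 0.5324828, tolerance = 1e-4)
  expect_equal(sr$O2, 0.5321389, tolerance = 1e-6)
  expect_gte(sr$Op, sr$O2)
  expect_equal(classify_outcome(sr), "OK")
  g <- glance(sr)
  expect_equal(g$sensitivity,
               sensitivity_score(sr$O1, sr$Op, sr$protocol))
})

test_that("outcome classification follows the rejection rules", {
  th <- rejection_thresholds()
  mk <- function(trajectory, O1, O2, settle_time, ...) {
    c(list(trajectory = trajectory, O1 = O1, O2 = O2,
           settle_time = settle_time, pre_converged = TRUE,
           post_converged = TRUE, numerical_failure = FALSE,
           output_node = "C"), list(...))
  }
  flat_t <- c(seq(0, 10, by = 0.1), seq(11, 1e4, length.out = 200))

  # short transient then flat at the new steady state
  x <- 0.5 + 0.1 * (1 - exp(-flat_t))
  traj <- tibble::tibble(time = flat_t, A = 0.5, B = 0.5, C = x)
  expect_equal(classify_outcome(mk(traj, O1 = 0.5, O2 = 0.6,
                                   settle_time = 15), th), "OK")

  # sustained sinusoid after the initial excursion
  x <- 0.5 + 0.05 * sin(flat_t)
  traj <- tibble::tibble(time = flat_t, A = 0.5, B = 0.5, C = x)
  expect_equal(classify_outcome(mk(traj, O1 = 0.5, O2 = 0.5,
                                   settle_time = Inf), th),
               "PERSISTENT_OSCILLATION")

  # decaying sinusoid that still rings above the floor at the horizon
  x <- 0.5 + 0.05 * exp(-flat_t / 5e3) * sin(flat_t)
  traj <- tibble::tibble(time = flat_t, A = 0.5, B = 0.5, C = x)
  expect_equal(classify_outcome(mk(traj, O1 = 0.5, O2 = 0.5,
                                   settle_time = Inf), th),
               "WEAKLY_DAMPED_OSCILLATION")

  # exponential relaxation slower than t_max / 5 never settles in budget
  tau <- th$t_max / 4
  x <- 0.6 - 0.1 * exp(-flat_t / tau)
  traj <- tibble::tibble(time = flat_t, A = 0.5, B = 0.5, C = x)
  st <- flat_t[which(rev(cummax(rev(abs(x - 0.6)))) < th$settle_tol)[1]]
  expect_equal(classify_outcome(mk(traj, O1 = 0.5, O2 = 0.6,
                                   settle_time = ifelse(is.na(st), Inf, st)),
                                th),
               "LONG_TRANSIENT")

  # vanishing steady state dominates
  x <- rep(5e-4, length(flat_t))
  traj <- tibble::tibble(time = flat_t, A = 0.5, B = 0.5, C = x)
  expect_equal(classify_outcome(mk(traj, O1 = 5e-4, O2 = 5e-4,
                                   settle_time = 1), th),
               "TINY_STEADY_STATE")

  expect_equal(classify_outcome(list(numerical_failure = TRUE), th),
               "NUMERICAL_FAILURE")
  expect_equal(classify_outcome(list(pre_converged = FALSE,
                                     pre_oscillating = TRUE), th),
               "PERSISTENT_OSCILLATION")
  expect_equal(classify_outcome(list(pre_converged = FALSE,
                                     pre_oscillating = FALSE), th),
               "NO_CONVERGENCE")
})

test_that("sensitivity and precision scores match their definitions", {
  prot <- stimulus_protocol()
  expect_equal(sensitivity_score(1, 1.4, prot), 2)
  expect_equal(sensitivity_score(1, 1, prot), 0)
  expect_equal(precision_score(1, 1.02, prot), 10)
  expect_equal(precision_score(1, 1.2, prot), 1)
  expect_identical(precision_score(1, 1, prot), Inf)
  # inhibitory responses score positively under the absolute-value form
  expect_equal(sensitivity_score(1, 0.6, prot), 2)
  expect_equal(precision_score(1, 0.98, prot), 10)
  expect_true(is.nan(sensitivity_score(0, 1, prot)))
})

test_that("scores are scale-invariant and precision is monotone", {
  prot <- stimulus_protocol()
  set.seed(5)
  for (i in 1:20) {
    O1 <- runif(1, 0.1, 1); Op <- runif(1); O2 <- runif(1)
    cc <- runif(1, 0.01, 100)
    expect_equal(sensitivity_score(cc * O1, cc * Op, prot),
                 sensitivity_score(O1, Op, prot))
    expect_equal(precision_score(cc * O1, cc * O2, prot),
                 precision_score(O1, O2, prot))
  }
  shifts <- seq(0.001, 0.5, length.out = 30)
  prec <- precision_score(1, 1 + shifts, prot)
  expect_true(all(diff(prec) < 0))
})

test_that("the solution criteria are strict inequalities", {
  expect_true(is_kinetic_solution(1.5, 20))
  expect_false(is_kinetic_solution(1.0, 20))
  expect_false(is_kinetic_solution(1.5, 10))
  expect_true(is_kinetic_solution(1.5, Inf))
  expect_false(is_kinetic_solution(NA_real_, 20))
})

test_that("score thresholds restate the 20% excursion and 2% return rules", {
  prot <- stimulus_protocol()
  # the relative excursion at which sensitivity crosses 1
  exc <- uniroot(function(d) sensitivity_score(1, 1 + d, prot) - 1,
                 c(1e-6, 5), tol = 1e-12)$root
  expect_equal(exc, 0.2, tolerance = 1e-9)
  # the relative steady-state shift at which precision crosses 10
  shift <- uniroot(function(d) precision_score(1, 1 + d, prot) - 10,
                   c(1e-9, 5), tol = 1e-12)$root
  expect_equal(shift, 0.02, tolerance = 1e-9)
})
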