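test_that("the NFBLB preset has the canonical structure", {
  m <- build_nfblb_model()
  expect_length(m$topology$nodes, 3)
  expect_length(m$param_names, 12)
  edges <- m$topology$edges
  expected <- data.frame(
    from = c("I", "B", "A", "F_B", "A", "F_C"),
    to   = c("A", "A", "B", "B",   "C", "C"),
    mode = c("activation", "deactivation", "activation", "deactivation",
             "activation", "deactivation")
  )
  expect_equal(as.data.frame(edges[c("from", "to", "mode")]), expected)

  # deterministic construction: two builds evaluate identically
  m2 <- build_nfblb_model()
  st <- c(A = 0.3, B = 0.7, C = 0.2)
  p <- all_ones_params()
  expect_identical(rate_of_change(m, st, p, input = 0.4),
                   rate_of_change(m2, st, p, input = 0.4))
})

test_that("rate equations reproduce hand-substituted values", {
  p <- all_ones_params()
  # symmetric point: every activation and deactivation term is 0.25/1.5
  expect_equal(rate_of_change(nfblb, c(A = .5, B = .5, C = .5), p,
                              input = .5),
               c(A = 0, B = 0, C = 0))
  # halving B halves A's deactivation term: dA = 0.5*0.5/1.5 - 0.25*0.5/1.5
  d <- rate_of_change(nfblb, c(A = .5, B = .25, C = .5), p, input = .5)
  expect_equal(d[["A"]], 1 / 12)
  # saturated boundary: at A = 1 the activation numerator (1 - A) vanishes
  d1 <- rate_of_change(nfblb, c(A = 1, B = .5, C = .5), p, input = .5)
  expect_equal(d1[["A"]], -0.5 * 1 / (1 + 1))
})

test_that("the generic builder reproduces the preset and rejects bad wiring", {
  g <- build_generic_model(nfblb_topology())
  set.seed(101)
  for (i in 1:10) {
    st <- setNames(runif(3), c("A", "B", "C"))
    p <- random_params()
    I <- runif(1, 0.1, 1)
    expect_equal(rate_of_change(g, st, p, input = I),
                 rate_of_change(nfblb, st, p, input = I))
  }

  # a node without a deactivating edge is ill-posed
  expect_error(network_topology(data.frame(
    from = c("I", "A", "F_B", "A", "F_C"),
    to   = c("A", "B", "B",   "C", "C"),
    mode = c("activation", "activation", "deactivation",
             "activation", "deactivation"))),
    "at least one activation")

  # an incoherent feed-forward wiring builds and evaluates finitely
  iff <- build_generic_model(ifflp_like_topology())
  expect_length(iff$param_names, 12)
  d <- rate_of_change(iff, c(A = .3, B = .4, C = .5),
                      setNames(rep(1, 12), iff$param_names), input = .5)
  expect_true(all(is.finite(d)))
})

test_that("compiled and interpreted rate laws integrate identically", {
  p <- random_params()
  interp <- build_generic_model(nfblb_topology()) # compiled = FALSE
  y0 <- c(A = 0.2, B = 0.8, C = 0.5)
  times <- seq(0, 5, by = 0.5)
  th <- rejection_thresholds()
  out_c <- kinmotif:::ode_run(nfblb, p, 0.5, y0, times, th)
  out_r <- kinmotif:::ode_run(interp, p, 0.5, y0, times, th)
  expect_equal(unclass(out_c)[, 2:4], unclass(out_r)[, 2:4],
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("the unit cube is forward-invariant on the boundary faces", {
  set.seed(7)
  for (i in 1:25) {
    p <- random_params()
    I <- runif(1, 0.1, 1)
    interior <- runif(2)
    # at n = 0 the deactivation term vanishes, so dn/dt >= 0
    expect_gte(rate_of_change(nfblb, c(A = 0, B = interior[1],
                                       C = interior[2]), p, input = I)[["A"]],
               0)
    expect_gte(rate_of_change(nfblb, c(A = interior[1], B = 0,
                                       C = interior[2]), p, input = I)[["B"]],
               0)
    expect_gte(rate_of_change(nfblb, c(A = interior[1], B = interior[2],
                                       C = 0), p, input = I)[["C"]], 0)
    # at n = 1 the activation term vanishes, so dn/dt <= 0
    expect_lte(rate_of_change(nfblb, c(A = 1, B = interior[1],
                                       C = interior[2]), p, input = I)[["A"]],
               0)
    expect_lte(rate_of_change(nfblb, c(A = interior[1], B = 1,
                                       C = interior[2]), p, input = I)[["B"]],
               0)
    expect_lte(rate_of_change(nfblb, c(A = interior[1], B = interior[2],
                                       C = 1), p, input = I)[["C"]], 0)
  }
})

test_that("saturated C-node kinetics reduce to zero-order rates", {
  # with K_AC = K_FCC = 1e-6 and C well inside (0, 1), dC/dt approaches
  # A*k_AC - F_C*k_FCC and the C concentration drops out of the rate law
  set.seed(13)
  for (i in 1:20) {
    p <- random_params()
    p[["K_AC"]] <- 1e-6
    p[["K_FCC"]] <- 1e-6
    A <- runif(1, 0.1, 0.9)
    C <- runif(1, 0.1, 0.9)
    dC <- rate_of_change(nfblb, c(A = A, B = 0.5, C = C), p,
                         input = 0.5)[["C"]]
    limit <- A * p[["k_AC"]] - 0.5 * p[["k_FCC"]]
    expect_lt(abs(dC - limit) / abs(limit), 1e-4)
  }
})
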