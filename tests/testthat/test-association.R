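test_that("Mann-Whitney z matches exact small-sample enumeration", {
  # all of a above all of b: U = 6, mu = 3, sd = sqrt(3)
  expect_equal(mann_whitney_z(c(3, 4, 5), c(1, 2)), sqrt(3))
  # antisymmetry under group swap
  expect_equal(mann_whitney_z(c(1, 2), c(3, 4, 5)), -sqrt(3))
  # identical groups carry no signal
  expect_equal(mann_whitney_z(c(1, 2, 3), c(1, 2, 3)), 0)
  # fully degenerate data
  expect_equal(mann_whitney_z(rep(1, 5), rep(1, 7)), 0)
  # infinite scores (perfect adaptation) rank above everything finite
  expect_gt(mann_whitney_z(c(Inf, Inf, 5), c(1, 2, 3)), 0)
})

test_that("tie-corrected z agrees with the reference rank test", {
  set.seed(31)
  for (i in 1:10) {
    a <- sample(1:8, 40, replace = TRUE) # heavy ties
    b <- sample(3:10, 55, replace = TRUE)
    z <- mann_whitney_z(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = FALSE))
    expect_equal(2 * stats::pnorm(-abs(z)), ref$p.value, tolerance = 1e-10)
  }
})

test_that("function labels follow the one-sided critical value", {
  expect_equal(classify_function(-8.75, 30.88), "PR")
  expect_equal(classify_function(26.57, 9.23), "PR,SN")
  expect_equal(classify_function(2.0, 2.0), "")
  expect_equal(classify_function(3.95, -34.32), "SN")
  # only positive exceedances count
  expect_equal(classify_function(-5, -5), "")
})

test_that("motif partition splits the screened rows by value class", {
  fx <- generate_fixture(n = 5000, m = 50, planted = c(K_BA = 1),
                         seed = 17)
  part <- partition_by_motif(fx, "K_BA", c(1L, 2L))
  expect_equal(nrow(part), sum(fx$outcome == "OK"))
  expect_true(all(part$in_motif[part$K_BA < 1e-1]))
  expect_false(any(part$in_motif[part$K_BA >= 1e-1]))
  # a mid-motif value belongs to the motif group
  expect_true(in_motif(10^-1.5, c(1L, 2L)))
  # single-class motif: non-motif group is the two-sided complement
  expect_equal(in_motif(c(10^-2, 10^-0.5, 10^0.5), 3L),
               c(FALSE, TRUE, FALSE))
  expect_error(partition_by_motif(fx, "K_BA", 1:5), "degenerate")
})

test_that("association detects planted score shifts and labels them", {
  fx <- generate_fixture(n = 8000, m = 74, planted = c(k_FBB = 3),
                         planting_fraction = 0.9,
                         shift_sensitivity = 0, shift_precision = 0.4,
                         seed = 8)
  enr <- enrich_classes(fx)
  motifs <- detect_motifs(enr)
  expect_true("k_FBB" %in% motifs$parameter)
  assoc <- associate_functions(fx, motifs)
  row <- assoc[assoc$parameter == "k_FBB", ]
  expect_gt(row$z_precision, 3.29)
  expect_lt(abs(row$z_sensitivity), 3.29)
  expect_equal(row$functions, "PR")
  expect_gt(row$Pr_m, row$Pr_nm)
  expect_equal(row$n_motif + row$n_non_motif, sum(fx$outcome == "OK"))
})

test_that("the kinetic-functionality network is bipartite", {
  fx <- generate_fixture(n = 8000, m = 74,
                         planted = c(k_FBB = 3, K_AC = 1),
                         planting_fraction = 0.9,
                         shift_sensitivity = c(0, 0.4),
                         shift_precision = c(0.4, 0.4), seed = 12)
  assoc <- associate_functions(fx, detect_motifs(enrich_classes(fx)))
  g <- build_bipartite_network(assoc)
  expect_true(igraph::bipartite_mapping(g)$res)
  el <- igraph::as_edgelist(g)
  # every edge joins a motif to a functionality, never motif to motif
  expect_true(all(el[, 2] %in% c("sensitivity", "precision") |
                    el[, 1] %in% c("sensitivity", "precision")))
  # no significant associations: two isolated function vertices remain
  empty <- assoc[0, ]
  g0 <- build_bipartite_network(empty)
  expect_equal(igraph::vcount(g0), 2)
  expect_equal(igraph::ecount(g0), 0)
})

test_that("cooperation tests flag exact and planted correlations", {
  fx <- generate_fixture(n = 400, m = 40, planted = c(k_FBB = 3),
                         seed = 21)
  motifs <- tibble::tibble(parameter = c("k_FBB", "K_BA"),
                           classes = list(3L, 1L),
                           interval = c("[1e-01,1e+00]", "[1e-03,1e-02]"))
  class(motifs) <- class(tibble::tibble())
  co <- pairwise_cooperation(fx, motifs)
  self <- co[co$parameter_1 == co$parameter_2, ]
  expect_true(all(self$r == 1))
  # exact linear dependence between two columns
  fx2 <- fx
  fx2$K_BA <- fx2$k_FBB^2 # linear in log10 scale
  co2 <- pairwise_cooperation(fx2, motifs)
  cross <- co2[co2$parameter_1 != co2$parameter_2, ]
  expect_equal(cross$r, 1, tolerance = 1e-12)
  expect_true(cross$correlated)
  expect_error(pairwise_cooperation(fx[0, ], motifs), "at least 3")
})

test_that("correlation p-values agree with a permutation oracle", {
  set.seed(3)
  x <- rnorm(40)
  y <- 0.5 * x + rnorm(40)
  p_exact <- cor.test(x, y)$p.value
  p_perm <- cor_perm_oracle(x, y, n_perm = 2000)
  # Monte-Carlo agreement: permutation p within ~3 MC standard errors
  se <- sqrt(p_perm * (1 - p_perm) / 2000)
  expect_lt(abs(p_exact - p_perm), 3 * se + 2e-3)
  # null case
  y0 <- rnorm(40)
  expect_lt(abs(cor.test(x, y0)$p.value -
                  cor_perm_oracle(x, y0, n_perm = 2000)), 0.08)
})
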