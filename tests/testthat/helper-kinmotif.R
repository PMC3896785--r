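# shared fixtures and independent oracles for the test suite

nfblb <- build_nfblb_model()

all_ones_params <- function(model = nfblb) {
  setNames(rep(1, length(model$param_names)), model$param_names)
}

random_params <- function(model = nfblb) {
  rg <- parameter_ranges(model)
  setNames(10^runif(nrow(rg), log10(rg$lower), log10(rg$upper)),
           rg$parameter)
}

# brute-force strict-tail hypergeometric p-value by direct combinatorial
# counting: P(X > x) = sum_{i > x} C(y, i) C(N - y, M - i) / C(N, M)
hyper_tail_oracle <- function(x, y, M, N) {
  if (x >= M) return(0)
  i <- seq.int(x + 1, M)
  i <- i[i <= y & (M - i) <= (N - y)]
  if (length(i) == 0) return(0)
  sum(exp(lchoose(y, i) + lchoose(N - y, M - i) - lchoose(N, M)))
}

# two-sided Pearson correlation p-value by permutation
cor_perm_oracle <- function(x, y, n_perm = 1000, seed = 1) {
  r_obs <- abs(cor(x, y))
  set.seed(seed)
  hits <- sum(replicate(n_perm, abs(cor(x, sample(y))) >= r_obs - 1e-12))
  (hits + 1) / (n_perm + 1)
}

# an incoherent feed-forward wiring (A drives B and C, B deactivates C)
# used for generic-builder smoke tests
ifflp_like_topology <- function() {
  network_topology(
    edges = data.frame(
      from = c("I", "F_A", "A", "F_B", "A", "B"),
      to   = c("A", "A",   "B", "B",   "C", "C"),
      mode = c("activation", "deactivation",
               "activation", "deactivation",
               "activation", "deactivation")
    ),
    constant_enzymes = c(F_A = 0.5, F_B = 0.5)
  )
}

# cache for expensive shared computations within one test run
.kinmotif_test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, code) {
  if (!exists(key, envir = .kinmotif_test_cache)) {
    assign(key, force(code), envir = .kinmotif_test_cache)
  }
  get(key, envir = .kinmotif_test_cache)
}
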