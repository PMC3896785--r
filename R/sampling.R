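#' Sampling ranges for the kinetic parameters of a model
#'
#' Catalytic rate constants `k` span `[0.1, 10]` and Michaelis-Menten
#' constants `K` span `[1e-3, 1e2]` by default, the ranges conventionally
#' used for this class of adaptation screens; both are sampled uniformly on
#' the log10 scale.
#'
#' The edge driven by the external input (for NFBLB: `k_IA`, `K_IA`) can be
#' excluded from sampling and fixed at 1, which narrows the screen to the
#' ten parameters usually profiled for motifs; by default it is sampled like
#' every other edge.
#'
#' @param model A `network_model`.
#' @param k_range,K_range Length-2 numeric ranges for `k`- and `K`-type
#'   parameters (0 < lower < upper).
#' @param sample_input_edge Sample the input edge's parameters (default
#'   `TRUE`) or fix them at 1.
#' @return A tibble with columns `parameter`, `type` (`"k"` or `"K"`),
#'   `lower`, `upper`, `sampled`.
#' @export
parameter_ranges <- function(model, k_range = c(1e-1, 1e1),
                             K_range = c(1e-3, 1e2),
                             sample_input_edge = TRUE) {
  stopifnot(inherits(model, "network_model"),
            length(k_range) == 2, length(K_range) == 2,
            0 < k_range[1], k_range[1] < k_range[2],
            0 < K_range[1], K_range[1] < K_range[2])
  pn <- model$param_names
  type <- ifelse(startsWith(pn, "k_"), "k", "K")
  topo <- model$topology
  input_stems <- topo$edges$stem[topo$edges$from == topo$input_label]
  input_params <- pn[sub("^[kK]_", "", pn) %in% input_stems]
  tibble(
    parameter = pn,
    type = type,
    lower = ifelse(type == "k", k_range[1], K_range[1]),
    upper = ifelse(type == "k", k_range[2], K_range[2]),
    sampled = sample_input_edge | !(pn %in% input_params)
  )
}

# run code under a fixed RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Latin hypercube sample of kinetic parameter sets
#'
#' Draws `n` parameter sets by Latin hypercube sampling on the log10 scale:
#' for each sampled parameter independently, the `n` draws occupy `n`
#' equal-width strata of its log10 range exactly once each (uniform within
#' the stratum), with independent random stratum permutations across
#' parameters. Parameters flagged as not sampled are fixed at 1.
#'
#' @param n Number of parameter sets (>= 1).
#' @param ranges A [parameter_ranges()] tibble.
#' @param seed Integer seed; the same seed reproduces the same matrix
#'   without disturbing the caller's RNG stream. `NULL` uses the current
#'   stream.
#' @return A tibble with `set_id` and one column per parameter.
#' @export
#' @examples
#' m <- build_nfblb_model()
#' sample_parameters(5, parameter_ranges(m), seed = 1)
sample_parameters <- function(n, ranges, seed = NULL) {
  stopifnot(n >= 1, is.data.frame(ranges))
  sampled <- ranges[ranges$sampled, ]
  with_local_seed(seed, {
    u <- lhs::randomLHS(n, nrow(sampled))
    lo <- log10(sampled$lower)
    hi <- log10(sampled$upper)
    vals <- 10^sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
    colnames(vals) <- sampled$parameter
    out <- as_tibble(vals)
    for (p in ranges$parameter[!ranges$sampled]) out[[p]] <- 1
    out <- out[, ranges$parameter]
    dplyr::bind_cols(tibble(set_id = seq_len(n)), out)
  })
}
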