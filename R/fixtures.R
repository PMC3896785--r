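#' Generate a synthetic screened matrix with planted value-class biases
#'
#' Emulates the statistical structure of a finished screen without running
#' any ODE: `n` rows of log-uniform parameter values, `m` of which are
#' flagged as kinetic solutions. For each planted parameter, solution rows
#' draw their value from the planted class with probability
#' `planting_fraction` (and log-uniformly over the whole range otherwise),
#' so the solution counts concentrate in that class the way a real motif
#' does. Sensitivity and precision scores are unit-variance Gaussian
#' baselines, shifted upward for rows whose planted-parameter value lies in
#' the planted class — which gives the association tests a known truth.
#'
#' This generator exercises the enrichment and association layers; it does
#' not emulate trajectory pathologies (every row is `OK`) or the joint
#' parameter dependencies a dynamical screen induces.
#'
#' @param n Total rows (sampled sets).
#' @param m Rows flagged as solutions (`m <= n`).
#' @param planted Named integer vector: planted class index per parameter,
#'   e.g. `c(k_FBB = 3)`. May be empty for a null fixture.
#' @param planting_fraction Probability a solution row draws the planted
#'   parameter from its planted class. Default 0.85.
#' @param shift_sensitivity,shift_precision Score shift added to rows whose
#'   planted-parameter value falls in the planted class (recycled over
#'   planted parameters; 0 disables). Default 0.
#' @param model Model whose parameters the fixture emulates.
#' @param ranges A [parameter_ranges()] tibble.
#' @param scheme A [value_class_scheme()].
#' @param seed Integer seed for reproducibility.
#' @return A `kinetic_screen`-classed tibble (synthetic), with `outcome`
#'   `"OK"` everywhere, scores, and `is_solution` flags.
#' @export
generate_fixture <- function(n, m, planted = c(),
                             planting_fraction = 0.85,
                             shift_sensitivity = 0, shift_precision = 0,
                             model = build_nfblb_model(),
                             ranges = parameter_ranges(model),
                             scheme = value_class_scheme(), seed = NULL) {
  stopifnot(m <= n, planting_fraction >= 0, planting_fraction <= 1)
  if (length(planted) > 0) {
    stopifnot(!is.null(names(planted)),
              all(names(planted) %in% ranges$parameter))
  }
  with_local_seed(seed, {
    vals <- purrr::map(seq_len(nrow(ranges)), function(i) {
      if (ranges$sampled[i]) {
        10^runif(n, log10(ranges$lower[i]), log10(ranges$upper[i]))
      } else {
        rep(1, n)
      }
    })
    names(vals) <- ranges$parameter
    tbl <- as_tibble(vals)
    sol <- seq_len(n) %in% sample.int(n, m)

    b <- scheme$breaks
    for (p in names(planted)) {
      cls <- planted[[p]]
      lo <- max(b[cls], ranges$lower[ranges$parameter == p])
      hi <- min(b[cls + 1], ranges$upper[ranges$parameter == p])
      plant <- sol & (runif(n) < planting_fraction)
      tbl[[p]][plant] <- 10^runif(sum(plant), log10(lo), log10(hi))
    }

    sens <- rnorm(n)
    prec <- rnorm(n)
    if (length(planted) > 0) {
      ss <- rep_len(shift_sensitivity, length(planted))
      sp <- rep_len(shift_precision, length(planted))
      for (i in seq_along(planted)) {
        p <- names(planted)[i]
        inm <- in_motif(tbl[[p]], planted[[i]], scheme)
        sens[inm] <- sens[inm] + ss[i]
        prec[inm] <- prec[inm] + sp[i]
      }
    }

    out <- dplyr::bind_cols(
      tibble(set_id = seq_len(n)), tbl,
      tibble(outcome = "OK", O1 = NA_real_, Op = NA_real_, O2 = NA_real_,
             settle_time = NA_real_, sensitivity = sens, precision = prec,
             is_solution = sol)
    )
    new_kinetic_screen(out, model, stimulus_protocol(),
                       rejection_thresholds(), solution_criteria(),
                       synthetic = TRUE)
  })
}
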