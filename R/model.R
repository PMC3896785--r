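#' Build a rate-equation model from a network topology
#'
#' Assembles the Michaelis-Menten rate laws of a three-node enzyme network.
#' Every node `n` obeys
#' \deqn{dn/dt = \sum_{act} E \, k \, (1-n) / ((1-n) + K)
#'             - \sum_{deact} E \, k \, n / (n + K),}
#' where `E` is the concentration of the regulating enzyme (another node's
#' active fraction, the external input, or a constant background enzyme) and
#' `(k, K)` are that edge's catalytic rate constant and Michaelis-Menten
#' constant. Active fractions live in `[0, 1]`; `1 - n` is the inactive form.
#' All quantities are dimensionless.
#'
#' @param topology A [network_topology()].
#' @return An object of class `network_model`: a list with `topology`,
#'   `param_names` (one `k_*` and one `K_*` per edge, in edge order), and a
#'   `rate` closure `function(state, params, input)` returning named
#'   per-node derivatives.
#' @seealso [build_nfblb_model()], [rate_of_change()]
#' @export
build_generic_model <- function(topology) {
  stopifnot(inherits(topology, "network_topology"))
  edges <- topology$edges
  nodes <- topology$nodes
  k_names <- paste0("k_", edges$stem)
  K_names <- paste0("K_", edges$stem)
  param_names <- as.vector(rbind(k_names, K_names))
  const <- topology$constant_enzymes
  input_label <- topology$input_label

  rate <- function(state, params, input) {
    d <- setNames(numeric(length(nodes)), nodes)
    for (i in seq_len(nrow(edges))) {
      src <- edges$from[i]
      tgt <- edges$to[i]
      E <- if (src == input_label) input
           else if (src %in% names(const)) const[[src]]
           else state[[src]]
      k <- params[[k_names[i]]]
      K <- params[[K_names[i]]]
      n <- state[[tgt]]
      if (edges$mode[i] == "activation") {
        d[tgt] <- d[tgt] + E * k * (1 - n) / ((1 - n) + K)
      } else {
        d[tgt] <- d[tgt] - E * k * n / (n + K)
      }
    }
    d
  }

  structure(
    list(topology = topology, param_names = param_names, rate = rate,
         compiled = FALSE),
    class = "network_model"
  )
}

#' Build the NFBLB chemotaxis network model
#'
#' The negative feed-back loop with a buffer node: the canonical three-node
#' adaptive circuit of E. coli chemotaxis. The input activates A, B
#' deactivates A (the negative feedback), A activates B and C, and constant
#' enzymes F_B and F_C (0.5 each) deactivate B and C. Twelve kinetic
#' parameters: `k_IA, K_IA, k_BA, K_BA, k_AB, K_AB, k_FBB, K_FBB, k_AC,
#' K_AC, k_FCC, K_FCC`.
#'
#' This preset additionally carries a compiled derivative routine used by
#' the ODE integrator, so large screens run at C speed; it evaluates the
#' same rate laws as the generic closure.
#'
#' @inheritParams nfblb_topology
#' @return A `network_model` (see [build_generic_model()]).
#' @export
#' @examples
#' m <- build_nfblb_model()
#' rate_of_change(m, c(A = 0.5, B = 0.5, C = 0.5),
#'                setNames(rep(1, 12), m$param_names), input = 0.5)
build_nfblb_model <- function(constant_enzymes = c(F_B = 0.5, F_C = 0.5)) {
  m <- build_generic_model(nfblb_topology(constant_enzymes))
  m$compiled <- TRUE
  m
}

#' Evaluate the per-node derivatives of a network model
#'
#' @param model A `network_model`.
#' @param state Named numeric vector of node active fractions, each in
#'   `[0, 1]` (e.g. `c(A = 0.5, B = 0.5, C = 0.5)`). May also carry the
#'   input under the topology's input label.
#' @param params Named numeric vector covering `model$param_names`, all
#'   positive.
#' @param input Input level; defaults to the value stored in `state`.
#' @return Named numeric vector of derivatives, one per node. Non-finite
#'   values are returned as-is so callers can reject the parameter set
#'   rather than abort a screen.
#' @export
rate_of_change <- function(model, state, params,
                           input = state[[model$topology$input_label]]) {
  stopifnot(inherits(model, "network_model"))
  missing_p <- setdiff(model$param_names, names(params))
  if (length(missing_p) > 0) {
    stop("missing parameters: ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  model$rate(state, params, input)
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model>", length(x$topology$nodes), "nodes,",
      length(x$param_names), "kinetic parameters",
      if (isTRUE(x$compiled)) "(compiled rate function)" else "", "\n")
  invisible(x)
}

# specialized derivative closure on bare numeric state vectors; used by the
# Newton iterations where named-vector dispatch would dominate the cost.
# Arithmetic matches the generic rate closure term for term.
make_rate_fn <- function(model, params, input) {
  if (isTRUE(model$compiled)) {
    p <- unname(params[model$param_names])
    const <- model$topology$constant_enzymes
    FB <- const[["F_B"]]
    FC <- const[["F_C"]]
    I <- input
    function(x) {
      A <- x[1]; B <- x[2]; C <- x[3]
      c(I * p[1] * (1 - A) / ((1 - A) + p[2]) -
          B * p[3] * A / (A + p[4]),
        A * p[5] * (1 - B) / ((1 - B) + p[6]) -
          FB * p[7] * B / (B + p[8]),
        A * p[9] * (1 - C) / ((1 - C) + p[10]) -
          FC * p[11] * C / (C + p[12]))
    }
  } else {
    nodes <- model$topology$nodes
    rate <- model$rate
    function(x) unname(rate(setNames(x, nodes), params, input))
  }
}

# deSolve interface: returns the arguments selecting the compiled NFBLB
# derivative routine or an R closure, plus the parms vector layout.
model_desolve_args <- function(model, params, input) {
  const <- model$topology$constant_enzymes
  if (isTRUE(model$compiled)) {
    parms <- c(unname(params[model$param_names]), input,
               const[["F_B"]], const[["F_C"]])
    list(func = "nfblb_derivs", dllname = "kinmotif",
         initfunc = "nfblb_init", parms = parms)
  } else {
    rate <- model$rate
    nodes <- model$topology$nodes
    list(func = function(t, y, p) {
      list(unname(rate(setNames(y, nodes), params, input)))
    }, parms = NULL)
  }
}
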