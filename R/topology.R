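#' Define a three-node enzyme network topology
#'
#' A topology is the wiring diagram of an enzyme network: which species
#' (node, external input, or constant background enzyme) activates or
#' deactivates each node. Every regulatory edge carries one Michaelis-Menten
#' reaction with a catalytic rate constant `k` and a Michaelis-Menten
#' constant `K`; [build_generic_model()] turns the topology into rate
#' equations.
#'
#' Each node must have at least one activating and at least one deactivating
#' edge. A node lacking either would drift monotonically toward 0 or 1, so
#' its dynamics on the unit interval are ill-posed and the topology is
#' rejected.
#'
#' @param edges A data frame with columns `from`, `to`, `mode`. `from` is a
#'   node label, the input label, or a constant-enzyme label; `to` is a node
#'   label; `mode` is `"activation"` or `"deactivation"`.
#' @param nodes Ordered node labels. Default `c("A", "B", "C")`.
#' @param input_label Label of the external stimulus. Default `"I"`.
#' @param constant_enzymes Named numeric vector of background enzymes held at
#'   fixed concentration (dimensionless). Default `c(F_B = 0.5, F_C = 0.5)`.
#' @param output_node The node whose activity is read out as the system
#'   output. Default `"C"`.
#'
#' @return An object of class `network_topology`: a list with the validated
#'   `edges` tibble (with a `parameter stem` column naming each edge's k/K
#'   pair), `nodes`, `input_label`, `constant_enzymes`, `output_node`.
#' @seealso [nfblb_topology()], [build_generic_model()]
#' @export
#' @examples
#' topo <- nfblb_topology()
#' topo$edges
network_topology <- function(edges,
                             nodes = c("A", "B", "C"),
                             input_label = "I",
                             constant_enzymes = c(F_B = 0.5, F_C = 0.5),
                             output_node = "C") {
  edges <- as_tibble(edges)
  stopifnot(all(c("from", "to", "mode") %in% names(edges)))
  if (!all(edges$mode %in% c("activation", "deactivation"))) {
    stop("edge `mode` must be 'activation' or 'deactivation'", call. = FALSE)
  }
  sources <- c(nodes, input_label, names(constant_enzymes))
  bad <- setdiff(unique(c(edges$from, edges$to)), sources)
  if (length(bad) > 0) {
    stop("unknown species in edge list: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!all(edges$to %in% nodes)) {
    stop("edge targets must be network nodes", call. = FALSE)
  }
  if (!output_node %in% nodes) stop("`output_node` must be a node", call. = FALSE)
  for (nd in nodes) {
    modes <- edges$mode[edges$to == nd]
    if (!("activation" %in% modes) || !("deactivation" %in% modes)) {
      stop("node ", nd, " must have at least one activation and one ",
           "deactivation edge", call. = FALSE)
    }
  }
  # parameter stem: edge I -> A gives k_IA / K_IA; F_B -> B gives k_FBB / K_FBB
  edges$stem <- paste0(gsub("_", "", edges$from), edges$to)
  if (anyDuplicated(edges$stem)) {
    stop("duplicate edges (same source and target) are not supported",
         call. = FALSE)
  }
  structure(
    list(edges = edges, nodes = nodes, input_label = input_label,
         constant_enzymes = constant_enzymes, output_node = output_node),
    class = "network_topology"
  )
}

#' The negative-feedback-loop-with-buffer (NFBLB) topology
#'
#' The three-node circuit matching E. coli chemotaxis: the input activates
#' node A (the CheA-bound receptor complex), A activates both B (CheB) and C
#' (CheY), and B feeds back to deactivate A. Constant background enzymes
#' F_B and F_C (concentration 0.5 each) deactivate B and C.
#'
#' @inheritParams network_topology
#' @return A `network_topology` with the six NFBLB edges.
#' @export
nfblb_topology <- function(constant_enzymes = c(F_B = 0.5, F_C = 0.5)) {
  network_topology(
    edges = tibble(
      from = c("I", "B", "A", "F_B", "A", "F_C"),
      to   = c("A", "A", "B", "B",   "C", "C"),
      mode = c("activation", "deactivation",
               "activation", "deactivation",
               "activation", "deactivation")
    ),
    constant_enzymes = constant_enzymes
  )
}

#' @export
print.network_topology <- function(x, ...) {
  cat("<network_topology> nodes:", paste(x$nodes, collapse = ", "),
      "| input:", x$input_label,
      "| output:", x$output_node, "\n")
  print(x$edges)
  invisible(x)
}
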