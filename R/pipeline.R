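#' Configuration of a full profiling run
#'
#' A run is a pure function of its configuration: model preset (or custom
#' edge list), sample size, seed, parameter ranges, stimulus protocol,
#' rejection thresholds, solution criteria, value-class scheme, and the
#' statistical thresholds of the enrichment, association and cooperation
#' stages. The configuration serializes to YAML ([write_config()]) and is
#' echoed into the output directory as provenance.
#'
#' @param model `"nfblb"` (default) or `"custom"`.
#' @param topology For `model = "custom"`, a data frame of edges
#'   (`from`, `to`, `mode`) passed to [network_topology()].
#' @param n_samples Number of parameter sets to sample.
#' @param seed Master seed; per-stage substreams are derived from it.
#' @param k_range,K_range Sampling ranges, see [parameter_ranges()].
#' @param sample_input_edge Sample the input edge's `k`/`K` (default) or fix
#'   them at 1; the input edge is excluded from motif profiling either way.
#' @param I1,I2 Stimulus protocol, see [stimulus_protocol()].
#' @param thresholds A [rejection_thresholds()].
#' @param criteria A [solution_criteria()].
#' @param per_decade Value classes per decade, see [value_class_scheme()].
#' @param alpha Enrichment significance threshold. Default `1e-3`.
#' @param tail Enrichment tail convention. Default `"strict"`.
#' @param z_crit Association critical z. Default 3.29.
#' @param cor_alpha Cooperation significance threshold. Default 0.05.
#' @param cor_scale Cooperation value scale, `"log10"` or `"raw"`.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return A list of class `run_config`.
#' @export
run_config <- function(model = "nfblb", topology = NULL,
                       n_samples = 1e5, seed = 1,
                       k_range = c(1e-1, 1e1), K_range = c(1e-3, 1e2),
                       sample_input_edge = TRUE,
                       I1 = 0.5, I2 = 0.6,
                       thresholds = rejection_thresholds(),
                       criteria = solution_criteria(),
                       per_decade = 1, alpha = 1e-3, tail = "strict",
                       z_crit = 3.29, cor_alpha = 0.05,
                       cor_scale = "log10", out_dir = NULL) {
  stopifnot(model %in% c("nfblb", "custom"))
  if (model == "custom" && is.null(topology)) {
    stop("custom model requires a `topology` edge list", call. = FALSE)
  }
  structure(
    list(model = model, topology = topology, n_samples = n_samples,
         seed = seed, k_range = k_range, K_range = K_range,
         sample_input_edge = sample_input_edge, I1 = I1, I2 = I2,
         thresholds = thresholds, criteria = criteria,
         per_decade = per_decade, alpha = alpha, tail = tail,
         z_crit = z_crit, cor_alpha = cor_alpha, cor_scale = cor_scale,
         out_dir = out_dir),
    class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  obj <- config
  obj$thresholds <- unclass(obj$thresholds)
  obj$criteria <- unclass(obj$criteria)
  if (!is.null(obj$topology)) obj$topology <- as.data.frame(obj$topology)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(run_config, modifyList(obj, list(
    thresholds = do.call(rejection_thresholds,
                         obj$thresholds[names(formals(rejection_thresholds))]),
    criteria = do.call(solution_criteria,
                       obj$criteria[names(formals(solution_criteria))]),
    topology = if (!is.null(obj$topology)) as_tibble(obj$topology)
  )))
}

config_model <- function(config) {
  if (config$model == "nfblb") build_nfblb_model()
  else build_generic_model(network_topology(config$topology))
}

# derive independent substream seeds (kept below 2^31) from the master seed
substream_seed <- function(seed, stage) {
  offsets <- c(sample = 11L, fixture = 23L)
  (as.integer(seed) * 1000003L + offsets[[stage]]) %% 2147483647L
}

#' Run the full profiling pipeline
#'
#' Sample, screen, enrich, associate, cooperate — the complete analysis in
#' one call. With `config$out_dir` set, writes `parameters.csv`,
#' `outcomes.csv`, `enrichment.csv`, `motifs.json`, `association.csv`,
#' `correlations.csv`, `network.graphml`, `network.json`, `summary.json`, a
#' `config.yaml` echo and a `run.log`; partial outputs are preserved when a
#' later stage fails.
#'
#' @param config A [run_config()].
#' @param progress Print per-stage progress.
#' @return A list bundle: `config`, `screened`, `enrichment`, `motifs`,
#'   `association`, `network`, `cooperation`, `summary` (tibble with N,
#'   n_ok, M, motif parameters, labels).
#' @export
run_pipeline <- function(config = run_config(), progress = FALSE) {
  out_dir <- config$out_dir
  logf <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    logf <- file.path(out_dir, "run.log")
  }
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    if (progress) message(msg)
    if (!is.null(logf)) cat(msg, "\n", file = logf, append = TRUE)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  model <- config_model(config)
  ranges <- parameter_ranges(model, config$k_range, config$K_range,
                             config$sample_input_edge)
  protocol <- stimulus_protocol(config$I1, config$I2)
  scheme <- value_class_scheme(min(ranges$lower), max(ranges$upper),
                               per_decade = config$per_decade)

  log_line("sampling n = ", config$n_samples, " parameter sets (LHS, log10)")
  params <- stage("sample", sample_parameters(
    config$n_samples, ranges, seed = substream_seed(config$seed, "sample")))
  if (!is.null(out_dir)) {
    readr::write_csv(params, file.path(out_dir, "parameters.csv"))
  }

  log_line("screening")
  screened <- stage("screen", screen_parameters(
    params, model, protocol, config$thresholds, config$criteria,
    checkpoint = if (!is.null(out_dir)) file.path(out_dir, "checkpoint.csv"),
    progress = progress))
  g <- glance(screened)
  log_line("screened ", g$n_sampled, ": ", g$n_ok, " OK, ",
           sum(screened$outcome == "TINY_STEADY_STATE"), " tiny, ",
           sum(screened$outcome %in% c("PERSISTENT_OSCILLATION",
                                       "WEAKLY_DAMPED_OSCILLATION")),
           " oscillatory, ",
           sum(screened$outcome == "LONG_TRANSIENT"), " long-transient; M = ",
           g$n_solutions, " solutions")
  if (!is.null(out_dir)) {
    write_screen_csv(screened, file.path(out_dir, "outcomes.csv"))
  }

  enrichment <- NULL
  motifs <- structure(tibble(parameter = character(), classes = list(),
                             interval = character()),
                      class = c("kinetic_motifs", class(tibble())),
                      scheme = scheme)
  if (g$n_solutions == 0) {
    log_line("no kinetic solutions at n = ", g$n_sampled,
             "; skipping enrichment and association (screens of this ",
             "kind typically need ~1e5 sets)")
  } else {
    log_line("enrichment test (alpha = ", config$alpha, ")")
    enrichment <- stage("enrich", enrich_classes(
      screened, scheme, alpha = config$alpha, tail = config$tail))
    motifs <- detect_motifs(enrichment)
    log_line("motifs: ", paste(motifs$parameter, motifs$interval,
                               collapse = "; "))
    if (!is.null(out_dir)) {
      write_enrichment_csv(enrichment, file.path(out_dir, "enrichment.csv"))
      write_motifs_json(motifs, file.path(out_dir, "motifs.json"))
    }
  }

  association <- NULL
  network <- NULL
  cooperation <- NULL
  if (nrow(motifs) > 0) {
    log_line("functional association (z_crit = ", config$z_crit, ")")
    association <- stage("associate", associate_functions(
      screened, motifs, scheme, z_crit = config$z_crit))
    network <- build_bipartite_network(association)
    cooperation <- stage("cooperate", pairwise_cooperation(
      screened, motifs, scale = config$cor_scale, alpha = config$cor_alpha))
    if (!is.null(out_dir)) {
      readr::write_csv(tidy(association),
                       file.path(out_dir, "association.csv"))
      readr::write_csv(cooperation, file.path(out_dir, "correlations.csv"))
      write_network(network, file.path(out_dir, "network.graphml"))
      write_network(network, file.path(out_dir, "network.json"))
    }
  }

  summary <- tibble(
    N = g$n_sampled, n_ok = g$n_ok, M = g$n_solutions,
    motif_parameters = paste(motifs$parameter, collapse = ","),
    functions = if (is.null(association)) "" else
      paste(association$parameter, association$functions,
            sep = ":", collapse = ";")
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  log_line("done")
  invisible(list(config = config, screened = screened,
                 enrichment = enrichment, motifs = motifs,
                 association = association, network = network,
                 cooperation = cooperation, summary = summary))
}
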