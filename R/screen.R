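#' Screen sampled parameter sets for adaptation dynamics
#'
#' Runs the simulate / classify / score loop over every row of a sampled
#' parameter matrix: each set is relaxed to its pre-stimulus steady state,
#' stepped from `I1` to `I2`, classified against the trajectory-rejection
#' rules, and — when it passes — scored for sensitivity and precision. Sets
#' with sensitivity above 1 and precision above 10 (by default) are flagged
#' as kinetic solutions. Per-row failures are labelled, never fatal.
#'
#' @param params Tibble from [sample_parameters()] (or any data frame
#'   carrying `set_id` and the model's parameter columns).
#' @param model A `network_model`.
#' @param protocol A [stimulus_protocol()].
#' @param thresholds A [rejection_thresholds()].
#' @param criteria A [solution_criteria()].
#' @param checkpoint Optional path; progress is written there every
#'   `checkpoint_every` rows and a later call with the same inputs resumes
#'   from it. The checkpoint records a hash of the inputs and refuses to
#'   resume against a different configuration.
#' @param checkpoint_every Rows between checkpoint writes. Default 1000.
#' @param progress Print a progress line every 1000 rows.
#' @return The input tibble with columns `outcome`, `O1`, `Op`, `O2`,
#'   `settle_time`, `sensitivity`, `precision`, `is_solution` appended;
#'   class `kinetic_screen`. Use [glance()] for the screen-level summary
#'   (N, OK fraction, M).
#' @export
screen_parameters <- function(params, model,
                              protocol = stimulus_protocol(),
                              thresholds = rejection_thresholds(),
                              criteria = solution_criteria(),
                              checkpoint = NULL, checkpoint_every = 1000,
                              progress = FALSE) {
  pn <- model$param_names
  missing_p <- setdiff(pn, names(params))
  if (length(missing_p) > 0) {
    stop("parameter matrix lacks columns: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  pm <- as.matrix(params[pn])
  n <- nrow(pm)
  cfg_hash <- rlang::hash(list(pm, protocol, thresholds, criteria))

  cols <- c("O1", "Op", "O2", "settle_time", "sensitivity", "precision")
  res <- as.data.frame(matrix(NA_real_, n, length(cols)))
  names(res) <- cols
  outcome <- rep(NA_character_, n)
  start <- 1L

  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    ck <- read_checkpoint(checkpoint)
    if (!identical(ck$hash, cfg_hash)) {
      stop("checkpoint was written under a different configuration",
           call. = FALSE)
    }
    done <- nrow(ck$table)
    if (done > 0) {
      outcome[seq_len(done)] <- ck$table$outcome
      res[seq_len(done), cols] <- ck$table[, cols]
      start <- done + 1L
    }
  }

  write_ck <- function(upto) {
    if (is.null(checkpoint)) return(invisible())
    tab <- dplyr::bind_cols(tibble(outcome = outcome[seq_len(upto)]),
                            res[seq_len(upto), , drop = FALSE])
    write_checkpoint(checkpoint, cfg_hash, tab)
  }

  if (start <= n) {
    for (i in start:n) {
      p <- setNames(pm[i, ], pn)
      if (!all(is.finite(p)) || any(p <= 0)) {
        outcome[i] <- "NUMERICAL_FAILURE"
      } else {
        s <- simulate_step_response(model, p, protocol, thresholds)
        outcome[i] <- classify_outcome(s, thresholds)
        res$O1[i] <- s$O1
        res$Op[i] <- s$Op
        res$O2[i] <- s$O2
        res$settle_time[i] <- s$settle_time
        if (outcome[i] == "OK") {
          res$sensitivity[i] <- sensitivity_score(s$O1, s$Op, protocol)
          res$precision[i] <- precision_score(s$O1, s$O2, protocol)
        }
      }
      if (i %% checkpoint_every == 0) write_ck(i)
      if (progress && i %% 1000 == 0) {
        message(sprintf("screened %d/%d (%d solutions so far)", i, n,
                        sum(is_kinetic_solution(res$sensitivity,
                                                res$precision, criteria))))
      }
    }
  }
  write_ck(n)

  out <- dplyr::bind_cols(
    as_tibble(params),
    tibble(outcome = outcome),
    as_tibble(res),
    tibble(is_solution = outcome == "OK" &
             is_kinetic_solution(res$sensitivity, res$precision, criteria))
  )
  new_kinetic_screen(out, model, protocol, thresholds, criteria)
}

new_kinetic_screen <- function(tbl, model, protocol, thresholds, criteria,
                               synthetic = FALSE) {
  structure(tbl,
            class = c("kinetic_screen", class(tibble())),
            model = model, protocol = protocol, thresholds = thresholds,
            criteria = criteria, synthetic = synthetic)
}

read_checkpoint <- function(path) {
  first <- readLines(path, n = 1)
  hash <- sub("^# kinmotif-checkpoint ", "", first)
  tab <- utils::read.csv(path, comment.char = "#")
  tab <- parse_inf(tab, c("precision", "settle_time"))
  list(hash = hash, table = tab)
}

write_checkpoint <- function(path, hash, tab) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# kinmotif-checkpoint", hash), con)
  utils::write.csv(serialize_inf(tab, c("precision", "settle_time")), con,
                   row.names = FALSE)
}

#' Parameters profiled for motifs in a screen
#'
#' All kinetic parameters except those on the edge driven by the external
#' input, which are conventionally excluded from enrichment profiling.
#'
#' @param model A `network_model`.
#' @return Character vector of parameter names.
#' @export
profiled_parameters <- function(model) {
  topo <- model$topology
  input_stems <- topo$edges$stem[topo$edges$from == topo$input_label]
  pn <- model$param_names
  pn[!(sub("^[kK]_", "", pn) %in% input_stems)]
}

#' @export
glance.kinetic_screen <- function(x, ...) {
  tibble(
    n_sampled = nrow(x),
    n_ok = sum(x$outcome == "OK", na.rm = TRUE),
    ok_fraction = sum(x$outcome == "OK", na.rm = TRUE) / nrow(x),
    n_solutions = sum(x$is_solution, na.rm = TRUE),
    solution_rate = sum(x$is_solution, na.rm = TRUE) / nrow(x)
  )
}

#' @export
tidy.kinetic_screen <- function(x, ...) {
  as_tibble(unclass_screen(x))
}

unclass_screen <- function(x) {
  attr(x, "model") <- NULL
  attr(x, "protocol") <- NULL
  attr(x, "thresholds") <- NULL
  attr(x, "criteria") <- NULL
  attr(x, "synthetic") <- NULL
  class(x) <- class(tibble())
  x
}
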