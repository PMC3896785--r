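#' Decade value classes for kinetic parameters
#'
#' Kinetic parameter values are binned into contiguous classes on the log10
#' scale. The default scheme is five decade-wide classes covering
#' `[1e-3, 1e2]`: class 1 is `[1e-3, 1e-2)`, ..., class 5 is `[1e1, 1e2]`
#' (left-closed bins, top class closed). `per_decade = 2` gives the
#' doubled-resolution scheme of ten half-decade classes.
#'
#' @param lower,upper Overall range covered (powers of 10 by convention).
#' @param per_decade Classes per decade. Default 1.
#' @return An object of class `value_class_scheme` with `breaks` and
#'   `labels`.
#' @export
value_class_scheme <- function(lower = 1e-3, upper = 1e2, per_decade = 1) {
  stopifnot(lower > 0, upper > lower, per_decade >= 1)
  n <- round((log10(upper) - log10(lower)) * per_decade)
  breaks <- 10^seq(log10(lower), log10(upper), length.out = n + 1)
  labels <- sprintf("[%.0e,%.0e]", breaks[-length(breaks)], breaks[-1])
  structure(list(breaks = breaks, labels = labels, n_classes = n),
            class = "value_class_scheme")
}

#' Assign parameter values to value classes
#'
#' Left-closed binning: a value exactly on an interior boundary belongs to
#' the class above it; the top class is closed at its upper bound. Values
#' outside the scheme's range signal a range/scheme mismatch and are an
#' error.
#'
#' @param value Numeric vector of parameter values.
#' @param scheme A [value_class_scheme()].
#' @return Integer vector of class indices (1-based).
#' @export
#' @examples
#' assign_value_class(c(10^-2.5, 1e-2, 1e2), value_class_scheme())
assign_value_class <- function(value, scheme = value_class_scheme()) {
  b <- scheme$breaks
  if (any(value < b[1] | value > b[length(b)])) {
    stop("values outside the value-class range [", format(b[1]), ", ",
         format(b[length(b)]),
         "]; check the sampling ranges against the scheme",
         call. = FALSE)
  }
  findInterval(value, b, rightmost.closed = TRUE)
}

#' Per-class counts for one parameter of a screened matrix
#'
#' `y` counts come from all `N` sampled rows, `x` from the `M` kinetic
#' solutions; conservation (`sum(x) == M`, `sum(y) == N`) holds by
#' construction.
#'
#' @param screened A screened parameter matrix ([screen_parameters()] or
#'   [generate_fixture()]).
#' @param parameter Column name of the parameter.
#' @param scheme A [value_class_scheme()].
#' @return A list with integer vectors `x`, `y` (one entry per class), and
#'   scalars `M`, `N`.
#' @export
tabulate_class_counts <- function(screened, parameter,
                                  scheme = value_class_scheme()) {
  v <- screened[[parameter]]
  if (is.null(v)) stop("no column `", parameter, "`", call. = FALSE)
  sol <- !is.na(screened$is_solution) & screened$is_solution
  M <- sum(sol)
  N <- length(v)
  if (M == 0) {
    stop("no kinetic solutions in the screen; enrichment is undefined. ",
         "Increase the sample size (screens of this kind typically need ",
         "~1e5 sets to collect enough solutions).", call. = FALSE)
  }
  cls <- assign_value_class(v, scheme)
  x <- tabulate(cls[sol], nbins = scheme$n_classes)
  y <- tabulate(cls, nbins = scheme$n_classes)
  list(x = x, y = y, M = M, N = N)
}

#' Hypergeometric enrichment p-value
#'
#' Under the null that the `M` solutions are drawn uniformly at random
#' without replacement from the `N` sampled sets, the solution count `x` in
#' a class containing `y` of the `N` values follows a hypergeometric
#' distribution. The p-value is the strict upper tail `P(X > x)` (the
#' default convention, which reproduces published enrichment tables of this
#' analysis); the inclusive tail `P(X >= x)` is available via `tail`.
#' Computed from the log-scale CDF for numerical stability and clamped below
#' at machine epsilon (values at the clamp are reported as `"<2.2E-16"` by
#' [format_pvalue()]).
#'
#' @param x Solution count(s) in the class (0 <= x <= M).
#' @param y Sampled count(s) in the class (0 <= y <= N).
#' @param M Total number of solutions.
#' @param N Total number of sampled sets.
#' @param tail `"strict"` (default) for `P(X > x)` or `"inclusive"` for
#'   `P(X >= x)`.
#' @return Numeric p-value vector in `[eps, 1]`.
#' @export
#' @examples
#' enrichment_pvalue(50, 50000, M = 74, N = 1e5) # ~7.6e-4
enrichment_pvalue <- function(x, y, M, N, tail = c("strict", "inclusive")) {
  tail <- match.arg(tail)
  if (any(x < 0) || any(y < 0) || any(x > M) || any(y > N) || M > N ||
      any(x > y)) {
    stop("invalid count combination: need 0 <= x <= min(y, M) <= N and ",
         "y <= N", call. = FALSE)
  }
  q <- if (tail == "strict") x else x - 1
  logp <- phyper(q, y, N - y, M, lower.tail = FALSE, log.p = TRUE)
  pmin(pmax(exp(logp), .Machine$double.eps), 1)
}

#' Enrichment test over all value classes of the profiled parameters
#'
#' For each parameter and each of its occupied value classes (classes with
#' at least one sampled value: all five for `K`-type parameters, the two
#' covered by the narrower `k` range for `k`-type), tests whether kinetic
#' solutions are over-represented in the class.
#'
#' @inheritParams tabulate_class_counts
#' @param alpha Significance threshold on the raw p-value (no
#'   multiple-testing correction). Default `1e-3`.
#' @param parameters Parameters to profile. Defaults to
#'   [profiled_parameters()] of the screen's model (the input edge is
#'   excluded).
#' @param tail Tail convention, see [enrichment_pvalue()].
#' @return A tibble of class `kinetic_enrichment`: `parameter`, `class`,
#'   `interval`, `x`, `y`, `p`, `p_label`, `significant`; attributes `M`,
#'   `N`, `alpha`, `scheme`.
#' @export
enrich_classes <- function(screened, scheme = value_class_scheme(),
                           alpha = 1e-3, parameters = NULL,
                           tail = c("strict", "inclusive")) {
  tail <- match.arg(tail)
  if (is.null(parameters)) {
    model <- attr(screened, "model")
    parameters <- if (!is.null(model)) profiled_parameters(model) else
      stop("supply `parameters` for screens without a stored model",
           call. = FALSE)
  }
  rows <- purrr::map_dfr(parameters, function(p) {
    ct <- tabulate_class_counts(screened, p, scheme)
    occupied <- which(ct$y > 0)
    pv <- enrichment_pvalue(ct$x[occupied], ct$y[occupied], ct$M, ct$N,
                            tail = tail)
    tibble(parameter = p, class = occupied,
           interval = scheme$labels[occupied],
           x = ct$x[occupied], y = ct$y[occupied], p = pv,
           p_label = format_pvalue(pv), significant = pv < alpha)
  })
  ct1 <- tabulate_class_counts(screened, parameters[1], scheme)
  structure(rows,
            class = c("kinetic_enrichment", class(tibble())),
            M = ct1$M, N = ct1$N, alpha = alpha, scheme = scheme,
            tail = tail)
}

#' Detect kinetic motifs from an enrichment table
#'
#' A parameter's motif is the union of its significantly enriched value
#' classes; parameters with no significant class are motif-free and absent
#' from the result.
#'
#' @param enrichment A `kinetic_enrichment` table from [enrich_classes()].
#' @param alpha Significance threshold; defaults to the one stored in the
#'   table.
#' @return A tibble of class `kinetic_motifs`: `parameter`, `classes`
#'   (list-column of class indices), `interval` (human-readable union, e.g.
#'   `"[1e-03,1e-01]"`); attribute `scheme`.
#' @export
detect_motifs <- function(enrichment, alpha = attr(enrichment, "alpha")) {
  stopifnot(alpha > 0, alpha < 1)
  scheme <- attr(enrichment, "scheme")
  sig <- enrichment[enrichment$p < alpha, ]
  motifs <- sig |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(classes = list(sort(.data$class)), .groups = "drop") |>
    dplyr::mutate(interval = purrr::map_chr(.data$classes, motif_interval,
                                            scheme = scheme))
  structure(motifs,
            class = c("kinetic_motifs", class(tibble())),
            scheme = scheme)
}

# label the union of classes as interval(s), merging contiguous runs
motif_interval <- function(classes, scheme) {
  b <- scheme$breaks
  runs <- split(classes, cumsum(c(1, diff(classes) != 1)))
  paste(vapply(runs, function(r) {
    sprintf("[%.0e,%.0e]", b[min(r)], b[max(r) + 1])
  }, character(1)), collapse = " u ")
}

#' Motif membership of parameter values
#'
#' @param value Numeric vector of parameter values.
#' @param classes Integer vector of motif class indices.
#' @param scheme A [value_class_scheme()].
#' @return Logical vector: does each value fall in one of the motif classes?
#' @export
in_motif <- function(value, classes, scheme = value_class_scheme()) {
  assign_value_class(value, scheme) %in% classes
}

#' @export
tidy.kinetic_enrichment <- function(x, ...) {
  as_tibble(unclass_enrichment(x))
}

#' @export
glance.kinetic_enrichment <- function(x, ...) {
  tibble(
    N = attr(x, "N"), M = attr(x, "M"),
    n_tests = nrow(x),
    n_significant = sum(x$significant),
    n_motif_parameters = dplyr::n_distinct(x$parameter[x$significant]),
    alpha = attr(x, "alpha")
  )
}

unclass_enrichment <- function(x) {
  for (a in c("M", "N", "alpha", "scheme", "tail")) attr(x, a) <- NULL
  class(x) <- class(tibble())
  x
}
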