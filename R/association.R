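#' Partition screened sets into motif and non-motif groups
#'
#' Splits all OK-classified (i.e. scored) screened rows by whether the given
#' parameter's value falls inside the motif interval. These two groups are
#' the basis of the functional-association rank test.
#'
#' @inheritParams tabulate_class_counts
#' @param parameter Parameter name.
#' @param classes Integer vector of motif class indices for that parameter.
#' @return The OK rows of `screened` as a tibble with a logical `in_motif`
#'   column. Errors when either group is empty.
#' @export
partition_by_motif <- function(screened, parameter, classes,
                               scheme = value_class_scheme()) {
  ok <- as_tibble(screened)[!is.na(screened$outcome) &
                              screened$outcome == "OK", ]
  ok$in_motif <- in_motif(ok[[parameter]], classes, scheme)
  if (!any(ok$in_motif) || all(ok$in_motif)) {
    stop("degenerate motif partition for ", parameter,
         ": one group is empty (scheme/range mismatch?)", call. = FALSE)
  }
  ok
}

#' Mann-Whitney rank-sum z-score
#'
#' Tie-corrected normal approximation of the Mann-Whitney U statistic, with
#' no continuity correction. Sign convention: positive when `a` is
#' stochastically larger than `b`. Fully degenerate data (every value tied)
#' gives z = 0.
#'
#' @param a,b Non-empty numeric vectors (infinite values allowed; they rank
#'   above/below everything finite).
#' @return A single z-score.
#' @export
#' @examples
#' mann_whitney_z(c(3, 4, 5), c(1, 2)) # +sqrt(3)
mann_whitney_z <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(0)
  (U - mu) / sqrt(sigma2)
}

#' Function labels from association z-scores
#'
#' A motif is labelled `PR` (improves precision) when its precision z-score
#' exceeds `z_crit`, and `SN` (improves sensitivity) when its sensitivity
#' z-score does. Only positive exceedances count: a strongly negative
#' z-score marks a detrimental, not an associated, role.
#'
#' @param z_sensitivity,z_precision Numeric z-score vectors.
#' @param z_crit Critical value; 3.29 is the upper 99.9% confidence bound.
#' @return Character vector of labels: `"PR"`, `"SN"`, `"PR,SN"`, or `""`.
#' @export
#' @examples
#' classify_function(z_sensitivity = 26.57, z_precision = 9.23) # "PR,SN"
classify_function <- function(z_sensitivity, z_precision, z_crit = 3.29) {
  mapply(function(zs, zp) {
    paste(c(if (zp > z_crit) "PR", if (zs > z_crit) "SN"), collapse = ",")
  }, z_sensitivity, z_precision, USE.NAMES = FALSE)
}

#' Associate kinetic motifs with sensitivity and precision
#'
#' For each motif parameter, compares the sensitivity and precision scores
#' of the motif group against the non-motif group (both drawn from all
#' OK-classified screened sets) with the Mann-Whitney rank test, reports the
#' group medians alongside the z-scores, and labels the motif's functional
#' role(s).
#'
#' @inheritParams tabulate_class_counts
#' @param motifs A `kinetic_motifs` table from [detect_motifs()].
#' @param z_crit Critical z. Default 3.29 (99.9% confidence).
#' @return A tibble of class `kinetic_association`: `parameter`, `motif`,
#'   `n_motif`, `n_non_motif`, `Pr_m`, `Pr_nm`, `z_precision`, `Sn_m`,
#'   `Sn_nm`, `z_sensitivity`, `functions`.
#' @export
associate_functions <- function(screened, motifs,
                                scheme = attr(motifs, "scheme"),
                                z_crit = 3.29) {
  if (is.null(scheme)) scheme <- value_class_scheme()
  rows <- purrr::pmap_dfr(
    list(motifs$parameter, motifs$classes, motifs$interval),
    function(p, classes, interval) {
      part <- partition_by_motif(screened, p, classes, scheme)
      m <- part[part$in_motif, ]
      nm <- part[!part$in_motif, ]
      tibble(
        parameter = p, motif = interval,
        n_motif = nrow(m), n_non_motif = nrow(nm),
        Pr_m = median(m$precision), Pr_nm = median(nm$precision),
        z_precision = mann_whitney_z(m$precision, nm$precision),
        Sn_m = median(m$sensitivity), Sn_nm = median(nm$sensitivity),
        z_sensitivity = mann_whitney_z(m$sensitivity, nm$sensitivity)
      )
    })
  rows$functions <- classify_function(rows$z_sensitivity, rows$z_precision,
                                      z_crit)
  structure(rows,
            class = c("kinetic_association", class(tibble())),
            z_crit = z_crit, scheme = scheme)
}

#' Bipartite kinetic-functionality network
#'
#' Left part: kinetic motifs (parameter plus enriched interval); right part:
#' the two functionalities, sensitivity and precision. An edge records a
#' significant positive association.
#'
#' @param association A `kinetic_association` from [associate_functions()].
#' @return An igraph graph with vertex attributes `type` (`FALSE` = motif,
#'   `TRUE` = function), `motif` (interval label for motif vertices).
#' @export
build_bipartite_network <- function(association) {
  motif_v <- tibble(name = association$parameter, type = FALSE,
                    motif = association$motif)
  fun_v <- tibble(name = c("sensitivity", "precision"), type = TRUE,
                  motif = NA_character_)
  edges <- dplyr::bind_rows(
    tibble(from = association$parameter[grepl("PR", association$functions)],
           to = "precision"),
    tibble(from = association$parameter[grepl("SN", association$functions)],
           to = "sensitivity")
  )
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = dplyr::bind_rows(motif_v, fun_v))
}

#' Pairwise cooperation of motif parameters among kinetic solutions
#'
#' Pearson correlation between every unordered pair of motif parameters,
#' computed over the kinetic-solution rows only. Values are log10-
#' transformed by default (sampling is log-uniform across decades, so the
#' raw scale is dominated by the top decade); `scale = "raw"` uses the
#' original values. A pair is flagged `correlated` when the two-sided
#' p-value is below `alpha`.
#'
#' @inheritParams associate_functions
#' @param scale `"log10"` (default) or `"raw"`.
#' @param alpha Correlation significance threshold. Default 0.05.
#' @return A tibble: `parameter_1`, `parameter_2`, `r`, `p`, `correlated`
#'   (self-pairs included with r = 1 for completeness of the symmetric
#'   matrix).
#' @export
pairwise_cooperation <- function(screened, motifs,
                                 scale = c("log10", "raw"), alpha = 0.05) {
  scale <- match.arg(scale)
  sol <- as_tibble(screened)[!is.na(screened$is_solution) &
                               screened$is_solution, ]
  if (nrow(sol) < 3) {
    stop("need at least 3 kinetic solutions for correlation tests",
         call. = FALSE)
  }
  pars <- motifs$parameter
  vals <- as.matrix(sol[pars])
  if (scale == "log10") vals <- log10(vals)
  pairs <- expand.grid(i = seq_along(pars), j = seq_along(pars))
  pairs <- pairs[pairs$i <= pairs$j, ]
  purrr::map2_dfr(pairs$i, pairs$j, function(i, j) {
    if (i == j) {
      tibble(parameter_1 = pars[i], parameter_2 = pars[j],
             r = 1, p = 0, correlated = TRUE)
    } else {
      ct <- cor.test(vals[, i], vals[, j], method = "pearson")
      tibble(parameter_1 = pars[i], parameter_2 = pars[j],
             r = unname(ct$estimate), p = ct$p.value,
             correlated = ct$p.value < alpha)
    }
  })
}

#' @export
tidy.kinetic_association <- function(x, ...) {
  out <- x
  attr(out, "z_crit") <- NULL
  attr(out, "scheme") <- NULL
  class(out) <- class(tibble())
  out
}

#' @export
glance.kinetic_association <- function(x, ...) {
  tibble(
    n_motifs = nrow(x),
    n_precision = sum(grepl("PR", x$functions)),
    n_sensitivity = sum(grepl("SN", x$functions)),
    n_dual = sum(x$functions == "PR,SN"),
    z_crit = attr(x, "z_crit")
  )
}
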