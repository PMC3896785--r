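#' Format p-values the way enrichment tables print them
#'
#' Scientific notation with two significant digits; values at or below
#' machine epsilon print as `"<2.2E-16"`.
#'
#' @param p Numeric p-value vector.
#' @return Character vector.
#' @export
#' @examples
#' format_pvalue(c(7.6e-4, 1, 1e-30))
format_pvalue <- function(p) {
  ifelse(p <= .Machine$double.eps, "<2.2E-16",
         toupper(formatC(p, format = "e", digits = 1)))
}

# numeric -> character with the literal "inf" sentinel, and back
serialize_inf <- function(tbl, cols) {
  for (col in intersect(cols, names(tbl))) {
    v <- tbl[[col]]
    tbl[[col]] <- ifelse(is.finite(v) | is.na(v),
                         formatC(v, format = "g", digits = 17), "inf")
  }
  tbl
}

parse_inf <- function(tbl, cols) {
  for (col in intersect(cols, names(tbl))) {
    v <- tbl[[col]]
    if (is.character(v)) {
      tbl[[col]] <- ifelse(v == "inf", Inf, suppressWarnings(as.numeric(v)))
    }
  }
  tbl
}

#' Write and read per-set screening outcomes
#'
#' One row per screened parameter set: the parameter values, outcome class,
#' `O1`, `Op`, `O2`, sensitivity, precision, and the solution flag. Infinite
#' precision (perfect adaptation) is serialized as the literal `"inf"` and
#' restored on read.
#'
#' @param screened A `kinetic_screen`.
#' @param path CSV file path.
#' @return `write_screen_csv()` returns `path` invisibly; `read_screen_csv()`
#'   returns a tibble (scores restored to numeric, `Inf` included).
#' @export
write_screen_csv <- function(screened, path) {
  tbl <- serialize_inf(as_tibble(unclass_screen(screened)),
                       c("precision", "settle_time"))
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_screen_csv
#' @export
read_screen_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           outcome = readr::col_character(),
                           precision = readr::col_character(),
                           settle_time = readr::col_character(),
                           .default = readr::col_guess()))
  parse_inf(tbl, c("precision", "settle_time"))
}

#' Write and read an enrichment table
#'
#' Mirrors the published layout (parameter x class: counts, p-value,
#' significance flag). The numeric `p` column keeps full precision; the
#' `p_label` column carries the two-significant-digit scientific form with
#' the `"<2.2E-16"` sentinel.
#'
#' @param enrichment A `kinetic_enrichment`.
#' @param path CSV file path.
#' @export
write_enrichment_csv <- function(enrichment, path) {
  readr::write_csv(as_tibble(unclass_enrichment(enrichment)), path)
  invisible(path)
}

#' @rdname write_enrichment_csv
#' @export
read_enrichment_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write and read detected motifs as JSON
#'
#' Parameter name mapped to its motif classes and the interval endpoints
#' (powers of 10) of each contiguous run.
#'
#' @param motifs A `kinetic_motifs` table.
#' @param path JSON file path.
#' @export
write_motifs_json <- function(motifs, path) {
  scheme <- attr(motifs, "scheme")
  b <- scheme$breaks
  obj <- setNames(purrr::map2(motifs$classes, motifs$interval,
                              function(cl, lab) {
                                list(classes = cl,
                                     lower = b[cl],
                                     upper = b[cl + 1],
                                     interval = lab)
                              }),
                  motifs$parameter)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_motifs_json
#' @param scheme Scheme to attach on read (defaults to the standard one).
#' @export
read_motifs_json <- function(path, scheme = value_class_scheme()) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  motifs <- tibble(
    parameter = names(obj),
    classes = unname(purrr::map(obj,
                                function(o) as.integer(unlist(o$classes)))),
    interval = unname(purrr::map_chr(obj, "interval"))
  )
  structure(motifs, class = c("kinetic_motifs", class(tibble())),
            scheme = scheme)
}

#' Export the bipartite kinetic-functionality network
#'
#' GraphML (via igraph) plus a plain JSON node/edge list.
#'
#' @param graph An igraph graph from [build_bipartite_network()].
#' @param path Output path (`.graphml` or `.json` decides the format).
#' @export
write_network <- function(graph, path) {
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    nodes <- tibble(
      name = igraph::V(graph)$name,
      type = ifelse(igraph::V(graph)$type, "function", "motif"),
      motif = igraph::V(graph)$motif
    )
    el <- igraph::as_edgelist(graph)
    edges <- tibble(from = el[, 1], to = el[, 2])
    jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (grepl("\\.graphml$", path)) {
    g <- igraph::read_graph(path, format = "graphml")
    igraph::V(g)$type <- as.logical(igraph::V(g)$type)
    g
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    igraph::graph_from_data_frame(
      obj$edges, directed = FALSE,
      vertices = transform(obj$nodes, type = obj$nodes$type == "function"))
  }
}
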