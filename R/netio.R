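#' Read a STRING links-style scored edge table
#'
#' Parses a tab/whitespace-separated file with a header naming at least
#' \code{protein1}, \code{protein2} and \code{combined_score}; any other
#' integer columns are kept as evidence-channel scores (STRING channels such
#' as \code{experiments}, \code{experiments_transferred}, \code{database},
#' \code{coexpression}, ...). Duplicate rows for the same unordered pair are
#' collapsed keeping the row with the maximum combined score, and the filter
#' is applied after that collapse. The returned network contains exactly the
#' surviving edges and their endpoint nodes.
#'
#' @param path input file.
#' @param filter an \code{\link{edge_filter}}.
#' @param species_label species label for the resulting network.
#' @return a \code{\link{ppi_network}}.
#' @export
read_string_tsv <- function(path, filter = edge_filter(), species_label = "") {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_fmt("%s: empty file, expected a header line", path)
  header <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
  needed <- c("protein1", "protein2", "combined_score")
  miss <- setdiff(needed, header)
  if (length(miss) > 0L) {
    stop_fmt("%s: header is missing required column(s): %s",
             path, paste(miss, collapse = ", "))
  }
  body <- lines[-1L]
  if (length(body) == 0L) {
    return(ppi_network(species = species_label))
  }
  rows <- strsplit(trimws(body), "[ \t]+")
  nf <- lengths(rows)
  bad <- which(nf != length(header))
  if (length(bad) > 0L) {
    stop_fmt("%s: line %d has %d fields, expected %d",
             path, bad[[1L]] + 1L, nf[[bad[[1L]]]], length(header))
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- header
  score_cols <- setdiff(header, c("protein1", "protein2"))
  edges <- data.frame(from = mat[, "protein1"], to = mat[, "protein2"],
                      stringsAsFactors = FALSE)
  for (cc in score_cols) {
    v <- suppressWarnings(as.numeric(mat[, cc]))
    bad <- which(is.na(v) | v != round(v))
    if (length(bad) > 0L) {
      stop_fmt("%s: line %d: column '%s' is not an integer score ('%s')",
               path, bad[[1L]] + 1L, cc, mat[bad[[1L]], cc])
    }
    edges[[if (cc == "combined_score") "combined_score" else cc]] <- as.integer(v)
  }
  net <- ppi_network(edges = edges, species = species_label)
  filter_network(net, filter, prune_orphans = TRUE)
}

#' Read a plain two/three-column edge list
#'
#' Accepts whitespace/tab-separated rows \code{id id [score]}. The score
#' scale is auto-detected: if any score exceeds 1 the values are taken as
#' STRING-style 0-1000 integers, otherwise as fractions in [0, 1] (scaled by
#' 1000). Rows without a score get combined score 1000. Files with no
#' evidence columns are treated as experimentally supported: the
#' \code{experiments} channel is set to the combined score. Lines starting
#' with \code{#} are comments, except \code{#node<TAB>id} records, which
#' declare isolated nodes (written by \code{\link{write_network}} so TSV
#' round trips preserve the node set).
#'
#' @param path input file.
#' @param species_label species label for the resulting network.
#' @return a \code{\link{ppi_network}}.
#' @export
read_edge_list <- function(path, species_label = "") {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  iso <- grepl("^#node[ \t]", lines)
  iso_nodes <- if (any(iso)) {
    vapply(strsplit(lines[iso], "[ \t]+"), `[[`, "", 2L)
  } else character()
  keep <- nzchar(trimws(lines)) & !grepl("^#", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) {
    return(ppi_network(nodes = iso_nodes, species = species_label))
  }
  rows <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(rows)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad) > 0L) {
    stop_fmt("%s: line %d has %d column(s), expected 2 or 3",
             path, lineno[[bad[[1L]]]], nf[[bad[[1L]]]])
  }
  from <- vapply(rows, `[[`, "", 1L)
  to <- vapply(rows, `[[`, "", 2L)
  score <- rep(NA_real_, length(rows))
  has3 <- nf == 3L
  if (any(has3)) {
    v <- suppressWarnings(as.numeric(vapply(rows[has3], `[[`, "", 3L)))
    if (anyNA(v)) {
      i <- which(has3)[which(is.na(v))[[1L]]]
      stop_fmt("%s: line %d: unparsable score", path, lineno[[i]])
    }
    score[has3] <- v
  }
  combined <- rep(1000L, length(rows))
  if (any(has3)) {
    raw_scale <- any(score[has3] > 1)
    combined[has3] <- if (raw_scale) as.integer(round(score[has3]))
                      else as.integer(round(score[has3] * 1000))
  }
  edges <- data.frame(from = from, to = to, combined_score = combined,
                      experiments = combined, stringsAsFactors = FALSE)
  # endpoints of dropped self-loops stay in the node set
  ppi_network(edges = edges, nodes = unique(c(iso_nodes, from, to)),
              species = species_label)
}

#' Write a network to SIF, GraphML or TSV
#'
#' TSV writes \code{from<TAB>to<TAB>score} with the combined score as a
#' fraction to 3 decimals, plus \code{#node} records for isolated nodes, so
#' \code{\link{read_edge_list}} reproduces the node and edge sets exactly.
#' SIF uses interaction type \code{pp} (isolated nodes as single-token
#' lines). GraphML (via igraph) stores the species label as node attribute
#' \code{species} and the combined score as edge attribute
#' \code{combined_score} -- directly loadable in Cytoscape.
#'
#' @param net a \code{\link{ppi_network}}.
#' @param path output file.
#' @param format one of \code{"tsv"}, \code{"sif"}, \code{"graphml"}.
#' @return invisibly, \code{path}.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(net, "ppi_network"))
  format <- match.arg(tolower(format[[1L]]), c("tsv", "sif", "graphml"))
  e <- net$edges
  isolated <- setdiff(net$nodes, unique(c(e$from, e$to)))
  if (format == "tsv") {
    out <- character()
    if (nrow(e) > 0L) {
      out <- sprintf("%s\t%s\t%.3f", e$from, e$to, e$combined_score / 1000)
    }
    if (length(isolated) > 0L) out <- c(out, sprintf("#node\t%s", isolated))
    writeLines(out, path)
  } else if (format == "sif") {
    out <- character()
    if (nrow(e) > 0L) out <- sprintf("%s pp %s", e$from, e$to)
    if (length(isolated) > 0L) out <- c(out, isolated)
    writeLines(out, path)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert between ppi_network and igraph
#'
#' @param net a \code{\link{ppi_network}}.
#' @return an undirected \code{igraph} graph with node attribute
#'   \code{species} and edge attributes \code{combined_score} (0-1000) plus
#'   any channel scores.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  verts <- data.frame(name = net$nodes, species = rep(net$species, n_nodes(net)),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(net$edges, directed = FALSE, vertices = verts)
}

#' Read a GraphML network written by \code{\link{write_network}}
#'
#' @param path GraphML file.
#' @param species_label species label; defaults to the stored \code{species}
#'   node attribute when present.
#' @return a \code{\link{ppi_network}}.
#' @export
read_network_graphml <- function(path, species_label = NULL) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::V(g)$name
  sp <- species_label
  if (is.null(sp)) {
    va <- igraph::vertex_attr(g, "species")
    sp <- if (!is.null(va) && length(va) > 0L) va[[1L]] else ""
  }
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- NULL
  if (nrow(el) > 0L) {
    edges <- el
    names(edges)[1:2] <- c("from", "to")
  }
  ppi_network(edges = edges, nodes = nodes, species = sp)
}
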