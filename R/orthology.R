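#' Many-to-many ortholog correspondence
#'
#' The predicted ortholog mapping between two species' protein identifiers,
#' as produced by compendia like OrthoList2. Pairs form a set; an identifier
#' on either side may take part in several pairs (one-to-many and
#' many-to-many mappings are common and are what makes a "perfect"
#' one-to-one network alignment unreachable in general).
#'
#' @param pairs data.frame (or two-column matrix) with columns \code{a} and
#'   \code{b}: species-A and species-B identifiers.
#' @return an object of class \code{ortholog_map} with elements
#'   \code{pairs} (deduplicated, sorted), \code{forward} (list: A-id ->
#'   character vector of B-ids) and \code{reverse} (B-id -> A-ids).
#' @export
ortholog_map <- function(pairs = NULL) {
  if (is.null(pairs) || nrow(as.data.frame(pairs)) == 0L) {
    pairs <- data.frame(a = character(), b = character(),
                        stringsAsFactors = FALSE)
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L) stop_fmt("ortholog pairs need two columns")
  pairs <- data.frame(a = as.character(pairs[[1L]]),
                      b = as.character(pairs[[2L]]),
                      stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 forward = split(pairs$b, pairs$a),
                 reverse = split(pairs$a, pairs$b)),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  multi <- sum(lengths(x$forward) > 1L)
  cat(sprintf(
    "ortholog_map: %d pairs, %d A-ids (%d one-to-many), %d B-ids\n",
    nrow(x$pairs), length(x$forward), multi, length(x$reverse)))
  invisible(x)
}

#' Read a two-column ortholog table
#'
#' @param path TSV with two columns (species-A id, species-B id); an
#'   optional header line is detected and skipped when its fields repeat in
#'   no data row (conventional header words like \code{human}/\code{worm}
#'   are simply treated as a pair otherwise, so prefer headerless files).
#'   Lines starting with \code{#} are ignored.
#' @param header logical; \code{NA} (default) auto-detects a first line
#'   whose second field matches \code{id|ortholog|gene|protein} case
#'   insensitively.
#' @return an \code{\link{ortholog_map}}.
#' @export
read_ortholog_table <- function(path, header = NA) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !grepl("^#", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) return(ortholog_map())
  rows <- strsplit(trimws(lines), "[ \t]+")
  if (is.na(header)) {
    header <- length(rows) > 0L &&
      grepl("id$|ortholog|gene|protein", rows[[1L]][min(2L, length(rows[[1L]]))],
            ignore.case = TRUE)
  }
  if (isTRUE(header)) {
    rows <- rows[-1L]
    lineno <- lineno[-1L]
  }
  if (length(rows) == 0L) return(ortholog_map())
  nf <- lengths(rows)
  bad <- which(nf != 2L)
  if (length(bad) > 0L) {
    stop_fmt("%s: line %d has %d column(s), expected 2",
             path, lineno[[bad[[1L]]]], nf[[bad[[1L]]]])
  }
  ortholog_map(data.frame(a = vapply(rows, `[[`, "", 1L),
                          b = vapply(rows, `[[`, "", 2L),
                          stringsAsFactors = FALSE))
}

#' Write an ortholog table
#' @param map an \code{\link{ortholog_map}}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_ortholog_table <- function(map, path) {
  stopifnot(inherits(map, "ortholog_map"))
  utils::write.table(map$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Is (a, b) a predicted ortholog pair?
#'
#' @param map an \code{\link{ortholog_map}}.
#' @param a species-A identifier.
#' @param b species-B identifier.
#' @return \code{TRUE} iff the pair is in the map; unknown identifiers give
#'   \code{FALSE}, never an error.
#' @export
is_ortholog_pair <- function(map, a, b) {
  stopifnot(inherits(map, "ortholog_map"))
  fw <- map$forward[[as.character(a)]]
  !is.null(fw) && as.character(b) %in% fw
}

#' Restrict an ortholog map to nodes present in two networks
#'
#' Evaluation of an alignment must only consider correspondences that the
#' alignment could possibly realize, i.e. pairs whose endpoints exist in the
#' respective networks.
#'
#' @param map an \code{\link{ortholog_map}} (A side = \code{netA} species).
#' @param netA,netB \code{\link{ppi_network}}s for the A and B side.
#' @return the restricted \code{\link{ortholog_map}}, with attribute
#'   \code{n_a_with_ortholog}: how many \code{netA} nodes retain >= 1
#'   ortholog.
#' @export
restrict_to_networks <- function(map, netA, netB) {
  stopifnot(inherits(map, "ortholog_map"),
            inherits(netA, "ppi_network"), inherits(netB, "ppi_network"))
  p <- map$pairs
  p <- p[p$a %in% netA$nodes & p$b %in% netB$nodes, , drop = FALSE]
  out <- ortholog_map(p)
  attr(out, "n_a_with_ortholog") <- length(out$forward)
  out
}
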