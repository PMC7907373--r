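#' Species-labeled PPI network
#'
#' An undirected protein-protein interaction network with a per-edge combined
#' confidence score on the STRING 0-1000 integer scale and optional
#' evidence-channel scores (e.g. \code{experiments},
#' \code{experiments_transferred}). Edges are stored canonically with
#' \code{from < to} (string order); self-loops are forbidden and each
#' unordered pair appears at most once. Nodes without surviving edges are
#' retained when explicitly listed (seeds or partners can legitimately be
#' left with no PPIs after evidence filtering).
#'
#' @param edges data.frame with character columns \code{from}, \code{to}, an
#'   integer \code{combined_score} in [0, 1000] (defaults to 1000 when
#'   absent), and any number of additional integer channel-score columns.
#' @param nodes optional character vector of node ids; endpoints of
#'   \code{edges} are always included.
#' @param species free-text species label.
#' @return an object of class \code{ppi_network}.
#' @export
ppi_network <- function(edges = NULL, nodes = character(), species = "") {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        combined_score = integer(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(edges))) {
    stop_fmt("edge table must have 'from' and 'to' columns")
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(edges$combined_score)) edges$combined_score <- rep(1000L, nrow(edges))
  score_cols <- setdiff(names(edges), c("from", "to"))
  for (cc in score_cols) {
    v <- edges[[cc]]
    if (!is.numeric(v)) stop_fmt("edge score column '%s' must be numeric", cc)
    v <- as.integer(round(v))
    if (any(v < 0L | v > 1000L, na.rm = TRUE)) {
      stop_fmt("edge score column '%s' outside [0, 1000]", cc)
    }
    edges[[cc]] <- v
  }
  # drop self-loops, canonicalize orientation, collapse duplicates (max score)
  loops <- edges$from == edges$to
  if (any(loops)) {
    warn_fmt("dropping %d self-loop(s)", sum(loops))
    edges <- edges[!loops, , drop = FALSE]
  }
  swap <- edges$from > edges$to
  if (any(swap)) {
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  if (nrow(edges) > 1L) {
    key <- paste(edges$from, edges$to, sep = "\r")
    ord <- order(key, -edges$combined_score)
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  structure(list(species = species, nodes = nodes, edges = edges),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network '%s': %d nodes, %d edges\n",
              x$species, n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Node and edge counts
#' @param net a \code{ppi_network}.
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

edge_keys <- function(net) paste(net$edges$from, net$edges$to, sep = "\r")

# Logical adjacency matrix over net$nodes (sorted id order).
adjacency_matrix <- function(net) {
  n <- n_nodes(net)
  A <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  if (n_edges(net) > 0L) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    A[cbind(i, j)] <- TRUE
    A[cbind(j, i)] <- TRUE
  }
  A
}

#' Edge confidence filter
#'
#' Encodes the STRING-style confidence cutoff (a fraction of the 0-1000
#' combined score, e.g. 0.7 for high confidence, 0.9 for highest) and the
#' experimental-evidence requirement. When \code{require_experimental} is
#' set, an edge survives only if its direct \code{experiments} channel is
#' positive; homology-transferred experimental evidence
#' (\code{experiments_transferred}) only counts when
#' \code{allow_transferred_evidence} is also set.
#'
#' @param min_combined minimum combined score as a fraction in [0, 1].
#' @param require_experimental require positive experimental evidence.
#' @param allow_transferred_evidence accept transferred experimental evidence.
#' @return an object of class \code{edge_filter}.
#' @export
edge_filter <- function(min_combined = 0, require_experimental = FALSE,
                        allow_transferred_evidence = FALSE) {
  if (!is.numeric(min_combined) || length(min_combined) != 1L ||
      is.na(min_combined) || min_combined < 0 || min_combined > 1) {
    stop_fmt("min_combined must be a single number in [0, 1]")
  }
  structure(list(min_combined = min_combined,
                 require_experimental = isTRUE(require_experimental),
                 allow_transferred_evidence = isTRUE(allow_transferred_evidence)),
            class = "edge_filter")
}

#' Apply an edge filter to a network
#'
#' @param net a \code{ppi_network}.
#' @param filter an \code{edge_filter}.
#' @param prune_orphans drop nodes left without edges (default keeps them,
#'   mirroring datasets where evidence filtering leaves proteins with no
#'   PPIs).
#' @return the filtered \code{ppi_network}.
#' @export
filter_network <- function(net, filter = edge_filter(), prune_orphans = FALSE) {
  stopifnot(inherits(net, "ppi_network"), inherits(filter, "edge_filter"))
  e <- net$edges
  keep <- e$combined_score >= as.integer(round(filter$min_combined * 1000))
  if (filter$require_experimental) {
    ev <- if ("experiments" %in% names(e)) e$experiments else rep(0L, nrow(e))
    if (filter$allow_transferred_evidence &&
        "experiments_transferred" %in% names(e)) {
      ev <- ev + e$experiments_transferred
    }
    keep <- keep & ev > 0L
  }
  e <- e[keep, , drop = FALSE]
  nodes <- if (prune_orphans) character() else net$nodes
  ppi_network(edges = e, nodes = nodes, species = net$species)
}

#' Extract the subnetwork seeded by chosen proteins
#'
#' Returns the subgraph induced on the seeds, their direct interaction
#' partners, and every interaction among that node set (including
#' partner-partner edges) -- the construction used to pull a disease-focused
#' neighborhood (e.g. APP, Tau and their partners) out of a larger
#' interactome.
#'
#' @param net a \code{ppi_network}.
#' @param seeds character vector of seed node ids; seeds absent from the
#'   network are reported (all absent is an error).
#' @return the induced \code{ppi_network}.
#' @export
extract_seeded_subnetwork <- function(net, seeds) {
  stopifnot(inherits(net, "ppi_network"))
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop_fmt("seeds must be non-empty")
  missing <- setdiff(seeds, net$nodes)
  present <- intersect(seeds, net$nodes)
  if (length(present) == 0L) {
    stop_fmt("no seed found in network: %s", paste(missing, collapse = ", "))
  }
  if (length(missing) > 0L) {
    warn_fmt("seed id(s) not in network: %s", paste(missing, collapse = ", "))
  }
  inc <- net$edges$from %in% present | net$edges$to %in% present
  keep_nodes <- union(present,
                      unique(c(net$edges$from[inc], net$edges$to[inc])))
  both <- net$edges$from %in% keep_nodes & net$edges$to %in% keep_nodes
  ppi_network(edges = net$edges[both, , drop = FALSE], nodes = keep_nodes,
              species = net$species)
}
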