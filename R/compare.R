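#' Evaluate an alignment against the predicted-ortholog gold standard
#'
#' A mapped pair (u, f(u)) is a correct node alignment when f(u) is any of
#' u's predicted orthologs (multi-mapping proteins make a perfect one-to-one
#' alignment impossible, so matching any predicted ortholog counts). Only
#' source nodes with at least one ortholog present in the target network are
#' evaluable; the rest are reported separately. Aligned interactions are the
#' conserved source edges; interologs are the conserved edges whose both
#' endpoint pairs are correct -- conserved interactions between orthologs.
#'
#' @param aln a \code{\link{network_alignment}} from \code{G} into \code{H}.
#' @param G source \code{\link{ppi_network}}.
#' @param H target \code{\link{ppi_network}}.
#' @param map an \code{\link{ortholog_map}} (restricted internally to the
#'   two networks).
#' @param similarity optional similarity matrix for the mean pair
#'   similarity.
#' @return an object of class \code{evaluation_report}: list with
#'   \code{n_mapped_pairs} (evaluable mapped pairs),
#'   \code{unevaluable_pairs}, \code{correct_node_alignments},
#'   \code{incorrect_node_alignments}, \code{aligned_interactions},
#'   \code{interologs_identified}, \code{s3}, \code{mean_pair_similarity}.
#' @export
evaluate_alignment <- function(aln, G, H, map, similarity = NULL) {
  check_alignment(aln, G, H)
  stopifnot(inherits(map, "ortholog_map"))
  map <- restrict_to_networks(map, G, H)
  src <- names(aln$mapping)
  tgt <- unname(aln$mapping)
  evaluable <- src %in% names(map$forward)
  correct_flag <- rep(FALSE, length(src))
  if (any(evaluable)) {
    correct_flag[evaluable] <- vapply(which(evaluable), function(k) {
      is_ortholog_pair(map, src[[k]], tgt[[k]])
    }, FALSE)
  }
  cons <- conserved_edges(aln, G, H)
  correct_nodes <- src[correct_flag]
  interologs <- cons[cons$from %in% correct_nodes &
                     cons$to %in% correct_nodes, , drop = FALSE]
  sim <- similarity_of_pairs(similarity, src, tgt)
  structure(list(
    n_mapped_pairs = sum(evaluable),
    unevaluable_pairs = sum(!evaluable),
    correct_node_alignments = sum(correct_flag),
    incorrect_node_alignments = sum(evaluable & !correct_flag),
    aligned_interactions = nrow(cons),
    interologs_identified = nrow(interologs),
    s3 = as.numeric(s3_score(aln, G, H)),
    mean_pair_similarity = if (is.null(similarity) || length(src) == 0L)
      NA_real_ else mean(sim),
    conserved = cons,
    interolog_edges = interologs,
    method = aln$method), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (%s)\n", x$method))
  cat(sprintf("  correct node alignments:   %d / %d\n",
              x$correct_node_alignments, x$n_mapped_pairs))
  cat(sprintf("  incorrect node alignments: %d\n", x$incorrect_node_alignments))
  cat(sprintf("  unevaluable mapped pairs:  %d\n", x$unevaluable_pairs))
  cat(sprintf("  aligned interactions:      %d\n", x$aligned_interactions))
  cat(sprintf("  interologs identified:     %d\n", x$interologs_identified))
  cat(sprintf("  S3: %.4f   mean pair similarity: %s\n", x$s3,
              if (is.na(x$mean_pair_similarity)) "NA"
              else sprintf("%.4f", x$mean_pair_similarity)))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param report an \code{evaluation_report}.
#' @param path optional file; when \code{NULL} the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
evaluation_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  x <- report[c("method", "n_mapped_pairs", "unevaluable_pairs",
                "correct_node_alignments", "incorrect_node_alignments",
                "aligned_interactions", "interologs_identified", "s3",
                "mean_pair_similarity")]
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Ortholog-guided reference alignment
#'
#' Emulates a manual alignment of the networks according to the predicted
#' ortholog mapping: candidate pairs are the ortholog pairs present in both
#' networks, assigned greedily in order of marginal conserved-edge gain
#' (ties lexicographic by source then target id), each source and each
#' target used at most once. One-to-many cases are thereby resolved toward
#' conserved interactions, and when two sources claim the same target the
#' assignment adding more conserved edges wins, the loser staying unmapped
#' (reported in \code{parameters$unmapped_with_orthologs}). Sources without
#' in-network orthologs stay unmapped, so the result is a partial alignment
#' flagged \code{partial = TRUE}.
#'
#' @param G source \code{\link{ppi_network}}.
#' @param H target \code{\link{ppi_network}}.
#' @param map an \code{\link{ortholog_map}}.
#' @return a partial \code{\link{network_alignment}} (method
#'   \code{"reference"}).
#' @export
reference_alignment <- function(G, H, map) {
  stopifnot(inherits(map, "ortholog_map"))
  map <- restrict_to_networks(map, G, H)
  cand <- map$pairs            # columns a (source), b (target), sorted lex
  adjH <- adjacency_matrix(H)
  mapping <- character()
  used_t <- character()
  target_size <- max_matching_size(cand)
  repeat {
    avail <- !(cand$a %in% names(mapping)) & !(cand$b %in% used_t)
    if (!any(avail)) break
    cc <- cand[avail, , drop = FALSE]
    gain <- vapply(seq_len(nrow(cc)), function(k) {
      s <- cc$a[[k]]
      t <- cc$b[[k]]
      nb <- union(G$edges$to[G$edges$from == s], G$edges$from[G$edges$to == s])
      nb <- nb[nb %in% names(mapping)]
      if (length(nb) == 0L) return(0L)
      sum(adjH[mapping[nb], t])
    }, 0L)
    # best gain first, ties lexicographic (cand is lex-sorted); keep only
    # assignments that do not reduce the number of pairs still alignable,
    # so the reference maps as many ortholog-bearing proteins as possible
    need <- target_size - length(mapping)
    chosen <- 0L
    for (k in order(-gain)) {
      rest <- cc[-k, , drop = FALSE]
      rest <- rest[rest$a != cc$a[[k]] & rest$b != cc$b[[k]], , drop = FALSE]
      if (max_matching_size(rest) >= need - 1L) {
        chosen <- k
        break
      }
    }
    if (chosen == 0L) break
    mapping[[cc$a[[chosen]]]] <- cc$b[[chosen]]
    used_t <- c(used_t, cc$b[[chosen]])
  }
  losers <- setdiff(names(map$forward), names(mapping))
  network_alignment(mapping, method = "reference",
                    parameters = list(unmapped_with_orthologs = losers),
                    partial = TRUE)
}

# Maximum-cardinality matching size of a bipartite candidate-pair table.
max_matching_size <- function(pairs) {
  if (nrow(pairs) == 0L) return(0L)
  a <- unique(pairs$a)
  b <- unique(pairs$b)
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("S\r", pairs$a), to = paste0("T\r", pairs$b)),
    directed = FALSE,
    vertices = data.frame(name = c(paste0("S\r", a), paste0("T\r", b)),
                          type = c(rep(FALSE, length(a)), rep(TRUE, length(b)))))
  igraph::max_bipartite_match(g)$matching_size
}

#' Unified network of an alignment
#'
#' The merged cross-species graph: nodes are aligned protein pairs
#' (source, target), edges are the conserved interactions between them. The
#' default membership rule keeps the aligned pairs incident to at least one
#' conserved edge; \code{"orthologous_pairs"} keeps pairs that are predicted
#' orthologs, \code{"all_pairs"} keeps every mapped pair. Pairs that are
#' also predicted orthologs are flagged \code{interolog_confirmed}: the
#' conserved interactions between two such pairs are interologs.
#'
#' @inheritParams evaluate_alignment
#' @param membership one of \code{"conserved_incident"},
#'   \code{"orthologous_pairs"}, \code{"all_pairs"}.
#' @return an object of class \code{unified_network}: list with
#'   \code{pairs} (data.frame source, target, interolog_confirmed) and
#'   \code{edges} (data.frame a, b of pair keys \code{"source|target"}).
#' @export
build_unified_network <- function(aln, G, H, map = NULL,
                                  membership = "conserved_incident") {
  check_alignment(aln, G, H)
  if (!membership %in% c("conserved_incident", "orthologous_pairs",
                         "all_pairs")) {
    stop_fmt("unknown membership rule '%s'", membership)
  }
  cons <- conserved_edges(aln, G, H)
  src <- names(aln$mapping)
  keep <- switch(membership,
    conserved_incident = src %in% c(cons$from, cons$to),
    orthologous_pairs = if (is.null(map)) rep(FALSE, length(src)) else
      vapply(src, function(s) is_ortholog_pair(map, s, aln$mapping[[s]]),
             FALSE),
    all_pairs = rep(TRUE, length(src)))
  psrc <- src[keep]
  pairs <- data.frame(source = psrc, target = unname(aln$mapping[psrc]),
                      stringsAsFactors = FALSE)
  pairs$interolog_confirmed <- if (is.null(map)) rep(NA, nrow(pairs)) else
    vapply(seq_len(nrow(pairs)),
           function(k) is_ortholog_pair(map, pairs$source[[k]],
                                        pairs$target[[k]]), FALSE)
  cons <- cons[cons$from %in% psrc & cons$to %in% psrc, , drop = FALSE]
  key <- stats::setNames(paste(pairs$source, pairs$target, sep = "|"),
                         pairs$source)
  a <- key[cons$from]
  b <- key[cons$to]
  edges <- data.frame(a = pmin(a, b), b = pmax(a, b),
                      stringsAsFactors = FALSE)
  edges <- unique(edges[order(edges$a, edges$b), , drop = FALSE])
  pairs <- pairs[order(pairs$source, pairs$target), , drop = FALSE]
  rownames(pairs) <- rownames(edges) <- NULL
  structure(list(pairs = pairs, edges = edges,
                 membership = membership, provenance = aln$method),
            class = "unified_network")
}

#' @export
print.unified_network <- function(x, ...) {
  cat(sprintf("unified_network (%s, %s): %d aligned pairs, %d conserved edges\n",
              x$provenance, x$membership, nrow(x$pairs), nrow(x$edges)))
  invisible(x)
}

#' Common network: intersection of two unified networks
#'
#' Keeps the protein pairs aligned identically in both unified networks and
#' the conserved interactions present in both between the retained pairs --
#' the cross-dataset "common network" construction.
#'
#' @param U1,U2 \code{unified_network}s over the same two species' id
#'   namespaces.
#' @return a \code{unified_network}.
#' @export
intersect_unified <- function(U1, U2) {
  stopifnot(inherits(U1, "unified_network"), inherits(U2, "unified_network"))
  k1 <- paste(U1$pairs$source, U1$pairs$target, sep = "|")
  k2 <- paste(U2$pairs$source, U2$pairs$target, sep = "|")
  keep <- k1 %in% k2
  pairs <- U1$pairs[keep, , drop = FALSE]
  flag2 <- stats::setNames(U2$pairs$interolog_confirmed, k2)
  pairs$interolog_confirmed <- pairs$interolog_confirmed &
    unname(flag2[k1[keep]])
  kept_keys <- k1[keep]
  e1 <- paste(U1$edges$a, U1$edges$b, sep = "\r")
  e2 <- paste(U2$edges$a, U2$edges$b, sep = "\r")
  edges <- U1$edges[e1 %in% e2 &
                    U1$edges$a %in% kept_keys &
                    U1$edges$b %in% kept_keys, , drop = FALSE]
  rownames(pairs) <- rownames(edges) <- NULL
  structure(list(pairs = pairs, edges = edges,
                 membership = U1$membership,
                 provenance = sprintf("intersect(%s, %s)",
                                      U1$provenance, U2$provenance)),
            class = "unified_network")
}

#' Export a unified network as a ppi_network
#'
#' Pair-nodes become nodes labeled \code{"sourceId|targetId"} (the
#' dual-labeled display convention), conserved edges become edges with
#' combined score 1000, ready for \code{\link{write_network}}.
#'
#' @param U a \code{unified_network}.
#' @param species species label for the export.
#' @return a \code{\link{ppi_network}}.
#' @export
unified_as_network <- function(U, species = "unified") {
  stopifnot(inherits(U, "unified_network"))
  edges <- NULL
  if (nrow(U$edges) > 0L) {
    edges <- data.frame(from = U$edges$a, to = U$edges$b,
                        combined_score = 1000L, stringsAsFactors = FALSE)
  }
  ppi_network(edges = edges,
              nodes = paste(U$pairs$source, U$pairs$target, sep = "|"),
              species = species)
}
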