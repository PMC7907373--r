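#' Objective configuration for global network alignment
#'
#' The alignment objective blends an edge-conservation term with the mean
#' sequence similarity of the mapped node pairs:
#' \deqn{alpha * edge\_term + (1 - alpha) * mean(sim[u, f(u)])}
#' \code{alpha = 1} is topology-only alignment, \code{alpha = 0} pure
#' sequence matching. The edge term defaults to S3 (symmetric substructure
#' score), which penalizes both unconserved source edges and spurious edges
#' induced on the image; plain EC (fraction of source edges conserved) is
#' selectable.
#'
#' @param alpha weight of the topological term, in [0, 1].
#' @param edge_term \code{"S3"} or \code{"EC"}.
#' @param similarity node-similarity matrix (rows = source ids, columns =
#'   target ids, values in [0, 1]) as built by
#'   \code{\link{build_similarity_matrix}}; may be \code{NULL} when
#'   \code{alpha = 1}. Pairs absent from the matrix score 0.
#' @return an object of class \code{objective_config}.
#' @export
objective_config <- function(alpha = 0.5, edge_term = c("S3", "EC"),
                             similarity = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop_fmt("alpha must be a single number in [0, 1]")
  }
  edge_term <- match.arg(toupper(edge_term[[1L]]), c("S3", "EC"))
  structure(list(alpha = alpha, edge_term = edge_term,
                 similarity = similarity),
            class = "objective_config")
}

#' One-to-one network alignment object
#'
#' @param mapping named character vector: names are source node ids, values
#'   target node ids; must be injective.
#' @param method free-text method label.
#' @param parameters list of run parameters (alpha, seed, population, ...).
#' @param objective_value the objective attained, if known.
#' @param partial \code{TRUE} for reference-style alignments that do not map
#'   every source node.
#' @return an object of class \code{network_alignment}.
#' @export
network_alignment <- function(mapping, method = "manual", parameters = list(),
                              objective_value = NA_real_, partial = FALSE) {
  mapping <- stats::setNames(as.character(mapping), names(mapping))
  if (length(mapping) > 0L && anyDuplicated(mapping) > 0L) {
    stop_fmt("alignment is not injective: target '%s' used more than once",
             mapping[duplicated(mapping)][[1L]])
  }
  if (length(mapping) > 0L && (is.null(names(mapping)) ||
                               anyDuplicated(names(mapping)) > 0L)) {
    stop_fmt("alignment mapping must have unique source-node names")
  }
  structure(list(mapping = mapping[order(names(mapping))], method = method,
                 parameters = parameters, objective_value = objective_value,
                 partial = isTRUE(partial)),
            class = "network_alignment")
}

#' @export
print.network_alignment <- function(x, ...) {
  cat(sprintf("network_alignment (%s): %d mapped pairs%s, objective %s\n",
              x$method, length(x$mapping),
              if (x$partial) " (partial)" else "",
              if (is.na(x$objective_value)) "NA"
              else sprintf("%.4f", x$objective_value)))
  invisible(x)
}

check_alignment <- function(aln, G, H, require_total = !aln$partial) {
  stopifnot(inherits(aln, "network_alignment"),
            inherits(G, "ppi_network"), inherits(H, "ppi_network"))
  unknown_s <- setdiff(names(aln$mapping), G$nodes)
  unknown_t <- setdiff(aln$mapping, H$nodes)
  if (length(unknown_s) > 0L) {
    stop_fmt("alignment maps unknown source node(s): %s",
             paste(utils::head(unknown_s, 5L), collapse = ", "))
  }
  if (length(unknown_t) > 0L) {
    stop_fmt("alignment maps to unknown target node(s): %s",
             paste(utils::head(unknown_t, 5L), collapse = ", "))
  }
  if (require_total && length(aln$mapping) != n_nodes(G)) {
    stop_fmt("alignment is not total on the source network (%d of %d nodes)",
             length(aln$mapping), n_nodes(G))
  }
  invisible(aln)
}

#' Conserved edges (aligned interactions) under an alignment
#'
#' A source edge (u, v) is conserved when its image (f(u), f(v)) is an edge
#' of the target network. For partial alignments only edges with both
#' endpoints mapped can be conserved.
#'
#' @param aln a \code{\link{network_alignment}} from \code{G} into \code{H}.
#' @param G source \code{\link{ppi_network}}.
#' @param H target \code{\link{ppi_network}}.
#' @return data.frame with columns \code{from}, \code{to} (source ids) of
#'   the conserved edges.
#' @export
conserved_edges <- function(aln, G, H) {
  check_alignment(aln, G, H)
  e <- G$edges
  fu <- aln$mapping[e$from]
  fv <- aln$mapping[e$to]
  hkeys <- edge_keys(H)
  ok <- !is.na(fu) & !is.na(fv) &
    (paste(pmin(fu, fv), pmax(fu, fv), sep = "\r") %in% hkeys)
  out <- e[ok, c("from", "to"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Symmetric substructure score (S3) of an alignment
#'
#' With C conserved edges, \eqn{|E_G|} source edges and I target edges
#' induced on the image of the mapping:
#' \deqn{S3 = C / (|E_G| + I - C)}
#' S3 is 1 exactly when the source edge set and the induced target edge set
#' coincide under the mapping. A zero denominator (both edge sets empty on
#' the mapped region) returns 0 with attribute \code{degenerate = TRUE}.
#'
#' @inheritParams conserved_edges
#' @return a number in [0, 1].
#' @export
s3_score <- function(aln, G, H) {
  check_alignment(aln, G, H)
  C <- nrow(conserved_edges(aln, G, H))
  mG <- if (aln$partial) {
    sum(G$edges$from %in% names(aln$mapping) &
        G$edges$to %in% names(aln$mapping))
  } else n_edges(G)
  img <- unname(aln$mapping)
  I <- sum(H$edges$from %in% img & H$edges$to %in% img)
  denom <- mG + I - C
  if (denom == 0L) {
    return(structure(0, degenerate = TRUE))
  }
  C / denom
}

#' Plain edge conservation (EC) of an alignment
#'
#' Fraction of source edges conserved: \eqn{C / |E_G|}; 0 (degenerate) for
#' an edgeless source.
#'
#' @inheritParams conserved_edges
#' @return a number in [0, 1].
#' @export
ec_score <- function(aln, G, H) {
  check_alignment(aln, G, H)
  mG <- if (aln$partial) {
    sum(G$edges$from %in% names(aln$mapping) &
        G$edges$to %in% names(aln$mapping))
  } else n_edges(G)
  if (mG == 0L) return(structure(0, degenerate = TRUE))
  nrow(conserved_edges(aln, G, H)) / mG
}

#' Alignment objective value
#'
#' @inheritParams conserved_edges
#' @param cfg an \code{\link{objective_config}}.
#' @return \code{alpha * edge_term + (1 - alpha) * mean pair similarity}, in
#'   [0, 1].
#' @export
alignment_objective <- function(aln, G, H, cfg) {
  stopifnot(inherits(cfg, "objective_config"))
  check_alignment(aln, G, H)
  topo <- if (cfg$edge_term == "S3") s3_score(aln, G, H) else ec_score(aln, G, H)
  sim <- 0
  if (length(aln$mapping) > 0L) {
    sim <- mean(similarity_of_pairs(cfg$similarity, names(aln$mapping),
                                    unname(aln$mapping)))
  }
  cfg$alpha * as.numeric(topo) + (1 - cfg$alpha) * sim
}

similarity_of_pairs <- function(S, src, tgt) {
  if (is.null(S) || length(src) == 0L) return(rep(0, length(src)))
  i <- match(src, rownames(S))
  j <- match(tgt, colnames(S))
  v <- rep(0, length(src))
  ok <- !is.na(i) & !is.na(j)
  v[ok] <- S[cbind(i[ok], j[ok])]
  v
}

# ---- internal fast objective machinery ------------------------------------
# Precomputed index-based view of an alignment instance. Node order on both
# sides is the sorted id order of ppi_network, so index-lexicographic equals
# id-lexicographic.
align_env <- function(G, H, cfg) {
  stopifnot(inherits(cfg, "objective_config"))
  nG <- n_nodes(G)
  nH <- n_nodes(H)
  if (nG > nH) {
    stop_fmt(paste("source network has more nodes (%d) than target (%d);",
                   "swap the networks so the smaller one is the source"),
             nG, nH)
  }
  eG <- cbind(match(G$edges$from, G$nodes), match(G$edges$to, G$nodes))
  S <- matrix(0, nG, nH)
  if (!is.null(cfg$similarity)) {
    i <- match(G$nodes, rownames(cfg$similarity))
    j <- match(H$nodes, colnames(cfg$similarity))
    oki <- which(!is.na(i))
    okj <- which(!is.na(j))
    S[oki, okj] <- cfg$similarity[i[oki], j[okj], drop = FALSE]
  }
  list(G = G, H = H, nG = nG, nH = nH, mG = nrow(eG), eG = eG,
       adjH = adjacency_matrix(H), S = S,
       alpha = cfg$alpha, edge_term = cfg$edge_term)
}

# perm: integer vector, perm[i] = target index of source i. Returns the
# blended objective.
objective_of_perm <- function(env, perm) {
  topo <- 0
  if (env$mG > 0L || env$edge_term == "S3") {
    C <- if (env$mG > 0L) {
      sum(env$adjH[cbind(perm[env$eG[, 1L]], perm[env$eG[, 2L]])])
    } else 0L
    if (env$edge_term == "S3") {
      I <- sum(env$adjH[perm, perm]) / 2
      denom <- env$mG + I - C
      topo <- if (denom == 0) 0 else C / denom
    } else {
      topo <- if (env$mG == 0L) 0 else C / env$mG
    }
  }
  sim <- if (env$nG > 0L) mean(env$S[cbind(seq_len(env$nG), perm)]) else 0
  env$alpha * topo + (1 - env$alpha) * sim
}

perm_to_alignment <- function(env, perm, method, parameters, objective) {
  network_alignment(
    stats::setNames(env$H$nodes[perm], env$G$nodes),
    method = method, parameters = parameters, objective_value = objective)
}

#' Write / read an alignment as TSV
#'
#' One row per mapped pair: \code{source_id<TAB>target_id<TAB>pair_similarity},
#' preceded by \code{#}-comment lines carrying method, parameters and
#' objective so every alignment file is self-describing.
#'
#' @param aln a \code{\link{network_alignment}}.
#' @param path TSV path.
#' @param similarity optional similarity matrix used to fill the third
#'   column (0 when absent).
#' @return \code{write_alignment_tsv}: invisibly \code{path};
#'   \code{read_alignment_tsv}: the \code{\link{network_alignment}}.
#' @export
write_alignment_tsv <- function(aln, path, similarity = NULL) {
  stopifnot(inherits(aln, "network_alignment"))
  pars <- vapply(aln$parameters, function(p) paste(format(p), collapse = ","),
                 "")
  head <- c(sprintf("# method\t%s", aln$method),
            sprintf("# objective\t%s", format(aln$objective_value, digits = 12)),
            sprintf("# partial\t%s", aln$partial),
            if (length(pars) > 0L) sprintf("# param\t%s\t%s", names(pars), pars))
  sim <- similarity_of_pairs(similarity, names(aln$mapping),
                             unname(aln$mapping))
  rows <- sprintf("%s\t%s\t%.4f", names(aln$mapping), unname(aln$mapping), sim)
  writeLines(c(head, rows), path)
  invisible(path)
}

#' @rdname write_alignment_tsv
#' @export
read_alignment_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  com <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  field <- function(key) {
    hit <- grep(sprintf("^# %s\t", key), com, value = TRUE)
    if (length(hit) == 0L) NULL else strsplit(hit[[1L]], "\t")[[1L]][[2L]]
  }
  params <- list()
  for (hit in grep("^# param\t", com, value = TRUE)) {
    parts <- strsplit(hit, "\t")[[1L]]
    val <- parts[[3L]]
    num <- suppressWarnings(as.numeric(val))
    params[[parts[[2L]]]] <- if (!is.na(num)) num else val
  }
  mapping <- character()
  if (length(body) > 0L) {
    rows <- strsplit(body, "\t", fixed = TRUE)
    mapping <- stats::setNames(vapply(rows, `[[`, "", 2L),
                               vapply(rows, `[[`, "", 1L))
  }
  network_alignment(mapping, method = field("method") %||% "unknown",
                    parameters = params,
                    objective_value = as.numeric(field("objective") %||% NA),
                    partial = identical(field("partial"), "TRUE"))
}
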