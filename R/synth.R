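#' Configuration of the paired-network evolution simulator
#'
#' Describes how two descendant species networks are generated from one
#' ancestral PPI network: the ancestor grows by duplication-divergence (each
#' new protein copies a template's interactions, keeping each with
#' probability \code{dd_retention} and linking to the template with
#' probability \code{dd_parent_link}); each species then independently loses
#' nodes and edges, gains spurious edges, duplicates some genes (creating
#' one-to-many orthology), and accumulates point mutations in its protein
#' sequences. Ortholog sequence similarity is controlled solely by
#' \code{mutation_rate}, while unrelated proteins have independent random
#' sequences, so the ortholog signal sits well above the background -- the
#' property that makes sequence similarity a useful alignment input.
#'
#' @param ancestor_size number of ancestral proteins (>= 3).
#' @param dd_retention probability a duplicated interaction is retained.
#' @param dd_parent_link probability a new protein interacts with its
#'   template.
#' @param edge_loss_rate per-edge loss probability per species.
#' @param edge_gain_rate expected spurious edges as a fraction of |E|.
#' @param node_loss_rate per-node loss probability per species.
#' @param duplication_rate probability a surviving protein is duplicated.
#' @param seq_length protein length in residues (>= 10).
#' @param mutation_rate per-site substitution probability per species.
#' @param seed master seed; every stage draws from a stream derived from it.
#' @return an object of class \code{speciation_config}.
#' @export
speciation_config <- function(ancestor_size = 30, dd_retention = 0.4,
                              dd_parent_link = 0.7, edge_loss_rate = 0.1,
                              edge_gain_rate = 0.05, node_loss_rate = 0.05,
                              duplication_rate = 0.1, seq_length = 100,
                              mutation_rate = 0.05, seed = 1) {
  cfg <- list(ancestor_size = as.integer(ancestor_size),
              dd_retention = dd_retention, dd_parent_link = dd_parent_link,
              edge_loss_rate = edge_loss_rate, edge_gain_rate = edge_gain_rate,
              node_loss_rate = node_loss_rate,
              duplication_rate = duplication_rate,
              seq_length = as.integer(seq_length),
              mutation_rate = mutation_rate, seed = as.integer(seed))
  probs <- c("dd_retention", "dd_parent_link", "edge_loss_rate",
             "node_loss_rate", "duplication_rate", "mutation_rate")
  bad <- character()
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      bad <- c(bad, p)
    }
  }
  if (!is.numeric(cfg$edge_gain_rate) || cfg$edge_gain_rate < 0) {
    bad <- c(bad, "edge_gain_rate")
  }
  if (cfg$ancestor_size < 3L) bad <- c(bad, "ancestor_size")
  if (cfg$seq_length < 10L) bad <- c(bad, "seq_length")
  if (length(bad) > 0L) {
    stop_fmt("invalid speciation_config field(s): %s",
             paste(unique(bad), collapse = ", "))
  }
  structure(cfg, class = "speciation_config")
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[[i]] <- sample(setdiff(AA20, chars[[i]]), 1L)
  }
  paste(chars, collapse = "")
}

#' Grow an ancestral PPI network by duplication-divergence
#'
#' Starts from a 3-clique; each subsequent protein copies a uniformly chosen
#' template, retains each template interaction with probability
#' \code{dd_retention} and links to the template with probability
#' \code{dd_parent_link}. Every protein receives an independent random
#' amino-acid sequence.
#'
#' @param config a \code{\link{speciation_config}}.
#' @return list with \code{net} (a \code{\link{ppi_network}}, species
#'   \code{"ancestor"}) and \code{sequences} (named character vector).
#' @export
generate_ancestor <- function(config) {
  stopifnot(inherits(config, "speciation_config"))
  with_seed(derive_seed(config$seed, "ancestor"), {
    n <- config$ancestor_size
    ids <- sprintf("anc%04d", seq_len(n))
    adj <- matrix(FALSE, n, n)
    adj[1:3, 1:3] <- TRUE
    diag(adj) <- FALSE
    for (i in seq_len(n)[-(1:3)]) {
      tpl <- sample.int(i - 1L, 1L)
      nb <- which(adj[tpl, seq_len(i - 1L)])
      keep <- nb[stats::runif(length(nb)) < config$dd_retention]
      adj[i, keep] <- TRUE
      adj[keep, i] <- TRUE
      if (stats::runif(1) < config$dd_parent_link) {
        adj[i, tpl] <- TRUE
        adj[tpl, i] <- TRUE
      }
    }
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    edges <- data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
                        combined_score = 999L, experiments = 999L,
                        stringsAsFactors = FALSE)
    seqs <- stats::setNames(
      vapply(ids, function(i) random_protein(config$seq_length), ""), ids)
    list(net = ppi_network(edges = edges, nodes = ids, species = "ancestor"),
         sequences = seqs)
  })
}

#' Derive one descendant species from the ancestor
#'
#' Independently per species: nodes are lost with probability
#' \code{node_loss_rate}; each survivor is duplicated with probability
#' \code{duplication_rate} (the duplicate inherits each interaction with
#' probability \code{dd_retention} and starts from the parent's unmutated
#' sequence); edges are lost with probability \code{edge_loss_rate};
#' \code{edge_gain_rate * |E|} spurious interactions are added between
#' uniform non-adjacent pairs; finally every sequence mutates at each site
#' with probability \code{mutation_rate} (to a uniformly chosen different
#' residue).
#'
#' @param ancestor output of \code{\link{generate_ancestor}}.
#' @param config a \code{\link{speciation_config}}.
#' @param side \code{"A"} or \code{"B"}; determines the id prefix and the
#'   independent random stream.
#' @return list with \code{net}, \code{sequences} and \code{ancestor_of}
#'   (named character vector: descendant id -> ancestor id).
#' @export
speciate <- function(ancestor, config, side = c("A", "B")) {
  stopifnot(inherits(config, "speciation_config"))
  side <- match.arg(side)
  with_seed(derive_seed(config$seed, "speciate", side), {
    anc_ids <- ancestor$net$nodes
    prefix <- if (side == "A") "spA_" else "spB_"
    survivors <- anc_ids[stats::runif(length(anc_ids)) >= config$node_loss_rate]
    if (length(survivors) == 0L) {
      warn_fmt("species %s lost every node (node_loss_rate = %g)",
               side, config$node_loss_rate)
      return(list(net = ppi_network(species = paste0("species", side)),
                  sequences = stats::setNames(character(), character()),
                  ancestor_of = stats::setNames(character(), character())))
    }
    new_id <- stats::setNames(paste0(prefix, survivors), survivors)
    e <- ancestor$net$edges
    e <- e[e$from %in% survivors & e$to %in% survivors, , drop = FALSE]
    edges <- data.frame(from = unname(new_id[e$from]),
                        to = unname(new_id[e$to]),
                        stringsAsFactors = FALSE)
    ancestor_of <- stats::setNames(survivors, unname(new_id))
    seqs <- stats::setNames(ancestor$sequences[survivors], unname(new_id))
    # gene duplication: creates the one-to-many rows of the ortholog map
    dup <- survivors[stats::runif(length(survivors)) < config$duplication_rate]
    for (d in dup) {
      parent <- new_id[[d]]
      dup_id <- paste0(parent, "d")
      nb <- unique(c(edges$to[edges$from == parent],
                     edges$from[edges$to == parent]))
      keep <- nb[stats::runif(length(nb)) < config$dd_retention]
      if (length(keep) > 0L) {
        edges <- rbind(edges, data.frame(from = dup_id, to = keep,
                                         stringsAsFactors = FALSE))
      }
      ancestor_of[[dup_id]] <- d
      seqs[[dup_id]] <- seqs[[parent]]
    }
    # edge loss, then spurious edge gain
    if (nrow(edges) > 0L) {
      edges <- edges[stats::runif(nrow(edges)) >= config$edge_loss_rate, ,
                     drop = FALSE]
    }
    all_ids <- names(ancestor_of)
    n_gain <- round(config$edge_gain_rate * nrow(edges))
    if (n_gain > 0L && length(all_ids) >= 2L) {
      have <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to),
                    sep = "\r")
      tries <- 0L
      while (n_gain > 0L && tries < 100L * n_gain) {
        uv <- sample(all_ids, 2L)
        key <- paste(min(uv), max(uv), sep = "\r")
        if (!key %in% have) {
          edges <- rbind(edges, data.frame(from = uv[[1L]], to = uv[[2L]],
                                           stringsAsFactors = FALSE))
          have <- c(have, key)
          n_gain <- n_gain - 1L
        }
        tries <- tries + 1L
      }
    }
    seqs <- vapply(seqs, mutate_protein, "", rate = config$mutation_rate)
    edges$combined_score <- 999L
    edges$experiments <- 999L
    list(net = ppi_network(edges = edges, nodes = names(ancestor_of),
                           species = paste0("species", side)),
         sequences = seqs, ancestor_of = ancestor_of)
  })
}

#' Generate a full paired-network benchmark with planted truth
#'
#' Composes \code{\link{generate_ancestor}} and two \code{\link{speciate}}
#' calls. The truth ortholog map pairs descendants sharing an ancestral
#' protein (many-to-many where duplication occurred); the truth interologs
#' are the pairs of edges, one per species, whose endpoints share ancestors
#' -- interactions conserved from the common ancestor. Optionally writes the
#' whole fixture as plain-text files (edge lists, FASTA, ortholog TSV,
#' config echo) readable back through the package's own readers.
#'
#' @param config a \code{\link{speciation_config}}.
#' @param dir optional output directory for the fixture files.
#' @return an object of class \code{synthetic_benchmark}: list with
#'   \code{netA}, \code{netB}, \code{sequencesA}, \code{sequencesB},
#'   \code{sequences} (both sides merged), \code{truth_map}
#'   (\code{\link{ortholog_map}}) and \code{truth_interologs} (data.frame
#'   a_from, a_to, b_from, b_to).
#' @export
make_benchmark <- function(config, dir = NULL) {
  stopifnot(inherits(config, "speciation_config"))
  anc <- generate_ancestor(config)
  A <- speciate(anc, config, side = "A")
  B <- speciate(anc, config, side = "B")
  pairs <- merge(data.frame(a = names(A$ancestor_of), anc = unname(A$ancestor_of),
                            stringsAsFactors = FALSE),
                 data.frame(b = names(B$ancestor_of), anc = unname(B$ancestor_of),
                            stringsAsFactors = FALSE), by = "anc")
  truth_map <- ortholog_map(pairs[, c("a", "b")])
  truth_interologs <- find_truth_interologs(A, B)
  bench <- structure(list(netA = A$net, netB = B$net,
                          sequencesA = A$sequences, sequencesB = B$sequences,
                          sequences = c(A$sequences, B$sequences),
                          truth_map = truth_map,
                          truth_interologs = truth_interologs,
                          config = config),
                     class = "synthetic_benchmark")
  if (!is.null(dir)) write_benchmark(bench, dir)
  bench
}

find_truth_interologs <- function(A, B) {
  out <- data.frame(a_from = character(), a_to = character(),
                    b_from = character(), b_to = character(),
                    stringsAsFactors = FALSE)
  eA <- A$net$edges
  eB <- B$net$edges
  if (nrow(eA) == 0L || nrow(eB) == 0L) return(out)
  # ancestral endpoint pair keys, order-normalized
  keyify <- function(e, anc_of) {
    u <- unname(anc_of[e$from])
    v <- unname(anc_of[e$to])
    paste(pmin(u, v), pmax(u, v), sep = "\r")
  }
  kA <- keyify(eA, A$ancestor_of)
  kB <- keyify(eB, B$ancestor_of)
  hits <- merge(data.frame(k = kA, a_from = eA$from, a_to = eA$to,
                           stringsAsFactors = FALSE),
                data.frame(k = kB, b_from = eB$from, b_to = eB$to,
                           stringsAsFactors = FALSE), by = "k")
  hits$k <- NULL
  hits <- hits[order(hits$a_from, hits$a_to, hits$b_from, hits$b_to), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(sprintf(paste0("synthetic_benchmark: A %d nodes/%d edges, ",
                     "B %d nodes/%d edges, %d ortholog pairs, %d interologs\n"),
              n_nodes(x$netA), n_edges(x$netA), n_nodes(x$netB),
              n_edges(x$netB), nrow(x$truth_map$pairs),
              nrow(x$truth_interologs)))
  invisible(x)
}

write_benchmark <- function(bench, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_network(bench$netA, file.path(dir, "netA.tsv"), "tsv")
  write_network(bench$netB, file.path(dir, "netB.tsv"), "tsv")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(bench$sequencesA),
                              file.path(dir, "seqA.fasta"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(bench$sequencesB),
                              file.path(dir, "seqB.fasta"))
  write_ortholog_table(bench$truth_map, file.path(dir, "orthologs.tsv"))
  utils::write.table(bench$truth_interologs,
                     file.path(dir, "truth_interologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(unclass(bench$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
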