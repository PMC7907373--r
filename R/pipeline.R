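#' Pipeline run configuration
#'
#' One object carrying every choice of a cross-species comparison run:
#' input paths, per-network edge filters, scoring scheme, objective and GA
#' parameters, output directory and master seed. All defaults are echoed
#' into the output metadata so no run is ambiguous.
#'
#' @param netA_path,netB_path network input files (STRING-style TSV when
#'   \code{string_format}, else plain edge lists).
#' @param sequences_path FASTA of protein sequences keyed by node id
#'   (covering both networks; may be \code{NULL} for topology-only runs).
#' @param orthologs_path two-column ortholog TSV (may be \code{NULL}).
#' @param string_format logical: inputs are STRING links-style tables.
#' @param filterA,filterB \code{\link{edge_filter}}s applied per network.
#' @param seedsA,seedsB optional seed protein ids for subnetwork extraction.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @param alpha,edge_term objective settings (see
#'   \code{\link{objective_config}}).
#' @param ga list of GA parameters overriding the \code{\link{ga_align}}
#'   defaults.
#' @param out_dir output directory.
#' @param seed master seed.
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(netA_path = NULL, netB_path = NULL,
                            sequences_path = NULL, orthologs_path = NULL,
                            string_format = FALSE,
                            filterA = edge_filter(), filterB = edge_filter(),
                            seedsA = NULL, seedsB = NULL,
                            scheme = scoring_scheme(),
                            alpha = 0.5, edge_term = "S3",
                            ga = list(), out_dir = tempfile("interolign_run_"),
                            seed = 1) {
  for (p in c(netA_path, netB_path, sequences_path, orthologs_path)) {
    if (!is.null(p) && !file.exists(p)) stop_fmt("input path not found: %s", p)
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop_fmt("alpha must be in [0, 1]")
  }
  structure(list(netA_path = netA_path, netB_path = netB_path,
                 sequences_path = sequences_path,
                 orthologs_path = orthologs_path,
                 string_format = isTRUE(string_format),
                 filterA = filterA, filterB = filterB,
                 seedsA = seedsA, seedsB = seedsB, scheme = scheme,
                 alpha = alpha, edge_term = edge_term, ga = ga,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

read_fasta_map <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

#' Build stage: read, filter and optionally seed-extract both networks
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{netA}, \code{netB} and \code{report} (node/edge
#'   counts per filter stage); networks and the JSON report are written
#'   under \code{config$out_dir}.
#' @export
run_build <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  one <- function(path, filt, seeds, label) {
    net <- if (config$string_format) {
      read_string_tsv(path, filt, species_label = label)
    } else {
      filter_network(read_edge_list(path, species_label = label), filt,
                     prune_orphans = FALSE)
    }
    stage <- list(loaded_nodes = n_nodes(net), loaded_edges = n_edges(net))
    if (!is.null(seeds)) {
      net <- extract_seeded_subnetwork(net, seeds)
      stage$seeded_nodes <- n_nodes(net)
      stage$seeded_edges <- n_edges(net)
    }
    list(net = net, stage = stage)
  }
  a <- one(config$netA_path, config$filterA, config$seedsA, "speciesA")
  b <- one(config$netB_path, config$filterB, config$seedsB, "speciesB")
  write_network(a$net, file.path(config$out_dir, "netA.built.tsv"), "tsv")
  write_network(b$net, file.path(config$out_dir, "netB.built.tsv"), "tsv")
  report <- list(netA = a$stage, netB = b$stage,
                 filterA = unclass(config$filterA),
                 filterB = unclass(config$filterB))
  jsonlite::write_json(report, file.path(config$out_dir, "build_report.json"),
                       auto_unbox = TRUE, digits = NA)
  list(netA = a$net, netB = b$net, report = report)
}

#' Similarity stage: cross-species node similarity matrix
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param netA,netB built networks (from \code{\link{run_build}}).
#' @return the similarity matrix; also written as TSV under
#'   \code{config$out_dir}.
#' @export
run_simscore <- function(config, netA, netB) {
  stopifnot(inherits(config, "pipeline_config"))
  seqs <- read_fasta_map(config$sequences_path)
  M <- build_similarity_matrix(netA, netB, seqs, config$scheme)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_similarity_tsv(M, file.path(config$out_dir, "similarity.tsv"))
  M
}

#' Alignment stage: GA global network alignment
#'
#' The smaller network is used as the source; when \code{netA} is larger
#' the networks are swapped and the swap recorded in the alignment
#' parameters.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param netA,netB built networks.
#' @param similarity similarity matrix (rows = netA ids); ignored when
#'   \code{alpha = 1}.
#' @return the \code{\link{network_alignment}} (source = smaller network);
#'   also written as TSV under \code{config$out_dir}.
#' @export
run_align <- function(config, netA, netB, similarity = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  swapped <- n_nodes(netA) > n_nodes(netB)
  if (swapped) {
    tmp <- netA; netA <- netB; netB <- tmp
    if (!is.null(similarity)) similarity <- t(similarity)
  }
  cfg <- objective_config(config$alpha, config$edge_term, similarity)
  ga_args <- utils::modifyList(
    list(G = netA, H = netB, cfg = cfg, seed = derive_seed(config$seed, "align")),
    config$ga)
  aln <- do.call(ga_align, ga_args)
  aln$parameters$swapped <- swapped
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_alignment_tsv(aln, file.path(config$out_dir, "alignment.tsv"),
                      similarity)
  aln
}

#' Evaluation stage: Table-style metrics against the ortholog map
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param aln alignment from \code{\link{run_align}}.
#' @param G,H the source and target networks of \code{aln}.
#' @param map ortholog map (source ids on the A side of the map).
#' @param similarity optional similarity matrix (rows = source ids).
#' @return the \code{evaluation_report}; also written as JSON.
#' @export
run_evaluate <- function(config, aln, G, H, map, similarity = NULL) {
  rep <- evaluate_alignment(aln, G, H, map, similarity)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  evaluation_to_json(rep, file.path(config$out_dir, "evaluation.json"))
  rep
}

#' Whole-pipeline driver
#'
#' build -> similarity -> align -> evaluate -> unify on one configuration.
#' Every artifact lands under \code{config$out_dir}; all randomness derives
#' from \code{config$seed}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{netA}, \code{netB}, \code{similarity},
#'   \code{alignment}, \code{evaluation} (NULL without an ortholog table)
#'   and \code{unified}.
#' @export
run_pipeline <- function(config) {
  built <- run_build(config)
  M <- NULL
  if (!is.null(config$sequences_path) && config$alpha < 1) {
    M <- run_simscore(config, built$netA, built$netB)
  }
  aln <- run_align(config, built$netA, built$netB, M)
  swapped <- isTRUE(aln$parameters$swapped)
  G <- if (swapped) built$netB else built$netA
  H <- if (swapped) built$netA else built$netB
  Ms <- if (swapped && !is.null(M)) t(M) else M
  map <- NULL
  evalrep <- NULL
  if (!is.null(config$orthologs_path)) {
    map <- read_ortholog_table(config$orthologs_path)
    if (swapped) map <- ortholog_map(map$pairs[, c("b", "a")])
    evalrep <- run_evaluate(config, aln, G, H, map, Ms)
  }
  unified <- build_unified_network(aln, G, H, map)
  write_network(unified_as_network(unified),
                file.path(config$out_dir, "unified.tsv"), "tsv")
  list(netA = built$netA, netB = built$netB, similarity = M,
       alignment = aln, evaluation = evalrep, unified = unified,
       swapped = swapped)
}

#' Simulation stage: write a synthetic benchmark fixture
#'
#' @param config a \code{\link{speciation_config}}.
#' @param dir output directory.
#' @return the \code{synthetic_benchmark} (fixture files written to
#'   \code{dir}).
#' @export
run_simulate <- function(config, dir) {
  make_benchmark(config, dir = dir)
}
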