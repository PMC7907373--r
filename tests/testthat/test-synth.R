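test_that("speciation config validation names the offending fields", {
  expect_error(speciation_config(ancestor_size = 2), "ancestor_size")
  expect_error(speciation_config(mutation_rate = 1.2), "mutation_rate")
  expect_error(speciation_config(seq_length = 5), "seq_length")
  expect_error(speciation_config(dd_retention = -0.1, edge_loss_rate = 2),
               "dd_retention.*edge_loss_rate|edge_loss_rate.*dd_retention")
})

test_that("full retention and linking grow a complete ancestor graph", {
  cfg <- speciation_config(ancestor_size = 12, dd_retention = 1,
                           dd_parent_link = 1, seed = 7)
  anc <- generate_ancestor(cfg)
  n <- n_nodes(anc$net)
  expect_equal(n_edges(anc$net), n * (n - 1) / 2)
  expect_equal(unname(nchar(anc$sequences)), rep(cfg$seq_length, n))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- speciation_config(ancestor_size = 15, seed = 99)
  expect_identical(generate_ancestor(cfg), generate_ancestor(cfg))
  expect_identical(make_benchmark(cfg)[c("netA", "netB", "sequences")],
                   make_benchmark(cfg)[c("netA", "netB", "sequences")])
  cfg2 <- speciation_config(ancestor_size = 15, seed = 100)
  expect_false(identical(make_benchmark(cfg)$netA$edges,
                         make_benchmark(cfg2)$netA$edges))
})

test_that("ancestor edge counts match an independently coded duplication-divergence generator", {
  p <- 0.4
  q <- 0.7
  n <- 30
  nseeds <- 60
  mine <- vapply(seq_len(nseeds), function(s) {
    cfg <- speciation_config(ancestor_size = n, dd_retention = p,
                             dd_parent_link = q, seed = 2000 + s)
    n_edges(generate_ancestor(cfg)$net)
  }, 0)
  set.seed(77)
  theirs <- vapply(seq_len(nseeds), function(s) dd_edge_count_oracle(n, p, q), 0)
  se <- sqrt(stats::var(mine) / nseeds + stats::var(theirs) / nseeds)
  expect_lt(abs(mean(mine) - mean(theirs)), 3 * se)
})

test_that("speciation with zero rates is the identity up to renaming", {
  cfg <- speciation_config(ancestor_size = 12, edge_loss_rate = 0,
                           edge_gain_rate = 0, node_loss_rate = 0,
                           duplication_rate = 0, mutation_rate = 0, seed = 3)
  anc <- generate_ancestor(cfg)
  A <- speciate(anc, cfg, side = "A")
  expect_equal(n_nodes(A$net), n_nodes(anc$net))
  expect_equal(n_edges(A$net), n_edges(anc$net))
  expect_equal(unname(A$ancestor_of[paste0("spA_", anc$net$nodes)]),
               anc$net$nodes)
  expect_equal(unname(A$sequences[paste0("spA_", anc$net$nodes)]),
               unname(anc$sequences[anc$net$nodes]))
  # edge set identical modulo the prefix
  expect_equal(A$net$edges$from, paste0("spA_", anc$net$edges$from))
  expect_equal(A$net$edges$to, paste0("spA_", anc$net$edges$to))
})

test_that("mutation hits the expected fraction of sites", {
  nseeds <- 60
  frac <- vapply(seq_len(nseeds), function(s) {
    cfg <- speciation_config(ancestor_size = 3, edge_loss_rate = 0,
                             node_loss_rate = 0, duplication_rate = 0,
                             seq_length = 200, mutation_rate = 0.05,
                             seed = 3000 + s)
    anc <- generate_ancestor(cfg)
    A <- speciate(anc, cfg, side = "A")
    before <- strsplit(anc$sequences, "")
    after <- strsplit(unname(A$sequences[paste0("spA_", names(before))]), "")
    mean(unlist(Map(function(x, y) x != y, before, after)))
  }, 0)
  se <- sqrt(0.05 * 0.95 / (200 * 3 * nseeds))
  expect_lt(abs(mean(frac) - 0.05), 3 * se)
})

test_that("total node loss leaves an empty network with a warning", {
  cfg <- speciation_config(ancestor_size = 5, node_loss_rate = 1, seed = 4)
  anc <- generate_ancestor(cfg)
  expect_warning(A <- speciate(anc, cfg, side = "A"), "lost every node")
  expect_equal(n_nodes(A$net), 0L)
})

test_that("zero-divergence benchmarks have closed-form planted truth", {
  cfg <- speciation_config(ancestor_size = 15, edge_loss_rate = 0,
                           edge_gain_rate = 0, node_loss_rate = 0,
                           duplication_rate = 0, mutation_rate = 0, seed = 5)
  anc <- generate_ancestor(cfg)
  b <- make_benchmark(cfg)
  expect_equal(nrow(b$truth_interologs), n_edges(anc$net))
  expect_equal(nrow(b$truth_map$pairs), n_nodes(anc$net))
  expect_true(all(lengths(b$truth_map$forward) == 1L))
})

test_that("gene duplication plants one-to-many ortholog rows", {
  hits <- vapply(1:20, function(s) {
    cfg <- speciation_config(ancestor_size = 30, duplication_rate = 0.2,
                             seed = 4000 + s)
    b <- make_benchmark(cfg)
    any(lengths(b$truth_map$forward) > 1L) ||
      any(lengths(b$truth_map$reverse) > 1L)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("planted interologs always join truth-mapped endpoints", {
  for (s in 1:5) {
    cfg <- speciation_config(ancestor_size = 20, duplication_rate = 0.15,
                             edge_gain_rate = 0.1, seed = 5000 + s)
    b <- make_benchmark(cfg)
    ti <- b$truth_interologs
    if (nrow(ti) == 0L) next
    keysA <- edge_keys(b$netA)
    keysB <- edge_keys(b$netB)
    expect_true(all(paste(pmin(ti$a_from, ti$a_to),
                          pmax(ti$a_from, ti$a_to), sep = "\r") %in% keysA))
    expect_true(all(paste(pmin(ti$b_from, ti$b_to),
                          pmax(ti$b_from, ti$b_to), sep = "\r") %in% keysB))
    ok_ends <- mapply(function(af, bf) is_ortholog_pair(b$truth_map, af, bf),
                      ti$a_from, ti$b_from) |
      mapply(function(af, bt) is_ortholog_pair(b$truth_map, af, bt),
             ti$a_from, ti$b_to)
    expect_true(all(ok_ends))
  }
})

test_that("benchmark fixtures round-trip through the package readers", {
  cfg <- speciation_config(ancestor_size = 12, duplication_rate = 0.2,
                           seed = 6)
  dir <- tempfile("bench_")
  b <- make_benchmark(cfg, dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("netA.tsv", "netB.tsv", "seqA.fasta", "seqB.fasta", "orthologs.tsv",
      "truth_interologs.tsv", "config.json")))))
  backA <- read_edge_list(file.path(dir, "netA.tsv"), "speciesA")
  expect_equal(backA$nodes, b$netA$nodes)
  expect_equal(backA$edges[c("from", "to", "combined_score")],
               b$netA$edges[c("from", "to", "combined_score")])
  backM <- read_ortholog_table(file.path(dir, "orthologs.tsv"))
  expect_equal(backM$pairs, b$truth_map$pairs)
  seqs <- Biostrings::readAAStringSet(file.path(dir, "seqA.fasta"))
  back_seqs <- stats::setNames(as.character(seqs), names(seqs))
  expect_equal(back_seqs[sort(names(back_seqs))],
               b$sequencesA[sort(names(b$sequencesA))])
  echo <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(echo$ancestor_size, 12L)
  expect_equal(echo$seed, 6L)
})
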