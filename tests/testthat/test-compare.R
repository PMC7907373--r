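toy_map <- function(...) ortholog_map(data.frame(...))

test_that("evaluation separates correct pairs, aligned interactions and interologs", {
  G <- toy_path()
  H <- toy_triangle()
  aln <- toy_path_triangle_alignment()

  # empty gold standard: nothing is evaluable, conserved edges unchanged
  ev <- evaluate_alignment(aln, G, H, ortholog_map())
  expect_equal(ev$correct_node_alignments, 0L)
  expect_equal(ev$interologs_identified, 0L)
  expect_equal(ev$aligned_interactions, 2L)
  expect_equal(ev$unevaluable_pairs, 3L)

  # only the a-b edge has both endpoint pairs orthologous
  map <- toy_map(a = c("a", "b", "c"), b = c("x", "y", "q"))
  ev <- evaluate_alignment(aln, G, H, map)
  expect_equal(ev$correct_node_alignments, 2L)
  expect_equal(ev$incorrect_node_alignments, 0L)   # c is unevaluable (no in-network ortholog)
  expect_equal(ev$unevaluable_pairs, 1L)
  expect_equal(ev$aligned_interactions, 2L)
  expect_equal(ev$interologs_identified, 1L)

  # any of several predicted orthologs counts as correct
  multi <- toy_map(a = c("a", "a", "b", "c"), b = c("x", "y", "y", "z"))
  ev <- evaluate_alignment(aln, G, H, multi)
  expect_equal(ev$correct_node_alignments, 3L)
  expect_equal(ev$interologs_identified, 2L)
})

test_that("evaluation metrics obey their accounting invariants on random instances", {
  set.seed(411)
  for (k in 1:10) {
    inst <- random_instance(sample(4:7, 1L), sample(7:9, 1L))
    map <- toy_map(a = sample(inst$G$nodes, 4L, replace = TRUE),
                   b = sample(inst$H$nodes, 4L, replace = TRUE))
    aln <- greedy_align(inst$G, inst$H,
                        objective_config(stats::runif(1), "S3", inst$S))
    ev <- evaluate_alignment(aln, inst$G, inst$H, map, inst$S)
    expect_lte(ev$interologs_identified, ev$aligned_interactions)
    expect_lte(ev$aligned_interactions, n_edges(inst$G))
    expect_equal(ev$correct_node_alignments + ev$incorrect_node_alignments,
                 ev$n_mapped_pairs)
    expect_equal(ev$n_mapped_pairs + ev$unevaluable_pairs, n_nodes(inst$G))
    expect_gte(ev$s3, 0)
    expect_lte(ev$s3, 1)
  }
})

test_that("the ortholog-guided reference alignment resolves multi-mapping toward conserved edges", {
  # all one-to-one, no conflicts: reference equals the map
  G <- toy_path()
  H <- toy_triangle()
  map <- toy_map(a = c("a", "b", "c"), b = c("x", "y", "z"))
  ref <- reference_alignment(G, H, map)
  expect_equal(ref$mapping, c(a = "x", b = "y", c = "z"))
  expect_true(ref$partial)

  # A maps to {B1, B2}; only B1 is adjacent to the image of A's neighbor
  G2 <- ppi_network(data.frame(from = "A", to = "N"))
  H2 <- ppi_network(data.frame(from = "B1", to = "M"),
                    nodes = c("B1", "B2", "M"))
  map2 <- toy_map(a = c("A", "A", "N"), b = c("B1", "B2", "M"))
  ref2 <- reference_alignment(G2, H2, map2)
  expect_equal(ref2$mapping[["A"]], "B1")

  # two sources share one ortholog with equal gain: smaller source id wins
  G3 <- ppi_network(nodes = c("s1", "s2"))
  H3 <- ppi_network(nodes = "t1")
  map3 <- toy_map(a = c("s1", "s2"), b = c("t1", "t1"))
  ref3 <- reference_alignment(G3, H3, map3)
  expect_equal(ref3$mapping, c(s1 = "t1"))
  expect_equal(ref3$parameters$unmapped_with_orthologs, "s2")
})

test_that("the reference alignment maximizes correct node alignments (exhaustive check)", {
  set.seed(412)
  for (k in 1:8) {
    inst <- random_instance(sample(3:5, 1L), sample(5:6, 1L))
    npairs <- sample(3:6, 1L)
    map <- toy_map(a = sample(inst$G$nodes, npairs, replace = TRUE),
                   b = sample(inst$H$nodes, npairs, replace = TRUE))
    ref <- reference_alignment(inst$G, inst$H, map)
    ev_ref <- evaluate_alignment(ref, inst$G, inst$H, map)
    # brute force: the most correct pairs any injective total mapping can make
    best <- 0L
    src <- inst$G$nodes
    recurse <- function(i, taken, acc) {
      if (i > length(src)) {
        best <<- max(best, acc)
        return(invisible())
      }
      for (t in inst$H$nodes) {
        if (!t %in% taken) {
          recurse(i + 1L, c(taken, t),
                  acc + as.integer(is_ortholog_pair(map, src[[i]], t)))
        }
      }
    }
    recurse(1L, character(), 0L)
    expect_equal(ev_ref$correct_node_alignments, best)
  }
})

test_that("unified networks keep aligned pairs incident to conserved interactions", {
  G <- toy_path()
  H <- toy_triangle()
  aln <- toy_path_triangle_alignment()
  map <- toy_map(a = c("a", "b"), b = c("x", "y"))

  U <- build_unified_network(aln, G, H, map)
  expect_equal(nrow(U$pairs), 3L)
  expect_equal(nrow(U$edges), 2L)
  expect_equal(sum(U$pairs$interolog_confirmed), 2L)

  Uall <- build_unified_network(aln, G, H, map, membership = "all_pairs")
  expect_equal(nrow(Uall$pairs), length(aln$mapping))

  # no conserved edges -> empty unified network under the default rule
  G1 <- ppi_network(data.frame(from = "a", to = "b"))
  H1 <- ppi_network(nodes = c("x", "y"))
  none <- build_unified_network(network_alignment(c(a = "x", b = "y")),
                                G1, H1, map)
  expect_equal(nrow(none$pairs), 0L)
  expect_equal(nrow(none$edges), 0L)

  expect_error(build_unified_network(aln, G, H, map, membership = "nope"),
               "membership")

  net <- unified_as_network(U)
  expect_equal(n_nodes(net), 3L)
  expect_true(all(grepl("|", net$nodes, fixed = TRUE)))
})

test_that("common-network extraction is a true intersection", {
  mk <- function(pairs, edges) {
    structure(list(pairs = pairs, edges = edges,
                   membership = "conserved_incident", provenance = "t"),
              class = "unified_network")
  }
  p1 <- data.frame(source = c("a", "b", "c"), target = c("x", "y", "z"),
                   interolog_confirmed = TRUE, stringsAsFactors = FALSE)
  e1 <- data.frame(a = c("a|x", "a|x"), b = c("b|y", "c|z"),
                   stringsAsFactors = FALSE)
  U1 <- mk(p1, e1)
  p2 <- data.frame(source = c("a", "b", "c"), target = c("x", "w", "z"),
                   interolog_confirmed = TRUE, stringsAsFactors = FALSE)
  e2 <- data.frame(a = "a|x", b = "c|z", stringsAsFactors = FALSE)
  U2 <- mk(p2, e2)

  common <- intersect_unified(U1, U2)
  expect_equal(common$pairs$source, c("a", "c"))
  expect_equal(nrow(common$edges), 1L)
  expect_equal(common$edges$a, "a|x")
  expect_equal(common$edges$b, "c|z")

  # idempotent, commutative, contained in both inputs
  expect_equal(intersect_unified(U1, U1)$pairs, U1$pairs)
  expect_equal(intersect_unified(U1, U1)$edges, U1$edges)
  ba <- intersect_unified(U2, U1)
  expect_equal(ba$pairs$source, common$pairs$source)
  expect_equal(nrow(intersect_unified(U1, mk(p2[0, ], e2[0, ]))$pairs), 0L)
  expect_true(all(paste(common$pairs$source, common$pairs$target) %in%
                  paste(p1$source, p1$target)))
  expect_true(all(paste(common$pairs$source, common$pairs$target) %in%
                  paste(p2$source, p2$target)))
})
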