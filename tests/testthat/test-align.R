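test_that("conserved edges follow the image of the mapping", {
  G <- toy_path()
  H <- toy_triangle()
  aln <- toy_path_triangle_alignment()
  cons <- conserved_edges(aln, G, H)
  expect_equal(nrow(cons), 2L)   # both path edges land on triangle edges

  # identity self-alignment conserves everything
  id <- network_alignment(stats::setNames(H$nodes, H$nodes))
  expect_equal(nrow(conserved_edges(id, H, H)), n_edges(H))

  # mapping the only edge onto a non-adjacent pair conserves nothing
  G1 <- ppi_network(data.frame(from = "a", to = "b"))
  H1 <- ppi_network(data.frame(from = c("x", "y"), to = c("y", "z")),
                    nodes = c("x", "y", "z", "w"))
  bad <- network_alignment(c(a = "x", b = "w"))
  expect_equal(nrow(conserved_edges(bad, G1, H1)), 0L)

  unknown <- network_alignment(c(a = "x", b = "y", nope = "z"))
  expect_error(conserved_edges(unknown, G1, H1), "nope")
})

test_that("S3 penalizes both missing and spurious induced edges", {
  H <- toy_triangle()
  id <- network_alignment(stats::setNames(H$nodes, H$nodes))
  expect_equal(s3_score(id, H, H), 1)

  # path onto triangle: C = 2, |E_G| = 2, induced = 3 -> 2/3
  expect_equal(s3_score(toy_path_triangle_alignment(), toy_path(), H), 2 / 3)

  G0 <- ppi_network(nodes = c("a", "b"))
  H0 <- ppi_network(nodes = c("x", "y"))
  s <- s3_score(network_alignment(c(a = "x", b = "y")), G0, H0)
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "degenerate"))
})

test_that("the objective blends topology and similarity as alpha dictates", {
  G <- toy_path()
  H <- toy_triangle()
  aln <- toy_path_triangle_alignment()
  S <- matrix(c(0.9, 0, 0, 0, 0.8, 0, 0, 0, 0.7), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("x", "y", "z")))
  expect_equal(alignment_objective(aln, G, H, objective_config(1, "S3", S)),
               as.numeric(s3_score(aln, G, H)))
  ones <- matrix(1, 3, 3, dimnames = dimnames(S))
  expect_equal(alignment_objective(aln, G, H, objective_config(0, "S3", ones)),
               1)
  expect_equal(alignment_objective(aln, G, H, objective_config(0.5, "S3", S)),
               0.5 * (2 / 3) + 0.5 * 0.8)
  # EC variant uses the plain conserved fraction
  expect_equal(alignment_objective(aln, G, H, objective_config(1, "EC", S)), 1)
})

test_that("exhaustive search agrees with an independently coded enumerator", {
  one <- exhaustive_align(ppi_network(nodes = "a"), ppi_network(nodes = "x"),
                          objective_config(1))
  expect_equal(one$mapping, c(a = "x"))

  tri <- toy_triangle()
  self <- exhaustive_align(tri, tri, objective_config(1))
  expect_equal(self$objective_value, 1)
  expect_equal(self$mapping, stats::setNames(tri$nodes, tri$nodes))  # lex-least automorphism

  set.seed(408)
  for (k in 1:5) {
    inst <- random_instance(4, 5)
    alpha <- sample(c(0, 0.5, 1), 1L)
    mine <- exhaustive_align(inst$G, inst$H,
                             objective_config(alpha, "S3", inst$S))
    indep <- enumerate_best_alignment(inst$G, inst$H, alpha, inst$S)
    expect_equal(mine$objective_value, indep$obj, tolerance = 1e-9)
    expect_equal(unname(mine$mapping[names(indep$mapping)]),
                 unname(indep$mapping))
  }
  expect_error(exhaustive_align(random_instance(8, 9)$G,
                                random_instance(8, 9)$H,
                                objective_config(1)),
               "<= 7")
})

test_that("greedy alignment follows the renewed-topology score with lexicographic ties", {
  # identical 4-cycles with identity similarity recover the identity mapping
  cyc <- function(ids) {
    ppi_network(data.frame(from = ids, to = ids[c(2, 3, 4, 1)]))
  }
  G <- cyc(c("a", "b", "c", "d"))
  H <- cyc(c("w", "x", "y", "z"))
  S <- diag(4)
  dimnames(S) <- list(G$nodes, H$nodes)
  aln <- greedy_align(G, H, objective_config(0.5, "S3", S))
  expect_equal(aln$mapping, c(a = "w", b = "x", c = "y", d = "z"))

  # all-zero similarity at alpha 0: pure tie-break, lexicographic pairing
  zero <- matrix(0, 4, 4, dimnames = list(G$nodes, H$nodes))
  aln <- greedy_align(G, H, objective_config(0, "S3", zero))
  expect_equal(aln$mapping, c(a = "w", b = "x", c = "y", d = "z"))

  # a planted high-similarity seed pair is matched first and neighbors follow:
  # hand trace of the greedy loop on a 5-node path vs its copy, where only
  # (c, y3) has similarity. Step 1 matches c-y3; afterwards T steers each
  # neighbor of c onto a neighbor of y3 in lexicographic order.
  P <- ppi_network(data.frame(from = c("a", "b", "c", "d"),
                              to = c("b", "c", "d", "e")))
  Q <- ppi_network(data.frame(from = c("y1", "y2", "y3", "y4"),
                              to = c("y2", "y3", "y4", "y5")))
  S2 <- matrix(0, 5, 5, dimnames = list(P$nodes, Q$nodes))
  S2["c", "y3"] <- 1
  aln <- greedy_align(P, Q, objective_config(0.5, "S3", S2))
  expect_equal(aln$mapping[["c"]], "y3")
  # hand simulation: after c-y3, candidates b and d tie at T = 1 for y2/y4;
  # lexicographic source order matches b first, to the smaller neighbor y2,
  # then d-y4, then a-y1 (T = 1 via b-y2), then e-y5.
  expect_equal(aln$mapping, c(a = "y1", b = "y2", c = "y3", d = "y4", e = "y5"))
})

test_that("the GA aligner is deterministic, monotone and total/injective", {
  set.seed(409)
  inst <- random_instance(6, 7)
  cfg <- objective_config(0.5, "S3", inst$S)
  a1 <- ga_align(inst$G, inst$H, cfg, population = 40, generations = 60,
                 patience = 15, seed = 11)
  a2 <- ga_align(inst$G, inst$H, cfg, population = 40, generations = 60,
                 patience = 15, seed = 11)
  expect_identical(a1$mapping, a2$mapping)
  expect_identical(a1$objective_value, a2$objective_value)

  trace <- attr(a1, "trace")
  expect_true(all(diff(trace) >= -1e-12))

  expect_equal(sort(names(a1$mapping)), inst$G$nodes)   # total
  expect_equal(anyDuplicated(a1$mapping), 0L)           # injective

  single <- ga_align(ppi_network(nodes = "a"), ppi_network(nodes = "x"),
                     objective_config(1), population = 4, generations = 5,
                     seed = 1)
  expect_equal(single$mapping, c(a = "x"))

  expect_error(ga_align(inst$H, inst$G, cfg, seed = 1), "swap")
  expect_error(ga_align(inst$G, inst$H, cfg, population = 1, seed = 1),
               "population")
})

test_that("alignments of self onto self with alpha = 1 recover full edge conservation", {
  # connected, automorphism-free network: S3 must reach exactly 1
  G <- ppi_network(data.frame(
    from = c("a", "a", "b", "b", "c", "d"),
    to   = c("b", "c", "c", "d", "e", "f")))
  aln <- ga_align(G, G, objective_config(1), population = 60,
                  generations = 120, patience = 25, restarts = 3, seed = 5)
  expect_equal(aln$objective_value, 1)
  expect_equal(as.numeric(s3_score(aln, G, G)), 1)
})

test_that("alignment TSV files are self-describing and round-trip", {
  set.seed(410)
  inst <- random_instance(5, 6)
  cfg <- objective_config(0.5, "S3", inst$S)
  aln <- greedy_align(inst$G, inst$H, cfg)
  path <- tempfile(fileext = ".tsv")
  write_alignment_tsv(aln, path, inst$S)
  back <- read_alignment_tsv(path)
  expect_equal(back$mapping, aln$mapping)
  expect_equal(back$method, "greedy")
  expect_equal(back$objective_value, aln$objective_value, tolerance = 1e-9)
  expect_equal(back$parameters$alpha, 0.5)
})
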