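#!/usr/bin/env Rscript
# Stage 5: build the unified conserved networks (aligned protein pairs +
# conserved interactions) from the GA and the reference alignments, then
# intersect them into the common network: the pairs aligned identically by
# both analyses and the conserved interactions found in both -- the
# high-confidence interolog core.
suppressMessages(library(interolign))

fix <- "results/fixtures/divergent"
netA <- read_edge_list(file.path(fix, "netA.tsv"), "speciesA")
netB <- read_edge_list(file.path(fix, "netB.tsv"), "speciesB")
map <- read_ortholog_table(file.path(fix, "orthologs.tsv"))
if (n_nodes(netA) > n_nodes(netB)) {
  G <- netB; H <- netA
  map <- ortholog_map(map$pairs[, c("b", "a")])
} else {
  G <- netA; H <- netB
}

ga <- read_alignment_tsv("results/alignment_ga_combined.tsv")
ref <- reference_alignment(G, H, map)

U_ga <- build_unified_network(ga, G, H, map)
U_ref <- build_unified_network(ref, G, H, map)
common <- intersect_unified(U_ga, U_ref)

for (x in list(list(U_ga, "unified_ga"), list(U_ref, "unified_reference"),
               list(common, "common"))) {
  print(x[[1L]])
  net <- unified_as_network(x[[1L]], species = x[[2L]])
  write_network(net, sprintf("results/%s.tsv", x[[2L]]), "tsv")
  write_network(net, sprintf("results/%s.sif", x[[2L]]), "sif")
}
message(sprintf(paste("common network: %d protein pairs and %d conserved",
                      "interactions aligned identically in both analyses;",
                      "%d pairs are interolog-confirmed predicted orthologs"),
                nrow(common$pairs), nrow(common$edges),
                sum(common$pairs$interolog_confirmed)))
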