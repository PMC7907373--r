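#!/usr/bin/env Rscript
# Stage 2: global pairwise sequence alignment of every species-A protein
# against every species-B protein of the divergent fixture, giving the
# biological node-similarity input for network alignment. The table below
# confirms the separation between ortholog and background similarity that
# the alignment objective relies on.
suppressMessages(library(interolign))

fix <- "results/fixtures/divergent"
netA <- read_edge_list(file.path(fix, "netA.tsv"), "speciesA")
netB <- read_edge_list(file.path(fix, "netB.tsv"), "speciesB")
seqs <- c(
  local({ s <- Biostrings::readAAStringSet(file.path(fix, "seqA.fasta"))
          stats::setNames(as.character(s), names(s)) }),
  local({ s <- Biostrings::readAAStringSet(file.path(fix, "seqB.fasta"))
          stats::setNames(as.character(s), names(s)) }))
map <- read_ortholog_table(file.path(fix, "orthologs.tsv"))

M <- build_similarity_matrix(netA, netB, seqs, scoring_scheme())
write_similarity_tsv(M, "results/similarity_divergent.tsv")

is_orth <- outer(rownames(M), colnames(M),
                 Vectorize(function(a, b) is_ortholog_pair(map, a, b)))
message(sprintf("similarity (percent/100) written for %d x %d pairs", nrow(M), ncol(M)))
message(sprintf("  mean ortholog-pair similarity:   %.3f", mean(M[is_orth])))
message(sprintf("  mean background similarity:      %.3f", mean(M[!is_orth])))
message(sprintf("  scoring: %s", attr(M, "scheme")))
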