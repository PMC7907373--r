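AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]

#' Scoring scheme for global protein alignment
#'
#' Substitution matrix plus affine gap penalties. Defaults are the de facto
#' standard for needle-style global protein alignment: BLOSUM62, gap open
#' 10, gap extend 0.5. A gap of length L costs
#' \code{gap_open + L * gap_extend}. The matrix is restricted to the 20
#' amino acids plus X, with X scoring 0 against everything (an unknown
#' residue neither helps nor hurts).
#'
#' @param matrix substitution matrix name (\code{"BLOSUM62"},
#'   \code{"BLOSUM45"}, \code{"BLOSUM80"}, \code{"PAM250"}, ... as shipped
#'   with Biostrings) or a symmetric numeric matrix with residue dimnames.
#' @param gap_open non-negative gap opening penalty.
#' @param gap_extend non-negative gap extension penalty; must not exceed
#'   \code{gap_open}.
#' @return an object of class \code{scoring_scheme}.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10,
                           gap_extend = 0.5) {
  name <- "custom"
  if (is.character(matrix)) {
    name <- matrix
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    matrix <- get(name, envir = env)
  }
  if (!is.matrix(matrix) || is.null(rownames(matrix))) {
    stop_fmt("substitution matrix must be a named matrix")
  }
  alphabet <- c(AA20, "X")
  miss <- setdiff(AA20, rownames(matrix))
  if (length(miss) > 0L) {
    stop_fmt("substitution matrix lacks residues: %s",
             paste(miss, collapse = ", "))
  }
  full <- base::matrix(0, length(alphabet), length(alphabet),
                       dimnames = list(alphabet, alphabet))
  full[AA20, AA20] <- matrix[AA20, AA20]
  full["X", ] <- 0
  full[, "X"] <- 0
  if (!isTRUE(all.equal(full, t(full)))) {
    stop_fmt("substitution matrix must be symmetric")
  }
  if (all(full == round(full))) storage.mode(full) <- "integer"
  if (gap_open < 0 || gap_extend < 0 || gap_extend > gap_open) {
    stop_fmt("need 0 <= gap_extend <= gap_open")
  }
  structure(list(matrix = full, gap_open = gap_open, gap_extend = gap_extend,
                 name = name),
            class = "scoring_scheme")
}

check_protein <- function(seq, label) {
  chars <- strsplit(seq, "")[[1L]]
  bad <- which(!chars %in% c(AA20, "X"))
  if (length(bad) > 0L) {
    stop_fmt("illegal character '%s' in %s at position %d",
             chars[[bad[[1L]]]], label, bad[[1L]])
  }
  invisible(seq)
}

#' Needleman-Wunsch global pairwise protein alignment
#'
#' True global alignment over the entire length of both proteins, end gaps
#' penalized, with affine gap costs. The dynamic programming is delegated to
#' \code{Biostrings::pairwiseAlignment} (\code{type = "global"}); the
#' percent similarity is the EMBOSS-style statistic: the percentage of
#' alignment columns in which both positions are residues whose substitution
#' score is strictly positive (i.e. matched or physicochemically similar),
#' over the full alignment length including gap columns.
#'
#' @param seq_a,seq_b protein sequences (20 amino acids plus X); one may be
#'   empty, not both.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @return an object of class \code{pairwise_alignment}: list with
#'   \code{aligned_a}, \code{aligned_b} (gapped strings of equal length),
#'   \code{score}, \code{percent_similarity}.
#' @export
needleman_wunsch <- function(seq_a, seq_b, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  seq_a <- toupper(as.character(seq_a))
  seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) == 0L && nchar(seq_b) == 0L) {
    stop_fmt("both sequences are empty")
  }
  check_protein(seq_a, "seq_a")
  check_protein(seq_b, "seq_b")
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) {
    n <- max(nchar(seq_a), nchar(seq_b))
    aln <- list(aligned_a = if (nchar(seq_a)) seq_a else strrep("-", n),
                aligned_b = if (nchar(seq_b)) seq_b else strrep("-", n),
                score = -(scheme$gap_open + n * scheme$gap_extend),
                percent_similarity = 0)
    return(structure(aln, class = "pairwise_alignment"))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = "global")
  full <- full_aligned_strings(pa, seq_a, seq_b)
  aln <- structure(list(aligned_a = full[[1L]],
                        aligned_b = full[[2L]],
                        score = Biostrings::score(pa),
                        percent_similarity = NA_real_),
                   class = "pairwise_alignment")
  aln$percent_similarity <- percent_similarity(aln, scheme)
  aln
}

# Rebuild the complete gapped strings (end gaps included) from the aligned
# views plus the untrimmed sequence overhangs; much faster than
# alignedPattern()/alignedSubject() and identical up to the (score-neutral,
# never-matching) ordering of the one-sided end-gap blocks. Vectorized over
# a PairwiseAlignments of several patterns vs one subject.
full_aligned_strings <- function(pa, seqs_a, seq_b) {
  va <- as.character(Biostrings::pattern(pa))
  vb <- as.character(Biostrings::subject(pa))
  sa <- Biostrings::start(Biostrings::pattern(pa))
  ea <- Biostrings::end(Biostrings::pattern(pa))
  sb <- Biostrings::start(Biostrings::subject(pa))
  eb <- Biostrings::end(Biostrings::subject(pa))
  pre_a <- substr(seqs_a, 1L, sa - 1L)
  post_a <- substr(seqs_a, ea + 1L, nchar(seqs_a))
  pre_b <- substr(rep(seq_b, length(va)), 1L, sb - 1L)
  post_b <- substr(rep(seq_b, length(va)), eb + 1L, nchar(seq_b))
  list(unname(paste0(pre_a, strrep("-", nchar(pre_b)), va,
                     post_a, strrep("-", nchar(post_b)))),
       unname(paste0(strrep("-", nchar(pre_a)), pre_b, vb,
                     strrep("-", nchar(post_a)), post_b)))
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment: length %d, score %.1f, similarity %.1f%%\n",
              nchar(x$aligned_a), x$score, x$percent_similarity))
  cat(x$aligned_a, "\n")
  cat(x$aligned_b, "\n")
  invisible(x)
}

# 256x256 byte-indexed lookup of strictly positive substitution scores.
positive_lookup <- function(scheme) {
  L <- matrix(FALSE, 256L, 256L)
  codes <- utf8ToInt(paste(rownames(scheme$matrix), collapse = ""))
  L[cbind(rep(codes, each = length(codes)) + 1L,
          rep(codes, times = length(codes)) + 1L)] <-
    as.vector(t(scheme$matrix) > 0)
  L
}

matched_columns <- function(aligned_a, aligned_b, lookup) {
  ra <- as.integer(charToRaw(aligned_a)) + 1L
  rb <- as.integer(charToRaw(aligned_b)) + 1L
  sum(lookup[cbind(ra, rb)])
}

#' Percent similarity of a global alignment
#'
#' 100 x (columns where both positions are residues with substitution score
#' > 0) / (total alignment length, gaps included).
#'
#' @param aln a \code{pairwise_alignment}.
#' @param scheme the \code{\link{scoring_scheme}} defining "similar".
#' @return a number in [0, 100].
#' @export
percent_similarity <- function(aln, scheme = scoring_scheme()) {
  stopifnot(inherits(aln, "pairwise_alignment"),
            nchar(aln$aligned_a) == nchar(aln$aligned_b))
  len <- nchar(aln$aligned_a)
  if (len == 0L) return(0)
  100 * matched_columns(aln$aligned_a, aln$aligned_b,
                        positive_lookup(scheme)) / len
}

#' Cross-species node similarity matrix
#'
#' Aligns every source-network protein against every target-network protein
#' (global Needleman-Wunsch) and stores percent similarity / 100, the
#' biological node-similarity input to network alignment. Rows are the
#' sorted source node ids, columns the sorted target node ids. Nodes without
#' a sequence get all-zero rows/columns (with a warning).
#'
#' @param netA source \code{\link{ppi_network}}.
#' @param netB target \code{\link{ppi_network}}.
#' @param sequences named character vector (or \code{AAStringSet}) keyed by
#'   node id, covering nodes of both networks.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @return numeric matrix in [0, 1] with attribute \code{scheme} describing
#'   the scoring choices.
#' @export
build_similarity_matrix <- function(netA, netB, sequences,
                                    scheme = scoring_scheme()) {
  stopifnot(inherits(netA, "ppi_network"), inherits(netB, "ppi_network"))
  seqs <- stats::setNames(toupper(as.character(sequences)), names(sequences))
  src <- netA$nodes
  tgt <- netB$nodes
  src_has <- src[src %in% names(seqs) & nzchar(seqs[src])]
  tgt_has <- tgt[tgt %in% names(seqs) & nzchar(seqs[tgt])]
  if (length(src_has) == 0L) stop_fmt("no sequences for any source node")
  if (length(tgt_has) == 0L) stop_fmt("no sequences for any target node")
  missing <- c(setdiff(src, src_has), setdiff(tgt, tgt_has))
  if (length(missing) > 0L) {
    warn_fmt("no sequence for %d node(s); their similarities are 0 (%s%s)",
             length(missing), paste(utils::head(missing, 5L), collapse = ", "),
             if (length(missing) > 5L) ", ..." else "")
  }
  M <- matrix(0, length(src), length(tgt), dimnames = list(src, tgt))
  lookup <- positive_lookup(scheme)
  tgt_set <- Biostrings::AAStringSet(seqs[tgt_has])
  for (s in src_has) {
    pa <- Biostrings::pairwiseAlignment(
      tgt_set, Biostrings::AAString(seqs[[s]]),
      substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
      type = "global")
    full <- full_aligned_strings(pa, as.character(tgt_set), seqs[[s]])
    M[s, tgt_has] <- vapply(seq_along(tgt_has), function(j) {
      matched_columns(full[[2L]][[j]], full[[1L]][[j]], lookup) /
        nchar(full[[1L]][[j]])
    }, 0)
  }
  attr(M, "scheme") <- sprintf("matrix=%s gap_open=%g gap_extend=%g",
                               scheme$name, scheme$gap_open, scheme$gap_extend)
  M
}

#' Write / read a similarity matrix as TSV
#'
#' First row holds the target ids, first column the source ids; a leading
#' \code{#} comment records the scoring choices so runs are self-describing.
#'
#' @param M similarity matrix from \code{\link{build_similarity_matrix}}.
#' @param path TSV path.
#' @return \code{write_similarity_tsv}: invisibly \code{path};
#'   \code{read_similarity_tsv}: the matrix.
#' @export
write_similarity_tsv <- function(M, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(attr(M, "scheme"))) {
    writeLines(paste0("# ", attr(M, "scheme")), con)
  }
  writeLines(paste(c("id", colnames(M)), collapse = "\t"), con)
  for (i in seq_len(nrow(M))) {
    writeLines(paste(c(rownames(M)[i], format(M[i, ], digits = 10,
                                              trim = TRUE, scientific = FALSE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  scheme_desc <- NULL
  if (length(lines) > 0L && grepl("^#", lines[[1L]])) {
    scheme_desc <- sub("^#\\s*", "", lines[[1L]])
    lines <- lines[-1L]
  }
  rows <- strsplit(lines, "\t", fixed = TRUE)
  tgt <- rows[[1L]][-1L]
  src <- vapply(rows[-1L], `[[`, "", 1L)
  M <- matrix(0, length(src), length(tgt), dimnames = list(src, tgt))
  for (i in seq_along(src)) {
    M[i, ] <- as.numeric(rows[[i + 1L]][-1L])
  }
  attr(M, "scheme") <- scheme_desc
  M
}
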