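# Independent oracles and shared fixtures. Everything here is coded from
# first principles (textbook recursions, brute-force enumeration) and never
# calls the implementation paths it is used to check.

# --- Needleman-Wunsch affine-gap DP (Gotoh), scores only ------------------
# Convention: a gap of length L costs gap_open + L * gap_extend; end gaps
# penalized (true global alignment).
nw_oracle_score <- function(a, b, scheme) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A)
  m <- length(B)
  S <- scheme$matrix
  go <- scheme$gap_open
  ge <- scheme$gap_extend
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)
  Iy <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) Ix[i + 1L, 1L] <- -(go + i * ge)
  for (j in seq_len(m)) Iy[1L, j + 1L] <- -(go + j * ge)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1L, j + 1L] <- max(M[i, j], Ix[i, j], Iy[i, j]) + S[A[[i]], B[[j]]]
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - go - ge,
                                Ix[i, j + 1L] - ge,
                                Iy[i, j + 1L] - go - ge)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - go - ge,
                                Iy[i + 1L, j] - ge,
                                Ix[i + 1L, j] - go - ge)
    }
  }
  max(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
}

random_aa_seq <- function(len, alphabet = c(strsplit("ARNDCQEGHILKMFPSTWYV",
                                                     "")[[1L]], "X")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# --- independent alignment objective from raw edge tables -----------------
# mapping: named character vector source -> target.
objective_oracle <- function(mapping, G, H, alpha, S = NULL,
                             edge_term = "S3") {
  hkeys <- paste(pmin(H$edges$from, H$edges$to),
                 pmax(H$edges$from, H$edges$to))
  conserved <- 0L
  for (k in seq_len(nrow(G$edges))) {
    u <- mapping[[G$edges$from[[k]]]]
    v <- mapping[[G$edges$to[[k]]]]
    if (paste(min(u, v), max(u, v)) %in% hkeys) conserved <- conserved + 1L
  }
  img <- unname(mapping)
  induced <- 0L
  for (k in seq_len(nrow(H$edges))) {
    if (H$edges$from[[k]] %in% img && H$edges$to[[k]] %in% img) {
      induced <- induced + 1L
    }
  }
  topo <- if (edge_term == "S3") {
    den <- nrow(G$edges) + induced - conserved
    if (den == 0L) 0 else conserved / den
  } else {
    if (nrow(G$edges) == 0L) 0 else conserved / nrow(G$edges)
  }
  sim <- 0
  if (!is.null(S) && length(mapping) > 0L) {
    vals <- vapply(names(mapping), function(s) {
      t <- mapping[[s]]
      if (s %in% rownames(S) && t %in% colnames(S)) S[s, t] else 0
    }, 0)
    sim <- mean(vals)
  }
  alpha * topo + (1 - alpha) * sim
}

# Second, independently coded nested-loop enumerator of injective total
# mappings; returns the best objective and the first (lexicographically
# least) mapping attaining it.
enumerate_best_alignment <- function(G, H, alpha, S = NULL,
                                     edge_term = "S3") {
  src <- G$nodes
  tgt <- H$nodes
  best <- list(obj = -Inf, mapping = NULL)
  recurse <- function(i, taken, mapping) {
    if (i > length(src)) {
      obj <- objective_oracle(mapping, G, H, alpha, S, edge_term)
      if (obj > best$obj + 1e-12) best <<- list(obj = obj, mapping = mapping)
      return(invisible())
    }
    for (t in tgt) {
      if (!t %in% taken) {
        mapping[[src[[i]]]] <- t
        recurse(i + 1L, c(taken, t), mapping)
      }
    }
  }
  recurse(1L, character(), stats::setNames(character(), character()))
  best
}

# --- toy instances used across modules ------------------------------------
# path a-b-c mapped onto triangle x-y-z
toy_path <- function() {
  ppi_network(data.frame(from = c("a", "b"), to = c("b", "c")),
              species = "toy-src")
}

toy_triangle <- function() {
  ppi_network(data.frame(from = c("x", "x", "y"), to = c("y", "z", "z")),
              species = "toy-tgt")
}

toy_path_triangle_alignment <- function() {
  network_alignment(c(a = "x", b = "y", c = "z"), method = "manual")
}

random_instance <- function(nG, nH, p = 0.4) {
  stopifnot(nG <= nH)
  gnodes <- sprintf("g%02d", seq_len(nG))
  hnodes <- sprintf("h%02d", seq_len(nH))
  rnd_edges <- function(nodes) {
    pairs <- t(utils::combn(nodes, 2L))
    keep <- stats::runif(nrow(pairs)) < p
    if (!any(keep)) keep[sample.int(nrow(pairs), 1L)] <- TRUE
    data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L],
               stringsAsFactors = FALSE)
  }
  S <- matrix(stats::runif(nG * nH), nG, nH,
              dimnames = list(gnodes, hnodes))
  list(G = ppi_network(rnd_edges(gnodes), nodes = gnodes, species = "rndG"),
       H = ppi_network(rnd_edges(hnodes), nodes = hnodes, species = "rndH"),
       S = S)
}

# --- duplicate duplication-divergence generator (edge counts only) --------
dd_edge_count_oracle <- function(n, p, q) {
  adj <- matrix(FALSE, n, n)
  adj[1:3, 1:3] <- TRUE
  diag(adj) <- FALSE
  for (i in 4:n) {
    tpl <- sample.int(i - 1L, 1L)
    for (j in which(adj[tpl, seq_len(i - 1L)])) {
      if (stats::runif(1) < p) {
        adj[i, j] <- TRUE
        adj[j, i] <- TRUE
      }
    }
    if (stats::runif(1) < q) {
      adj[i, tpl] <- TRUE
      adj[tpl, i] <- TRUE
    }
  }
  sum(adj) / 2
}
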