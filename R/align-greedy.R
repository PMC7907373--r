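#' Greedy seed-and-extend network alignment
#'
#' Baseline aligner in the spirit of NETAL's greedy search: it repeatedly
#' aligns the unmatched source/target pair (u, w) with the best blended
#' score \code{alpha * T(u, w) + (1 - alpha) * sim(u, w)}, where
#' \code{T(u, w)} is the fraction of u's already-aligned neighbors whose
#' images are neighbors of w (0 while u has no aligned neighbor) -- so the
#' topological information is renewed after every match. Ties are broken
#' lexicographically by (source id, target id), making the result fully
#' deterministic without a seed.
#'
#' @inheritParams ga_align
#' @return a \code{\link{network_alignment}}.
#' @export
greedy_align <- function(G, H, cfg) {
  env <- align_env(G, H, cfg)
  perm <- greedy_align_perm(env)
  perm_to_alignment(env, perm, method = "greedy",
                    parameters = list(alpha = env$alpha,
                                      edge_term = env$edge_term),
                    objective = objective_of_perm(env, perm))
}

# Index-level greedy loop shared with the GA initial population.
greedy_align_perm <- function(env) {
  nG <- env$nG
  nH <- env$nH
  adjG <- if (nG > 0L) {
    A <- matrix(FALSE, nG, nG)
    if (env$mG > 0L) {
      A[env$eG] <- TRUE
      A[env$eG[, c(2L, 1L), drop = FALSE]] <- TRUE
    }
    A
  } else matrix(FALSE, 0L, 0L)
  perm <- rep(NA_integer_, nG)
  free_t <- rep(TRUE, nH)
  free_s <- rep(TRUE, nG)
  for (step in seq_len(nG)) {
    U <- which(free_s)
    W <- which(free_t)
    mapped_s <- which(!free_s)
    Tmat <- matrix(0, length(U), length(W))
    if (length(mapped_s) > 0L) {
      deg_al <- rowSums(adjG[U, mapped_s, drop = FALSE])
      num <- (adjG[U, mapped_s, drop = FALSE] + 0) %*%
        (env$adjH[perm[mapped_s], W, drop = FALSE] + 0)
      nz <- deg_al > 0
      Tmat[nz, ] <- num[nz, , drop = FALSE] / deg_al[nz]
    }
    score <- env$alpha * Tmat +
      (1 - env$alpha) * env$S[U, W, drop = FALSE]
    # lexicographic tie-break: smallest source index, then target index
    best <- max(score)
    hit <- which(score >= best - 1e-12, arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    u <- U[[hit[1L, 1L]]]
    w <- W[[hit[1L, 2L]]]
    perm[[u]] <- w
    free_s[[u]] <- FALSE
    free_t[[w]] <- FALSE
  }
  perm
}

#' Exhaustive optimal alignment (testing oracle)
#'
#' Enumerates every injective total mapping of the source into the target
#' and returns the one of maximum objective; ties are broken by the
#' lexicographically least mapping tuple (targets listed in sorted source-id
#' order). Guarded to tiny instances, where full enumeration is feasible.
#'
#' @inheritParams ga_align
#' @return a \code{\link{network_alignment}}.
#' @export
exhaustive_align <- function(G, H, cfg) {
  env <- align_env(G, H, cfg)
  if (env$nG > 7L || env$nH > 8L) {
    stop_fmt("exhaustive_align is limited to |V_G| <= 7 and |V_H| <= 8 (got %d, %d)",
             env$nG, env$nH)
  }
  best <- new.env(parent = emptyenv())
  best$obj <- -Inf
  best$perm <- NULL
  perm <- integer(env$nG)
  used <- rep(FALSE, env$nH)
  recurse <- function(i) {
    if (i > env$nG) {
      obj <- objective_of_perm(env, perm)
      if (obj > best$obj + 1e-12) {   # strict improvement: first (lex-least) wins ties
        best$obj <- obj
        best$perm <- perm
      }
      return(invisible())
    }
    for (w in seq_len(env$nH)) {
      if (!used[[w]]) {
        perm[[i]] <<- w
        used[[w]] <<- TRUE
        recurse(i + 1L)
        used[[w]] <<- FALSE
      }
    }
  }
  if (env$nG == 0L) {
    best$obj <- 0
    best$perm <- integer(0)
  } else {
    recurse(1L)
  }
  perm_to_alignment(env, best$perm, method = "exhaustive",
                    parameters = list(alpha = env$alpha,
                                      edge_term = env$edge_term),
                    objective = best$obj)
}
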