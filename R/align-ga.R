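#' Genetic-algorithm global network alignment
#'
#' Evolves a population of one-to-one alignments (injective arrays over
#' target indices) toward maximum objective, in the spirit of GA-based
#' aligners such as MAGNA++: the population is recombined and mutated every
#' generation until the alignment can no longer be improved. Specifics:
#' tournament selection (size 2), position-wise crossover with conflict
#' repair (an unassigned source gets the free target of highest sequence
#' similarity), random-transposition mutation, and elitism (the
#' \code{elite_count} best survive unchanged, so the best objective is
#' non-decreasing across generations). The initial population holds the
#' \code{\link{greedy_align}} solution plus random injective mappings.
#' The run stops after \code{generations} generations or once
#' \code{patience} generations pass without improvement; \code{restarts}
#' independent runs (seeds derived from \code{seed}) are performed and the
#' best result returned. All randomness flows from \code{seed}; the same
#' inputs and seed give identical output.
#'
#' @param G source network (must not have more nodes than \code{H}).
#' @param H target network.
#' @param cfg an \code{\link{objective_config}}.
#' @param population number of alignments per generation (>= 2).
#' @param generations maximum generations per restart.
#' @param crossover_rate probability a child is produced by crossover rather
#'   than copied from a parent.
#' @param mutation_rate probability a child is mutated.
#' @param elite_count number of top alignments carried over unchanged.
#' @param patience generations without improvement before early stop.
#' @param restarts independent GA runs; the best alignment wins.
#' @param seed integer seed (mandatory for reproducibility).
#' @return a \code{\link{network_alignment}} with attribute \code{trace}
#'   (best objective per generation of the winning restart).
#' @export
ga_align <- function(G, H, cfg, population = 100, generations = 200,
                     crossover_rate = 0.8, mutation_rate = 0.3,
                     elite_count = 2, patience = 30, restarts = 1,
                     seed = 1) {
  env <- align_env(G, H, cfg)
  if (population < 2) stop_fmt("population must be >= 2")
  elite_count <- max(1L, min(as.integer(elite_count), population - 1L))
  greedy_perm <- greedy_align_perm(env)

  best_obj <- -Inf
  best_perm <- NULL
  best_trace <- NULL
  for (r in seq_len(restarts)) {
    res <- with_seed(derive_seed(seed, "ga-restart", r), {
      ga_run(env, population, generations, crossover_rate, mutation_rate,
             elite_count, patience, greedy_perm)
    })
    if (res$objective > best_obj + 1e-12) {
      best_obj <- res$objective
      best_perm <- res$perm
      best_trace <- res$trace
    }
  }
  aln <- perm_to_alignment(
    env, best_perm, method = "ga",
    parameters = list(alpha = env$alpha, edge_term = env$edge_term,
                      population = population, generations = generations,
                      crossover_rate = crossover_rate,
                      mutation_rate = mutation_rate,
                      elite_count = elite_count, patience = patience,
                      restarts = restarts, seed = seed),
    objective = best_obj)
  attr(aln, "trace") <- best_trace
  aln
}

# One GA run under the current RNG state.
ga_run <- function(env, population, generations, crossover_rate,
                   mutation_rate, elite_count, patience, greedy_perm) {
  nG <- env$nG
  nH <- env$nH
  pop <- vector("list", population)
  pop[[1L]] <- greedy_perm
  for (k in 2:population) pop[[k]] <- sample.int(nH, nG)
  fit <- vapply(pop, function(p) objective_of_perm(env, p), 0)

  trace <- numeric(0)
  stall <- 0L
  gen <- 0L
  while (gen < generations) {
    gen <- gen + 1L
    ord <- order(fit, decreasing = TRUE)
    newpop <- pop[ord[seq_len(elite_count)]]
    newfit <- fit[ord[seq_len(elite_count)]]
    while (length(newpop) < population) {
      child <- if (stats::runif(1) < crossover_rate) {
        ga_crossover(env, ga_tournament(pop, fit), ga_tournament(pop, fit))
      } else {
        ga_tournament(pop, fit)
      }
      if (stats::runif(1) < mutation_rate) {
        child <- ga_mutate(child, nG, nH)
      }
      newpop[[length(newpop) + 1L]] <- child
      newfit[[length(newfit) + 1L]] <- objective_of_perm(env, child)
    }
    improved <- max(newfit) > max(fit) + 1e-12
    pop <- newpop
    fit <- newfit
    trace[[gen]] <- max(fit)
    stall <- if (improved) 0L else stall + 1L
    if (stall >= patience) break
  }
  ibest <- which.max(fit)
  list(perm = pop[[ibest]], objective = fit[[ibest]], trace = trace)
}

ga_tournament <- function(pop, fit) {
  i <- sample.int(length(pop), 2L)
  pop[[if (fit[[i[[1L]]]] >= fit[[i[[2L]]]]) i[[1L]] else i[[2L]]]]
}

# Position-wise inheritance from either parent; positions whose inherited
# target is already taken are re-assigned to the free target of highest
# similarity (ties: lowest index).
ga_crossover <- function(env, p1, p2) {
  nG <- length(p1)
  pick <- stats::runif(nG) < 0.5
  child <- ifelse(pick, p1, p2)
  used <- rep(FALSE, env$nH)
  for (i in seq_len(nG)) {
    if (used[[child[[i]]]]) child[[i]] <- NA_integer_ else used[[child[[i]]]] <- TRUE
  }
  holes <- which(is.na(child))
  for (i in holes) {
    free <- which(!used)
    j <- free[[which.max(env$S[i, free])]]
    child[[i]] <- j
    used[[j]] <- TRUE
  }
  child
}

# Random transposition: swap the targets of two source positions, or move
# one source to a random unused target (when the target side is larger).
ga_mutate <- function(perm, nG, nH) {
  free <- setdiff(seq_len(nH), perm)
  if (nG >= 2L && (length(free) == 0L || stats::runif(1) < 0.5)) {
    ij <- sample.int(nG, 2L)
    perm[ij] <- perm[rev(ij)]
  } else if (length(free) > 0L) {
    perm[[sample.int(nG, 1L)]] <- free[[sample.int(length(free), 1L)]]
  }
  perm
}
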