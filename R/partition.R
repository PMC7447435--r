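# Signed-graph partitioners operating on the region adjacency graph. All
# three are deterministic: ties are broken by the lowest (min node id,
# max node id) edge, and cluster representatives are the smallest member id.

#' GASP average-linkage agglomeration
#'
#' Iteratively contracts the currently strongest attractive edge (highest
#' signed weight) while one exists; after each contraction, parallel edges
#' are merged with an interface-size-weighted average of their signed
#' weights (contact areas add). Terminates when every remaining edge is
#' repulsive (weight <= 0).
#'
#' @param rag a [build_rag()] graph.
#' @param beta_bias splitting bias in (0, 1); higher values tend to
#'   over-segment. Default 0.6.
#' @param weights optional signed edge weights (one per RAG edge, in edge
#'   order) overriding the probability-derived weights.
#' @return integer cluster assignment per node, dense 1..K, named by node id.
#' @export
gasp_average <- function(rag, beta_bias = 0.6, weights = NULL) {
  g <- rag_graph(rag, beta_bias, weights)
  n <- nrow(rag$nodes)
  rep_of <- seq_len(n)
  if (nrow(g) > 0L) {
    eu <- pmin(g$u, g$v); ev <- pmax(g$u, g$v)
    ew <- g$w; ea <- g$area
    repeat {
      if (!length(ew) || max(ew) <= 0) break
      cand <- which(ew == max(ew))
      best <- cand[order(eu[cand], ev[cand])][1L]
      a <- eu[best]; b <- ev[best]           # a < b: contract b into a
      rep_of[rep_of == b] <- a
      eu[eu == b] <- a; ev[ev == b] <- a
      sw <- eu > ev
      if (any(sw)) { tmp <- eu[sw]; eu[sw] <- ev[sw]; ev[sw] <- tmp }
      keep <- eu != ev
      eu <- eu[keep]; ev <- ev[keep]; ew <- ew[keep]; ea <- ea[keep]
      if (length(ew)) {
        key <- paste(eu, ev)
        if (anyDuplicated(key)) {
          # rowsum(reorder = FALSE) rows follow first appearance, matching key[first]
          wsum <- as.numeric(rowsum(ew * ea, key, reorder = FALSE))
          asum <- as.numeric(rowsum(ea, key, reorder = FALSE))
          first <- !duplicated(key)
          eu <- eu[first]; ev <- ev[first]
          ew <- wsum / asum
          ea <- asum
        }
      }
    }
  }
  finalize_partition(rep_of, rag)
}

#' Mutex watershed partitioning
#'
#' Processes edges in order of decreasing absolute signed weight. An
#' attractive edge merges its two clusters unless a mutual-exclusion
#' constraint already separates them; a repulsive edge installs such a
#' constraint unless the clusters are already merged. Zero-weight edges are
#' skipped. The result is invariant to any positive rescaling of all
#' weights.
#'
#' @inheritParams gasp_average
#' @return integer cluster assignment per node, dense 1..K, named by node id.
#' @export
mutex_watershed <- function(rag, beta_bias = 0.6, weights = NULL) {
  g <- rag_graph(rag, beta_bias, weights)
  n <- nrow(rag$nodes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  mutex <- vector("list", n)    # per-root: node ids whose roots are excluded
  has_mutex <- function(ra, rb) {
    pa <- mutex[[ra]]
    if (length(pa) && any(vapply(pa, find, integer(1)) == rb)) return(TRUE)
    FALSE
  }
  if (nrow(g) > 0L) {
    ord <- order(-abs(g$w), pmin(g$u, g$v), pmax(g$u, g$v))
    for (i in ord) {
      w <- g$w[i]
      if (w == 0) next
      ra <- find(g$u[i]); rb <- find(g$v[i])
      if (ra == rb) next
      if (w > 0) {
        if (!has_mutex(ra, rb)) {
          r <- min(ra, rb); s <- max(ra, rb)
          parent[s] <- r
          mutex[r] <- list(c(mutex[[r]], mutex[[s]]))  # [ ] keeps NULL slots
          mutex[s] <- list(integer(0))
        }
      } else {
        mutex[[ra]] <- c(mutex[[ra]], rb)
        mutex[[rb]] <- c(mutex[[rb]], ra)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  finalize_partition(roots, rag)
}

#' Greedy multicut with local-move refinement
#'
#' Approximately minimizes the multicut objective (sum of signed weights
#' over cut edges). Phase 1 greedily contracts the maximum-weight attractive
#' edge, summing parallel edge weights, until no attractive edge remains.
#' Phase 2 hill-climbs with single-node moves (to an adjacent cluster or to
#' a new singleton) until no move improves the objective. The achieved
#' objective is attached as attribute \code{"objective"}.
#'
#' @inheritParams gasp_average
#' @return integer cluster assignment per node, dense 1..K, named by node id,
#'   with attribute \code{objective}.
#' @export
multicut_greedy <- function(rag, beta_bias = 0.6, weights = NULL) {
  g <- rag_graph(rag, beta_bias, weights)
  n <- nrow(rag$nodes)
  rep_of <- seq_len(n)
  if (nrow(g) > 0L) {
    eu <- pmin(g$u, g$v); ev <- pmax(g$u, g$v); ew <- g$w
    repeat {
      if (!length(ew) || max(ew) <= 0) break
      cand <- which(ew == max(ew))
      best <- cand[order(eu[cand], ev[cand])][1L]
      a <- eu[best]; b <- ev[best]
      rep_of[rep_of == b] <- a
      eu[eu == b] <- a; ev[ev == b] <- a
      sw <- eu > ev
      if (any(sw)) { tmp <- eu[sw]; eu[sw] <- ev[sw]; ev[sw] <- tmp }
      keep <- eu != ev
      eu <- eu[keep]; ev <- ev[keep]; ew <- ew[keep]
      if (length(ew)) {
        key <- paste(eu, ev)
        if (anyDuplicated(key)) {
          wsum <- as.numeric(rowsum(ew, key, reorder = FALSE))
          first <- !duplicated(key)
          eu <- eu[first]; ev <- ev[first]
          ew <- wsum
        }
      }
    }
    # Phase 2: local refinement (single-node moves + whole-cluster merges)
    # from three deterministic starts; keep the best objective.
    inc <- vector("list", n)
    for (i in seq_len(nrow(g))) {
      inc[[g$u[i]]] <- c(inc[[g$u[i]]], i)
      inc[[g$v[i]]] <- c(inc[[g$v[i]]], i)
    }
    refine <- function(assign_vec) {
      improved <- TRUE
      sweeps <- 0L
      while (improved && sweeps < 100L) {
        improved <- FALSE
        sweeps <- sweeps + 1L
        for (node in seq_len(n)) {
          ei <- inc[[node]]
          if (!length(ei)) next
          other <- ifelse(g$u[ei] == node, g$v[ei], g$u[ei])
          cur <- assign_vec[node]
          wn <- g$w[ei]
          oc <- assign_vec[other]
          # cost contribution of node's incident edges: sum of w over cut edges
          base <- sum(wn[oc != cur])
          cands <- unique(oc[oc != cur])
          free_id <- max(assign_vec) + 1L
          cands <- c(cands, free_id)      # move to a fresh singleton
          deltas <- vapply(cands, function(cl) sum(wn[oc != cl]) - base,
                           numeric(1))
          k <- which(deltas < -1e-12)
          if (length(k)) {
            k <- k[order(deltas[k], cands[k])][1L]
            assign_vec[node] <- cands[k]
            improved <- TRUE
          }
        }
        # cluster-merge moves: joining clusters A and B uncuts their mutual
        # edges, changing the objective by -W(A, B)
        cut <- assign_vec[g$u] != assign_vec[g$v]
        if (any(cut)) {
          ca <- pmin(assign_vec[g$u[cut]], assign_vec[g$v[cut]])
          cb <- pmax(assign_vec[g$u[cut]], assign_vec[g$v[cut]])
          key <- paste(ca, cb)
          wsum <- as.numeric(rowsum(g$w[cut], key, reorder = FALSE))
          first <- !duplicated(key)
          pos <- which(wsum > 1e-12)
          if (length(pos)) {
            top <- pos[order(-wsum[pos])][1L]
            a <- ca[first][top]; b <- cb[first][top]
            assign_vec[assign_vec == b] <- a
            improved <- TRUE
          }
        }
      }
      assign_vec
    }
    objective_of <- function(a) sum(g$w[a[g$u] != a[g$v]])
    assign_vec <- NULL
    obj <- Inf
    for (start in list(rep_of, seq_len(n), rep(1L, n))) {
      cand <- refine(start)
      co <- objective_of(cand)
      if (co < obj - 1e-12) { obj <- co; assign_vec <- cand }
    }
  } else {
    assign_vec <- rep_of
    obj <- 0
  }
  out <- finalize_partition(assign_vec, rag)
  attr(out, "objective") <- obj
  out
}

#' Exact multicut by exhaustive enumeration
#'
#' Enumerates every set partition of the nodes (restricted growth strings)
#' and returns one minimizing the multicut objective; ties are broken by
#' fewer clusters, then by the lexicographically smallest assignment. A
#' small-instance oracle: refuses graphs with more than 12 nodes.
#'
#' @inheritParams gasp_average
#' @return optimal partition with attribute \code{objective}.
#' @export
multicut_exact <- function(rag, beta_bias = 0.6, weights = NULL) {
  n <- nrow(rag$nodes)
  if (n > 12L) stop("multicut_exact is limited to graphs with <= 12 nodes")
  g <- rag_graph(rag, beta_bias, weights)
  best_obj <- Inf; best_k <- Inf; best <- rep(1L, n)
  a <- integer(n)
  recurse <- function(i, a, kmax) {
    if (i > n) {
      obj <- if (nrow(g)) sum(g$w[a[g$u] != a[g$v]]) else 0
      k <- kmax
      if (obj < best_obj - 1e-12 ||
          (abs(obj - best_obj) <= 1e-12 && k < best_k)) {
        best_obj <<- obj; best_k <<- k; best <<- a
      }
      return(invisible(NULL))
    }
    for (cl in seq_len(kmax + 1L)) {
      a[i] <- cl
      recurse(i + 1L, a, max(kmax, cl))
    }
  }
  a[1] <- 1L
  recurse(2L, a, 1L)
  out <- finalize_partition(best, rag)
  attr(out, "objective") <- best_obj
  out
}

#' Partition a RAG with a named algorithm
#'
#' Convenience dispatcher used by the pipeline and CLI.
#'
#' @param rag a [build_rag()] graph.
#' @param algorithm one of \code{"gasp"}, \code{"mutex"}, \code{"multicut"},
#'   \code{"multicut_exact"}.
#' @param beta_bias splitting bias in (0, 1).
#' @return integer cluster assignment per node.
#' @export
partition_rag <- function(rag, algorithm = c("gasp", "mutex", "multicut",
                                             "multicut_exact"),
                          beta_bias = 0.6) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         gasp = gasp_average(rag, beta_bias),
         mutex = mutex_watershed(rag, beta_bias),
         multicut = multicut_greedy(rag, beta_bias),
         multicut_exact = multicut_exact(rag, beta_bias))
}
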