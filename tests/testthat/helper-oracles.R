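# Independent oracle implementations used to cross-check the package's
# numerics. These deliberately avoid the package's own code paths.

# Signed modularity straight from its definition, with explicit loops:
# Q = (w+ / (w+ + w-)) * Q+ - (w- / (w+ + w-)) * Q-, where Q+/Q- are
# weighted Newman-Girvan modularities of the positive / |negative| subgraphs.
oracle_signed_modularity <- function(nodes, edges, membership,
                                     gamma_pos = 1, gamma_neg = 1) {
  lab <- membership[nodes]
  sub_q <- function(w_fun, gamma) {
    # symmetric weight lookup over the chosen subgraph
    W <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (r in seq_len(nrow(edges))) {
      w <- w_fun(edges$weight[r])
      W[edges$from[r], edges$to[r]] <- w
      W[edges$to[r], edges$from[r]] <- w
    }
    two_m <- sum(W)
    if (two_m == 0) return(0)
    q <- 0
    for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
      if (lab[i] == lab[j]) {
        q <- q + W[i, j] / two_m -
          gamma * sum(W[i, ]) * sum(W[j, ]) / two_m^2
      }
    }
    q
  }
  wp <- sum(pmax(edges$weight, 0)) * 2
  wn <- sum(pmax(-edges$weight, 0)) * 2
  if (wp + wn == 0) return(0)
  (wp / (wp + wn)) * sub_q(function(w) max(w, 0), gamma_pos) -
    (wn / (wp + wn)) * sub_q(function(w) max(-w, 0), gamma_neg)
}

# All set partitions of n labelled items as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, max_used) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (k in seq_len(max_used + 1L))
      recurse(c(prefix, k), max(max_used, k))
  }
  recurse(integer(0), 0L)
  out
}

# Exhaustive maximum signed modularity over every partition.
exhaustive_best_q <- function(net, gamma_pos = 1, gamma_neg = 1) {
  n <- length(net$nodes)
  best <- -Inf
  for (p in all_partitions(n)) {
    m <- stats::setNames(p, net$nodes)
    q <- signed_modularity(net, m, gamma_pos, gamma_neg)
    if (q > best) best <- q
  }
  best
}

random_signed_network <- function(n, p_edge = 0.5, p_neg = 0.3) {
  nodes <- paste0("n", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  w <- stats::runif(nrow(pairs), 0.2, 1) *
    ifelse(stats::runif(nrow(pairs)) < p_neg, -1, 1)
  signed_network(data.frame(from = nodes[pairs[, 1]],
                            to = nodes[pairs[, 2]], weight = w),
                 nodes = nodes)
}

two_clique_net <- function() {
  # two positive 3-cliques joined by one negative edge
  nodes <- paste0("n", 1:6)
  pos <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  edges <- data.frame(from = nodes[pos[, 1]], to = nodes[pos[, 2]],
                      weight = 1)
  edges <- rbind(edges, data.frame(from = "n3", to = "n4", weight = -1))
  signed_network(edges, nodes)
}

# d-separation oracle via the moralized ancestral graph criterion:
# x and y are d-separated by Z iff they are disconnected (after removing Z)
# in the moralization of the subgraph induced by the ancestors of {x, y} u Z.
oracle_d_separated <- function(edges, nodes, x, y, z) {
  parents <- function(v) edges$from[edges$to == v]
  anc <- unique(c(x, y, z))
  repeat {
    more <- unique(unlist(lapply(anc, parents)))
    new_anc <- union(anc, more)
    if (length(new_anc) == length(anc)) break
    anc <- new_anc
  }
  sub <- edges[edges$from %in% anc & edges$to %in% anc, , drop = FALSE]
  # moralize: undirected skeleton plus edges between co-parents
  und <- unique(rbind(sub[, c("from", "to")],
                      do.call(rbind, lapply(anc, function(v) {
                        pa <- parents(v)
                        pa <- pa[pa %in% anc]
                        if (length(pa) < 2) return(NULL)
                        cmb <- t(utils::combn(pa, 2))
                        data.frame(from = cmb[, 1], to = cmb[, 2])
                      }))))
  keep <- setdiff(anc, z)
  if (!(x %in% keep) || !(y %in% keep)) return(TRUE)
  und <- und[und$from %in% keep & und$to %in% keep, , drop = FALSE]
  # breadth-first reachability from x
  reach <- x
  repeat {
    nb <- unique(c(und$to[und$from %in% reach], und$from[und$to %in% reach]))
    new_reach <- union(reach, intersect(nb, keep))
    if (length(new_reach) == length(reach)) break
    reach <- new_reach
  }
  !(y %in% reach)
}

# All DAGs on n nodes with the fixed topological order v1 < v2 < ... < vn
# (every DAG is isomorphic to one of these).
all_ordered_dags <- function(n) {
  nodes <- paste0("v", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  lapply(seq_len(2^m) - 1L, function(mask) {
    keep <- bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0
    list(nodes = nodes,
         edges = data.frame(from = nodes[pairs[keep, 1]],
                            to = nodes[pairs[keep, 2]],
                            stringsAsFactors = FALSE))
  })
}

# Small, fast synthetic configuration for plumbing tests (not the study
# defaults; those are exercised by the acceptance suite).
small_config <- function(seed = 1, ...) {
  synthetic_config(n_prok_otus = 40, n_fungal_otus = 40,
                   n_prok_clusters = 4, n_fungal_clusters = 4,
                   seed = seed, ...)
}
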