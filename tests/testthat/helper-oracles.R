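# Independent oracles and toy-graph builders used across the suite.
# Everything here is deliberately naive (loops, enumeration) and never calls
# the package code paths it is used to check.

# Build a CellGraph from an explicit symmetric weight matrix.
graph_from_weights <- function(w, metric = "pcc") {
  w <- as.matrix(w)
  diag(w) <- 0
  if (is.null(rownames(w)))
    dimnames(w) <- list(paste0("c", seq_len(nrow(w))),
                        paste0("c", seq_len(nrow(w))))
  structure(list(weights = w, metric = metric, snn_k = NA_integer_),
            class = "CellGraph")
}

# Build a CellGraph from an edge list (i, j, w) over n nodes.
graph_from_edges <- function(n, edges) {
  w <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    w[i, j] <- w[j, i] <- edges[r, 3]
  }
  graph_from_weights(w)
}

# Two equal-weight cliques of size `size` joined by one weak edge.
two_clique_graph <- function(size = 3, w_in = 1, w_bridge = 0.1) {
  n <- 2L * size
  w <- matrix(0, n, n)
  a <- seq_len(size); b <- size + a
  w[a, a] <- w_in; w[b, b] <- w_in
  w[size, size + 1L] <- w[size + 1L, size] <- w_bridge
  graph_from_weights(w)
}

# Exact t-step walk probability from `start` by enumerating every length-t
# node sequence (exponential; fine for toy graphs).
walk_prob_bruteforce <- function(m, start, t) {
  n <- nrow(m)
  prob <- numeric(n)
  recurse <- function(node, steps, p) {
    if (steps == 0L) {
      prob[node] <<- prob[node] + p
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (m[node, nxt] > 0) recurse(nxt, steps - 1L, p * m[node, nxt])
    }
  }
  recurse(start, t, 1)
  unname(prob)
}

# Degree-weighted L2 distance between two probability rows (direct sum).
rw_distance_bruteforce <- function(pi, pj, deg) {
  s <- 0
  for (k in seq_along(pi)) s <- s + (pi[k] - pj[k])^2 / deg[k]
  unname(sqrt(s))
}

# Cell-to-cluster distance, written out directly from its two definitions.
ccd_bruteforce <- function(members, k, probs, deg, mode) {
  if (mode == "literal") {
    unname(mean(probs[members, k]))
  } else {
    pc <- colMeans(probs[members, , drop = FALSE])
    s <- 0
    for (j in seq_len(ncol(probs))) s <- s + (pc[j] - probs[k, j])^2 / deg[j]
    unname(sqrt(s))
  }
}

# Average intra-cluster squared distance of a partition (full recomputation).
sigma_bruteforce <- function(partition, probs, deg, mode) {
  n <- nrow(probs)
  total <- 0
  for (members in partition) {
    for (k in members) total <- total + ccd_bruteforce(members, k, probs, deg, mode)^2
  }
  unname(total / n)
}

# Adjusted Rand index by counting agreeing/disagreeing item pairs.
ari_paircount <- function(truth, pred) {
  n <- length(truth)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- truth[i] == truth[j]; sp <- pred[i] == pred[j]
    if (st && sp) n11 <- n11 + 1
    else if (st && !sp) n10 <- n10 + 1
    else if (!st && sp) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# All partitions of n items into at most `max_blocks` blocks, as restricted
# growth strings (label vectors).
all_partitions <- function(n, max_blocks) {
  out <- list()
  recurse <- function(labels, next_block) {
    pos <- length(labels) + 1L
    if (pos > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (b in seq_len(min(next_block, max_blocks))) {
      recurse(c(labels, b), max(next_block, b + 1L))
    }
  }
  recurse(integer(0), 1L)
  out
}

# Best one-to-one matching accuracy by exhausting permutations (small k only).
acc_bruteforce <- function(truth, pred) {
  tab <- table(truth, pred)
  k <- max(nrow(tab), ncol(tab))
  full <- matrix(0, k, k)
  full[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(k))) {
    best <- max(best, sum(full[cbind(seq_len(k), p)]))
  }
  best / length(truth)
}
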