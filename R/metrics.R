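# External clustering-agreement scores. ARI is implemented directly from the
# contingency-table formula; NMI/AMI follow the standard information-theoretic
# definitions; Acc is the best one-to-one cluster-to-class matching accuracy.

.contingency <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop("label vectors differ in length")
  if (length(labels_true) < 2L) stop("need at least 2 observations")
  table(true = as.character(labels_true), pred = as.character(labels_pred))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions. With contingency counts
#' \eqn{t_{ij}}, row sums \eqn{a_i}, column sums \eqn{b_j} and m observations,
#' \deqn{ARI = \frac{\sum_{ij}\binom{t_{ij}}{2} - E}{\tfrac12\big[\sum_i
#'   \binom{a_i}{2} + \sum_j \binom{b_j}{2}\big] - E}, \quad
#'   E = \sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2} \Big/ \binom{m}{2}.}
#' Ranges from about -1 (systematic disagreement) through 0 (chance) to 1
#' (identical partitions up to label renaming).
#'
#' @param labels_true,labels_pred Vectors of cluster labels, equal length.
#' @return A single numeric value.
#' @export
adjusted_rand_index <- function(labels_true, labels_pred) {
  tab <- .contingency(labels_true, labels_pred)
  m <- sum(tab)
  sum_t <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(m, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)   # both partitions trivial and identical in structure
  (sum_t - expected) / denom
}

.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(unname(p) * log(unname(p)))
}

.mutual_info <- function(tab) {
  m <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    t_ij <- tab[i, j]
    if (t_ij > 0)
      mi <- mi + (t_ij / m) * log(t_ij * m / (a[i] * b[j]))
  }
  unname(mi)
}

# Expected mutual information under the permutation (hypergeometric) model.
.expected_mi <- function(tab) {
  m <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  lf <- lgamma(seq_len(m + 1))   # lf[k+1] = log(k!)
  emi <- 0
  for (ai in a) for (bj in b) {
    lo <- max(1, ai + bj - m)
    hi <- min(ai, bj)
    if (hi < lo) next
    for (nij in lo:hi) {
      lp <- lf[ai + 1] + lf[bj + 1] + lf[m - ai + 1] + lf[m - bj + 1] -
        lf[m + 1] - lf[nij + 1] - lf[ai - nij + 1] - lf[bj - nij + 1] -
        lf[m - ai - bj + nij + 1]
      emi <- emi + (nij / m) * log(nij * m / (ai * bj)) * exp(lp)
    }
  }
  unname(emi)
}

# Hungarian algorithm (potentials / shortest augmenting path, O(n^3)) for the
# square assignment problem: minimises sum cost[i, perm(i)].
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p_match <- integer(n + 1)   # p_match[j] = row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p_match[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p_match[j0]; delta <- Inf; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p_match[j]] <- u[p_match[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p_match[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p_match[j0] <- p_match[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  for (j in 2:(n + 1)) if (p_match[j] > 0L) perm[p_match[j]] <- j - 1L
  perm
}

#' Clustering agreement scores against ground truth
#'
#' Computes four external evaluation scores from the true-vs-predicted
#' contingency table:
#' * `ari` — adjusted Rand index ([adjusted_rand_index()]);
#' * `nmi` — normalised mutual information, `MI / mean(H_true, H_pred)`
#'   (arithmetic normalisation);
#' * `ami` — adjusted mutual information,
#'   `(MI - E[MI]) / (mean(H_true, H_pred) - E[MI])`, with the expectation
#'   under the permutation model;
#' * `acc` — accuracy under the best one-to-one matching of predicted
#'   clusters to true classes (optimal assignment on the contingency table).
#'
#' @param labels_true,labels_pred Vectors of cluster labels, equal length.
#' @return A list with elements `ari`, `nmi`, `ami`, `acc` and attribute
#'   `nmi_normalization = "arithmetic"`.
#' @export
clustering_scores <- function(labels_true, labels_pred) {
  tab <- .contingency(labels_true, labels_pred)
  m <- sum(tab)
  h_true <- .entropy(rowSums(tab))
  h_pred <- .entropy(colSums(tab))
  mi <- .mutual_info(tab)
  nmi <- if (h_true == 0 && h_pred == 0) 1
         else if (mi == 0) 0
         else mi / ((h_true + h_pred) / 2)
  ami <- if (h_true == 0 && h_pred == 0) 1 else {
    emi <- .expected_mi(tab)
    den <- (h_true + h_pred) / 2 - emi
    if (abs(den) < .Machine$double.eps^0.5) 0 else (mi - emi) / den
  }
  k <- max(nrow(tab), ncol(tab))
  cost <- matrix(0, k, k)   # pad rectangular tables with zero-count rows/cols
  cost[seq_len(nrow(tab)), seq_len(ncol(tab))] <- -tab
  perm <- .hungarian(cost)
  matched <- sum(vapply(seq_len(nrow(tab)), function(i) {
    j <- perm[i]
    if (j <= ncol(tab)) tab[i, j] else 0
  }, numeric(1)))
  structure(list(ari = adjusted_rand_index(labels_true, labels_pred),
                 nmi = nmi, ami = ami, acc = matched / m),
            nmi_normalization = "arithmetic")
}
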