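# Independent reference implementations used to cross-check package results.
# These deliberately use different algorithms/code paths than the package:
# dense Floyd-Warshall for efficiency, powerset filtering with a hand-rolled
# BFS for enumeration, and naive per-node summation for PageRank.

# Global efficiency via dense Floyd-Warshall on the full weight matrix.
fw_ge <- function(W, deleted = character(), mode = "inverse-weight",
                  renormalize = FALSE) {
  ids <- rownames(W)
  n <- nrow(W)
  len <- matrix(Inf, n, n)
  pos <- W > 0
  len[pos] <- if (mode == "inverse-weight") 1 / W[pos] else 1
  if (length(deleted)) {
    di <- match(deleted, ids)
    len[di, ] <- Inf
    len[, di] <- Inf
  }
  diag(len) <- 0
  D <- len
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  inv <- 1 / D
  diag(inv) <- 0
  N <- if (renormalize) n - length(deleted) else n
  if (N < 2) return(0)
  sum(inv) / (N * (N - 1))
}

# Is the induced subgraph on `s` connected? Hand-rolled BFS on the pair list.
is_conn_subset <- function(s, adj) {
  if (length(s) <= 1L) return(TRUE)
  keep <- adj[, 1L] %in% s & adj[, 2L] %in% s
  e <- adj[keep, , drop = FALSE]
  seen <- s[1L]
  frontier <- s[1L]
  while (length(frontier)) {
    nb <- unique(c(e[e[, 1L] %in% frontier, 2L],
                   e[e[, 2L] %in% frontier, 1L]))
    frontier <- setdiff(nb, seen)
    seen <- c(seen, frontier)
  }
  length(seen) == length(s)
}

# Brute-force enumeration: filter every subset of size <= K for
# connectedness. Returns the canonical sorted key set.
enum_oracle <- function(atlas, lobe, K) {
  mem <- lobe_parcels(atlas, lobe)
  adj <- atlas$adjacency
  keys <- character()
  for (k in seq_len(min(K, length(mem)))) {
    for (s in utils::combn(mem, k, simplify = FALSE)) {
      if (is_conn_subset(s, adj)) {
        keys <- c(keys, paste(sort(s), collapse = ","))
      }
    }
  }
  sort(keys, method = "radix")
}

# Naive fixed-point iteration of the PageRank recursion with explicit
# per-node sums (teleport term weighted by d, links by 1 - d).
pr_oracle <- function(W, d = 0.15, tol = 1e-14, iters = 10000L) {
  n <- nrow(W)
  A <- (W > 0) * 1
  outdeg <- rowSums(A)
  p <- rep(1 / n, n)
  for (t in seq_len(iters)) {
    pn <- numeric(n)
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(n)) {
        if (outdeg[j] == 0) {
          s <- s + p[j] / n
        } else if (A[j, i] > 0) {
          s <- s + p[j] / outdeg[j]
        }
      }
      pn[i] <- d / n + (1 - d) * s
    }
    if (sum(abs(pn - p)) < tol) break
    p <- pn
  }
  stats::setNames(p, rownames(W))
}
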