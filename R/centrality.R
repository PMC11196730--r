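#' PageRank centrality of connectome parcels
#'
#' Computes the fixed point of the recursion
#' \deqn{PR(P_i) = \frac{d}{n} + (1-d) \sum_{(j,i) \in E}
#'       \frac{PR(P_j)}{Outdegree(P_j)},}
#' in which the teleport term is weighted by `d` and the link term by
#' `1 - d` — the transpose of the more common damping placement, so the
#' default `d = 0.15` reproduces standard 0.85-damped PageRank. The
#' symmetric connectome is expanded into a directed graph with both arc
#' directions per positive-weight edge; out-degree is the unweighted arc
#' count (a streamline-weighted transition variant is available via
#' `weighted = TRUE` for sensitivity analysis). Dangling nodes (isolates)
#' are treated as linking uniformly to all nodes, which keeps the scores
#' summing to 1.
#'
#' @param c a `connectome`.
#' @param d teleport parameter in `[0, 1]` (default 0.15).
#' @param tol L1 convergence tolerance (default `1e-12`).
#' @param max_iter iteration cap (default 1000).
#' @param weighted use streamline-weighted transition probabilities instead
#'   of uniform out-degree splitting (default `FALSE`).
#' @return Named numeric vector of PageRank scores summing to 1.
#' @export
pagerank_scores <- function(c, d = 0.15, tol = 1e-12, max_iter = 1000L,
                            weighted = FALSE) {
  stopifnot(inherits(c, "connectome"), d >= 0, d <= 1)
  w <- c$weights
  n <- nrow(w)
  a <- if (weighted) w else (w > 0) * 1
  out_deg <- rowSums(a)
  dangling <- out_deg == 0
  # row-stochastic transition matrix; dangling rows link uniformly everywhere
  trans <- a / ifelse(out_deg > 0, out_deg, 1)
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    p_new <- d / n + (1 - d) *
      (drop(crossprod(trans, p)) + sum(p[dangling]) / n)
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      names(p) <- c$parcels
      return(p)
    }
  }
  stop("PageRank did not converge in ", max_iter,
       " iterations (L1 residual ", format(delta, digits = 3), ")")
}

#' Rank parcels by PageRank within each hemisphere
#'
#' Ranks every parcel's score within its hemisphere (rank 1 = highest score;
#' exact ties broken by lexicographic ID) and additionally over the whole
#' graph, so that on the full-scale 379-node atlas the overall ranks span
#' 1..379.
#'
#' @param scores named score vector from [pagerank_scores()].
#' @param atlas the matching `atlas_topology`.
#' @return Data frame with columns `parcel`, `hemisphere`, `score`,
#'   `rank_hemisphere`, `rank_overall`.
#' @export
rank_per_hemisphere <- function(scores, atlas) {
  stopifnot(inherits(atlas, "atlas_topology"))
  missing <- setdiff(atlas$parcels, names(scores))
  if (length(missing)) {
    stop("scores missing for parcel(s): ", paste(missing, collapse = ", "))
  }
  out <- data.frame(parcel = atlas$parcels,
                    hemisphere = unname(atlas$hemisphere[atlas$parcels]),
                    score = unname(scores[atlas$parcels]),
                    stringsAsFactors = FALSE)
  rank_of <- function(df) {
    o <- order(-df$score, df$parcel, method = "radix")
    r <- integer(nrow(df))
    r[o] <- seq_len(nrow(df))
    r
  }
  out$rank_hemisphere <- stats::ave(seq_len(nrow(out)), out$hemisphere,
                                    FUN = function(idx) rank_of(out[idx, ]))
  out$rank_overall <- rank_of(out)
  o <- order(out$parcel, method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' How well does PageRank predict the worst deletions?
#'
#' For each subject, the predicted parcel is the one with the highest
#' PageRank within the lobe (ties lexicographic). Three nested success
#' criteria are scored against that subject's single-deletion efficiency
#' ordering: (1) the prediction equals the worst single deletion; (2) it
#' equals the worst single deletion or is physically adjacent to it; (3) it
#' is among the subject's 3 worst single deletions (ties at the third slot
#' resolved lexicographically). Criterion 1 success implies criterion 2
#' success, so `rate_worst <= rate_worst_or_neighbor` always.
#'
#' @param sweeps list of `resection_sweep` objects for one lobe, one per
#'   subject.
#' @param scores_list list of [pagerank_scores()] vectors, same subject
#'   order.
#' @param atlas the matching `atlas_topology`.
#' @param lobe lobe label.
#' @return A `prediction_rates` list with `lobe`, `hemisphere`, `n`, per-
#'   criterion counts, the three rates, and `"n/d; p%"` labels.
#' @export
pr_prediction_rates <- function(sweeps, scores_list, atlas, lobe) {
  stopifnot(length(sweeps) == length(scores_list), length(sweeps) >= 1L,
            inherits(atlas, "atlas_topology"))
  members <- lobe_parcels(atlas, lobe)
  n <- length(sweeps)
  succ <- matrix(FALSE, n, 3L)
  for (i in seq_len(n)) {
    sw <- sweeps[[i]]
    if (!inherits(sw, "resection_sweep") || !identical(sw$lobe, lobe)) {
      stop("missing or mismatched sweep for subject ", i)
    }
    singles <- sw$records[sw$records$size == 1L, , drop = FALSE]
    o <- order(singles$ge, singles$parcels, method = "radix")
    worst <- singles$parcels[o[1L]]
    top3 <- singles$parcels[o][seq_len(min(3L, nrow(singles)))]
    sc <- scores_list[[i]][members]
    pred <- members[order(-sc, members, method = "radix")[1L]]
    succ[i, 1L] <- pred == worst
    succ[i, 2L] <- pred == worst || pred %in% adjacent_parcels(atlas, worst)
    succ[i, 3L] <- pred %in% top3
    stopifnot(!succ[i, 1L] || succ[i, 2L])
  }
  counts <- colSums(succ)
  structure(list(
    lobe = lobe, hemisphere = lobe_hemisphere(atlas, lobe), n = n,
    count_worst = counts[1L], count_worst_or_neighbor = counts[2L],
    count_top3 = counts[3L],
    rate_worst = counts[1L] / n,
    rate_worst_or_neighbor = counts[2L] / n,
    rate_top3 = counts[3L] / n,
    label_worst = format_percent(counts[1L], n),
    label_worst_or_neighbor = format_percent(counts[2L], n),
    label_top3 = format_percent(counts[3L], n)
  ), class = "prediction_rates")
}
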