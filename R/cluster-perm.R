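# Cluster-based permutation inference over sensor graphs (or a 1-D time
# axis, which is just a chain graph). Candidate clusters are connected
# components of nodes with uncorrected p below threshold (split by statistic
# sign for signed statistics); each is scored by the summed absolute
# statistic, and compared against a max-statistic permutation null.

#' Find candidate clusters in a statistic map
#'
#' Connected components of nodes whose uncorrected p falls below `alpha`,
#' split so that all members share the statistic's sign when `signed = TRUE`.
#' Each cluster is scored by the sum of absolute member statistics.
#'
#' @param stat numeric statistic per node.
#' @param p uncorrected p-value per node (same length).
#' @param adjacency symmetric logical/0-1 adjacency matrix over nodes.
#' @param alpha cluster-forming threshold (default 0.05).
#' @param signed split components by sign of `stat`.
#' @return list of clusters, each a list with `members` (node indices),
#'   `stat` (summed |stat|) and `sign`; empty list when nothing passes.
#' @export
find_clusters <- function(stat, p, adjacency, alpha = 0.05, signed = TRUE) {
  n <- length(stat)
  if (length(p) != n || nrow(adjacency) != n || ncol(adjacency) != n) {
    stop("`stat`, `p` and `adjacency` must agree in size")
  }
  cand <- which(p < alpha & is.finite(stat))
  if (length(cand) == 0L) return(list())
  sub <- adjacency[cand, cand, drop = FALSE]
  if (signed) {
    s <- sign(stat[cand])
    sub <- sub & outer(s, s, `==`)
  }
  g <- igraph::graph_from_adjacency_matrix(sub * 1, mode = "undirected")
  comp <- igraph::components(g)$membership
  lapply(seq_len(max(comp)), function(ci) {
    members <- cand[comp == ci]
    list(members = members, stat = sum(abs(stat[members])),
         sign = if (signed) sign(stat[members][1]) else NA_real_)
  })
}

#' Max-statistic permutation p-values for observed clusters
#'
#' Ranks each observed cluster statistic against a null of per-permutation
#' extreme cluster statistics and attaches the cluster effect size
#' `d_cluster` = (observed - null mean) / null SD. p is the plain proportion
#' of null values at least as extreme as the observed one (optionally with
#' +1 smoothing); ties count against significance.
#'
#' @param clusters output of [find_clusters()].
#' @param null_max numeric vector: per-permutation maximum (or minimum, for
#'   `tail = "lower"`) cluster statistic; permutations with no cluster should
#'   contribute 0 (upper tail) or Inf (lower tail).
#' @param tail `"upper"` (large statistic extreme; k', norm, |sum t|) or
#'   `"lower"` (small statistic extreme; summed angle).
#' @param smooth use (b + 1)/(n + 1) instead of b/n.
#' @return `clusters` with `p` and `d_cluster` added, ordered by p.
#' @export
permutation_pvalues <- function(clusters, null_max, tail = c("upper", "lower"),
                                smooth = FALSE) {
  tail <- match.arg(tail)
  n_perm <- length(null_max)
  if (n_perm < 100) warning("fewer than 100 permutations; p-values are coarse")
  if (length(clusters) == 0L) return(list())
  mu <- mean(null_max[is.finite(null_max)])
  sdv <- stats::sd(null_max[is.finite(null_max)])
  out <- lapply(clusters, function(cl) {
    b <- if (tail == "upper") sum(null_max >= cl$stat) else
      sum(null_max <= cl$stat)
    cl$p <- if (smooth) (b + 1) / (n_perm + 1) else b / n_perm
    cl$d_cluster <- if (sdv > 0) (cl$stat - mu) / sdv else NA_real_
    cl
  })
  out[order(vapply(out, `[[`, numeric(1), "p"))]
}

#' Extreme cluster statistic of one (permuted) map
#'
#' Convenience for building max-statistic nulls: the largest (or smallest)
#' cluster score in a map, or 0 / Inf when no cluster forms.
#'
#' @inheritParams find_clusters
#' @param tail see [permutation_pvalues()].
#' @return a single number.
#' @export
max_cluster_stat <- function(stat, p, adjacency, alpha = 0.05, signed = TRUE,
                             tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  cl <- find_clusters(stat, p, adjacency, alpha, signed)
  if (length(cl) == 0L) return(if (tail == "upper") 0 else Inf)
  stats <- vapply(cl, `[[`, numeric(1), "stat")
  if (tail == "upper") max(stats) else min(stats)
}

#' Chain adjacency for temporal cluster tests
#'
#' @param n number of time points.
#' @return n x n logical adjacency linking consecutive samples.
#' @export
chain_adjacency <- function(n) {
  adj <- matrix(FALSE, n, n)
  if (n > 1) {
    idx <- seq_len(n - 1)
    adj[cbind(idx, idx + 1)] <- TRUE
    adj[cbind(idx + 1, idx)] <- TRUE
  }
  adj
}
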