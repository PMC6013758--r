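# Independent oracles, deliberately implemented differently from the package.

# Floyd-Warshall all-pairs shortest paths over unit-weight edges + weighted
# extra links; disconnected pairs get 1.5 x the finite diameter.
fw_distances <- function(net, extra_links = NULL) {
  ids <- net$nodes
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  if (nrow(net$edges)) {
    for (i in seq_len(nrow(net$edges))) {
      a <- net$edges[i, 1]; b <- net$edges[i, 2]
      d[a, b] <- d[b, a] <- min(d[a, b], 1)
    }
  }
  if (!is.null(extra_links) && NROW(extra_links)) {
    for (i in seq_len(NROW(extra_links))) {
      a <- as.character(extra_links$a[i]); b <- as.character(extra_links$b[i])
      w <- extra_links$weight[i]
      d[a, b] <- d[b, a] <- min(d[a, b], w)
    }
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  fin <- d[is.finite(d) & d > 0]
  sur <- if (length(fin)) 1.5 * max(fin) else 1
  d[!is.finite(d)] <- sur
  d
}

# Minimum spanning tree weight by exhaustive enumeration of all edge subsets
# of size m-1 on the complete graph over `members` (feasible for m <= 6).
brute_mst_weight <- function(members, dmat) {
  m <- length(members)
  if (m <= 1) return(0)
  pairs <- utils::combn(members, 2)
  ne <- ncol(pairs)
  wts <- dmat[cbind(pairs[1, ], pairs[2, ])]
  best <- Inf
  for (subset in utils::combn(ne, m - 1, simplify = FALSE)) {
    # spanning + acyclic <=> m-1 edges connecting all m vertices
    reached <- members[1]
    repeat {
      grow <- FALSE
      for (k in subset) {
        a <- pairs[1, k]; b <- pairs[2, k]
        if (a %in% reached && !(b %in% reached)) { reached <- c(reached, b); grow <- TRUE }
        if (b %in% reached && !(a %in% reached)) { reached <- c(reached, a); grow <- TRUE }
      }
      if (!grow) break
    }
    if (length(reached) == m) best <- min(best, sum(wts[subset]))
  }
  best
}

# Direct double-loop stress evaluation.
naive_stress <- function(pos, d, w) {
  s <- 0
  n <- nrow(pos)
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    real <- sqrt(sum((pos[u, ] - pos[v, ])^2))
    s <- s + w[u, v] * (real - d[u, v])^2
  }
  s
}

# Exhaustive axis-interval rectangle intersection count (padding-inflated).
oracle_overlap_pairs <- function(lay, padding = 2) {
  pos <- lay$positions; he <- lay$half_extents
  n <- nrow(pos)
  hits <- 0L
  if (n < 2) return(0L)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sep_x <- max(pos[i, 1] - he[i, 1], pos[j, 1] - he[j, 1]) -
             min(pos[i, 1] + he[i, 1], pos[j, 1] + he[j, 1])
    sep_y <- max(pos[i, 2] - he[i, 2], pos[j, 2] - he[j, 2]) -
             min(pos[i, 2] + he[i, 2], pos[j, 2] + he[j, 2])
    if (sep_x < padding && sep_y < padding) hits <- hits + 1L
  }
  hits
}

# Point-in-polygon via mgcv::in.out (independent of the package's ray caster).
oracle_inside <- function(pt, rings) {
  bnd <- do.call(rbind, lapply(rings, function(r) rbind(r, c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  as.logical(mgcv::in.out(bnd, matrix(pt, 1, 2)))
}
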