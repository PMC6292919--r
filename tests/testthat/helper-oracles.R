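# Independent oracle implementations used to cross-check the package.
# These deliberately use different algorithms/code paths than the package
# internals.

# Levenshtein distance by explicit dynamic programming over the full
# (n+1) x (m+1) table.
oracle_levenshtein <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca)
  m <- length(cb)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (ca[i] == cb[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
    }
  }
  d[n + 1, m + 1]
}

# Overlap coefficient by per-element scan (no set ops).
oracle_overlap <- function(x, y) {
  x <- unique(x)
  y <- unique(y)
  inter <- 0L
  for (g in x) if (any(y == g)) inter <- inter + 1L
  inter / min(length(x), length(y))
}

# Hypergeometric upper tail P(X >= x) via explicit binomial-coefficient
# sums (no phyper / dhyper).
oracle_hyper_tail <- function(x, N, K, n) {
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  if (x > hi) return(0)
  i <- max(x, lo):hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Yekutieli step-up from the definition:
# q_(i) = min_{j >= i} min(1, p_(j) * m * c(m) / j), c(m) = sum 1/k.
oracle_by <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric())
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  ps <- p[ord]
  raw <- pmin(1, ps * m * cm / seq_len(m))
  q_sorted <- rev(cummin(rev(raw)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Benjamini-Hochberg step-up (for the BY >= BH comparison).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  raw <- pmin(1, p[ord] * m / seq_len(m))
  q <- numeric(m)
  q[ord] <- rev(cummin(rev(raw)))
  q
}

# Naive UPGMA directly from the definition: the distance between two
# clusters is the mean of ALL pairwise original distances between their
# members (no Lance-Williams recursion). Ties break by the
# lexicographically smallest pair of sorted member-label strings. Returns
# the merge heights and the member sets merged at each step.
oracle_upgma <- function(d, labels) {
  clusters <- as.list(labels)
  heights <- numeric(0)
  merged_sets <- list()
  rownames(d) <- colnames(d) <- labels
  while (length(clusters) > 1L) {
    best <- NULL
    best_d <- Inf
    best_key <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        dv <- mean(d[clusters[[a]], clusters[[b]]])
        key <- paste(sort(c(paste(sort(clusters[[a]]), collapse = "|"),
                            paste(sort(clusters[[b]]), collapse = "|"))),
                     collapse = "||")
        if (dv < best_d - 1e-12 ||
            (abs(dv - best_d) <= 1e-12 && !is.null(best_key) && key < best_key)) {
          best_d <- dv
          best <- c(a, b)
          best_key <- key
        }
      }
    }
    heights <- c(heights, best_d)
    new_cluster <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merged_sets[[length(merged_sets) + 1L]] <- new_cluster
    clusters <- c(clusters[-best], list(new_cluster))
  }
  list(height = heights, merged = merged_sets)
}

# member sets merged at each step of an hclust tree
hclust_merge_sets <- function(h) {
  sets <- vector("list", nrow(h$merge))
  expand <- function(i) {
    if (i < 0) h$labels[-i] else sets[[i]]
  }
  for (s in seq_len(nrow(h$merge))) {
    sets[[s]] <- sort(c(expand(h$merge[s, 1]), expand(h$merge[s, 2])))
  }
  sets
}

# Connected components by union-find over an explicit edge list.
oracle_components <- function(nodes, edges_from, edges_to) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(edges_from)) {
    ra <- find(edges_from[i])
    rb <- find(edges_to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  unname(split(nodes, roots))
}
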