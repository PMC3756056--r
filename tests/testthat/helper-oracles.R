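# Independent oracles, written apart from the package implementation.

# Brute-force O(n^3) complete-linkage agglomerator.  Tracks the partition
# after every merge so any k-cut can be read off directly.
naive_complete_linkage <- function(D) {
  n <- nrow(D)
  members <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1L)
  partitions <- vector("list", n)      # partitions[[k]] = partition into k
  partitions[[n]] <- lapply(seq_len(n), identity)
  for (step in seq_len(n - 1L)) {
    best <- Inf; bi <- bj <- NA_integer_
    for (i in seq_along(members)) {
      for (j in seq_along(members)) {
        if (j <= i) next
        dd <- max(D[members[[i]], members[[j]]])
        if (dd < best) { best <- dd; bi <- i; bj <- j }
      }
    }
    heights[step] <- best
    members[[bi]] <- c(members[[bi]], members[[bj]])
    members[[bj]] <- NULL
    partitions[[n - step]] <- members
  }
  list(heights = heights, partitions = partitions)
}

# Partition equality irrespective of cluster labels: compare
# co-membership indicator matrices.
co_membership <- function(assignment) {
  outer(assignment, assignment, "==")
}

partition_from_list <- function(members, n) {
  a <- integer(n)
  for (i in seq_along(members)) a[members[[i]]] <- i
  a
}

# Hand-applied BH step-up: q_(i) = min_{j >= i} m p_(j) / j, clipped.
bh_by_hand <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(1, min(m * p[ord][js] / js))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Direct chi-square statistic Sum (O - E)^2 / E.
chisq_stat_by_hand <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# F statistic of y ~ [1, X] vs intercept-only, via normal equations.
f_stat_by_hand <- function(X, y) {
  Z <- cbind(1, X)
  beta <- solve(t(Z) %*% Z, t(Z) %*% y)
  rss1 <- sum((y - Z %*% beta)^2)
  rss0 <- sum((y - mean(y))^2)
  df1 <- ncol(Z) - 1L
  df2 <- length(y) - ncol(Z)
  ((rss0 - rss1) / df1) / (rss1 / df2)
}

# Small helper: a normalized two-block merged matrix built from the
# generators, used across test files.
make_test_merged <- function(seed = 1, n_genes = 20, n_per = 6,
                             noise_sd = 0.5, shift = c(0, 1)) {
  cents <- make_subtype_centroids(n_genes, separation = 2, seed = seed)
  ref <- generate_reference_cohort(cents, n_per, noise_sd, "ref",
                                   seed = seed + 1)
  g <- generate_backcross_genotypes(10, 5, seed = seed + 2)
  qry <- generate_query_cohort(g, list(), cents, rep(0.2, 5),
                               platform_shift = shift,
                               noise_sd = noise_sd, seed = seed + 3)
  merged <- merge_matrices(list(ref$expression, qry$expression))
  list(merged = normalize_unitization(merged),
       ref = ref, query = qry, genotypes = g)
}

# A hand-built 12-leaf tree (valid hclust object): five A-labeled
# reference leaves r1..r5, five B-labeled s1..s5, a query q that joins
# the A block, and an outlier z.
handmade_tree <- function() {
  merge <- rbind(
    c(-1, -2), c(1, -3), c(2, -4), c(3, -5),      # A block
    c(-6, -7), c(5, -8), c(6, -9), c(7, -10),     # B block
    c(4, -11),                                    # q joins A block
    c(9, 8),                                      # (A+q) joins B
    c(10, -12))                                   # z last
  structure(list(
    merge = merge,
    height = c(0.10, 0.11, 0.12, 0.13, 0.14, 0.15, 0.16, 0.17, 2, 3, 4),
    order = 1:12,
    labels = c(paste0("r", 1:5), paste0("s", 1:5), "q", "z"),
    method = "complete"), class = "hclust")
}
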