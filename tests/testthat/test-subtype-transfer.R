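test_that("correlation distances match a direct computation", {
  fix <- make_test_merged(seed = 3, n_genes = 42)
  d <- pairwise_distances(fix$merged)
  v <- fix$merged$values
  n <- ncol(v)
  for (i in c(1, 5, n)) {
    for (j in c(2, n - 1)) {
      r <- sum(scale(v[, i]) * scale(v[, j])) / (nrow(v) - 1)
      expect_equal(d$d[i, j], max(0, 1 - r), tolerance = 1e-12)
    }
  }
  expect_true(all(abs(d$d - t(d$d)) < 1e-12))
  expect_true(all(diag(d$d) == 0))

  # identical profiles at distance 0; anti-proportional at distance 2
  m <- fix$merged
  m$values <- cbind(a = c(-1, 0, 1), b = c(-1, 0, 1), c = c(1, 0, -1))
  rownames(m$values) <- paste0("g", 1:3)
  m$block_of_sample <- setNames(rep("d", 3), colnames(m$values))
  d2 <- pairwise_distances(m)
  expect_equal(d2$d["a", "b"], 0)
  expect_equal(d2$d["a", "c"], 2)

  m$values[, "b"] <- 0
  expect_error(pairwise_distances(m), "zero-variance.*b")
})

test_that("complete linkage reproduces the hand-worked 3-sample tree", {
  D <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  D["a", "b"] <- D["b", "a"] <- 1
  D["a", "c"] <- D["c", "a"] <- 5
  D["b", "c"] <- D["c", "b"] <- 4
  dm <- structure(list(sample_ids = letters[1:3], d = D,
                       metric = "euclidean"), class = "distance_matrix")
  tree <- complete_linkage_tree(dm)
  expect_equal(tree$height, c(1, 5))
  expect_equal(unname(cut_tree_at_k(tree, 2)[c("a", "b", "c")]),
               c(1, 1, 2))
  expect_equal(length(unique(cut_tree_at_k(tree, 1))), 1L)
  expect_equal(length(unique(cut_tree_at_k(tree, 3))), 3L)
  expect_error(cut_tree_at_k(tree, 4), "k")

  # n = 2 degenerate tree
  D2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"),
                                                    c("x", "y")))
  dm2 <- structure(list(sample_ids = c("x", "y"), d = D2,
                        metric = "euclidean"), class = "distance_matrix")
  expect_equal(complete_linkage_tree(dm2)$height, 3)
})

test_that("trees and all cuts match the brute-force agglomerator", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(3:8, 1)
    X <- matrix(rnorm(n * 6), 6, n,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:n)))
    D <- as.matrix(dist(t(X)))
    dm <- structure(list(sample_ids = colnames(X), d = D,
                         metric = "euclidean"),
                    class = "distance_matrix")
    tree <- complete_linkage_tree(dm)
    oracle <- naive_complete_linkage(D)
    expect_equal(tree$height, oracle$heights, tolerance = 1e-12)
    expect_true(all(diff(tree$height) >= 0))
    for (k in 1:n) {
      mine <- cut_tree_at_k(tree, k)
      ref <- partition_from_list(oracle$partitions[[k]], n)
      expect_identical(co_membership(unname(mine)), co_membership(ref))
    }
  }
})

test_that("sub-cluster proportions honor the strict >4 qualification", {
  assignment <- setNames(c(1, 1, 1, 1, 1, 2, 2, 2, 2, 3),
                         paste0("s", 1:10))
  labels <- setNames(c("A", "A", "A", "B", "B", "A", "A", "B", "B"),
                     paste0("s", 1:9))  # s10 is unlabeled
  sp <- subcluster_label_proportions(assignment, labels, min_ref = 4)
  expect_true(sp$qualified[1])                 # 5 refs > 4
  expect_equal(unname(sp$proportions[1, ]), c(0.6, 0.4))
  expect_false(sp$qualified[2])                # exactly 4: disqualified
  expect_true(all(is.na(sp$proportions[2, ])))
  expect_false(sp$qualified[3])                # 0 refs
})

test_that("probability transfer averages qualifying cuts", {
  tree <- handmade_tree()
  labels <- setNames(rep(c("A", "B"), each = 5),
                     c(paste0("r", 1:5), paste0("s", 1:5)))
  probs <- transfer_subtype_probabilities(tree, labels, c("q", "z"),
                                          k_min = 2, k_max = 3)
  # k=2: q sits with all 10 refs -> (0.5, 0.5); k=3: with the 5 A refs
  expect_equal(unname(probs$probs["q", ]), c(0.75, 0.25))
  expect_equal(unname(probs$n_contributing_cuts["q"]), 2L)
  # z is a singleton at every cut: unassigned
  expect_true(probs$unassigned["z"])
  expect_equal(unname(probs$n_contributing_cuts["z"]), 0L)
  expect_true(all(is.na(probs$probs["z", ])))

  # unanimity: restrict cuts to k=3 only
  p3 <- transfer_subtype_probabilities(tree, labels, "q", k_min = 3,
                                       k_max = 3)
  expect_equal(unname(p3$probs["q", ]), c(1, 0))
  expect_error(transfer_subtype_probabilities(tree, character(), "q"),
               "reference")
})

test_that("transfer matches an independent re-walk of the tree", {
  fix <- make_test_merged(seed = 17, n_per = 8, noise_sd = 1)
  merged <- fix$merged
  d <- pairwise_distances(merged)
  tree <- complete_linkage_tree(d)
  ref_labels <- fix$ref$true_labels
  query_ids <- names(fix$query$true_labels)
  k_min <- 2; k_max <- 15; min_ref <- 4
  probs <- transfer_subtype_probabilities(tree, ref_labels, query_ids,
                                          k_min, k_max, min_ref)
  # scripted re-walk, written independently of the implementation
  labs <- sort(unique(ref_labels))
  for (q in query_ids) {
    acc <- NULL
    for (k in k_min:k_max) {
      ct <- cutree(tree, k)
      mates <- names(ct)[ct == ct[[q]]]
      refs <- intersect(mates, names(ref_labels))
      if (length(refs) >= min_ref + 1) {
        acc <- rbind(acc, prop.table(table(factor(ref_labels[refs],
                                                  labs))))
      }
    }
    if (is.null(acc)) {
      expect_true(probs$unassigned[q])
    } else {
      expect_equal(unname(probs$probs[q, ]), unname(colMeans(acc)),
                   tolerance = 1e-12)
      expect_equal(unname(probs$n_contributing_cuts[q]), nrow(acc))
    }
  }
  # assigned vectors are proper distributions
  ok <- !probs$unassigned
  expect_true(all(abs(rowSums(probs$probs[ok, , drop = FALSE]) - 1)
                  < 1e-9))
  expect_true(all(probs$probs[ok, ] >= 0))
})

test_that("calls take the argmax with deterministic tie handling", {
  probs <- structure(list(
    probs = matrix(c(0.75, 0.25, 0.5, 0.5, NA, NA), 3, 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"), c("A", "B"))),
    n_contributing_cuts = setNames(c(2L, 1L, 0L), c("s1", "s2", "s3")),
    unassigned = setNames(c(FALSE, FALSE, TRUE), c("s1", "s2", "s3")),
    subtype_labels = c("A", "B")), class = "subtype_probs")
  calls <- call_subtypes(probs)
  expect_equal(calls$call, c("A", "A", NA))
  expect_equal(calls$tie_broken, c(FALSE, TRUE, FALSE))
  calls2 <- call_subtypes(probs, tie_rule = "unassign")
  expect_equal(calls2$call, c("A", NA, NA))
})

test_that("nearest-centroid comparator recovers clean cohorts", {
  cents <- make_subtype_centroids(42, separation = 2, seed = 51)
  ref <- generate_reference_cohort(cents, 6, noise_sd = 0.5, seed = 52)
  # a query equal to a centroid is called with correlation 1
  q <- cents$centroids[, "Her2", drop = FALSE]
  colnames(q) <- "probe"
  out <- nearest_centroid_classify(ref$expression$values,
                                   ref$true_labels, q)
  expect_equal(out$call, "Her2")
  expect_gt(out$correlation, 0.97)

  # noiseless cohort: 100% agreement with latent truth
  g <- generate_backcross_genotypes(30, 4, seed = 53)
  q0 <- generate_query_cohort(g, list(), cents, rep(0.2, 5),
                              noise_sd = 0, seed = 54)
  calls <- nearest_centroid_classify(ref$expression$values,
                                     ref$true_labels,
                                     q0$expression$values)
  expect_equal(setNames(calls$call, calls$sample_id), q0$true_labels)

  flat <- q0$expression$values
  flat[, 1] <- 1
  expect_warning(
    out2 <- nearest_centroid_classify(ref$expression$values,
                                      ref$true_labels, flat),
    "zero-variance")
  expect_true(is.na(out2$call[1]))
})

test_that("agreement uses the jointly-assigned denominator", {
  mk <- function(calls) data.frame(sample_id = paste0("s", 1:4),
                                   call = calls,
                                   stringsAsFactors = FALSE)
  same <- classification_agreement(mk(c("A", "A", "B", "B")),
                                   mk(c("A", "A", "B", "B")))
  expect_equal(same$concordance, 1)
  opp <- classification_agreement(mk(c("A", "A", "B", "B")),
                                  mk(c("B", "B", "A", "A")))
  expect_equal(opp$concordance, 0)
  mix <- classification_agreement(mk(c("A", "A", "B", NA)),
                                  mk(c("A", "B", "B", "A")))
  expect_equal(mix$concordance, 2 / 3)
  expect_equal(mix$n_joint, 3L)
  expect_error(classification_agreement(
    mk(c("A", "A", "B", "B")),
    data.frame(sample_id = "zz", call = "A")), "no samples")
})

test_that("pipeline calls are invariant to sample order", {
  fix <- make_test_merged(seed = 23, n_per = 8, noise_sd = 1)
  run <- function(merged) {
    tree <- complete_linkage_tree(pairwise_distances(merged))
    probs <- transfer_subtype_probabilities(
      tree, fix$ref$true_labels, names(fix$query$true_labels), 2, 15, 4)
    calls <- call_subtypes(probs)
    setNames(calls$call, calls$sample_id)
  }
  base <- run(fix$merged)
  perm <- fix$merged
  set.seed(99)
  idx <- sample(ncol(perm$values))
  perm$values <- perm$values[, idx]
  perm$block_of_sample <- perm$block_of_sample[idx]
  expect_identical(run(perm)[names(base)], base)
})

test_that("raising min_ref never assigns more query samples", {
  fix <- make_test_merged(seed = 29, n_per = 8, noise_sd = 1.5)
  tree <- complete_linkage_tree(pairwise_distances(fix$merged))
  n_assigned <- vapply(c(0, 2, 4, 6, 10), function(mr) {
    p <- transfer_subtype_probabilities(
      tree, fix$ref$true_labels, names(fix$query$true_labels),
      2, 15, mr)
    sum(!p$unassigned)
  }, numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})
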