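# Semi-supervised subtype label transfer: joint complete-linkage
# clustering of labeled reference and unlabeled query samples, tree cuts
# at every k in a range, and aggregation of reference-label proportions
# from qualifying sub-clusters.  Plus a nearest-centroid comparator.

#' Pairwise sample distances
#'
#' Correlation distance `1 - r` (default; range `[0, 2]`) or Euclidean
#' distance between sample profiles over the panel genes.
#'
#' @param merged a normalized `merged_matrix`.
#' @param metric `"one_minus_pearson"` or `"euclidean"`.
#' @return an object of class `"distance_matrix"`: list with
#'   `sample_ids`, symmetric matrix `d` (zero diagonal) and `metric`.
#' @export
pairwise_distances <- function(merged,
                               metric = c("one_minus_pearson",
                                          "euclidean")) {
  stopifnot(inherits(merged, "merged_matrix"))
  metric <- match.arg(metric)
  if (!isTRUE(merged$normalized))
    stop2("distances are computed on the normalized merged matrix")
  v <- merged$values
  if (ncol(v) < 2L) stop2("need at least 2 samples")
  if (metric == "one_minus_pearson") {
    sds <- apply(v, 2L, sd)
    if (any(sds == 0))
      stop2(sprintf("zero-variance sample profile(s): %s",
                    paste(colnames(v)[sds == 0], collapse = ", ")))
    d <- 1 - cor(v)
    d[d < 0] <- 0
  } else {
    d <- as.matrix(dist(t(v)))
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  structure(list(sample_ids = colnames(v), d = d, metric = metric),
            class = "distance_matrix")
}

#' Complete-linkage agglomerative tree
#'
#' Agglomerative clustering where the distance between two clusters is
#' the maximum pairwise distance between their members, guaranteeing
#' nondecreasing merge heights.
#'
#' @param d a `distance_matrix`.
#' @return an [stats::hclust] object whose labels are the sample ids.
#' @export
complete_linkage_tree <- function(d) {
  stopifnot(inherits(d, "distance_matrix"))
  if (!all(is.finite(d$d))) stop2("non-finite distances")
  hclust(as.dist(d$d), method = "complete")
}

#' Cut a tree into exactly k clusters
#'
#' Undoes the last `k - 1` merges of the agglomeration.
#'
#' @param tree an `hclust` tree.
#' @param k number of clusters, `1 <= k <= n`.
#' @return named integer vector of cluster memberships.
#' @export
cut_tree_at_k <- function(tree, k) {
  n <- length(tree$labels)
  k <- check_scalar_int(k, "k", min = 1)
  if (k > n) stop2(sprintf("`k` must be <= n = %d", n))
  cutree(tree, k = k)
}

#' Reference-label proportions per sub-cluster
#'
#' A sub-cluster qualifies when it contains strictly more than `min_ref`
#' labeled reference samples (default 4, i.e. at least 5); qualifying
#' clusters get the empirical label distribution of their reference
#' members, others are disqualified.
#'
#' @param assignment named cluster membership vector (from
#'   [cut_tree_at_k()]).
#' @param reference_labels named character vector, reference sample id ->
#'   subtype label.
#' @param min_ref disqualification threshold (strict, default 4).
#' @param subtype_labels label vocabulary (column order of the result);
#'   defaults to the sorted labels present.
#' @return list with `proportions` (clusters x labels matrix, `NA` rows
#'   for disqualified clusters), `n_ref` and `qualified`.
#' @export
subcluster_label_proportions <- function(assignment, reference_labels,
                                         min_ref = 4,
                                         subtype_labels = NULL) {
  min_ref <- check_scalar_int(min_ref, "min_ref", min = 0)
  if (is.null(subtype_labels))
    subtype_labels <- sort(unique(reference_labels))
  clusters <- sort(unique(assignment))
  ref_in <- intersect(names(assignment), names(reference_labels))
  props <- matrix(NA_real_, length(clusters), length(subtype_labels),
                  dimnames = list(as.character(clusters), subtype_labels))
  n_ref <- integer(length(clusters))
  for (i in seq_along(clusters)) {
    members <- names(assignment)[assignment == clusters[i]]
    refs <- intersect(members, ref_in)
    n_ref[i] <- length(refs)
    if (n_ref[i] > min_ref) {
      counts <- table(factor(reference_labels[refs],
                             levels = subtype_labels))
      props[i, ] <- as.numeric(counts) / n_ref[i]
    }
  }
  list(proportions = props, n_ref = n_ref, qualified = n_ref > min_ref)
}

#' Transfer subtype probabilities to query samples
#'
#' Cuts the joint reference+query tree at every `k` in `[k_min, k_max]`;
#' at each cut, a query sample inherits the reference-label proportion
#' vector of its sub-cluster if that sub-cluster qualifies (more than
#' `min_ref` reference members).  The final probability vector is the
#' unweighted mean of the collected vectors; samples with zero qualifying
#' cuts are unassigned.
#'
#' @param tree joint `hclust` tree over reference and query samples.
#' @param reference_labels named character vector of reference labels.
#' @param query_ids ids of the unlabeled samples.
#' @param k_min,k_max cut range, defaults 2 and 20 (`k_min >= 2`,
#'   `k_max <= n`).
#' @param min_ref sub-cluster qualification threshold (strict; default 4).
#' @param subtype_labels label vocabulary; defaults to the sorted
#'   reference labels.
#' @return an object of class `"subtype_probs"`: list with `probs`
#'   (query x labels matrix, `NA` rows when unassigned),
#'   `n_contributing_cuts` and `unassigned`.
#' @export
transfer_subtype_probabilities <- function(tree, reference_labels,
                                           query_ids, k_min = 2,
                                           k_max = 20, min_ref = 4,
                                           subtype_labels = NULL) {
  if (length(reference_labels) == 0L)
    stop2("no reference labels supplied")
  n <- length(tree$labels)
  k_min <- check_scalar_int(k_min, "k_min", min = 2)
  k_max <- check_scalar_int(k_max, "k_max", min = k_min)
  if (k_max > n) stop2(sprintf("`k_max` must be <= n = %d", n))
  if (is.null(subtype_labels))
    subtype_labels <- sort(unique(reference_labels))
  acc <- matrix(0, length(query_ids), length(subtype_labels),
                dimnames = list(query_ids, subtype_labels))
  n_cuts <- stats::setNames(integer(length(query_ids)), query_ids)
  for (k in k_min:k_max) {
    assignment <- cut_tree_at_k(tree, k)
    sp <- subcluster_label_proportions(assignment, reference_labels,
                                       min_ref, subtype_labels)
    cl_of_query <- as.character(assignment[query_ids])
    ok <- sp$qualified[match(cl_of_query, rownames(sp$proportions))]
    if (any(ok)) {
      acc[ok, ] <- acc[ok, , drop = FALSE] +
        sp$proportions[cl_of_query[ok], , drop = FALSE]
      n_cuts[ok] <- n_cuts[ok] + 1L
    }
  }
  probs <- acc / ifelse(n_cuts > 0L, n_cuts, NA_real_)
  structure(list(probs = probs, n_contributing_cuts = n_cuts,
                 unassigned = n_cuts == 0L,
                 subtype_labels = subtype_labels),
            class = "subtype_probs")
}

#' Call subtypes from probability vectors
#'
#' Argmax over the probability vector; exact ties are broken
#' lexicographically by label name (default) or lead to unassignment.
#'
#' @param probs a `subtype_probs` object.
#' @param tie_rule `"lexicographic"` or `"unassign"`.
#' @return data.frame(`sample_id`, `call` (`NA` when unassigned),
#'   `tie_broken`).
#' @export
call_subtypes <- function(probs, tie_rule = c("lexicographic",
                                              "unassign")) {
  stopifnot(inherits(probs, "subtype_probs"))
  tie_rule <- match.arg(tie_rule)
  labels <- colnames(probs$probs)
  call <- rep(NA_character_, nrow(probs$probs))
  tie <- rep(FALSE, nrow(probs$probs))
  for (i in seq_len(nrow(probs$probs))) {
    if (probs$unassigned[i]) next
    p <- probs$probs[i, ]
    top <- labels[p == max(p)]
    if (length(top) > 1L) {
      tie[i] <- TRUE
      if (tie_rule == "lexicographic") {
        call[i] <- sort(top)[1L]
      } # else stays unassigned
    } else {
      call[i] <- top
    }
  }
  data.frame(sample_id = rownames(probs$probs), call = call,
             tie_broken = tie, stringsAsFactors = FALSE)
}

#' Nearest-centroid comparator classifier
#'
#' Per-label centroid is the mean reference profile; each query sample is
#' assigned to the label of the most-correlated centroid.  Used as the
#' performance comparator for the co-clustering transfer.
#'
#' @param reference genes x samples numeric matrix of labeled reference
#'   profiles.
#' @param labels named character vector of reference labels (names are
#'   reference sample ids).
#' @param query genes x samples numeric matrix on the same gene space.
#' @return data.frame(`sample_id`, `call`, `correlation`); zero-variance
#'   query profiles are unassigned with a warning.
#' @export
nearest_centroid_classify <- function(reference, labels, query) {
  if (!identical(rownames(reference), rownames(query)))
    stop2("reference and query must share one gene space")
  labels <- labels[colnames(reference)]
  if (anyNA(labels)) stop2("every reference sample needs a label")
  lab_set <- sort(unique(labels))
  centroids <- vapply(lab_set, function(l) {
    rowMeans(reference[, labels == l, drop = FALSE])
  }, numeric(nrow(reference)))
  call <- rep(NA_character_, ncol(query))
  rmax <- rep(NA_real_, ncol(query))
  dead <- apply(query, 2L, sd) == 0
  if (any(dead))
    warning(sprintf("zero-variance query profile(s) unassigned: %s",
                    paste(colnames(query)[dead], collapse = ", ")),
            call. = FALSE)
  live <- which(!dead)
  if (length(live)) {
    r <- cor(query[, live, drop = FALSE], centroids)
    idx <- apply(r, 1L, which.max)
    call[live] <- lab_set[idx]
    rmax[live] <- r[cbind(seq_along(live), idx)]
  }
  data.frame(sample_id = colnames(query), call = call,
             correlation = rmax, stringsAsFactors = FALSE)
}

#' Agreement between two call vectors
#'
#' Concordance is the fraction of samples assigned by both methods whose
#' calls agree; the confusion matrix includes an `unassigned` level.
#'
#' @param calls_a,calls_b data.frames with `sample_id` and `call` columns
#'   over the same sample set.
#' @return list with `concordance`, `n_joint` (samples assigned by both)
#'   and `confusion`.
#' @export
classification_agreement <- function(calls_a, calls_b) {
  common <- intersect(calls_a$sample_id, calls_b$sample_id)
  if (length(common) == 0L) stop2("call sets share no samples")
  a <- calls_a$call[match(common, calls_a$sample_id)]
  b <- calls_b$call[match(common, calls_b$sample_id)]
  fa <- factor(ifelse(is.na(a), "unassigned", a))
  fb <- factor(ifelse(is.na(b), "unassigned", b))
  lev <- sort(unique(c(levels(fa), levels(fb))))
  confusion <- table(factor(fa, lev), factor(fb, lev), dnn = c("a", "b"))
  joint <- !is.na(a) & !is.na(b)
  concordance <- if (any(joint)) mean(a[joint] == b[joint]) else NA_real_
  list(concordance = concordance, n_joint = sum(joint),
       confusion = confusion)
}

#' Macro-averaged call accuracy against a truth vector
#'
#' Mean over truth classes of the fraction of that class's samples
#' called correctly; unassigned samples count as errors.
#'
#' @param calls data.frame(`sample_id`, `call`).
#' @param truth named character vector of true labels.
#' @return scalar in `[0, 1]`.
#' @export
macro_accuracy <- function(calls, truth) {
  got <- calls$call[match(names(truth), calls$sample_id)]
  per_class <- vapply(sort(unique(truth)), function(l) {
    in_class <- truth == l
    mean(!is.na(got[in_class]) & got[in_class] == l)
  }, numeric(1))
  mean(per_class)
}
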