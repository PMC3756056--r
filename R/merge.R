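# Ortholog panel restriction, cross-dataset merging and unitization
# normalization into [-1, 1].

#' Filter a panel to unambiguous one-to-one orthologs
#'
#' Retains exactly those panel genes with one and only one partner in the
#' ortholog table whose partner likewise maps back only to them (1:1 in
#' both directions).  Output order follows the panel order, so the
#' operation is order-stable and idempotent.
#'
#' @param panel character vector of reference-species gene ids.
#' @param table data.frame with columns `gene_a` (reference species) and
#'   `gene_b`.
#' @return data.frame(`gene_a`, `gene_b`) of retained pairs; a warning
#'   (not an error) is issued when no pair survives.
#' @export
filter_unambiguous_orthologs <- function(panel, table) {
  if (length(panel) < 1L) stop2("`panel` must be non-empty")
  if (!all(c("gene_a", "gene_b") %in% names(table)))
    stop2("`table` must have columns `gene_a` and `gene_b`")
  tab <- unique(table[, c("gene_a", "gene_b")])
  fwd <- table(tab$gene_a)   # partners per reference gene
  rev <- table(tab$gene_b)   # reference genes per partner
  keep <- vapply(panel, function(g) {
    rows <- tab[tab$gene_a == g, , drop = FALSE]
    nrow(rows) == 1L && fwd[[g]] == 1L && rev[[rows$gene_b]] == 1L
  }, logical(1))
  out <- do.call(rbind, lapply(panel[keep], function(g) {
    tab[tab$gene_a == g, , drop = FALSE]
  }))
  if (is.null(out))
    out <- data.frame(gene_a = character(), gene_b = character())
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no unambiguous ortholog pairs retained", call. = FALSE)
  out
}

# Which namespace (gene_a or gene_b) does a matrix use?
namespace_of <- function(m, shared) {
  in_a <- sum(shared$gene_a %in% rownames(m$values))
  in_b <- sum(shared$gene_b %in% rownames(m$values))
  if (in_a == 0L && in_b == 0L)
    stop2(sprintf("dataset '%s' contains none of the shared panel genes",
                  m$dataset_id))
  if (in_a >= in_b) "gene_a" else "gene_b"
}

#' Restrict matrices to the shared ortholog panel and align rows
#'
#' Each output matrix contains exactly the shared genes, in the shared
#' order, renamed to the reference-species namespace.  A shared gene
#' missing from any matrix is dropped from all matrices (intersection
#' semantics) with a warning.
#'
#' @param matrices list of `expr_matrix` objects (either namespace).
#' @param shared data.frame(`gene_a`, `gene_b`) from
#'   [filter_unambiguous_orthologs()].
#' @return list of `expr_matrix` objects on the common panel.
#' @export
restrict_and_align <- function(matrices, shared) {
  if (nrow(shared) == 0L) stop2("`shared` panel is empty")
  ns <- vapply(matrices, namespace_of, character(1), shared = shared)
  present <- rep(TRUE, nrow(shared))
  for (i in seq_along(matrices)) {
    ids <- shared[[ns[i]]]
    present <- present & ids %in% rownames(matrices[[i]]$values)
  }
  if (!any(present))
    stop2("no shared gene is present in every dataset")
  if (!all(present)) {
    dropped <- shared$gene_a[!present]
    warning(sprintf(
      "dropping %d shared gene(s) missing from at least one dataset: %s",
      length(dropped), paste(dropped, collapse = ", ")), call. = FALSE)
  }
  shared <- shared[present, , drop = FALSE]
  lapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    v <- m$values[shared[[ns[i]]], , drop = FALSE]
    rownames(v) <- shared$gene_a
    expression_matrix(v, m$species, m$platform_id, m$dataset_id)
  })
}

#' Merge aligned expression matrices into one block-annotated matrix
#'
#' Column-concatenates matrices that share an identical gene list and
#' records each sample's dataset of origin.
#'
#' @param aligned list of `expr_matrix` objects with identical gene ids
#'   in identical order and globally unique sample ids.
#' @return an object of class `"merged_matrix"`: list with `values`,
#'   `block_of_sample` (named character) and `normalized = FALSE`.
#' @export
merge_matrices <- function(aligned) {
  if (length(aligned) < 1L) stop2("need at least one matrix")
  genes <- rownames(aligned[[1L]]$values)
  for (m in aligned) {
    if (!identical(rownames(m$values), genes))
      stop2(sprintf("gene order mismatch in dataset '%s'", m$dataset_id))
  }
  values <- do.call(cbind, lapply(aligned, function(m) m$values))
  block <- unlist(lapply(aligned, function(m) {
    stats::setNames(rep(m$dataset_id, ncol(m$values)),
                    colnames(m$values))
  }))
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))]
    stop2(sprintf("duplicate sample id(s) across datasets: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  structure(list(values = values, block_of_sample = block,
                 normalized = FALSE),
            class = "merged_matrix")
}

unitize <- function(x, eps = .Machine$double.eps * 100) {
  cx <- x - mean(x)
  m <- max(abs(cx))
  if (m < eps) rep(0, length(x)) else cx / m
}

#' Unitization normalization into \[-1, 1\]
#'
#' For each normalization group -- a gene's values within one dataset
#' block (`per_gene_per_block`, the default) or across the whole merged
#' matrix (`per_gene_global`) -- the group mean is subtracted and the
#' result divided by the maximum absolute deviation, bounding every value
#' in `[-1, 1]`.  Constant groups map to all zeros.  The per-block scope
#' removes any affine per-platform shift (offset plus positive scale)
#' exactly.
#'
#' @param merged an unnormalized `merged_matrix`.
#' @param scope `"per_gene_per_block"` or `"per_gene_global"`.
#' @return the `merged_matrix` with normalized values and
#'   `normalized = TRUE`.
#' @export
normalize_unitization <- function(merged,
                                  scope = c("per_gene_per_block",
                                            "per_gene_global")) {
  stopifnot(inherits(merged, "merged_matrix"))
  scope <- match.arg(scope)
  if (isTRUE(merged$normalized))
    stop2("matrix is already normalized")
  v <- merged$values
  if (scope == "per_gene_global") {
    v <- t(apply(v, 1L, unitize))
    dimnames(v) <- dimnames(merged$values)
  } else {
    for (b in unique(merged$block_of_sample)) {
      cols <- which(merged$block_of_sample == b)
      v[, cols] <- t(apply(v[, cols, drop = FALSE], 1L, unitize))
    }
  }
  merged$values <- v
  merged$normalized <- TRUE
  merged$scope <- scope
  merged
}
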