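# Lightweight S3 containers for the pipeline's domain objects.

#' Construct an expression matrix
#'
#' A genes-by-samples matrix of (log-scale) expression values tagged with
#' its species, platform and dataset of origin.  Gene and sample
#' identifiers are carried as dimnames and must be unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   complete dimnames.
#' @param species species tag, e.g. `"human"` or `"mouse"`.
#' @param platform_id platform tag (carried as provenance only).
#' @param dataset_id dataset tag; must be unique across matrices that are
#'   later merged.
#' @return an object of class `"expr_matrix"`.
#' @export
expression_matrix <- function(values, species, platform_id, dataset_id) {
  if (!is.matrix(values) || !is.numeric(values))
    stop2("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop2("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop2("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop2("duplicate sample ids in expression matrix")
  if (!all(is.finite(values)))
    stop2("expression values must be finite")
  structure(
    list(values = values, species = as.character(species),
         platform_id = as.character(platform_id),
         dataset_id = as.character(dataset_id)),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s / %s / %s]\n",
              nrow(x$values), ncol(x$values), x$species, x$platform_id,
              x$dataset_id))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.merged_matrix <- function(x, ...) {
  cat(sprintf("merged_matrix: %d genes x %d samples, %d blocks, %s\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$block_of_sample)),
              if (x$normalized) "normalized" else "unnormalized"))
  invisible(x)
}

#' Construct a planted susceptibility locus
#'
#' Describes a marker whose risk genotype (backcross) or risk founder
#' (outbred) tilts the latent subtype of a simulated tumor toward a target
#' subtype.
#'
#' @param marker_index integer index of the marker in the genotype object.
#' @param target_subtype character vector of one or more subtype labels
#'   receiving the probability tilt (split evenly across the set).
#' @param effect probability shift in `[0, 1]` added to the target
#'   subtype's probability (before renormalization) in carriers.
#' @param risk_founder for outbred designs, the founder index whose
#'   carriers (dosage > 0) receive the tilt; ignored for backcrosses,
#'   where the heterozygous genotype is the risk genotype.
#' @return an object of class `"planted_locus"`.
#' @export
planted_locus <- function(marker_index, target_subtype, effect,
                          risk_founder = NULL) {
  marker_index <- check_scalar_int(marker_index, "marker_index", min = 1)
  effect <- check_scalar_num(effect, "effect", min = 0, max = 1)
  if (!is.character(target_subtype) || length(target_subtype) < 1L)
    stop2("`target_subtype` must be one or more subtype labels")
  structure(
    list(marker_index = marker_index,
         target_subtype = target_subtype,
         effect = effect,
         risk_founder = risk_founder),
    class = "planted_locus")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data (%s): %d markers x %d samples",
              x$design, length(x$marker_ids), length(x$sample_ids)))
  if (x$design == "outbred") cat(sprintf(", %d founders", x$n_founders))
  cat("\n")
  invisible(x)
}

#' @export
print.subtype_probs <- function(x, ...) {
  cat(sprintf(
    "subtype_probs: %d query samples (%d assigned), labels: %s\n",
    nrow(x$probs), sum(!x$unassigned),
    paste(colnames(x$probs), collapse = ", ")))
  invisible(x)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort [%s]: %d genes x %d samples\n",
              x$expression$platform_id, nrow(x$expression$values),
              ncol(x$expression$values)))
  print(table(x$true_labels))
  invisible(x)
}
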