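# TSV dialects for all pipeline artifacts.  Numbers are serialized with
# 10 significant digits so write -> read -> write is byte-identical.

read_tsv_checked <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read / write an expression TSV
#'
#' Dialect: one header row; first column `gene_id`, remaining columns one
#' per sample.  Duplicate gene or sample ids and non-numeric cells are
#' hard errors.
#'
#' @param path file path.
#' @param species,platform_id,dataset_id tags attached to the matrix on
#'   read.
#' @return an `expr_matrix`.
#' @export
read_expression_tsv <- function(path, species = "unknown",
                                platform_id = "unknown",
                                dataset_id = NULL) {
  df <- read_tsv_checked(path)
  if (names(df)[1L] != "gene_id")
    stop2(sprintf("%s: first column must be `gene_id`", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  dup <- header[-1L][duplicated(header[-1L])]
  if (length(dup))
    stop2(sprintf("%s: duplicate sample column(s): %s", path,
                  paste(unique(dup), collapse = ", ")))
  if (anyDuplicated(df$gene_id)) {
    bad <- unique(df$gene_id[duplicated(df$gene_id)])
    stop2(sprintf("%s: duplicate gene id(s): %s", path,
                  paste(bad, collapse = ", ")))
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]]))
      stop2(sprintf("%s: non-numeric value in column `%s`", path,
                    names(vals)[j]))
  }
  m <- as.matrix(vals)
  rownames(m) <- df$gene_id
  expression_matrix(m, species, platform_id,
                    dataset_id %||% platform_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_expression_tsv
#' @param matrix an `expr_matrix` or plain numeric matrix with dimnames.
#' @export
write_expression_tsv <- function(matrix, path) {
  v <- if (inherits(matrix, "expr_matrix")) matrix$values else matrix
  df <- data.frame(gene_id = rownames(v), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(v, check.names = FALSE))
  write_tsv_lines(df, path)
  invisible(path)
}

#' Read a sample annotation TSV
#'
#' Required columns: `sample_id`, `dataset_id`, `species`, `platform`,
#' `subtype` (a configured label or `NA` for unlabeled samples) and
#' `metastasis` (0/1/`NA`).  Unknown subtype strings are hard errors
#' (comparisons are case-sensitive).
#'
#' @param path file path.
#' @param allowed_labels permitted subtype vocabulary.
#' @return data.frame of annotations.
#' @export
read_annotation_tsv <- function(path, allowed_labels = PAM50_SUBTYPES) {
  df <- read_tsv_checked(path)
  need <- c("sample_id", "dataset_id", "species", "platform", "subtype",
            "metastasis")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop2(sprintf("%s: missing column(s): %s", path,
                  paste(missing, collapse = ", ")))
  bad <- setdiff(stats::na.omit(unique(df$subtype)), allowed_labels)
  if (length(bad))
    stop2(sprintf("%s: unknown subtype label(s) %s; allowed: %s", path,
                  paste(bad, collapse = ", "),
                  paste(allowed_labels, collapse = ", ")))
  if (anyDuplicated(df$sample_id))
    stop2(sprintf("%s: duplicate sample ids", path))
  df
}

#' @rdname read_annotation_tsv
#' @param annotation annotation data.frame.
#' @export
write_annotation_tsv <- function(annotation, path) {
  write_tsv_lines(annotation, path)
  invisible(path)
}

#' Read / write ortholog tables
#'
#' Two columns: `gene_a` (reference species) and `gene_b`.
#'
#' @param path file path.
#' @export
read_ortholog_tsv <- function(path) {
  df <- read_tsv_checked(path)
  if (!all(c("gene_a", "gene_b") %in% names(df)))
    stop2(sprintf("%s: need columns `gene_a`, `gene_b`", path))
  df
}

#' @rdname read_ortholog_tsv
#' @param table ortholog data.frame.
#' @export
write_ortholog_tsv <- function(table, path) {
  write_tsv_lines(table, path)
  invisible(path)
}

#' Read / write genotype tables
#'
#' Backcross dialect: columns `marker_id`, `chrom`, `pos_mb`, then one
#' column per sample with codes `A` (homozygous) / `H` (heterozygous).
#' Outbred dialect (long): `marker_id`, `chrom`, `pos_mb`, `sample_id`,
#' `founder_id`, `dosage`.
#'
#' @param path file path.
#' @return a `genotype_data` object.
#' @export
read_backcross_tsv <- function(path) {
  df <- read_tsv_checked(path)
  fixed <- c("marker_id", "chrom", "pos_mb")
  if (!all(fixed %in% names(df)[1:3]))
    stop2(sprintf("%s: first columns must be %s", path,
                  paste(fixed, collapse = ", ")))
  geno <- as.matrix(df[, -(1:3), drop = FALSE])
  if (!all(geno %in% c("A", "H")))
    stop2(sprintf("%s: genotype codes must be A or H", path))
  rownames(geno) <- df$marker_id
  structure(list(marker_ids = df$marker_id,
                 sample_ids = colnames(geno),
                 chrom = as.character(df$chrom),
                 pos_mb = as.numeric(df$pos_mb),
                 design = "backcross", geno = geno),
            class = "genotype_data")
}

#' @rdname read_backcross_tsv
#' @param g a `genotype_data` object of the matching design.
#' @export
write_backcross_tsv <- function(g, path) {
  stopifnot(g$design == "backcross")
  df <- data.frame(marker_id = g$marker_ids, chrom = g$chrom,
                   pos_mb = g$pos_mb, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(g$geno, check.names = FALSE))
  write_tsv_lines(df, path)
  invisible(path)
}

#' @rdname read_backcross_tsv
#' @export
read_founder_tsv <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("marker_id", "chrom", "pos_mb", "sample_id", "founder_id",
            "dosage")
  if (!all(need %in% names(df)))
    stop2(sprintf("%s: need columns %s", path,
                  paste(need, collapse = ", ")))
  marker_ids <- unique(df$marker_id)
  sample_ids <- unique(df$sample_id)
  founders <- unique(df$founder_id)
  dosage <- array(0L, c(length(marker_ids), length(sample_ids),
                        length(founders)),
                  dimnames = list(marker_ids, sample_ids, founders))
  dosage[cbind(match(df$marker_id, marker_ids),
               match(df$sample_id, sample_ids),
               match(df$founder_id, founders))] <- as.integer(df$dosage)
  map <- df[!duplicated(df$marker_id), c("marker_id", "chrom", "pos_mb")]
  map <- map[match(marker_ids, map$marker_id), ]
  structure(list(marker_ids = marker_ids, sample_ids = sample_ids,
                 chrom = as.character(map$chrom),
                 pos_mb = as.numeric(map$pos_mb),
                 design = "outbred", n_founders = length(founders),
                 dosage = dosage),
            class = "genotype_data")
}

#' @rdname read_backcross_tsv
#' @export
write_founder_tsv <- function(g, path) {
  stopifnot(g$design == "outbred")
  founders <- dimnames(g$dosage)[[3L]]
  df <- expand.grid(marker_idx = seq_along(g$marker_ids),
                    sample_id = g$sample_ids, founder_id = founders,
                    stringsAsFactors = FALSE)
  df <- df[order(df$marker_idx, match(df$sample_id, g$sample_ids),
                 match(df$founder_id, founders)), ]
  out <- data.frame(marker_id = g$marker_ids[df$marker_idx],
                    chrom = g$chrom[df$marker_idx],
                    pos_mb = g$pos_mb[df$marker_idx],
                    sample_id = df$sample_id,
                    founder_id = df$founder_id,
                    dosage = g$dosage[cbind(df$marker_idx,
                                            match(df$sample_id,
                                                  g$sample_ids),
                                            match(df$founder_id,
                                                  founders))],
                    stringsAsFactors = FALSE)
  write_tsv_lines(out, path)
  invisible(path)
}

#' Write a merged matrix with its JSON sidecar
#'
#' The matrix goes to `<path>`; block membership and normalization
#' metadata go to `<path>.json`.
#'
#' @param merged a `merged_matrix`.
#' @param path file path for the TSV.
#' @export
write_merged_tsv <- function(merged, path) {
  write_expression_tsv(merged$values, path)
  meta <- list(block_of_sample = as.list(merged$block_of_sample),
               normalized = merged$normalized,
               scope = merged$scope %||% NA)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_merged_tsv
#' @export
read_merged_tsv <- function(path) {
  em <- read_expression_tsv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  block <- unlist(meta$block_of_sample)
  structure(list(values = em$values,
                 block_of_sample = block[colnames(em$values)],
                 normalized = isTRUE(meta$normalized),
                 scope = if (is.character(meta$scope)) meta$scope else NULL),
            class = "merged_matrix")
}

#' Write transfer outputs
#'
#' Probabilities TSV: `sample_id`, one column per subtype label,
#' `n_contributing_cuts` (unassigned samples carry `NA` probabilities).
#' Calls TSV: `sample_id`, `call` (`unassigned` when no call),
#' `tie_broken`.
#'
#' @param probs a `subtype_probs` object.
#' @param calls a calls data.frame.
#' @param path file path.
#' @export
write_probabilities_tsv <- function(probs, path) {
  df <- data.frame(sample_id = rownames(probs$probs),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(probs$probs, check.names = FALSE))
  df$n_contributing_cuts <- probs$n_contributing_cuts
  write_tsv_lines(df, path)
  invisible(path)
}

#' @rdname write_probabilities_tsv
#' @export
write_calls_tsv <- function(calls, path) {
  out <- calls
  out$call <- ifelse(is.na(out$call), "unassigned", out$call)
  write_tsv_lines(out, path)
  invisible(path)
}

#' @rdname write_probabilities_tsv
#' @param scan a genome-scan result data.frame.
#' @export
write_scan_tsv <- function(scan, path) {
  write_tsv_lines(scan, path)
  invisible(path)
}
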