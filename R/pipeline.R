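# End-to-end orchestration: simulate -> merge/normalize -> classify ->
# scan -> report.  One config governs a run; identical config + seeds
# give byte-identical outputs.

#' Default run configuration
#'
#' The default synthetic study: a 50-gene panel of which 42 survive
#' ortholog filtering, five subtypes with separation 2.0 and unit noise,
#' a 60-sample labeled reference, a 60-sample backcross-driven query
#' cohort with one locus tilting carriers toward the basal subtype
#' (effect 0.4), and metastasis at the incidence of the outbred cross
#' (72/124).
#'
#' @param seed master seed; per-stage seeds are derived as small fixed
#'   offsets.
#' @return nested list understood by [run_full_pipeline()].
#' @export
default_run_config <- function(seed = 1) {
  seed <- check_scalar_int(seed, "seed")
  list(
    seeds = list(centroids = seed + 1, reference = seed + 2,
                 genotypes = seed + 3, query = seed + 4,
                 metastasis = seed + 5, orthologs = seed + 6,
                 metastasis_test = seed + 7),
    generator = list(
      panel_size = 50, n_genes_used = 42,
      subtype_labels = PAM50_SUBTYPES,
      separation = 2.0, noise_sd = 1.0,
      n_ref_per_subtype = 12,
      n_query = 60, n_markers = 200, design = "backcross",
      recomb_rate = 0.01,
      frac_ambiguous = 0, frac_missing = 0.16,
      base_probs = rep(0.2, 5),
      planted = list(list(marker_index = 10, target_subtype = "Basal",
                          effect = 0.4)),
      platform_shift = c(0.5, 1.5),
      metastasis_incidence = 72 / 124),
    normalization = list(scope = "per_gene_per_block"),
    transfer = list(metric = "one_minus_pearson", k_min = 2, k_max = 20,
                    min_ref = 4, tie_rule = "lexicographic"),
    scan = list(targets = list(basal = "Basal"), fdr_level = 0.05),
    fdr_level = 0.05)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [default_run_config()];
#'   missing keys fall back to the defaults.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_run_config(user$seed %||% 1)
  merge_cfg <- function(base, user) {
    for (k in names(user)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
        merge_cfg(base[[k]], user[[k]]) else user[[k]]
    }
    base
  }
  validate_config(merge_cfg(base, user[setdiff(names(user), "seed")]))
}

#' @rdname read_run_config
#' @param config config list to validate.
#' @export
validate_config <- function(config) {
  tr <- config$transfer
  if (tr$k_min > tr$k_max)
    stop2("config error: k_min must be <= k_max")
  if (config$fdr_level <= 0 || config$fdr_level >= 1)
    stop2("config error: fdr_level must be in (0, 1)")
  gen <- config$generator
  if (abs(sum(gen$base_probs) - 1) > 1e-8)
    stop2("config error: base_probs must sum to 1")
  config
}

simulate_stage <- function(config) {
  gen <- config$generator
  seeds <- config$seeds
  panel <- sprintf("G%03d", seq_len(gen$panel_size))
  orth <- build_ortholog_table(panel, gen$frac_ambiguous,
                               gen$frac_missing, seed = seeds$orthologs)
  shared <- filter_unambiguous_orthologs(panel, orth)
  centroids <- make_subtype_centroids(nrow(shared), gen$subtype_labels,
                                      gen$separation,
                                      seed = seeds$centroids)
  # centroids live on the retained panel, reference namespace
  rownames(centroids$centroids) <- shared$gene_a
  reference <- generate_reference_cohort(centroids, gen$n_ref_per_subtype,
                                         gen$noise_sd, "ref",
                                         seed = seeds$reference)
  genotypes <- if (identical(gen$design, "outbred")) {
    generate_outbred_genotypes(gen$n_query, gen$n_markers,
                               gen$n_founders %||% 8,
                               recomb_rate = gen$recomb_rate,
                               seed = seeds$genotypes)
  } else {
    generate_backcross_genotypes(gen$n_query, gen$n_markers,
                                 recomb_rate = gen$recomb_rate,
                                 seed = seeds$genotypes)
  }
  loci <- lapply(gen$planted, function(l) {
    planted_locus(l$marker_index, l$target_subtype, l$effect,
                  l$risk_founder)
  })
  query <- generate_query_cohort(genotypes, loci, centroids,
                                 gen$base_probs, gen$platform_shift,
                                 gen$noise_sd, "query",
                                 seed = seeds$query)
  # query cohort is expressed in the second-species namespace
  rownames(query$expression$values) <- shared$gene_b
  metastasis <- stats::setNames(
    generate_metastasis_status(gen$n_query, gen$metastasis_incidence,
                               seed = seeds$metastasis),
    query$expression$values |> colnames())
  query$metastasis <- metastasis
  list(panel = panel, ortholog_table = orth, shared = shared,
       centroids = centroids, reference = reference,
       genotypes = genotypes, query = query)
}

write_simulation <- function(sim, out_dir) {
  write_ortholog_tsv(sim$ortholog_table,
                     file.path(out_dir, "ortholog_table.tsv"))
  write_expression_tsv(sim$reference$expression,
                       file.path(out_dir, "reference_expression.tsv"))
  write_expression_tsv(sim$query$expression,
                       file.path(out_dir, "query_expression.tsv"))
  ann <- rbind(
    data.frame(sample_id = names(sim$reference$true_labels),
               dataset_id = "ref", species = "human", platform = "ref",
               subtype = unname(sim$reference$true_labels),
               metastasis = NA_integer_, stringsAsFactors = FALSE),
    data.frame(sample_id = names(sim$query$true_labels),
               dataset_id = "query", species = "mouse",
               platform = "query", subtype = NA_character_,
               metastasis = unname(sim$query$metastasis),
               stringsAsFactors = FALSE))
  write_annotation_tsv(ann, file.path(out_dir, "annotation.tsv"))
  if (sim$genotypes$design == "backcross") {
    write_backcross_tsv(sim$genotypes, file.path(out_dir, "genotypes.tsv"))
  } else {
    write_founder_tsv(sim$genotypes, file.path(out_dir, "genotypes.tsv"))
  }
  invisible(out_dir)
}

#' Run the full pipeline
#'
#' Executes simulate, merge/normalize, classify (co-clustering transfer
#' plus the nearest-centroid comparator), genome scan(s) and the
#' subtype-metastasis independence test; writes every stage's artifacts
#' under `out_dir` and returns (and writes) a run report.
#'
#' @param config config list (see [default_run_config()]).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the run report list (also written to
#'   `report.json`).
#' @export
run_full_pipeline <- function(config = default_run_config(),
                              out_dir = tempfile("subtypemap_run_")) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()

  sim <- simulate_stage(config)
  write_simulation(sim, out_dir)
  report$simulate <- list(
    panel_size = length(sim$panel),
    shared_genes = nrow(sim$shared),
    n_reference = length(sim$reference$true_labels),
    n_query = length(sim$query$true_labels),
    n_markers = length(sim$genotypes$marker_ids))

  shared <- sim$shared
  aligned <- restrict_and_align(list(sim$reference$expression,
                                     sim$query$expression), shared)
  merged <- merge_matrices(aligned)
  merged <- normalize_unitization(merged, config$normalization$scope)
  write_merged_tsv(merged, file.path(out_dir, "merged_normalized.tsv"))
  report$merge <- list(genes = nrow(merged$values),
                       samples = ncol(merged$values),
                       value_min = min(merged$values),
                       value_max = max(merged$values))

  ref_labels <- sim$reference$true_labels
  query_ids <- names(sim$query$true_labels)
  d <- pairwise_distances(merged, config$transfer$metric)
  tree <- complete_linkage_tree(d)
  k_max <- min(config$transfer$k_max, ncol(merged$values))
  probs <- transfer_subtype_probabilities(
    tree, ref_labels, query_ids, config$transfer$k_min, k_max,
    config$transfer$min_ref,
    subtype_labels = config$generator$subtype_labels)
  calls <- call_subtypes(probs, config$transfer$tie_rule)
  write_probabilities_tsv(probs, file.path(out_dir, "probabilities.tsv"))
  write_calls_tsv(calls, file.path(out_dir, "calls.tsv"))

  ref_block <- merged$values[, merged$block_of_sample == "ref",
                             drop = FALSE]
  query_block <- merged$values[, merged$block_of_sample == "query",
                               drop = FALSE]
  nc_calls <- nearest_centroid_classify(ref_block, ref_labels,
                                        query_block)
  write_calls_tsv(nc_calls[, c("sample_id", "call")],
                  file.path(out_dir, "calls_nearest_centroid.tsv"))
  agree <- classification_agreement(calls, nc_calls)
  report$classify <- list(
    n_assigned = sum(!is.na(calls$call)),
    n_unassigned = sum(is.na(calls$call)),
    macro_accuracy = macro_accuracy(calls, sim$query$true_labels),
    concordance_with_centroid = agree$concordance,
    n_jointly_assigned = agree$n_joint)

  report$scans <- list()
  for (scan_name in names(config$scan$targets)) {
    target <- config$scan$targets[[scan_name]]
    y <- binarize_subtype(calls, target)
    if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
      warning(sprintf("scan '%s': phenotype is constant, skipped",
                      scan_name), call. = FALSE)
      next
    }
    scan <- genome_scan(sim$genotypes, y, config$scan$fdr_level)
    write_scan_tsv(scan, file.path(out_dir,
                                   sprintf("scan_%s.tsv", scan_name)))
    top <- scan[which.min(scan$p_value), ]
    report$scans[[scan_name]] <- list(
      n_markers = nrow(scan), n_cases = sum(y == 1L),
      n_significant = sum(scan$significant),
      top_marker = top$marker_id, top_chrom = top$chrom,
      top_pos_mb = top$pos_mb, top_p = top$p_value, top_q = top$q_value)
  }

  met <- sim$query$metastasis
  mt <- tryCatch(
    subtype_metastasis_test(calls, met,
                            seed = config$seeds$metastasis_test),
    error = function(e) NULL)
  report$metastasis <- if (is.null(mt)) {
    list(p_value = NA_real_, method = "not run")
  } else {
    list(p_value = mt$p_value, statistic = mt$statistic,
         method = mt$method)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
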