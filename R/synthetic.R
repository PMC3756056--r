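# Synthetic-data generators.  Every generator is a pure function of its
# arguments and an explicit integer seed; the caller's RNG state is left
# untouched (withr::with_seed).

#' Build a default marker map
#'
#' Distributes markers as evenly as possible across equally sized
#' chromosomes, evenly spaced within each chromosome.  Mouse-like
#' defaults: 19 autosomes of 100 Mb.
#'
#' @param n_markers total number of markers.
#' @param n_chrom number of chromosomes.
#' @param chrom_length_mb chromosome length in Mb.
#' @return data.frame with columns `chrom` (character) and `pos_mb`
#'   (numeric, 1-based Mb, nondecreasing within chromosome).
#' @export
marker_map <- function(n_markers, n_chrom = 19, chrom_length_mb = 100) {
  n_markers <- check_scalar_int(n_markers, "n_markers", min = 1)
  n_chrom <- check_scalar_int(n_chrom, "n_chrom", min = 1)
  n_chrom <- min(n_chrom, n_markers)
  per <- diff(round(seq(0, n_markers, length.out = n_chrom + 1)))
  chrom <- rep(as.character(seq_len(n_chrom)), times = per)
  pos <- unlist(lapply(per, function(k) {
    seq(1, chrom_length_mb, length.out = k)
  }), use.names = FALSE)
  data.frame(chrom = chrom, pos_mb = pos, stringsAsFactors = FALSE)
}

#' Generate subtype centroids
#'
#' Draws one mean log-expression profile per subtype.  Centroids are
#' `separation` times a fixed standard-normal draw, so the mean pairwise
#' centroid distance scales exactly linearly with `separation` and
#' `separation = 0` collapses all centroids onto the origin.
#'
#' @param n_genes number of panel genes (>= 2).
#' @param labels subtype label vector (>= 2 labels); defaults to the five
#'   intrinsic subtypes.
#' @param separation nonnegative scalar controlling inter-centroid
#'   distance.
#' @param seed integer seed.
#' @return an object of class `"centroid_set"`: list with `labels`,
#'   `centroids` (genes x labels matrix) and `separation`.
#' @export
make_subtype_centroids <- function(n_genes, labels = PAM50_SUBTYPES,
                                   separation = 2, seed = 1) {
  n_genes <- check_scalar_int(n_genes, "n_genes", min = 2)
  if (length(labels) < 2L || anyDuplicated(labels))
    stop2("`labels` must be >= 2 distinct subtype labels")
  separation <- check_scalar_num(separation, "separation", min = 0)
  z <- withr::with_seed(seed, matrix(rnorm(n_genes * length(labels)),
                                     nrow = n_genes))
  centroids <- separation * z
  dimnames(centroids) <- list(sprintf("G%03d", seq_len(n_genes)),
                              as.character(labels))
  structure(list(labels = as.character(labels), centroids = centroids,
                 separation = separation),
            class = "centroid_set")
}

new_cohort <- function(values, labels, species, platform_id, dataset_id,
                       metastasis = NULL) {
  em <- expression_matrix(values, species, platform_id, dataset_id)
  structure(list(expression = em,
                 true_labels = stats::setNames(labels, colnames(values)),
                 platform_id = platform_id,
                 metastasis = metastasis),
            class = "sim_cohort")
}

#' Generate a labeled reference cohort
#'
#' Each sample is its subtype centroid plus i.i.d. Gaussian noise; the
#' latent label is recorded.  Emulates a labeled human reference cohort.
#'
#' @param centroids a `centroid_set`.
#' @param n_per_subtype samples per subtype (>= 1).
#' @param noise_sd nonnegative noise standard deviation.
#' @param platform_id platform tag (also used as dataset id and sample-id
#'   prefix).
#' @param seed integer seed.
#' @param species species tag, default `"human"`.
#' @return an object of class `"sim_cohort"`.
#' @export
generate_reference_cohort <- function(centroids, n_per_subtype,
                                      noise_sd = 1, platform_id = "ref",
                                      seed = 1, species = "human") {
  stopifnot(inherits(centroids, "centroid_set"))
  n_per_subtype <- check_scalar_int(n_per_subtype, "n_per_subtype", min = 1)
  noise_sd <- check_scalar_num(noise_sd, "noise_sd", min = 0)
  labs <- rep(centroids$labels, each = n_per_subtype)
  n <- length(labs)
  g <- nrow(centroids$centroids)
  noise <- withr::with_seed(seed, matrix(rnorm(g * n, sd = noise_sd), g, n))
  values <- centroids$centroids[, labs, drop = FALSE] + noise
  colnames(values) <- sprintf("%s_s%03d", platform_id, seq_len(n))
  rownames(values) <- rownames(centroids$centroids)
  new_cohort(values, labs, species, platform_id, platform_id)
}

#' Generate backcross genotypes
#'
#' Simulates an N2 backcross: every marker is homozygous (`"A"`) or
#' heterozygous (`"H"`) with marginal frequency 1/2 each, and neighboring
#' markers on a chromosome are linked through a symmetric Markov
#' recombination process with switch probability
#' `min(0.5, recomb_rate * distance_mb)`.
#'
#' @param n_samples,n_markers sizes (>= 1).
#' @param chrom_map optional data.frame(`chrom`, `pos_mb`); defaults to
#'   [marker_map()].
#' @param recomb_rate recombination probability per Mb (default 0.01).
#' @param seed integer seed.
#' @return an object of class `"genotype_data"` with `design =
#'   "backcross"` and a markers x samples character matrix `geno` of
#'   codes `"A"`/`"H"`.
#' @export
generate_backcross_genotypes <- function(n_samples, n_markers,
                                         chrom_map = NULL,
                                         recomb_rate = 0.01, seed = 1) {
  n_samples <- check_scalar_int(n_samples, "n_samples", min = 1)
  n_markers <- check_scalar_int(n_markers, "n_markers", min = 1)
  if (is.null(chrom_map)) chrom_map <- marker_map(n_markers)
  if (nrow(chrom_map) != n_markers)
    stop2("`chrom_map` must have one row per marker")
  state <- withr::with_seed(seed, {
    g <- matrix(NA_integer_, n_markers, n_samples)
    for (chr in unique(chrom_map$chrom)) {
      idx <- which(chrom_map$chrom == chr)
      g[idx[1L], ] <- rbinom(n_samples, 1L, 0.5)
      for (i in seq_along(idx)[-1L]) {
        d <- abs(chrom_map$pos_mb[idx[i]] - chrom_map$pos_mb[idx[i - 1L]])
        r <- min(0.5, recomb_rate * d)
        flip <- rbinom(n_samples, 1L, r)
        g[idx[i], ] <- ifelse(flip == 1L, 1L - g[idx[i - 1L], ],
                              g[idx[i - 1L], ])
      }
    }
    g
  })
  geno <- matrix(c("A", "H")[state + 1L], n_markers, n_samples)
  marker_ids <- sprintf("m%04d", seq_len(n_markers))
  sample_ids <- sprintf("bc_s%04d", seq_len(n_samples))
  dimnames(geno) <- list(marker_ids, sample_ids)
  structure(list(marker_ids = marker_ids, sample_ids = sample_ids,
                 chrom = as.character(chrom_map$chrom),
                 pos_mb = as.numeric(chrom_map$pos_mb),
                 design = "backcross", geno = geno),
            class = "genotype_data")
}

#' Generate outbred (multi-founder) genotypes
#'
#' Each sample carries two founder haplotypes per chromosome, each a
#' Markov founder mosaic: the founder at the first marker is uniform over
#' founders, and at each subsequent marker the haplotype switches, with
#' probability `min(0.5, recomb_rate * distance_mb)`, to a founder drawn
#' uniformly from the other founders.  Founder dosages sum to 2 at every
#' (marker, sample).
#'
#' @inheritParams generate_backcross_genotypes
#' @param n_founders number of founder strains (>= 2; default 8).
#' @return an object of class `"genotype_data"` with `design = "outbred"`
#'   and a markers x samples x founders integer dosage array `dosage`.
#' @export
generate_outbred_genotypes <- function(n_samples, n_markers,
                                       n_founders = 8, chrom_map = NULL,
                                       recomb_rate = 0.01, seed = 1) {
  n_samples <- check_scalar_int(n_samples, "n_samples", min = 1)
  n_markers <- check_scalar_int(n_markers, "n_markers", min = 1)
  n_founders <- check_scalar_int(n_founders, "n_founders", min = 2)
  if (is.null(chrom_map)) chrom_map <- marker_map(n_markers)
  if (nrow(chrom_map) != n_markers)
    stop2("`chrom_map` must have one row per marker")
  haps <- withr::with_seed(seed, {
    h <- array(NA_integer_, c(n_markers, n_samples, 2L))
    for (chr in unique(chrom_map$chrom)) {
      idx <- which(chrom_map$chrom == chr)
      for (ph in 1:2) {
        h[idx[1L], , ph] <- sample.int(n_founders, n_samples, replace = TRUE)
        for (i in seq_along(idx)[-1L]) {
          d <- abs(chrom_map$pos_mb[idx[i]] - chrom_map$pos_mb[idx[i - 1L]])
          r <- min(0.5, recomb_rate * d)
          prev <- h[idx[i - 1L], , ph]
          switch_to <- 1L + (prev - 1L +
            sample.int(n_founders - 1L, n_samples, replace = TRUE)) %%
            n_founders
          sw <- rbinom(n_samples, 1L, r) == 1L
          h[idx[i], , ph] <- ifelse(sw, switch_to, prev)
        }
      }
    }
    h
  })
  dosage <- array(0L, c(n_markers, n_samples, n_founders))
  for (ph in 1:2) {
    idx <- cbind(rep(seq_len(n_markers), n_samples),
                 rep(seq_len(n_samples), each = n_markers),
                 as.vector(haps[, , ph]))
    dosage[idx] <- dosage[idx] + 1L
  }
  marker_ids <- sprintf("m%04d", seq_len(n_markers))
  sample_ids <- sprintf("do_s%04d", seq_len(n_samples))
  dimnames(dosage) <- list(marker_ids, sample_ids,
                           sprintf("F%d", seq_len(n_founders)))
  structure(list(marker_ids = marker_ids, sample_ids = sample_ids,
                 chrom = as.character(chrom_map$chrom),
                 pos_mb = as.numeric(chrom_map$pos_mb),
                 design = "outbred", n_founders = n_founders,
                 dosage = dosage),
            class = "genotype_data")
}

locus_carriers <- function(genotypes, locus) {
  if (locus$marker_index > length(genotypes$marker_ids))
    stop2("planted locus refers to a marker outside the map")
  if (genotypes$design == "backcross") {
    genotypes$geno[locus$marker_index, ] == "H"
  } else {
    if (is.null(locus$risk_founder))
      stop2("outbred planted locus needs a `risk_founder`")
    genotypes$dosage[locus$marker_index, , locus$risk_founder] > 0L
  }
}

#' Generate a genotype-driven unlabeled query cohort
#'
#' Per sample, a latent subtype is drawn from `base_probs` tilted by each
#' planted locus: for carriers of the risk genotype (backcross
#' heterozygote) or risk founder (outbred), the probability vector is
#' scaled by `1 - effect` and the freed `effect` mass moved onto the
#' target subtype (split evenly across a multi-label target set), so
#' `effect = 1` forces every carrier into the target subtype and
#' `effect = 0` leaves the prior untouched.  Expression is the latent
#' subtype's centroid plus Gaussian noise, then shifted by an affine
#' per-platform transform `value * scale + offset`.
#'
#' @param genotypes a `genotype_data` object; its samples become the
#'   cohort samples.
#' @param loci list of [planted_locus()] objects (possibly empty).
#' @param centroids a `centroid_set`.
#' @param base_probs probability vector over `centroids$labels`, summing
#'   to 1 (tolerance 1e-8).
#' @param platform_shift numeric `c(offset, scale)` affine platform
#'   effect; default `c(0, 1)`.
#' @param noise_sd nonnegative noise standard deviation.
#' @param platform_id platform/dataset tag.
#' @param seed integer seed.
#' @param species species tag, default `"mouse"`.
#' @return an object of class `"sim_cohort"`; `true_labels` records the
#'   latent truth.
#' @export
generate_query_cohort <- function(genotypes, loci, centroids, base_probs,
                                  platform_shift = c(0, 1), noise_sd = 1,
                                  platform_id = "query", seed = 1,
                                  species = "mouse") {
  stopifnot(inherits(genotypes, "genotype_data"),
            inherits(centroids, "centroid_set"))
  labels <- centroids$labels
  if (length(base_probs) != length(labels))
    stop2("`base_probs` must have one entry per subtype label")
  if (any(base_probs < 0) || abs(sum(base_probs) - 1) > 1e-8)
    stop2("`base_probs` must be nonnegative and sum to 1 (tolerance 1e-8)")
  noise_sd <- check_scalar_num(noise_sd, "noise_sd", min = 0)
  n <- length(genotypes$sample_ids)
  probs <- matrix(rep(as.numeric(base_probs), each = n), nrow = n)
  colnames(probs) <- labels
  for (locus in loci) {
    stopifnot(inherits(locus, "planted_locus"))
    tgt <- match(locus$target_subtype, labels)
    if (anyNA(tgt)) stop2("planted locus targets an unknown subtype label")
    carrier <- locus_carriers(genotypes, locus)
    probs[carrier, ] <- (1 - locus$effect) * probs[carrier, , drop = FALSE]
    probs[carrier, tgt] <- probs[carrier, tgt] +
      locus$effect / length(tgt)
  }
  probs <- probs / rowSums(probs)
  g <- nrow(centroids$centroids)
  values <- withr::with_seed(seed, {
    lab_idx <- vapply(seq_len(n), function(i) {
      sample.int(length(labels), 1L, prob = probs[i, ])
    }, integer(1))
    noise <- matrix(rnorm(g * n, sd = noise_sd), g, n)
    list(lab_idx = lab_idx,
         values = centroids$centroids[, lab_idx, drop = FALSE] + noise)
  })
  lab <- labels[values$lab_idx]
  mat <- values$values * platform_shift[2L] + platform_shift[1L]
  dimnames(mat) <- list(rownames(centroids$centroids), genotypes$sample_ids)
  new_cohort(mat, lab, species, platform_id, platform_id)
}

#' Generate metastasis status
#'
#' I.i.d. Bernoulli indicators, generated from randomness disjoint from
#' the subtype machinery, so metastasis is independent of subtype by
#' construction.
#'
#' @param n number of animals.
#' @param incidence metastasis probability in `[0, 1]`.
#' @param seed integer seed.
#' @return integer 0/1 vector of length `n`.
#' @export
generate_metastasis_status <- function(n, incidence, seed = 1) {
  n <- check_scalar_int(n, "n", min = 1)
  incidence <- check_scalar_num(incidence, "incidence", min = 0, max = 1)
  withr::with_seed(seed, rbinom(n, 1L, incidence))
}

#' Build a synthetic ortholog table
#'
#' Emits one-to-one pairs for retained panel genes, two partners for an
#' ambiguous fraction, and no pair for a missing fraction.  Partner
#' (second-species) identifiers are the panel identifiers suffixed
#' `"_ms"` (`"_ms2"` for the extra ambiguous partner).
#'
#' @param panel character vector of reference-species gene ids.
#' @param frac_ambiguous,frac_missing fractions in `[0, 1]`, summing to
#'   at most 1; counts are `round(frac * length(panel))`.
#' @param seed integer seed (selects which genes are ambiguous/missing).
#' @return data.frame with columns `gene_a` (reference species) and
#'   `gene_b`.
#' @export
build_ortholog_table <- function(panel, frac_ambiguous = 0,
                                 frac_missing = 0, seed = 1) {
  if (length(panel) < 1L) stop2("`panel` must be non-empty")
  frac_ambiguous <- check_scalar_num(frac_ambiguous, "frac_ambiguous", 0, 1)
  frac_missing <- check_scalar_num(frac_missing, "frac_missing", 0, 1)
  if (frac_ambiguous + frac_missing > 1)
    stop2("`frac_ambiguous + frac_missing` must be <= 1")
  n <- length(panel)
  n_amb <- round(frac_ambiguous * n)
  n_mis <- round(frac_missing * n)
  pick <- withr::with_seed(seed, sample.int(n, n_amb + n_mis))
  amb <- panel[pick[seq_len(n_amb)]]
  mis <- panel[pick[n_amb + seq_len(n_mis)]]
  keep <- setdiff(panel, mis)
  rows <- lapply(keep, function(g) {
    if (g %in% amb) {
      data.frame(gene_a = g, gene_b = paste0(g, c("_ms", "_ms2")),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene_a = g, gene_b = paste0(g, "_ms"),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
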