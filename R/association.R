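# Genome scans for loci associated with derived subtype calls: exact 2x2
# tests for backcross genotypes, founder-dosage F-tests for outbred
# designs, BH FDR control, and the subtype-metastasis independence test.

#' Binarize subtype calls into a case/control phenotype
#'
#' 1 for samples called into the target subtype set, 0 otherwise;
#' unassigned samples are excluded with a message reporting the count.
#'
#' @param calls data.frame(`sample_id`, `call`).
#' @param target non-empty character vector of target subtype labels
#'   (e.g. `"Basal"`, or `c("LumB", "Her2")` for a composite phenotype).
#' @return named integer 0/1 vector over the assigned samples.
#' @export
binarize_subtype <- function(calls, target) {
  if (length(target) < 1L) stop2("`target` must be non-empty")
  assigned <- !is.na(calls$call)
  if (!any(assigned)) stop2("all samples are unassigned")
  n_drop <- sum(!assigned)
  if (n_drop > 0L)
    message(sprintf("excluding %d unassigned sample(s) from phenotype",
                    n_drop))
  stats::setNames(as.integer(calls$call[assigned] %in% target),
                  calls$sample_id[assigned])
}

#' Two-sided exact test for a 2x2 table
#'
#' Conditions on both margins; the two-sided p-value is the sum of
#' hypergeometric point probabilities of all tables no more probable than
#' the observed one (relative tolerance 1e-12 on the comparison).
#'
#' @param tab 2x2 integer matrix of counts.
#' @return p-value in `(0, 1]`.
#' @export
exact_test_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L) || any(tab < 0) || any(tab != round(tab)))
    stop2("`tab` must be a 2x2 table of nonnegative counts")
  m <- sum(tab[1L, ])          # row-1 margin
  n <- sum(tab[2L, ])          # row-2 margin
  k <- sum(tab[, 1L])          # column-1 margin
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(tab[1L, 1L], m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Per-marker association for a backcross
#'
#' For every marker, a two-sided exact test on the 2x2 table of genotype
#' (homozygous/heterozygous) against the binary phenotype.  Monomorphic
#' markers get p = 1 and a flag.  The chi-square alternative (no
#' continuity correction) is available via `method`.
#'
#' @param g `genotype_data` with `design = "backcross"`.
#' @param y named 0/1 phenotype vector (names are sample ids present in
#'   `g`).
#' @param method `"exact"` (default) or `"chisq"`.
#' @return data.frame(`marker_id`, `p_value`, `direction`,
#'   `monomorphic`); `direction` is the genotype code with the higher
#'   case fraction.
#' @export
marker_association_backcross <- function(g, y, method = c("exact",
                                                          "chisq")) {
  stopifnot(inherits(g, "genotype_data"))
  if (g$design != "backcross") stop2("`g` must be a backcross design")
  method <- match.arg(method)
  ids <- intersect(g$sample_ids, names(y))
  if (length(ids) == 0L) stop2("phenotype and genotypes share no samples")
  y <- y[ids]
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L)
    stop2("need at least one case and one control")
  geno <- g$geno[, ids, drop = FALSE]
  res <- lapply(seq_along(g$marker_ids), function(m) {
    row <- geno[m, ]
    mono <- length(unique(row)) == 1L
    if (mono) return(list(p = 1, dir = NA_character_, mono = TRUE))
    tab2 <- cbind(H = c(sum(row == "H" & y == 1L),
                        sum(row == "H" & y == 0L)),
                  A = c(sum(row == "A" & y == 1L),
                        sum(row == "A" & y == 0L)))
    p <- if (method == "exact") {
      exact_test_2x2(tab2)
    } else {
      suppressWarnings(chisq.test(tab2, correct = FALSE)$p.value)
    }
    case_frac <- tab2[1L, ] / colSums(tab2)
    dir <- if (case_frac[["H"]] == case_frac[["A"]]) NA_character_
           else names(which.max(case_frac))
    list(p = p, dir = dir, mono = FALSE)
  })
  data.frame(marker_id = g$marker_ids,
             p_value = vapply(res, `[[`, numeric(1), "p"),
             direction = vapply(res, `[[`, character(1), "dir"),
             monomorphic = vapply(res, `[[`, logical(1), "mono"),
             stringsAsFactors = FALSE)
}

# Overall F-test of y ~ founder dosages (one founder dropped to absorb
# the sum-to-2 constraint), coded from the RSS decomposition.  Founder
# attribution uses per-founder marginal slopes: joint-model coefficients
# are unstable (aliased) when a founder dosage is confounded with the
# remaining founders under the sum-to-2 constraint.
founder_f_test <- function(X, y) {
  n <- length(y)
  slopes <- apply(X, 2L, function(col) {
    v <- stats::var(col)
    if (v == 0) 0 else stats::cov(col, y) / v
  })
  Xr <- X[, -ncol(X), drop = FALSE]
  keep <- apply(Xr, 2L, function(col) stats::var(col) > 0)
  Xr <- Xr[, keep, drop = FALSE]
  rss0 <- sum((y - mean(y))^2)
  if (ncol(Xr) == 0L || rss0 == 0)
    return(list(p = 1, slopes = slopes, flagged = TRUE))
  fit <- stats::lm.fit(cbind(1, Xr), y)
  rank1 <- fit$rank
  flagged <- rank1 < ncol(Xr) + 1L
  rss1 <- sum(fit$residuals^2)
  df1 <- rank1 - 1L
  df2 <- n - rank1
  if (df1 <= 0L || df2 <= 0L)
    return(list(p = 1, slopes = slopes, flagged = TRUE))
  fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  p <- pf(fstat, df1, df2, lower.tail = FALSE)
  p <- max(p, .Machine$double.xmin)   # keep p in (0, 1]
  list(p = p, slopes = slopes, flagged = flagged, fstat = fstat)
}

#' Per-marker founder-dosage association for an outbred design
#'
#' For every marker, the binary phenotype is regressed on the founder
#' dosage matrix (one founder column dropped, since dosages sum to 2);
#' the p-value is the overall F-test against the intercept-only model,
#' and the top founder is the founder with the largest marginal
#' regression slope of phenotype on its dosage (the attribution used to
#' color association peaks by founder strain; marginal slopes stay
#' well-defined even when the joint fit is rank-deficient).
#'
#' @param g `genotype_data` with `design = "outbred"`.
#' @param y named 0/1 phenotype vector.
#' @return data.frame(`marker_id`, `p_value`, `direction` (top founder),
#'   `monomorphic` (degenerate/rank-deficient flag)).
#' @export
marker_association_founder <- function(g, y) {
  stopifnot(inherits(g, "genotype_data"))
  if (g$design != "outbred") stop2("`g` must be an outbred design")
  ids <- intersect(g$sample_ids, names(y))
  if (length(ids) == 0L) stop2("phenotype and genotypes share no samples")
  y <- as.numeric(y[ids])
  if (stats::var(y) == 0) stop2("constant phenotype")
  founders <- dimnames(g$dosage)[[3L]]
  si <- match(ids, g$sample_ids)
  res <- lapply(seq_along(g$marker_ids), function(m) {
    X <- g$dosage[m, si, , drop = TRUE]
    ft <- founder_f_test(X, y)
    top <- founders[which.max(ft$slopes)]
    list(p = ft$p, dir = top, flag = ft$flagged)
  })
  data.frame(marker_id = g$marker_ids,
             p_value = vapply(res, `[[`, numeric(1), "p"),
             direction = vapply(res, `[[`, character(1), "dir"),
             monomorphic = vapply(res, `[[`, logical(1), "flag"),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} m p_(j) / j`, clipped at
#' 1, mapped back to input order.
#'
#' @param p vector of p-values in `(0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop2("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Genome scan for subtype-associated loci
#'
#' Dispatches to the design-appropriate per-marker test, applies
#' Benjamini-Hochberg FDR across all markers of the scan, and returns
#' results in natural genomic order (chromosome "2" before "10").
#'
#' @param g a `genotype_data` object (backcross or outbred).
#' @param y named 0/1 phenotype vector (from [binarize_subtype()]).
#' @param fdr_level FDR threshold for the `significant` flag (default
#'   0.05).
#' @param method per-marker test for backcross designs (see
#'   [marker_association_backcross()]).
#' @return data.frame(`marker_id`, `chrom`, `pos_mb`, `p_value`,
#'   `q_value`, `direction`, `monomorphic`, `significant`).
#' @export
genome_scan <- function(g, y, fdr_level = 0.05, method = "exact") {
  fdr_level <- check_scalar_num(fdr_level, "fdr_level", min = 0, max = 1)
  per <- if (g$design == "backcross") {
    marker_association_backcross(g, y, method = method)
  } else {
    marker_association_founder(g, y)
  }
  out <- data.frame(marker_id = g$marker_ids, chrom = g$chrom,
                    pos_mb = g$pos_mb, p_value = per$p_value,
                    q_value = bh_fdr(per$p_value),
                    direction = per$direction,
                    monomorphic = per$monomorphic,
                    stringsAsFactors = FALSE)
  out$significant <- out$q_value <= fdr_level
  out <- out[chrom_order(out$chrom), ]
  out <- out[order(match(out$chrom, unique(out$chrom)), out$pos_mb), ]
  rownames(out) <- NULL
  out
}

#' Test independence of subtype calls and metastasis
#'
#' Chi-square test of independence on the subtype x metastasis
#' contingency table over assigned samples.  When any expected cell count
#' falls below 5 the p-value is replaced by a seeded Monte-Carlo
#' permutation p (tables resampled conditional on the margins).
#'
#' @param calls data.frame(`sample_id`, `call`).
#' @param metastasis named 0/1 vector (`NA` allowed; such samples are
#'   dropped from this test only).
#' @param n_perm Monte-Carlo permutations for the small-count fallback
#'   (default 10000).
#' @param seed integer seed for the fallback.
#' @return list with `p_value`, `statistic`, `method` and `table`.
#' @export
subtype_metastasis_test <- function(calls, metastasis, n_perm = 10000,
                                    seed = 1) {
  met <- metastasis[match(calls$sample_id, names(metastasis))]
  ok <- !is.na(calls$call) & !is.na(met)
  tab <- table(subtype = calls$call[ok], metastasis = met[ok])
  if (nrow(tab) < 2L)
    stop2("need at least two subtype levels among assigned samples")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5)) {
    p <- withr::with_seed(seed, suppressWarnings(
      chisq.test(tab, simulate.p.value = TRUE, B = n_perm)$p.value))
    method <- "monte-carlo"
  } else {
    p <- ct$p.value
    method <- "chi-square"
  }
  list(p_value = p, statistic = unname(ct$statistic), method = method,
       table = tab)
}
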