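test_that("subtype binarization targets label sets and drops unassigned", {
  calls <- data.frame(sample_id = paste0("s", 1:4),
                      call = c("Basal", "LumA", "Basal", NA),
                      stringsAsFactors = FALSE)
  expect_message(y <- binarize_subtype(calls, "Basal"), "1 unassigned")
  expect_equal(unname(y), c(1L, 0L, 1L))
  expect_equal(names(y), paste0("s", 1:3))

  composite <- data.frame(sample_id = paste0("s", 1:3),
                          call = c("LumB", "Her2", "LumA"),
                          stringsAsFactors = FALSE)
  expect_equal(unname(binarize_subtype(composite, c("LumB", "Her2"))),
               c(1L, 1L, 0L))

  all_na <- data.frame(sample_id = "s1", call = NA_character_)
  expect_error(binarize_subtype(all_na, "Basal"), "unassigned")
})

test_that("exact 2x2 test agrees with fisher.test across all small tables", {
  # exhaustive sweep over every table with total n <= 12
  max_diff <- 0
  for (n in 2:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      tab <- matrix(c(a, c, b, d), 2, 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      p_mine <- exact_test_2x2(tab)
      p_ref <- fisher.test(tab)$p.value
      max_diff <- max(max_diff, abs(p_mine - min(1, p_ref)))
    }
  }
  expect_lt(max_diff, 1e-12)

  # perfectly separated table vs direct enumeration
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  expect_equal(exact_test_2x2(tab), 2 * 1 / choose(20, 10),
               tolerance = 1e-12)
  # modal balanced table: every table is at most as probable
  expect_equal(exact_test_2x2(matrix(5, 2, 2)), 1)
})

test_that("backcross scans flag monomorphic markers and report direction", {
  g <- generate_backcross_genotypes(60, 6, seed = 61)
  g$geno[3, ] <- "A"  # force monomorphic
  y <- setNames(rep(c(0L, 1L), 30), g$sample_ids)
  res <- marker_association_backcross(g, y)
  expect_equal(nrow(res), 6L)
  expect_true(res$monomorphic[3])
  expect_equal(res$p_value[3], 1)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))

  # direction points at the genotype with the higher case fraction
  g2 <- generate_backcross_genotypes(200, 1, seed = 62)
  carrier <- g2$geno[1, ] == "H"
  y2 <- setNames(as.integer(carrier), g2$sample_ids)
  set.seed(63)
  y2[sample(which(carrier), 20)] <- 0L  # imperfect but H-skewed
  res2 <- marker_association_backcross(g2, y2)
  expect_equal(res2$direction, "H")
  expect_error(marker_association_backcross(
    g2, setNames(rep(1L, 200), g2$sample_ids)), "case")
})

test_that("founder F statistic matches the normal-equations oracle", {
  g <- generate_outbred_genotypes(150, 12, n_founders = 8, seed = 71)
  set.seed(72)
  y <- setNames(rbinom(150, 1, 0.4), g$sample_ids)
  res <- marker_association_founder(g, y)
  for (m in c(1, 5, 12)) {
    X <- g$dosage[m, , ]
    Xr <- X[, -8]
    keep <- apply(Xr, 2, var) > 0
    f_oracle <- f_stat_by_hand(Xr[, keep], as.numeric(y))
    df1 <- sum(keep); df2 <- 150 - df1 - 1
    p_oracle <- pf(f_oracle, df1, df2, lower.tail = FALSE)
    expect_equal(res$p_value[m], p_oracle, tolerance = 1e-8)
  }
})

test_that("a planted founder wins the scan and is attributed correctly", {
  g <- generate_outbred_genotypes(120, 500, n_founders = 8, seed = 73)
  set.seed(74)
  y <- setNames(rbinom(120, 1, 0.3), g$sample_ids)
  # plant: founder 3 dosage 2 in all cases, 0 in all controls
  g$dosage[250, , ] <- 0L
  g$dosage[250, y == 1, 3] <- 2L
  g$dosage[250, y == 0, 1] <- 2L
  res <- marker_association_founder(g, y)
  expect_equal(which.min(res$p_value), 250L)
  expect_equal(res$direction[250], "F3")

  # constant dosages: degenerate guard
  g$dosage[100, , ] <- 0L
  g$dosage[100, , 2] <- 2L
  res2 <- marker_association_founder(g, y)
  expect_equal(res2$p_value[100], 1)
  expect_true(res2$monomorphic[100])

  expect_error(marker_association_founder(
    g, setNames(rep(0L, 120), g$sample_ids)), "constant")
})

test_that("BH q-values follow the step-up formula", {
  expect_equal(bh_fdr(0.05), 0.05)
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p), bh_by_hand(p))
  expect_equal(bh_fdr(p), rep(0.04, 4))  # hand-derived for this input

  set.seed(81)
  for (i in 1:10) {
    p <- runif(50)^2
    q <- bh_fdr(p)
    expect_equal(q, bh_by_hand(p), tolerance = 1e-14)
    expect_true(all(q <= 1))
    expect_true(all(q >= min(p) / 50))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 0)), "p-values")
  expect_error(bh_fdr(c(0.5, 1.2)), "p-values")
})

test_that("genome scans order results naturally and respect marker shuffles", {
  cm <- data.frame(chrom = c("10", "2", "2", "1"),
                   pos_mb = c(1, 10, 5, 50))
  g <- generate_backcross_genotypes(80, 4, chrom_map = cm, seed = 91)
  y <- setNames(rep(c(0L, 1L), 40), g$sample_ids)
  scan <- genome_scan(g, y)
  expect_equal(scan$chrom, c("1", "2", "2", "10"))
  expect_equal(scan$pos_mb, c(50, 5, 10, 1))

  # shuffling marker input order leaves the canonical result unchanged
  idx <- c(3, 1, 4, 2)
  g2 <- g
  g2$marker_ids <- g$marker_ids[idx]
  g2$chrom <- g$chrom[idx]
  g2$pos_mb <- g$pos_mb[idx]
  g2$geno <- g$geno[idx, ]
  rownames(g2$geno) <- g2$marker_ids
  scan2 <- genome_scan(g2, y)
  expect_equal(scan2[order(scan2$marker_id), names(scan)],
               scan[order(scan$marker_id), ],
               ignore_attr = TRUE)
})

test_that("null scans carry no association signal", {
  # effect = 0 at all loci: p-values are uniform (chi-square marker test,
  # well-separated markers, large n so discreteness is negligible)
  cents <- make_subtype_centroids(10, separation = 2, seed = 101)
  cm <- marker_map(500, n_chrom = 19, chrom_length_mb = 2000)
  g <- generate_backcross_genotypes(2000, 500, chrom_map = cm, seed = 102)
  q <- generate_query_cohort(g, list(), cents, rep(0.2, 5), seed = 103)
  y <- setNames(as.integer(q$true_labels == "Basal"),
                names(q$true_labels))
  res <- marker_association_backcross(g, y, method = "chisq")
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("chi-square statistic matches the direct formula", {
  set.seed(111)
  tab <- matrix(rpois(10, 20) + 5, 5, 2)
  calls <- data.frame(
    sample_id = paste0("s", seq_len(sum(tab))),
    call = rep(rep(paste0("T", 1:5), 2), as.vector(tab)),
    stringsAsFactors = FALSE)
  met <- setNames(rep(rep(c(0L, 1L), each = 5), as.vector(tab)),
                  calls$sample_id)
  out <- subtype_metastasis_test(calls, met)
  expect_equal(out$statistic, chisq_stat_by_hand(table(calls$call, met)),
               tolerance = 1e-10)

  # proportional rows: statistic 0, p = 1
  prop_calls <- data.frame(sample_id = paste0("p", 1:40),
                           call = rep(c("A", "B"), each = 20),
                           stringsAsFactors = FALSE)
  prop_met <- setNames(rep(c(0L, 1L), 20), prop_calls$sample_id)
  out2 <- subtype_metastasis_test(prop_calls, prop_met)
  expect_equal(out2$statistic, 0)
  expect_equal(out2$p_value, 1)

  one_level <- data.frame(sample_id = c("a", "b"), call = c("A", "A"))
  expect_error(subtype_metastasis_test(
    one_level, setNames(c(0L, 1L), c("a", "b"))), "two subtype")
})

test_that("small expected counts trigger the seeded permutation fallback", {
  calls <- data.frame(sample_id = paste0("s", 1:12),
                      call = rep(c("A", "B", "C"), each = 4),
                      stringsAsFactors = FALSE)
  met <- setNames(rep(c(0L, 1L), 6), calls$sample_id)
  out <- subtype_metastasis_test(calls, met, n_perm = 2000, seed = 7)
  expect_equal(out$method, "monte-carlo")
  out2 <- subtype_metastasis_test(calls, met, n_perm = 2000, seed = 7)
  expect_identical(out$p_value, out2$p_value)
})
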