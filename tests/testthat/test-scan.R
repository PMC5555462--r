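test_that("strain means are log2 means with parentals excluded", {
  ph <- make_phenos(list("AcB01|baseline" = c(4, 16),
                         "BcA01|baseline" = c(8, 8),
                         "A/J|baseline" = c(2, 2),
                         "CSS4|baseline" = c(2, 2)))
  y <- strain_means(ph, "baseline")
  expect_equal(sort(names(y)), c("AcB01", "BcA01"))
  expect_equal(unname(y["AcB01"]), 3.0)
  expect_warning(y2 <- strain_means(ph, "OVA-OVA"), "no records")
  expect_length(y2, 0)
})

test_that("fit_marker equals the pooled two-sample t-test on a toy vector", {
  y <- c(1, 2, 3, 11, 12, 13)
  g <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_marker(y, g)
  oracle <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)
  expect_equal(fit$beta, 10.0)
  expect_equal(fit$p, oracle$p.value)
  expect_equal(fit$t_stat, unname(oracle$statistic))
  expect_equal(fit$neg_log10_p, -log10(fit$p))
  expect_equal(fit$n_used, 6)
  # allele characters code A = 1, B = 0
  fit_chr <- fit_marker(y, c("B", "B", "B", "A", "A", "A"))
  expect_equal(fit_chr$beta, fit$beta)
})

test_that("monomorphic and thin markers are skipped with a reason", {
  y <- rnorm(8)
  mono <- fit_marker(y, rep(1, 8))
  expect_true(mono$skipped)
  expect_equal(mono$reason, "monomorphic")
  expect_true(is.na(mono$p))
  thin <- fit_marker(y, c(1, 1, rep(0, 6)))
  expect_true(thin$skipped)
  expect_equal(thin$reason, "insufficient class size")
  # H and missing calls are dropped before class counting
  het <- fit_marker(c(y, 0), c("A", "A", "A", "B", "B", "B", "H", NA, "A"))
  expect_equal(het$n_used, 7)
})

test_that("fit_marker is exchangeable over strain order", {
  set.seed(41)
  y <- rnorm(10)
  g <- rep(c(0, 1), 5)
  ord <- sample(10)
  expect_equal(fit_marker(y[ord], g[ord]), fit_marker(y, g))
})

test_that("regression p equals the pooled t-test p on random instances", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    g <- c(rep(1, 3), rep(0, 3), rbinom(n - 6, 1, runif(1, 0.2, 0.8)))
    y <- rnorm(n, mean = g * runif(1, 0, 2))
    fit <- fit_marker(y, g)
    oracle <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)$p.value
    expect_lt(abs(fit$p - oracle) / oracle, 1e-12)
  }
})

test_that("scan_genome returns one aligned row per marker, deterministically", {
  fix <- shared_small()
  ph <- simulate_phenotypes(fix$panel, qtl_spec(), n_per_strain = 6,
                            seed = 91)
  y <- strain_means(ph, "baseline")
  sc <- scan_genome(y, fix$panel, fix$map)
  expect_s3_class(sc, "scan_result")
  expect_equal(nrow(sc), nrow(fix$map))
  expect_identical(sc$marker_id, fix$map$id)
  expect_equal(sc$neg_log10_p[!sc$skipped],
               -log10(sc$p[!sc$skipped]))
  expect_true(all(sc$p[!sc$skipped] > 0 & sc$p[!sc$skipped] <= 1))
  expect_identical(sc, scan_genome(y, fix$panel, fix$map))
  names(y)[1] <- "ghost"
  expect_error(scan_genome(y, fix$panel, fix$map), "ghost")
})

test_that("quantile rule is the ceiling-order-statistic convention", {
  expect_equal(quantile_rule(sample(1:100), 0.95), 95)
  expect_equal(quantile_rule(c(3, 1, 2), 1), 3)
  expect_equal(quantile_rule(c(3, 1, 2), 0), 1)
  expect_error(quantile_rule(numeric(0), 0.5), "empty")
  expect_error(quantile_rule(1:5, 1.2), "q must")
  set.seed(43)
  draws <- rnorm(10000)
  expect_equal(quantile_rule(draws, 0.95), sort(draws)[9500])
})

test_that("permutation thresholds are seeded, monotone in alpha, and label-free", {
  fix <- shared_small()
  ph <- simulate_phenotypes(fix$panel, qtl_spec(), n_per_strain = 6,
                            seed = 92)
  y <- strain_means(ph, "baseline")
  thr5 <- permutation_threshold(y, fix$panel, fix$map, alpha = 0.05,
                                n_perm = 200, seed = 7)
  thr5b <- permutation_threshold(y, fix$panel, fix$map, alpha = 0.05,
                                 n_perm = 200, seed = 7)
  expect_equal(thr5$threshold_neg_log10, thr5b$threshold_neg_log10)
  thr1 <- permutation_threshold(y, fix$panel, fix$map, alpha = 0.01,
                                n_perm = 200, seed = 7)
  expect_gte(thr1$threshold_neg_log10, thr5$threshold_neg_log10)
  # alpha = 1 gives the smallest permutation maximum: everything passes
  thr_all <- permutation_threshold(y, fix$panel, fix$map, alpha = 1,
                                   n_perm = 200, seed = 7)
  expect_lte(thr_all$threshold_neg_log10, thr5$threshold_neg_log10)
  # strain names are labels only: renaming them consistently in the
  # response and the panel leaves the threshold bit-identical
  relabel <- stats::setNames(paste0("S", seq_len(nrow(fix$panel$geno))),
                             rownames(fix$panel$geno))
  y2 <- stats::setNames(y, relabel[names(y)])
  panel2 <- fix$panel
  rownames(panel2$geno) <- relabel[rownames(panel2$geno)]
  names(panel2$family) <- relabel[names(panel2$family)]
  names(panel2$minor_fraction) <- relabel[names(panel2$minor_fraction)]
  thr_rel <- permutation_threshold(y2, panel2, fix$map, alpha = 0.05,
                                   n_perm = 200, seed = 7)
  expect_equal(thr_rel$threshold_neg_log10, thr5$threshold_neg_log10)
  expect_error(permutation_threshold(y, fix$panel, fix$map, alpha = 2),
               "alpha")
  expect_error(permutation_threshold(y, fix$panel, fix$map, n_perm = 50),
               "n_perm")
})

test_that("threshold sets report both scales consistently", {
  th <- threshold_set(3.498, condition = "baseline", n_perm = 10000)
  expect_equal(th$threshold_p, 10^(-th$threshold_neg_log10))
  expect_output(print(th), "baseline")
})

test_that("regions are maximal significant runs bounded by marker positions", {
  # toy scan over chromosome 4 mirroring a two-marker significant run
  mk <- data.frame(
    marker_id = sprintf("c4_%d", 1:5), chr = "4",
    pos_mbp = c(70.00, 81.46, 86.17, 95.00, 101.00),
    beta = 1, se = 1, t_stat = 1,
    p = c(0.5, 1e-5, 3e-5, 0.2, 0.9),
    neg_log10_p = -log10(c(0.5, 1e-5, 3e-5, 0.2, 0.9)),
    n_used = 31, skipped = FALSE, reason = NA_character_,
    stringsAsFactors = FALSE)
  class(mk) <- c("scan_result", "data.frame")
  thr <- threshold_set(3.5, condition = "baseline")
  reg <- call_regions(mk, thr)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start_mbp, 81.46)
  expect_equal(reg$end_mbp, 86.17)
  expect_equal(reg$peak_marker, "c4_2")
  expect_equal(reg$peak_p, 1e-5)
  expect_equal(reg$condition, "baseline")
  expect_lte(reg$peak_p, thr$threshold_p)

  # nothing significant: empty frame
  none <- mk; none$p[] <- 0.5
  expect_equal(nrow(call_regions(none, thr)), 0)

  # significant markers on two chromosomes never merge
  two <- mk
  two$chr <- c("4", "4", "4", "5", "5")
  two$p <- c(1e-5, 0.5, 0.5, 0.5, 1e-5)
  regs <- call_regions(two, thr)
  expect_equal(nrow(regs), 2)
  expect_setequal(regs$chr, c("4", "5"))
  expect_equal(regs$start_mbp, regs$end_mbp)  # single-marker regions

  # skipped markers are transparent inside a run
  sk <- mk
  sk$p <- c(0.9, 1e-5, 0.5, 1e-5, 0.9)
  sk$skipped <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  reg_sk <- call_regions(sk, thr)
  expect_equal(nrow(reg_sk), 1)
  expect_equal(c(reg_sk$start_mbp, reg_sk$end_mbp), c(81.46, 95.00))

  # gap = 1 bridges a single interior non-significant marker
  gap <- mk
  gap$p <- c(0.9, 1e-5, 0.5, 1e-5, 0.9)
  expect_equal(nrow(call_regions(gap, thr)), 2)
  bridged <- call_regions(gap, thr, gap = 1)
  expect_equal(nrow(bridged), 1)
  expect_equal(c(bridged$start_mbp, bridged$end_mbp), c(81.46, 95.00))
})

test_that("region calling is idempotent under per-chromosome splitting", {
  fix <- shared_small()
  mk4 <- fix$map$id[fix$map$chr == "4"][2]
  q <- qtl_spec(effects = data.frame(marker_id = mk4, effect = 2))
  ph <- simulate_phenotypes(fix$panel, q, n_per_strain = 8, seed = 93)
  y <- strain_means(ph, "baseline")
  sc <- scan_genome(y, fix$panel, fix$map)
  thr <- permutation_threshold(y, fix$panel, fix$map, n_perm = 300,
                               seed = 8, condition = "baseline")
  all_at_once <- call_regions(sc, thr)
  by_chr <- do.call(rbind, lapply(unique(sc$chr), function(ch) {
    sub <- sc[sc$chr == ch, ]
    class(sub) <- class(sc)
    call_regions(sub, thr)
  }))
  rownames(by_chr) <- NULL
  expect_equal(as.data.frame(all_at_once), as.data.frame(by_chr))
  # every marker inside each region is significant (gap = 0 soundness)
  for (r in seq_len(nrow(all_at_once))) {
    inside <- sc$chr == all_at_once$chr[r] & !sc$skipped &
      sc$pos_mbp >= all_at_once$start_mbp[r] &
      sc$pos_mbp <= all_at_once$end_mbp[r]
    expect_true(all(sc$p[inside] <= thr$threshold_p))
  }
})

test_that("the genome-wide peak localizes to a planted QTL's chromosome", {
  # a strong QTL also separates the two family backgrounds, which lifts
  # association genome-wide; the strongest signal must still sit on the
  # planted chromosome in the majority of replicates
  map <- default_marker_map()
  mk <- "m4_039"
  hits <- vapply(1:60, function(i) {
    panel <- breed_rcs_panel(breeding_config(seed = 3000 + i), map)
    q <- qtl_spec(effects = data.frame(marker_id = mk, effect = 1.5))
    ph <- simulate_phenotypes(panel, q, n_per_strain = 10,
                              conditions = "baseline", seed = 3000 + i)
    y <- strain_means(ph, "baseline")
    sc <- scan_genome(y, panel, map)
    sc$chr[which.min(sc$p)] == "4"
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})
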