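# Fate assignment, differential expression and the threshold sweep.

make_fate_table <- function(cm, terminated_lines = character()) {
  est <- data.frame(sample = sprintf("L%03d", seq_along(cm)), CM = cm,
                    EPDC = 1 - cm, SC = 0, residual_norm = 0,
                    n_markers_used = 10, stringsAsFactors = FALSE)
  class(est) <- c("fraction_estimates", "data.frame")
  assign_outcome(est, terminated_lines)
}

test_that("outcome assignment follows the 0:100 and >= threshold conventions", {
  ft <- make_fate_table(c(0.30, 0.299, 0.9), terminated_lines = "T001")
  expect_equal(ft$cm_fraction[ft$line == "T001"], 0)
  expect_true(ft$terminated[ft$line == "T001"])
  lab30 <- fate_at_threshold(ft, 0.3)
  expect_equal(unname(lab30[c("L001", "L002", "L003", "T001")]),
               c("CM", "EPDC", "CM", "EPDC"))
  # a terminated line is EPDC-fated at every positive threshold
  for (k in seq(0.1, 0.9, 0.2)) {
    expect_equal(unname(fate_at_threshold(ft, k)["T001"]), "EPDC")
  }
  est <- data.frame(sample = "L001", CM = 0.5, EPDC = 0.5, SC = 0,
                    residual_norm = 0, n_markers_used = 1)
  class(est) <- c("fraction_estimates", "data.frame")
  expect_error(assign_outcome(est, "L001"), "duplicate")
})

test_that("the t statistic and p-value match brute-force formula evaluation", {
  # one gene, two 5-sample groups; Welch formulas written out by hand
  v1 <- c(5.1, 4.8, 5.5, 5.0, 4.9)
  v2 <- c(6.2, 6.0, 5.8, 6.5, 6.1)
  expr <- matrix(2^c(v1, v2) - 1, nrow = 1,
                 dimnames = list("g1", sprintf("s%d", 1:10)))
  de <- differential_expression(expr, rep(c("CM", "EPDC"), each = 5))
  s1 <- sum((v1 - mean(v1))^2) / 4
  s2 <- sum((v2 - mean(v2))^2) / 4
  t_oracle <- (mean(v1) - mean(v2)) / sqrt(s1 / 5 + s2 / 5)
  df_oracle <- (s1 / 5 + s2 / 5)^2 /
    ((s1 / 5)^2 / 4 + (s2 / 5)^2 / 4)
  p_oracle <- 2 * pt(abs(t_oracle), df_oracle, lower.tail = FALSE)
  expect_equal(de$t, t_oracle, tolerance = 1e-10)
  expect_equal(de$p, p_oracle, tolerance = 1e-10)
  expect_equal(de$mean_diff, mean(v1) - mean(v2), tolerance = 1e-10)
  expect_error(differential_expression(expr, c(rep("CM", 2), rep("EPDC", 8))),
               ">= 3")
})

test_that("differential expression has power on planted shifts", {
  recovered <- vapply(1:20, function(s) {
    d <- planted_de_matrix(n_genes = 500, n1 = 60, n2 = 30, n_shift = 50,
                           shift = 2, seed = 200 + s)
    de <- differential_expression(d$expr, d$labels, q_cut = 0.1)
    sum(de$significant & de$gene %in% d$shifted)
  }, numeric(1))
  expect_gte(mean(recovered), 45)
})

test_that("threshold sweep finds the planted partition and keeps books", {
  pr <- tiny_profiles(n_genes = 600, n_markers = 10)
  co <- simulate_ipsc_cohort(n_lines = 184, n_terminated = 37, profiles = pr,
                             n_signature = 60, effect_size = 1.5, seed = 31)
  f <- co$true_fractions[, "CM"]
  f[co$metadata$terminated] <- 0
  ft <- make_fate_table(f, character())
  ft$line <- co$metadata$line
  expr <- co$ipsc_expr
  colnames(expr) <- co$metadata$line
  sw <- threshold_sweep(expr, ft, q_cut = 0.1, n_perm = 20, seed = 32)
  expect_equal(sw$best_threshold, 0.3)
  expect_true(all(sw$de_counts >= 0))
  expect_lte(sw$strongest_at_best, length(sw$de_gene_union))
  expect_true(sw$best_threshold %in% sw$thresholds)
  # observed count far above the permutation null
  expect_gt(sw$de_counts[as.character(sw$best_threshold)],
            max(sw$null_counts))

  # invariance to sample and gene ordering
  perm_s <- withr::with_seed(33, sample(ncol(expr)))
  perm_g <- withr::with_seed(34, sample(nrow(expr)))
  ft2 <- ft[perm_s, ]
  sw2 <- threshold_sweep(expr[perm_g, ], ft2, q_cut = 0.1, n_perm = 2,
                         seed = 1)
  expect_equal(sw2$de_counts, sw$de_counts)
  expect_equal(sw2$best_threshold, sw$best_threshold)
  expect_setequal(sw2$de_gene_union, sw$de_gene_union)
})

test_that("degenerate thresholds are skipped and all-skipped is an error", {
  ft <- make_fate_table(c(rep(0.9, 20), rep(0.1, 20)))
  expr <- planted_de_matrix(n_genes = 50, n1 = 20, n2 = 20, seed = 9)$expr
  colnames(expr) <- ft$line
  sw <- threshold_sweep(expr, ft, thresholds = c(0, 0.5, 0.95), n_perm = 2,
                        seed = 1)
  # 0 and 0.95 leave an empty class -> only 0.5 is testable
  expect_equal(sw$thresholds, 0.5)
  expect_setequal(sw$skipped, c(0, 0.95))
  expect_error(threshold_sweep(expr, ft, thresholds = c(0, 0.99), n_perm = 2,
                               seed = 1),
               "skipped")
})

test_that("strongest-p bookkeeping counts minima at the selected threshold", {
  p <- matrix(c(0.001, 0.01,
                0.02,  0.005,
                0.003, 0.004), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("0.3", "0.5")))
  res <- strongest_fraction(p, "0.3")
  expect_equal(res$count, 2)        # genes a and c
  expect_equal(res$pct, 66.7)
})

test_that("signature finalisation applies the borderline pathway rule", {
  d <- data.frame(gene = c("sig1", "bord1", "bord2", "null1"),
                  t = c(5, 3, 3, 0.1),
                  p = c(1e-8, 0.001, 0.001, 0.9),
                  q = c(1e-5, 0.2, 0.2, 0.95),
                  mean_diff = c(2, 1, -1, 0.1),
                  significant = c(TRUE, FALSE, FALSE, FALSE))
  sweep <- structure(list(de_best = d), class = "sweep_result")
  ann <- list(bord1 = "WNT", bord2 = character())
  sig <- finalize_signature(sweep, borderline_p = 0.0015,
                            pathway_annotations = ann)
  expect_setequal(sig$gene, c("sig1", "bord1"))  # bord2 lacks an annotation
  expect_equal(sig$direction[sig$gene == "bord1"], 1)
  expect_true(sig$borderline[sig$gene == "bord1"])
  # without borderline candidates the signature is the q-significant set
  sig0 <- finalize_signature(sweep, borderline_p = 0.0015)
  expect_equal(sig0$gene, "sig1")
})

test_that("completion percentage matches the worked arithmetic", {
  s <- differentiation_summary(rep(c(FALSE, TRUE), c(193, 39)))
  expect_equal(s$n_total, 232)
  expect_equal(s$pct_completed, 83.2)
})
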