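# The synthetic cohort generator: planted-truth invariants, determinism,
# and the stated error conditions.

test_that("reference profiles satisfy the marker invariants", {
  pr <- simulate_reference_profiles(n_genes = 3000, n_populations = 3,
                                    n_markers_per_pop = 50, fold_change = 8,
                                    seed = 1)
  markers <- unlist(pr$marker_map)
  expect_length(markers, 150)
  expect_equal(anyDuplicated(markers), 0)   # disjoint across populations
  expect_true(all(pr$mean_expr >= 0))
  for (k in pr$populations) {
    mk <- pr$marker_map[[k]]
    own <- pr$mean_expr[mk, k]
    other <- pr$mean_expr[mk, setdiff(pr$populations, k), drop = FALSE]
    expect_true(all(own / apply(other, 1, max) >= 8 - 1e-9))
  }
  # single population: no overlap constraint applies
  pr1 <- simulate_reference_profiles(n_genes = 100, n_populations = 1,
                                     n_markers_per_pop = 5, seed = 2)
  expect_length(pr1$marker_map, 1)
  expect_error(simulate_reference_profiles(n_genes = 10, n_populations = 3,
                                           n_markers_per_pop = 4),
               "capacity")
  expect_error(simulate_reference_profiles(fold_change = 1), "fold_change")
})

test_that("bulk mixtures are exact at zero noise and recoverable by least squares", {
  pr <- tiny_profiles()
  pure <- simulate_bulk_mixtures(pr, matrix(c(1, 0, 0), 1), noise_sd = 0)
  expect_equal(unname(pure[, 1]), unname(pr$mean_expr[, "CM"]))
  half <- simulate_bulk_mixtures(pr, matrix(c(0.5, 0.5, 0), 1), noise_sd = 0)
  expect_equal(unname(half[, 1]),
               unname((pr$mean_expr[, 1] + pr$mean_expr[, 2]) / 2))
  # closed-form least-squares oracle on the noiseless design
  mix <- simulate_bulk_mixtures(pr, matrix(c(0.3, 0.7, 0), 1), noise_sd = 0)
  beta <- qr.solve(pr$mean_expr, mix[, 1])
  expect_equal(unname(beta), c(0.3, 0.7, 0), tolerance = 1e-9)
  expect_error(simulate_bulk_mixtures(pr, matrix(c(0.5, 0.2, 0.1), 1)),
               "sum to 1")
})

test_that("cohort generator emits coherent planted truth", {
  pr <- tiny_profiles()
  co <- simulate_ipsc_cohort(n_lines = 60, n_terminated = 12, profiles = pr,
                             seed = 5)
  expect_s3_class(co, "synthetic_cohort")
  expect_equal(unname(rowSums(co$true_fractions)), rep(1, 60),
               tolerance = 1e-9)
  # terminated lines have no derived-sample column
  term <- co$metadata$line[co$metadata$terminated]
  expect_length(term, 12)
  expect_false(any(term %in% colnames(co$cvpc_expr)))
  expect_equal(ncol(co$cvpc_expr), 48)
  # cTnT tracks the true CM fraction by construction
  comp <- !co$metadata$terminated
  expect_gt(cor(co$metadata$cTnT_pct[comp],
                co$true_fractions[comp, "CM"]), 0.8)
  # 91 signature genes split 36 positive / 55 negative
  co91 <- simulate_ipsc_cohort(n_lines = 40, n_terminated = 5, profiles = pr,
                               n_signature = 91, seed = 6)
  expect_equal(sum(co91$signature_truth$sign == 1), 36)
  expect_equal(sum(co91$signature_truth$sign == -1), 55)
  expect_error(simulate_ipsc_cohort(xi_mix = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("generators are bit-reproducible for a fixed seed", {
  pr <- tiny_profiles()
  expect_identical(tiny_profiles(seed = 9), tiny_profiles(seed = 9))
  expect_identical(simulate_ipsc_cohort(n_lines = 30, n_terminated = 5,
                                        profiles = pr, seed = 4),
                   simulate_ipsc_cohort(n_lines = 30, n_terminated = 5,
                                        profiles = pr, seed = 4))
  g <- simulate_genotypes(20, 50, seed = 8)
  expect_identical(g, simulate_genotypes(20, 50, seed = 8))
})

test_that("null cohorts carry no differential signal", {
  pr <- tiny_profiles(n_genes = 600, n_markers = 10)
  co <- simulate_ipsc_cohort(n_lines = 80, n_terminated = 16, profiles = pr,
                             effect_size = 0, seed = 3)
  f <- co$true_fractions[, "CM"]
  f[co$metadata$terminated] <- 0
  lab <- ifelse(f >= 0.3, "CM", "EPDC")
  de <- differential_expression(co$ipsc_expr, lab)
  expect_lte(sum(de$significant), 3)
  # p-values are uniform under the global null
  expect_gt(ks.test(de$p, "punif")$p.value, 0.01)
})

test_that("clone pairs share the latent fate when correlation is 1", {
  pr <- tiny_profiles()
  co <- simulate_ipsc_cohort(n_lines = 40, n_terminated = 0, profiles = pr,
                             clone_pairs = 5, clone_correlation = 1,
                             seed = 12)
  tf <- co$true_fractions
  latent <- tf[, "CM"] / (tf[, "CM"] + tf[, "EPDC"])  # inverts the sc scaling
  for (i in 1:5) {
    expect_equal(unname(latent[2 * i - 1]), unname(latent[2 * i]),
                 tolerance = 1e-12)
    expect_equal(co$metadata$subject[2 * i - 1], co$metadata$subject[2 * i])
  }
})

test_that("allele-count generator reflects the planted X-inactivation states", {
  pr <- tiny_profiles()
  co <- simulate_ipsc_cohort(n_lines = 40, n_terminated = 5, profiles = pr,
                             pct_female = 1,
                             xi_mix = c(XaXa = 0.5, XaXi = 0.5, mosaic = 0),
                             seed = 21)
  counts <- simulate_ase_counts(co, depth = 1000, seed = 22)
  gi <- attr(counts, "gene_info")
  nonesc <- gi$gene[gi$chrom == "chrX" & !gi$escape]
  xaxi <- co$xi_truth$line[co$xi_truth$state == "XaXi"][1]
  sub <- counts[counts$sample == xaxi & counts$gene %in% nonesc, ]
  aif <- pmax(sub$ref_count, sub$alt_count) / (sub$ref_count + sub$alt_count)
  expect_true(all(aif > 0.95))  # binomial tail at skew 0.99, depth 1000
  auto <- counts[counts$chrom == "chr1", ]
  aif_a <- pmax(auto$ref_count, auto$alt_count) /
    (auto$ref_count + auto$alt_count)
  expect_lt(abs(mean(aif_a) - 0.5), 0.1)
  expect_error(simulate_ase_counts(co, depth = 0), "depth")
  expect_error(simulate_ase_counts(co, escape_fraction = 1.5), "escape")
})

test_that("genotype dosages follow Hardy-Weinberg proportions", {
  g <- simulate_genotypes(400, 200, maf_range = c(0.5, 0.5), seed = 2)
  expect_true(all(g$dosages %in% 0:2))
  expect_equal(mean(g$dosages), 1, tolerance = 0.05)  # HWE symmetry at MAF 0.5
  expect_error(simulate_genotypes(10, 0), "n_variants")
  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.6)), "maf_range")
  # causal effect is only applied through the explicit helper
  gc <- simulate_genotypes(50, 20, causal = list(variant = 3, beta = 0.2),
                           seed = 3)
  y <- rep(0.5, 50)
  expect_equal(apply_causal_effect(gc, y),
               y + 0.2 * gc$dosages[3, ], ignore_attr = TRUE)
})
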