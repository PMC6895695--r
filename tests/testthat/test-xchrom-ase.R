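# Allelic imbalance fractions, PAR masking and X-inactivation tests.

test_that("AIF arithmetic, coverage filter and swap invariance are exact", {
  counts <- ase_rows(c("a", "b", "c"), "chrX", c(3e6, 4e6, 5e6), "s1",
                     ref = c(50, 99, 3), alt = c(50, 1, 2))
  tab <- compute_aif(counts, min_coverage = 20)
  expect_equal(tab$aif[tab$gene == "a"], 0.5)
  expect_equal(tab$aif[tab$gene == "b"], 0.99)
  expect_false("c" %in% tab$gene)          # 5 reads < 20 dropped
  expect_equal(attr(tab, "n_dropped"), 1)
  # ref/alt swap invariance
  swapped <- counts
  swapped$ref_count <- counts$alt_count
  swapped$alt_count <- counts$ref_count
  expect_equal(compute_aif(swapped, 20)$aif, tab$aif)
  neg <- counts; neg$ref_count[1] <- -1
  expect_error(compute_aif(neg), "negative")
})

test_that("PAR masking excludes exactly the overlapping chrX genes", {
  # 20-gene fixture spanning PAR1 (60,001-2,699,520), the PAR1 boundary,
  # the body of chrX, PAR2 (154,931,044-155,260,560), and an autosome
  starts <- c(100000, 2699520, 2700000, seq(5e6, 1.4e8, length.out = 13),
              154931000, 155000000, 200000, 100000)
  chrom <- c(rep("chrX", 18), "chr5", "chr5")
  genes <- sprintf("G%02d", 1:20)
  counts <- ase_rows(genes, chrom, round(starts), "s1",
                     ref = rep(30, 20), alt = rep(30, 20))
  tab <- mask_par(compute_aif(counts, 20))
  # inside PAR1; straddling the PAR1 end; inside/overlapping PAR2
  expect_setequal(tab$gene[tab$is_par], c("G01", "G02", "G17", "G18"))
  # just beyond the PAR1 boundary is kept
  expect_false(tab$is_par[tab$gene == "G03"])
  # autosomal genes untouched even at PAR-like coordinates
  expect_false(any(tab$is_par[tab$chrom == "chr5"]))
  expect_error(mask_par(tab, par1 = c(100, 50)), "malformed")
})

test_that("planted XaXi and XaXa groups separate on chrX but not autosomes", {
  pr <- tiny_profiles()
  co <- simulate_ipsc_cohort(n_lines = 30, n_terminated = 0, profiles = pr,
                             pct_female = 1,
                             xi_mix = c(0.5, 0.5, 0), seed = 61)
  counts <- simulate_ase_counts(co, depth = 200, seed = 62)
  tab <- mask_par(compute_aif(counts, 20))
  grouping <- setNames(co$xi_truth$state, co$xi_truth$line)
  res <- compare_aif_groups(tab, grouping, scope = "chrX")
  expect_lt(res$p, 1e-4)
  expect_gt(res$group_medians[["XaXi"]], res$group_medians[["XaXa"]])
  # autosomal scope carries no signal
  res_a <- compare_aif_groups(tab, grouping, scope = "autosomes")
  expect_gt(res_a$p, 1e-3)
  # copied groups (identical values) sit at the null center
  four <- co$xi_truth$line[1:4]
  dup <- tab[tab$sample %in% four, ]
  dup2 <- rbind(as.data.frame(dup),
                transform(dup, sample = paste0(sample, "x")))
  class(dup2) <- class(tab)
  same2 <- c(setNames(rep("A", 4), four),
             setNames(rep("B", 4), paste0(four, "x")))
  res_same <- compare_aif_groups(dup2, same2, scope = "chrX")
  expect_gt(res_same$p, 0.9)
  expect_error(compare_aif_groups(tab, setNames(c("A", "B"), c("zz", "yy")),
                                  scope = "chrX"),
               "empty|two groups")
})

test_that("regional AIF differences localise planted reactivation", {
  hits <- 0
  for (s in 1:5) {
    # two groups of 8 female lines; reactivation planted only in 2.8-40 Mb
    n_genes <- 40
    starts <- round(seq(3e6, 1.5e8, length.out = n_genes))
    lines <- sprintf("F%02d", 1:16)
    rows <- list()
    withr::with_seed(900 + s, {
      for (i in seq_along(lines)) {
        in_region <- starts < 4e7
        balanced <- if (i <= 8) in_region else rep(FALSE, n_genes)
        p_ref <- ifelse(balanced, 0.5, 0.99)
        tot <- rpois(n_genes, 200)
        ref <- rbinom(n_genes, tot, p_ref)
        rows[[i]] <- ase_rows(sprintf("X%02d", 1:n_genes), "chrX", starts,
                              lines[i], ref, tot - ref)
      }
    })
    tab <- mask_par(compute_aif(do.call(rbind, rows), 20))
    iv <- data.frame(name = c("p_arm", "q_arm"),
                     start = c(2.8e6, 4.1e7), end = c(4e7, 1.55e8))
    prof <- aif_difference_profile(tab, group_a = lines[1:8],
                                   group_b = lines[9:16], intervals = iv)
    tests <- prof$interval_tests
    ok <- tests$p[tests$name == "p_arm"] < 0.05 &&
      tests$p[tests$name == "q_arm"] > 0.05
    hits <- hits + ok
    # sign convention: reactivated group_a has lower AIF in the region
    expect_lt(mean(prof$delta$delta_aif[prof$delta$start < 4e7]), 0)
  }
  expect_gte(hits, 4)
})

test_that("escape genes planted biallelic in both groups centre at zero", {
  starts <- round(seq(3e6, 1e8, length.out = 20))
  lines <- sprintf("F%02d", 1:10)
  rows <- list()
  withr::with_seed(71, {
    for (i in seq_along(lines)) {
      p_ref <- ifelse(seq_len(20) <= 5, 0.5, 0.99)  # first 5 escape
      tot <- rpois(20, 300)
      ref <- rbinom(20, tot, p_ref)
      rows[[i]] <- ase_rows(sprintf("X%02d", 1:20), "chrX", starts,
                            lines[i], ref, tot - ref)
    }
  })
  tab <- mask_par(compute_aif(do.call(rbind, rows), 20))
  esc <- setNames(ifelse(seq_len(20) <= 5, "escape", "non_escape"),
                  sprintf("X%02d", 1:20))
  prof <- aif_difference_profile(tab, lines[1:5], lines[6:10],
                                 intervals = data.frame(name = "all",
                                                        start = 1,
                                                        end = 1.6e8),
                                 escape_annotations = esc)
  d_esc <- prof$delta$delta_aif[prof$delta$escape_status == "escape"]
  expect_lt(max(abs(d_esc)), 0.05)
  # a group with identical composition gives identically zero differences
  dup <- tab[tab$sample %in% lines[1:5], ]
  dup$sample <- paste0(dup$sample, "b")
  tab2 <- rbind(as.data.frame(tab), dup)
  class(tab2) <- class(tab)
  prof0 <- aif_difference_profile(tab2, lines[1:5], paste0(lines[1:5], "b"),
                                  intervals = data.frame(name = "all",
                                                         start = 1,
                                                         end = 1.6e8))
  expect_true(all(prof0$delta$delta_aif == 0))
})

test_that("higher coverage cutoffs stabilise per-gene mean AIF", {
  # balanced truth at three depths: variance of the folded mean shrinks
  v <- vapply(c(20, 100, 500), function(depth) {
    withr::with_seed(81, {
      tot <- rpois(2000, depth)
      ref <- rbinom(2000, tot, 0.5)
    })
    tab <- compute_aif(ase_rows(rep(sprintf("g%02d", 1:40), each = 50),
                                "chr2", rep(1e6, 2000),
                                rep(sprintf("s%02d", 1:50), 40), ref,
                                tot - ref),
                       min_coverage = min(10, depth))
    m <- tapply(tab$aif, tab$gene, mean)
    var(m)
  }, numeric(1))
  expect_true(all(diff(v) <= 1e-12))
  # folded-binomial bias bound at depth >= 100
  withr::with_seed(82, {
    tot <- rpois(5000, 100)
    ref <- rbinom(5000, tot, 0.5)
  })
  tab <- compute_aif(ase_rows(sprintf("g%04d", 1:5000), "chr3",
                              rep(1e6, 5000), "s1", ref, tot - ref), 20)
  expect_gte(mean(tab$aif), 0.5)
  expect_lte(mean(tab$aif), 0.55)
})
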