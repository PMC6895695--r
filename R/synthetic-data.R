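# Synthetic cohort generation.
#
# Every downstream stage (deconvolution, fate sweep, signature models, AIF,
# association, replication) is exercised on cohorts generated here, with the
# planted truth emitted alongside the data but never consumed by the analysis
# functions themselves.

#' Simulate population reference expression profiles
#'
#' Builds mean TPM profiles for `n_populations` cell populations (by default
#' named CM, EPDC and SC, the cardiomyocyte / epicardium-derived / stem-cell
#' trio) with `n_markers_per_pop` planted marker genes per population.  A
#' marker's mean in its own population exceeds its mean in every other
#' population by `fold_change`.
#'
#' @param n_genes total number of genes.
#' @param n_populations number of populations.
#' @param n_markers_per_pop planted markers per population (disjoint across
#'   populations).
#' @param fold_change marker overexpression fold change (> 1).
#' @param seed integer seed.
#' @return object of class `reference_profiles`: list with `genes`,
#'   `populations`, `mean_expr` (genes x populations), `marker_map`.
#' @export
simulate_reference_profiles <- function(n_genes = 3000, n_populations = 3,
                                        n_markers_per_pop = 50,
                                        fold_change = 8, seed = 1) {
  if (fold_change <= 1) stop_config("fold_change must be > 1")
  if (n_markers_per_pop * n_populations > n_genes) {
    stop_config("marker capacity exceeded: ", n_markers_per_pop, " x ",
                n_populations, " > ", n_genes, " genes")
  }
  pops <- if (n_populations <= 3) {
    c("CM", "EPDC", "SC")[seq_len(n_populations)]
  } else {
    paste0("P", seq_len(n_populations))
  }
  genes <- sprintf("g%05d", seq_len(n_genes))
  with_seed(seed, {
    baseline <- stats::rlnorm(n_genes, meanlog = log(10), sdlog = 1)
    mean_expr <- matrix(rep(baseline, n_populations), ncol = n_populations,
                        dimnames = list(genes, pops))
    marker_map <- vector("list", n_populations)
    names(marker_map) <- pops
    idx <- matrix(seq_len(n_markers_per_pop * n_populations),
                  nrow = n_markers_per_pop)
    for (k in seq_len(n_populations)) {
      mk <- idx[, k]
      mean_expr[mk, k] <- mean_expr[mk, k] * fold_change
      marker_map[[k]] <- genes[mk]
    }
    structure(list(genes = genes, populations = pops, mean_expr = mean_expr,
                   marker_map = marker_map, fold_change = fold_change),
              class = "reference_profiles")
  })
}

#' Simulate bulk RNA-seq mixtures of reference populations
#'
#' Each sample is the fraction-weighted average of the reference population
#' profiles, perturbed by multiplicative log-normal noise
#' (`expr * exp(N(0, noise_sd))`).  Multiplicative noise keeps TPM
#' nonnegative and heteroskedastic; `noise_sd = 0` reproduces the exact
#' mixture.
#'
#' @param profiles a `reference_profiles` object.
#' @param fractions samples x populations matrix of composition vectors;
#'   each row nonnegative and summing to 1 (tolerance 1e-6).
#' @param noise_sd log-scale standard deviation of the multiplicative noise.
#' @param seed integer seed.
#' @return genes x samples TPM matrix.
#' @export
simulate_bulk_mixtures <- function(profiles, fractions, noise_sd = 0.1,
                                   seed = 1) {
  stopifnot(inherits(profiles, "reference_profiles"))
  fractions <- as.matrix(fractions)
  if (ncol(fractions) != length(profiles$populations)) {
    stop_config("fractions must have one column per population")
  }
  if (any(fractions < 0) || any(abs(rowSums(fractions) - 1) > 1e-6)) {
    stop_config("each composition vector must be nonnegative and sum to 1")
  }
  expr <- profiles$mean_expr %*% t(fractions)
  colnames(expr) <- rownames(fractions) %||%
    sprintf("s%03d", seq_len(nrow(fractions)))
  if (noise_sd > 0) {
    expr <- with_seed(seed, expr * exp(matrix(
      stats::rnorm(length(expr), sd = noise_sd), nrow = nrow(expr))))
  }
  expr
}

#' Simulate an iPSC cohort with planted fate structure
#'
#' Generates a cohort mimicking a large iPSC differentiation study: each line
#' carries a latent cardiomyocyte fate fraction `f_CM`; planted signature
#' genes have iPSC expression shifted with the fate; differentiated (CVPC)
#' bulk samples are mixtures of the reference populations at the line's true
#' fractions; terminated lines never produce a CVPC sample and are assigned
#' `cm_fraction = 0`.  Female lines receive an X-inactivation state
#' (XaXa / XaXi / mosaic) and an optional fate predisposition offset.
#'
#' The defaults restate the design of the motivating study: 184 lines of
#' which ~37 terminate, 91 signature genes split 36 up-in-CM / 55 up-in-EPDC,
#' ~61% female lines, and a completed-line CM fraction distribution
#' concentrated near 1 with a low-fraction minority, so that roughly
#' 125 lines are CM-fated and 59 EPDC-fated at the 30:70 threshold.
#'
#' @param n_lines number of iPSC lines.
#' @param n_signature number of planted signature genes.
#' @param effect_size scale of the planted expression shifts (the iPSC
#'   expression noise sd is 1 on the log2 scale).  Per-gene magnitudes are
#'   heterogeneous, uniform on `[0.27, 0.40] * effect_size`, so the planted
#'   signature spans weakly-to-clearly significant genes at the reference
#'   cohort size; `signature_truth$effect_size` records the per-gene value.
#' @param pct_female fraction of female lines.
#' @param xi_mix length-3 fractions of XaXa / XaXi / mosaic states among
#'   female lines (must sum to 1).
#' @param profiles optional `reference_profiles`; simulated by default.
#' @param n_terminated number of terminated differentiations.
#' @param signature_mode `"threshold"` plants the effect on the fate group at
#'   `partition` (the 30:70 regime); `"linear"` makes it linear in f_CM.
#' @param partition CM-fraction partition used by `"threshold"` mode.
#' @param sex_effect increase in female lines' probability of the CM-fated
#'   mixture component (0.26 gives ~80% power for the sex term of the
#'   covariate GLM at p < 0.01, n = 184).
#' @param clone_pairs number of line pairs sharing a subject (clones).
#' @param clone_correlation correlation of latent fate within a clone pair
#'   (1 = identical outcome).
#' @param noise_sd multiplicative noise sd of the CVPC bulk mixtures.
#' @param seed integer seed.
#' @return object of class `synthetic_cohort`: list with `ipsc_expr`,
#'   `cvpc_expr`, `metadata`, `true_fractions`, `signature_truth`,
#'   `xi_truth`, `profiles`.
#' @export
simulate_ipsc_cohort <- function(n_lines = 184, n_signature = 91,
                                 effect_size = 1.5, pct_female = 113 / 184,
                                 xi_mix = c(XaXa = 0.35, XaXi = 0.45,
                                            mosaic = 0.20),
                                 profiles = NULL,
                                 n_terminated = round(n_lines * 37 / 184),
                                 signature_mode = c("threshold", "linear"),
                                 partition = 0.3, sex_effect = 0.26,
                                 clone_pairs = 0, clone_correlation = 0,
                                 noise_sd = 0.1, seed = 1) {
  signature_mode <- match.arg(signature_mode)
  if (abs(sum(xi_mix) - 1) > 1e-8) stop_config("xi_mix must sum to 1")
  if (length(xi_mix) != 3L) stop_config("xi_mix must have 3 components")
  if (is.null(profiles)) {
    profiles <- simulate_reference_profiles(seed = substream(seed, 11))
  }
  n_genes <- length(profiles$genes)
  if (n_signature > n_genes) stop_config("n_signature exceeds gene count")

  with_seed(substream(seed, 12), {
    lines <- sprintf("L%04d", seq_len(n_lines))
    sex <- ifelse(stats::runif(n_lines) < pct_female, "F", "M")

    # latent fate fraction: a CM-skewed and an EPDC-skewed mixture
    # component; sex acts on the component probability (female lines are
    # predisposed to the CM component), which reproduces the observed
    # female/male CM-fated rates of roughly 0.77 vs 0.53
    p_hi <- pmin(0.50 + sex_effect * (sex == "F"), 1)
    f <- ifelse(stats::runif(n_lines) < p_hi,
                stats::rbeta(n_lines, 6, 1),
                stats::rbeta(n_lines, 1.2, 6))
    # differentiations terminated before day 25 are the low tail of the
    # latent fate propensity (they are assigned 0% CM downstream)
    terminated <- rank(f + stats::rnorm(n_lines, 0, 0.15),
                       ties.method = "first") <= n_terminated

    subject <- paste0("S", seq_len(n_lines))
    if (clone_pairs > 0) {
      if (2 * clone_pairs > n_lines) stop_config("too many clone pairs")
      for (i in seq_len(clone_pairs)) {
        a <- 2 * i - 1L; b <- 2 * i
        subject[b] <- subject[a]
        f[b] <- clone_correlation * f[a] + (1 - clone_correlation) * f[b]
      }
    }

    # planted signature genes drawn from non-marker genes; sign split
    # mirrors the 36 up-in-CM / 55 up-in-EPDC regime.  Per-gene magnitudes
    # are heterogeneous (uniform on [0.27, 0.40] x effect_size): at the
    # reference design (n = 184, effect_size = 1.5) the planted two-class
    # t-statistics straddle the q < 0.1 detection boundary, which is what
    # makes the fate-threshold optimum identifiable — uniformly saturated
    # effects would be detected at every candidate threshold alike
    marker_genes <- unlist(profiles$marker_map, use.names = FALSE)
    pool <- setdiff(profiles$genes, marker_genes)
    # signature genes are robustly expressed (baseline TPM >= 10 where
    # possible): near the TPM floor the additive log2 shift would be
    # censored away
    base_tpm <- profiles$mean_expr[pool, 1]
    expressed <- pool[base_tpm >= 10]
    if (length(expressed) < n_signature) {
      expressed <- pool[order(base_tpm, decreasing = TRUE)][
        seq_len(min(length(pool), max(n_signature, length(pool) %/% 2)))]
    }
    sig_genes <- sample(expressed, n_signature)
    n_pos <- round(n_signature * 36 / 91)
    sig_sign <- c(rep(1, n_pos), rep(-1, n_signature - n_pos))
    sig_mag <- effect_size * stats::runif(n_signature, 0.27, 0.40)

    fate_score <- if (signature_mode == "threshold") {
      ifelse(f >= partition & !terminated, 0.5, -0.5)
    } else {
      f - 0.5
    }
    base_l2 <- log2p1(profiles$mean_expr[, 1])
    ipsc_l2 <- matrix(stats::rnorm(n_genes * n_lines, sd = 1),
                      nrow = n_genes) + base_l2
    dimnames(ipsc_l2) <- list(profiles$genes, lines)
    shift <- outer(sig_sign * sig_mag, fate_score)
    ipsc_l2[sig_genes, ] <- ipsc_l2[sig_genes, ] + shift
    ipsc_expr <- pmax(2^ipsc_l2 - 1, 0)

    # true CVPC composition; tiny residual stem-cell component
    n_pops <- length(profiles$populations)
    sc <- pmin(abs(stats::rnorm(n_lines, 0, 0.004)), 0.05)
    cm <- f * (1 - sc)
    true_fractions <- cbind(cm, (1 - f) * (1 - sc), sc)
    if (n_pops == 2) true_fractions <- cbind(cm / (cm + (1 - f) * (1 - sc)),
                                             1 - cm / (cm + (1 - f) * (1 - sc)))
    if (n_pops > 3) true_fractions <- cbind(true_fractions,
                                            matrix(0, n_lines, n_pops - 3))
    true_fractions <- true_fractions / rowSums(true_fractions)
    dimnames(true_fractions) <- list(lines, profiles$populations)

    completed <- !terminated
    cvpc_expr <- simulate_bulk_mixtures(
      profiles, true_fractions[completed, , drop = FALSE],
      noise_sd = noise_sd, seed = substream(seed, 13))
    colnames(cvpc_expr) <- lines[completed]

    ctnt <- ifelse(completed,
                   100 * pmin(pmax(f + stats::rnorm(n_lines, 0, 0.05), 0), 1),
                   NA_real_)

    metadata <- data.frame(
      line = lines, subject = subject, sex = sex,
      age = round(stats::runif(n_lines, 20, 65)),
      ethnicity = sample(c("European", "Asian", "Hispanic"), n_lines,
                         replace = TRUE, prob = c(0.6, 0.25, 0.15)),
      passage = sample(12:40, n_lines, replace = TRUE),
      terminated = terminated, cTnT_pct = ctnt,
      stringsAsFactors = FALSE)

    females <- lines[sex == "F"]
    # X-reactivated (XaXa) lines are predisposed to the CM fate: tilt the
    # state weights by the latent fate propensity (xi_coupling = 0 would
    # restore independence)
    xi_coupling <- 1.5
    f_fem <- f[sex == "F"]
    xi_state <- vapply(f_fem, function(fi) {
      w <- xi_mix * exp(c(1, -1, 0) * xi_coupling * (fi - 0.5))
      sample(c("XaXa", "XaXi", "mosaic"), 1, prob = w / sum(w))
    }, character(1))
    xi_truth <- data.frame(
      line = females, state = xi_state,
      rho = ifelse(xi_state == "mosaic",
                   stats::runif(length(females), 0.2, 0.8),
                   ifelse(xi_state == "XaXa", 1, 0)),
      stringsAsFactors = FALSE)

    structure(list(
      ipsc_expr = ipsc_expr, cvpc_expr = cvpc_expr, metadata = metadata,
      true_fractions = true_fractions,
      signature_truth = data.frame(gene = sig_genes, sign = sig_sign,
                                   effect_size = sig_mag,
                                   stringsAsFactors = FALSE),
      xi_truth = xi_truth, profiles = profiles),
      class = "synthetic_cohort")
  })
}

#' @exportS3Method base::print
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic iPSC cohort:", ncol(x$ipsc_expr), "lines (",
      sum(x$metadata$terminated), "terminated ),",
      nrow(x$ipsc_expr), "genes,", nrow(x$signature_truth),
      "planted signature genes\n")
  invisible(x)
}

#' Simulate allele-specific read counts
#'
#' Generates gene-level allele counts reflecting each female line's
#' X-inactivation state: non-escape chrX genes in XaXi lines are monoallelic
#' (allele fraction near 0 or 1), XaXa lines and escape genes are biallelic
#' (near 0.5), mosaic lines reactivate each gene independently with
#' probability rho, and autosomal genes are biallelic in every line.  Counts
#' are binomial with total read depth Poisson-distributed around `depth`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param depth mean reads per gene (>= 1).
#' @param n_chrx_genes,n_autosomal_genes genes simulated per compartment.
#' @param escape_fraction fraction of chrX genes escaping inactivation.
#' @param skew allele fraction of the active allele in monoallelic genes.
#' @param seed integer seed.
#' @return data.frame with columns gene, chrom, start, end, sample,
#'   ref_count, alt_count; the per-gene annotation (escape status) is in
#'   `attr(, "gene_info")`.
#' @export
simulate_ase_counts <- function(cohort, depth = 200, n_chrx_genes = 60,
                                n_autosomal_genes = 40, escape_fraction = 0.2,
                                skew = 0.99, seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (depth < 1) stop_config("depth must be >= 1")
  if (escape_fraction < 0 || escape_fraction > 1) {
    stop_config("escape_fraction must lie in [0, 1]")
  }
  with_seed(substream(seed, 21), {
    cx_start <- sort(round(stats::runif(n_chrx_genes, 2.8e6, 1.549e8)))
    auto_start <- sort(round(stats::runif(n_autosomal_genes, 1e6, 2.4e8)))
    gene_info <- data.frame(
      gene = c(sprintf("XG%03d", seq_len(n_chrx_genes)),
               sprintf("AG%03d", seq_len(n_autosomal_genes))),
      chrom = c(rep("chrX", n_chrx_genes), rep("chr1", n_autosomal_genes)),
      start = c(cx_start, auto_start),
      end = c(cx_start, auto_start) + 5000L,
      escape = c(stats::runif(n_chrx_genes) < escape_fraction,
                 rep(FALSE, n_autosomal_genes)),
      stringsAsFactors = FALSE)

    xi <- cohort$xi_truth
    females <- xi$line
    rows <- list()
    for (i in seq_along(females)) {
      s <- females[i]
      reactivated <- switch(xi$state[i],
        XaXa = rep(TRUE, n_chrx_genes),
        XaXi = rep(FALSE, n_chrx_genes),
        mosaic = stats::runif(n_chrx_genes) < xi$rho[i])
      balanced <- reactivated | gene_info$escape[seq_len(n_chrx_genes)]
      # which parental allele stays active is arbitrary per line
      active_ref <- stats::runif(1) < 0.5
      p_ref <- ifelse(balanced, 0.5, if (active_ref) skew else 1 - skew)
      frac <- c(p_ref, rep(0.5, n_autosomal_genes))
      tot <- stats::rpois(nrow(gene_info), depth)
      ref <- stats::rbinom(nrow(gene_info), tot, frac)
      rows[[i]] <- data.frame(gene = gene_info$gene, chrom = gene_info$chrom,
                              start = gene_info$start, end = gene_info$end,
                              sample = s, ref_count = ref,
                              alt_count = tot - ref,
                              stringsAsFactors = FALSE)
    }
    # autosomal balanced counts for male lines too
    males <- setdiff(cohort$metadata$line, females)
    ag <- gene_info[gene_info$chrom != "chrX", , drop = FALSE]
    for (s in males) {
      tot <- stats::rpois(nrow(ag), depth)
      ref <- stats::rbinom(nrow(ag), tot, 0.5)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = ag$gene, chrom = ag$chrom, start = ag$start, end = ag$end,
        sample = s, ref_count = ref, alt_count = tot - ref,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "gene_info") <- gene_info
    out
  })
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' @param n_lines number of lines (columns).
#' @param n_variants number of biallelic variants (rows).
#' @param maf_range minor-allele-frequency interval, subset of (0, 0.5\].
#' @param causal optional `list(variant = <row index>, beta = <effect>)`;
#'   recorded as planted truth, applied to an outcome only via
#'   [apply_causal_effect()].
#' @param seed integer seed.
#' @return object of class `genotype_sim`: list with `dosages`
#'   (variants x lines, values 0/1/2), `maf`, `causal`.
#' @export
simulate_genotypes <- function(n_lines, n_variants, maf_range = c(0.05, 0.5),
                               causal = NULL, seed = 1) {
  if (n_variants <= 0) stop_config("n_variants must be positive")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop_config("maf_range must be a subset of (0, 0.5]")
  }
  with_seed(substream(seed, 31), {
    maf <- stats::runif(n_variants, maf_range[1], maf_range[2])
    dos <- matrix(stats::rbinom(n_variants * n_lines, 2, rep(maf, n_lines)),
                  nrow = n_variants,
                  dimnames = list(sprintf("v%06d", seq_len(n_variants)),
                                  sprintf("L%04d", seq_len(n_lines))))
    structure(list(dosages = dos, maf = maf, causal = causal),
              class = "genotype_sim")
  })
}

#' Add a planted causal genotype effect to an outcome vector
#'
#' @param geno a `genotype_sim` with a non-NULL `causal` component.
#' @param outcome numeric outcome per line (same order as dosage columns).
#' @return outcome plus `beta * dosage` at the causal variant.
#' @export
apply_causal_effect <- function(geno, outcome) {
  stopifnot(inherits(geno, "genotype_sim"))
  if (is.null(geno$causal)) return(outcome)
  outcome + geno$causal$beta * geno$dosages[geno$causal$variant, ]
}
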