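# Orchestration: resolved run configuration and the end-to-end pipeline.

#' Build and validate a pipeline run configuration
#'
#' Defaults are the constants of the motivating analysis: 50 markers per
#' population at p < 1e-13, CM-fraction thresholds 0 to 0.9 in steps of
#' 0.1, DE significance q < 0.1, 100 permutations, borderline nominal
#' p < 0.0015, 10 CV folds, allele-count coverage >= 20 reads, replication
#' alpha 0.05 and genome-wide significance 5e-8.
#'
#' @param top_n markers per population for the signature matrix.
#' @param p_cutoff marker selection p cutoff.
#' @param thresholds candidate CM-fraction thresholds.
#' @param q_cut DE q-value cutoff.
#' @param n_perm label permutations for the sweep null.
#' @param borderline_p nominal p for annotated borderline signature genes.
#' @param folds cross-validation folds of the joint model.
#' @param min_coverage minimum allele-count coverage.
#' @param alpha nominal replication threshold.
#' @param gw_sig genome-wide significance level.
#' @param maf_filter minor-allele-frequency filter of the variant scan.
#' @param seed integer seed governing all randomness of the run.
#' @return object of class `run_config` (a validated named list).
#' @export
cardiofate_config <- function(top_n = 50, p_cutoff = 1e-13,
                              thresholds = (0:9) / 10, q_cut = 0.1,
                              n_perm = 100, borderline_p = 0.0015,
                              folds = 10, min_coverage = 20, alpha = 0.05,
                              gw_sig = 5e-8, maf_filter = 0.05, seed = 1) {
  cfg <- list(top_n = top_n, p_cutoff = p_cutoff, thresholds = thresholds,
              q_cut = q_cut, n_perm = n_perm, borderline_p = borderline_p,
              folds = folds, min_coverage = min_coverage, alpha = alpha,
              gw_sig = gw_sig, maf_filter = maf_filter, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop_config("invalid config: ", msg)
  chk(cfg$top_n >= 1, "top_n must be >= 1")
  chk(cfg$p_cutoff > 0 && cfg$p_cutoff <= 1, "p_cutoff must be in (0, 1]")
  chk(all(cfg$thresholds >= 0 & cfg$thresholds < 1),
      "thresholds must be CM fractions in [0, 1)")
  chk(cfg$q_cut > 0 && cfg$q_cut < 1, "q_cut must be in (0, 1)")
  chk(cfg$n_perm >= 1, "n_perm must be >= 1")
  chk(cfg$borderline_p > 0 && cfg$borderline_p < 1,
      "borderline_p must be in (0, 1)")
  chk(cfg$folds >= 2, "folds must be >= 2")
  chk(cfg$min_coverage >= 0, "min_coverage must be >= 0")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  chk(cfg$gw_sig > 0 && cfg$gw_sig < 1, "gw_sig must be in (0, 1)")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed must be scalar")
  invisible(cfg)
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes the stages in dependency order — deconvolution, fate threshold
#' sweep and signature finalisation, per-gene and joint signature models,
#' enrichment, allelic-imbalance analysis, covariate/genotype association,
#' and (optionally) cross-cohort replication — writing each stage's table to
#' `outdir` together with the resolved configuration and a log.  All
#' randomness flows from `config$seed`.  Optional inputs that are absent
#' (gene sets, genotypes, allele counts, a second cohort) skip their stage
#' with a logged notice.
#'
#' @param cohort a `synthetic_cohort` (or a list with the same fields built
#'   from files via the `read_*` functions).
#' @param config a `run_config` from [cardiofate_config()].
#' @param outdir output directory (created if needed); `NULL` for no files.
#' @param gene_sets optional named list of gene-set collections (GMT via
#'   [read_gmt()]).
#' @param genotypes optional `genotype_sim` or dosage matrix.
#' @param ase_counts optional allele-count data.frame; simulated from the
#'   cohort when `NULL` and the cohort is synthetic.
#' @param cohort_b optional second `synthetic_cohort` for replication.
#' @return list with the per-stage result objects and the resolved config.
#' @export
run_pipeline <- function(cohort, config = cardiofate_config(),
                         outdir = NULL, gene_sets = NULL, genotypes = NULL,
                         ase_counts = NULL, cohort_b = NULL) {
  validate_config(config)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  log <- character()
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message("[cardiofate] ", msg)
  }
  emit <- function(x, name, stage) {
    if (!is.null(outdir)) {
      write_tsv(x, file.path(outdir, paste0(name, ".tsv")), stage = stage,
                config = config)
    }
  }
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  res <- list(config = config)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_config("stage '", stage, "' failed: ", conditionMessage(e))
    })
  }

  # --- deconvolution -------------------------------------------------------
  res$deconvolution <- run_stage("deconvolution", {
    profs <- cohort$profiles
    # pseudo-replicate profiles: 12 low-noise draws per population are
    # enough for marker p-values to clear the stringent selection cutoff
    n_rep <- 12L
    reps <- do.call(cbind, lapply(seq_along(profs$populations), function(k) {
      fr <- matrix(0, n_rep, length(profs$populations))
      fr[, k] <- 1
      simulate_bulk_mixtures(profs, fr, noise_sd = 0.05,
                             seed = substream(config$seed, 50 + k))
    }))
    colnames(reps) <- paste0(rep(profs$populations, each = n_rep), "_r",
                             seq_len(n_rep))
    sig <- build_signature_matrix(reps,
                                  rep(profs$populations, each = n_rep),
                                  top_n = config$top_n,
                                  p_cutoff = config$p_cutoff)
    est <- estimate_fractions(cohort$cvpc_expr, sig)
    purity <- stats::setNames(cohort$metadata$cTnT_pct / 100,
                              cohort$metadata$line)
    cor_purity <- correlate_fraction_with_purity(est, purity[est$sample],
                                                 population = "CM")
    note(sprintf("deconvolution: %d markers, %d samples, r(cTnT) = %.3f",
                 length(sig$genes), nrow(est), cor_purity$r))
    emit(as.data.frame(est), "fractions", "deconvolution")
    list(signature = sig, estimates = est, purity_correlation = cor_purity)
  })

  # --- fate sweep ----------------------------------------------------------
  res$fate <- run_stage("fate_assignment", {
    terminated <- cohort$metadata$line[cohort$metadata$terminated]
    fate <- assign_outcome(res$deconvolution$estimates, terminated)
    expr <- filter_expressed(cohort$ipsc_expr)
    sweep <- threshold_sweep(expr, fate, thresholds = config$thresholds,
                             q_cut = config$q_cut, n_perm = config$n_perm,
                             seed = substream(config$seed, 60))
    signature <- finalize_signature(sweep,
                                    borderline_p = config$borderline_p)
    note(sprintf("fate sweep: best threshold %.2f, %d DE genes, %d signature genes",
                 sweep$best_threshold,
                 sweep$de_counts[as.character(sweep$best_threshold)],
                 nrow(signature)))
    emit(data.frame(threshold = sweep$thresholds,
                    de_count = unname(sweep$de_counts)),
         "sweep", "fate_assignment")
    emit(signature, "signature", "fate_assignment")
    list(fate_table = fate, sweep = sweep, signature = signature)
  })

  fate_lab <- fate_at_threshold(res$fate$fate_table,
                                res$fate$sweep$best_threshold)
  outcome <- stats::setNames(res$fate$fate_table$cm_fraction,
                             res$fate$fate_table$line)

  # --- signature models ----------------------------------------------------
  res$signature_model <- run_stage("signature_model", {
    genes <- res$fate$signature$gene
    if (length(genes) == 0L) {
      note("signature model: no signature genes, stage skipped")
      NULL
    } else {
      sx <- cohort$ipsc_expr[genes, names(outcome), drop = FALSE]
      fits <- fit_signature_gene_models(sx, outcome)
      joint <- if (length(outcome) >= 3 * config$folds) {
        joint_lasso_cv(sx, outcome, folds = config$folds,
                       seed = substream(config$seed, 70))
      } else NULL
      note(sprintf("signature model: %d per-gene fits%s", nrow(fits),
                   if (!is.null(joint)) {
                     sprintf(", joint CV R2 = %.3f", joint$cv_r2_mean)
                   } else ""))
      emit(fits, "gene_fits", "signature_model")
      list(per_gene = fits, joint = joint)
    }
  })

  # --- enrichment ----------------------------------------------------------
  res$enrichment <- run_stage("enrichment", {
    cs <- contrast_statistic(cohort$ipsc_expr[, names(fate_lab)], fate_lab)
    if (is.null(gene_sets)) {
      note("enrichment: no gene sets supplied, set-level stage skipped")
      list(contrast = cs, sets = NULL)
    } else {
      gs <- gene_set_test(stats::setNames(cs$statistic, cs$gene), gene_sets)
      note(sprintf("enrichment: %d sets tested, %d at q < 0.05",
                   nrow(gs), sum(gs$q < 0.05)))
      emit(gs, "enrichment", "enrichment")
      list(contrast = cs, sets = gs)
    }
  })

  # --- allelic imbalance ---------------------------------------------------
  res$aif <- run_stage("xchrom_ase", {
    counts <- ase_counts %||%
      simulate_ase_counts(cohort, seed = substream(config$seed, 80))
    aif <- mask_par(compute_aif(counts,
                                min_coverage = config$min_coverage))
    females <- cohort$metadata$line[cohort$metadata$sex == "F"]
    grouping <- fate_lab[intersect(names(fate_lab), females)]
    test <- if (length(unique(grouping)) == 2L) {
      compare_aif_groups(aif, grouping, scope = "chrX")
    } else NULL
    note(sprintf("AIF: %d gene-sample values, %d PAR-masked%s",
                 nrow(aif), sum(aif$is_par),
                 if (!is.null(test)) {
                   sprintf(", CM vs EPDC p = %.3g", test$p)
                 } else ""))
    emit(as.data.frame(aif), "aif", "xchrom_ase")
    list(table = aif, fate_test = test)
  })

  # --- association ---------------------------------------------------------
  res$association <- run_stage("association", {
    md <- cohort$metadata[match(names(fate_lab), cohort$metadata$line), ]
    fit <- covariate_glm(md[, c("sex", "age", "ethnicity", "passage")],
                         fate_lab)
    scan <- if (!is.null(genotypes)) {
      dos <- if (inherits(genotypes, "genotype_sim")) genotypes$dosages
             else genotypes
      variant_scan(dos[, names(outcome), drop = FALSE], outcome,
                   covariates = md[, c("passage", "sex")],
                   maf_filter = config$maf_filter, gw_sig = config$gw_sig)
    } else {
      note("association: no genotypes supplied, variant scan skipped")
      NULL
    }
    note(sprintf("association: sex p = %.3g (Z test)%s",
                 fit$p[grepl("^sex", fit$term)][1],
                 if (!is.null(scan)) {
                   sprintf(", scan lambda = %.3f", attr(scan, "lambda_gc"))
                 } else ""))
    emit(as.data.frame(fit), "covariate_fit", "association")
    if (!is.null(scan)) emit(as.data.frame(scan), "scan", "association")
    list(covariates = fit, scan = scan)
  })

  # --- replication ---------------------------------------------------------
  res$replication <- run_stage("replication", {
    if (is.null(cohort_b)) {
      note("replication: no second cohort supplied, stage skipped")
      NULL
    } else {
      d_a <- res$fate$sweep$de_best
      term_b <- cohort_b$metadata$terminated
      lab_b <- ifelse(term_b, "EPDC", "CM")
      d_b <- differential_expression(cohort_b$ipsc_expr, lab_b,
                                     q_cut = config$q_cut)
      rep_res <- contrast_replication(
        d_a[, c("gene", "mean_diff", "p")],
        d_b[, c("gene", "mean_diff", "p")],
        res$fate$signature, alpha = config$alpha)
      note(sprintf("replication: %d/%d signature genes, fold %.2f, Fisher p = %.3g",
                   rep_res$n_replicated, rep_res$n_signature,
                   rep_res$fold_enrichment, rep_res$fisher_p))
      rep_res
    }
  })

  if (!is.null(outdir)) {
    writeLines(yaml::as.yaml(unclass(config)),
               file.path(outdir, "config.yaml"))
    writeLines(log, file.path(outdir, "run.log"))
  }
  res$log <- log
  res
}
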