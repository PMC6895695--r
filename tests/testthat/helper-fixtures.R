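# Shared fixtures, built in code at test time.

# small reference profiles: 300 genes, 3 populations x 10 markers
tiny_profiles <- function(seed = 42, n_genes = 300, n_markers = 10) {
  simulate_reference_profiles(n_genes = n_genes, n_populations = 3,
                              n_markers_per_pop = n_markers,
                              fold_change = 8, seed = seed)
}

# pseudo-replicate pure-population profiles for signature building
pseudo_replicates <- function(profiles, n_rep = 12, noise_sd = 0.05,
                              seed = 1) {
  pops <- profiles$populations
  reps <- do.call(cbind, lapply(seq_along(pops), function(k) {
    fr <- matrix(0, n_rep, length(pops))
    fr[, k] <- 1
    simulate_bulk_mixtures(profiles, fr, noise_sd = noise_sd,
                           seed = seed + k)
  }))
  colnames(reps) <- paste0(rep(pops, each = n_rep), "_r", seq_len(n_rep))
  list(expr = reps, populations = rep(pops, each = n_rep))
}

# labelled expression matrix with planted mean shifts, for DE tests
planted_de_matrix <- function(n_genes = 500, n1 = 30, n2 = 30,
                              n_shift = 0, shift = 0, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * (n1 + n2)), nrow = n_genes,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n1 + n2))))
    if (n_shift > 0) m[seq_len(n_shift), seq_len(n1)] <-
        m[seq_len(n_shift), seq_len(n1)] + shift
    list(expr = pmax(2^m - 1, 0),   # so log2(TPM+1) recovers m exactly
         labels = rep(c("CM", "EPDC"), c(n1, n2)),
         shifted = rownames(m)[seq_len(n_shift)])
  })
}

# signature-gene design with a known fraction of informative genes and a
# target oracle R2 for the joint model
make_joint_design <- function(n = 150, n_genes = 91, n_info = 35,
                              target_r2 = 0.5, seed = 1) {
  withr::with_seed(seed, {
    # latent log2 expression kept positive so log2(TPM + 1) recovers it
    L <- matrix(rnorm(n * n_genes, mean = 6), n, n_genes)
    signal <- rowMeans(L[, seq_len(n_info)])
    noise_sd <- sd(signal) * sqrt(1 / max(target_r2, 1e-12) - 1)
    y01 <- signal + rnorm(n, 0, noise_sd)
    y <- (y01 - min(y01)) / diff(range(y01))
    expr <- t(pmax(2^L - 1, 0))
    dimnames(expr) <- list(sprintf("g%03d", seq_len(n_genes)),
                           sprintf("L%03d", seq_len(n)))
    list(expr = expr, outcome = y,
         informative = rownames(expr)[seq_len(n_info)])
  })
}

# allele-count rows from explicit values
ase_rows <- function(gene, chrom, start, sample, ref, alt, width = 5000L) {
  data.frame(gene = gene, chrom = chrom, start = start,
             end = start + width, sample = sample,
             ref_count = ref, alt_count = alt, stringsAsFactors = FALSE)
}
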