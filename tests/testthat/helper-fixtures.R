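# Small fixture builders shared across test files.

# 4 strains x 3 SNPs, one untyped cell
tiny_geno <- function() {
  al <- matrix(c("A", "A", "C", "C",
                 "T", "T", "G", "G",
                 "C", NA,  "C", "A"),
               nrow = 4,
               dimnames = list(c("s1", "s2", "s3", "s4"), NULL))
  genotype_matrix(rep("chr1", 3), c(100L, 200L, 300L), al)
}

# expression matrix from a strain-level mean matrix (probes x strains),
# replicated with optional per-array noise
expr_from_means <- function(means, replicates = 2, noise_sd = 0,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  strains <- colnames(means)
  arrays <- paste0(rep(strains, each = replicates), "_r",
                   seq_len(replicates))
  a2s <- stats::setNames(rep(strains, each = replicates), arrays)
  vals <- means[, a2s, drop = FALSE] +
    matrix(rnorm(nrow(means) * length(arrays), 0, noise_sd),
           nrow(means), length(arrays))
  dimnames(vals) <- list(rownames(means), arrays)
  expression_matrix(vals, array_to_strain = a2s)
}
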