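#' Strain panel with phenotype labels
#'
#' A strain panel couples an ordered set of strain names with a per-strain
#' phenotype label. Phenotype-contrast operations (differential expression,
#' the cluster permutation test, module scoring) use only strains labelled
#' `susceptible` or `resistant`; strains labelled `unknown` are carried but
#' excluded from contrasts.
#'
#' @param strain_ids character vector of unique strain names.
#' @param phenotype character vector, one of `"susceptible"`, `"resistant"`,
#'   `"unknown"` per strain. Defaults to all unknown.
#' @return An object of class `strain_panel`.
#' @export
strain_panel <- function(strain_ids,
                         phenotype = rep("unknown", length(strain_ids))) {
  strain_ids <- as.character(strain_ids)
  if (anyDuplicated(strain_ids)) {
    stop("strain_ids must be unique")
  }
  phenotype <- as.character(phenotype)
  if (length(phenotype) != length(strain_ids)) {
    stop("phenotype must have one label per strain")
  }
  ok <- phenotype %in% c("susceptible", "resistant", "unknown")
  if (!all(ok)) {
    stop("unknown phenotype label(s): ", paste(unique(phenotype[!ok]), collapse = ", "))
  }
  structure(list(strain_ids = strain_ids,
                 phenotype = stats::setNames(phenotype, strain_ids)),
            class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  tab <- table(factor(x$phenotype, c("susceptible", "resistant", "unknown")))
  cat(sprintf("strain_panel: %d strains (%d susceptible, %d resistant, %d unknown)\n",
              length(x$strain_ids), tab[[1]], tab[[2]], tab[[3]]))
  invisible(x)
}

# strains usable in a phenotype contrast; errors unless >=2 per class
contrast_strains <- function(panel) {
  ph <- panel$phenotype
  sus <- names(ph)[ph == "susceptible"]
  res <- names(ph)[ph == "resistant"]
  if (length(sus) < 2L || length(res) < 2L) {
    stop("phenotype contrast requires at least 2 susceptible and 2 resistant strains")
  }
  list(susceptible = sus, resistant = res)
}

#' Strain-by-SNP genotype matrix
#'
#' Holds single-character alleles for a panel of strains at a set of SNPs
#' with 1-based genomic coordinates. Missing (untyped) genotypes are stored
#' as `NA` internally and rendered with the configurable missing symbol
#' (default `=`) on disk. SNPs are kept sorted by (chromosome, position).
#'
#' @param chrom character vector, chromosome per SNP.
#' @param pos integer vector, 1-based position per SNP, strictly increasing
#'   within each chromosome.
#' @param alleles character matrix, strains in rows (rownames = strain ids),
#'   SNPs in columns; `NA` marks an untyped call.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, alleles) {
  if (is.null(rownames(alleles))) stop("alleles must have strain rownames")
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (length(chrom) != ncol(alleles) || length(pos) != ncol(alleles)) {
    stop("chrom/pos length must equal number of SNP columns")
  }
  if (anyDuplicated(paste(chrom, pos))) stop("duplicate (chrom, pos) entries")
  ord <- order(factor(chrom, unique(chrom)), pos)
  if (is.unsorted(ord)) {
    warning("SNPs not sorted by (chrom, pos); sorting")
    chrom <- chrom[ord]; pos <- pos[ord]
    alleles <- alleles[, ord, drop = FALSE]
  }
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome ", cc)
  }
  untyped_everywhere <- colSums(!is.na(alleles)) == 0L
  if (any(untyped_everywhere)) {
    stop("SNP(s) with no typed strain: ",
         paste(head(which(untyped_everywhere)), collapse = ", "))
  }
  colnames(alleles) <- paste0(chrom, ":", pos)
  structure(list(chrom = chrom, pos = pos, alleles = alleles),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d strains x %d SNPs on %d chromosome(s); %.1f%% untyped\n",
              nrow(x$alleles), ncol(x$alleles), length(unique(x$chrom)),
              100 * mean(is.na(x$alleles))))
  invisible(x)
}

n_strains <- function(geno) nrow(geno$alleles)
n_snps <- function(geno) ncol(geno$alleles)

# subset SNP columns, keeping the container valid
geno_subset <- function(geno, idx) {
  genotype_matrix(geno$chrom[idx], geno$pos[idx],
                  geno$alleles[, idx, drop = FALSE])
}

#' Copy-number variant region set
#'
#' CNVRs are genomic intervals (1-based, inclusive) with a per-strain
#' integer copy-number class; `NA` marks an untyped strain.
#'
#' @param regions data.frame with columns `cnvr_id`, `chrom`, `start`, `end`.
#' @param genotype integer matrix, strains in rows (rownames = strain ids),
#'   regions in columns (colnames = cnvr ids).
#' @return An object of class `cnvr_set`.
#' @export
cnvr_set <- function(regions, genotype) {
  stopifnot(all(c("cnvr_id", "chrom", "start", "end") %in% names(regions)))
  regions <- as.data.frame(regions)
  regions$cnvr_id <- as.character(regions$cnvr_id)
  if (anyDuplicated(regions$cnvr_id)) stop("cnvr ids must be unique")
  if (any(regions$start > regions$end)) stop("CNVR start must be <= end")
  if (is.null(rownames(genotype))) stop("genotype must have strain rownames")
  if (ncol(genotype) != nrow(regions)) stop("one genotype column per region required")
  colnames(genotype) <- regions$cnvr_id
  structure(list(regions = regions, genotype = genotype), class = "cnvr_set")
}

#' @export
print.cnvr_set <- function(x, ...) {
  cat(sprintf("cnvr_set: %d regions x %d strains\n",
              nrow(x$regions), nrow(x$genotype)))
  invisible(x)
}

#' Probe-by-array expression matrix with detection calls
#'
#' Log-scale expression values with a parallel boolean detection matrix
#' (a probe is "detected" on an array when its signal exceeded the array's
#' negative controls; the calls are taken as given, not recomputed) and an
#' array-to-strain map for replicate structure.
#'
#' @param values numeric probe x array matrix (rownames = probe ids,
#'   colnames = array ids).
#' @param detected logical matrix, same shape as `values`.
#' @param array_to_strain named character vector mapping array id -> strain.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, detected = NULL, array_to_strain) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have probe rownames and array colnames")
  }
  if (is.null(detected)) {
    detected <- matrix(TRUE, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  }
  if (!identical(dim(values), dim(detected))) {
    stop("detected must have the same shape as values")
  }
  dimnames(detected) <- dimnames(values)
  missing_map <- setdiff(colnames(values), names(array_to_strain))
  if (length(missing_map)) {
    stop("arrays without strain mapping: ", paste(missing_map, collapse = ", "))
  }
  structure(list(values = values,
                 detected = detected,
                 array_to_strain = array_to_strain[colnames(values)]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d arrays (%d strains); %.1f%% detected\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$array_to_strain)), 100 * mean(x$detected)))
  invisible(x)
}

# arrays belonging to each strain, in column order
arrays_by_strain <- function(expr) {
  split(colnames(expr$values), expr$array_to_strain)[unique(expr$array_to_strain)]
}
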