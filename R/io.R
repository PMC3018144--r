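# Readers and writers for the pipeline's tabular formats. All genomic
# coordinates are 1-based and inclusive; every writer states this in a
# leading '#' comment line, and every reader skips such lines.

COORD_HEADER <- "# coordinates: 1-based, inclusive"

write_tsv_commented <- function(df, path, comments = COORD_HEADER) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comments, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
}

read_tsv_commented <- function(path, ...) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read a strain-by-SNP genotype table
#'
#' Expects a TSV with columns `chrom`, `pos`, then one column per strain
#' holding single allele characters, with `missing_symbol` (default `=`)
#' marking untyped calls. Rows are sorted by (chrom, pos) on read; unsorted
#' input triggers a warning.
#'
#' @param path path to the TSV file.
#' @param missing_symbol character used for untyped genotypes.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, missing_symbol = "=") {
  df <- read_tsv_commented(path, colClasses = "character")
  if (!all(c("chrom", "pos") %in% names(df))) {
    stop("genotype file must have 'chrom' and 'pos' columns: ", path)
  }
  strains <- setdiff(names(df), c("chrom", "pos"))
  if (!length(strains)) stop("genotype file has no strain columns: ", path)
  al <- t(as.matrix(df[, strains, drop = FALSE]))
  rownames(al) <- strains
  al[al == missing_symbol] <- NA_character_
  bad <- which(!is.na(al) & nchar(al) != 1L, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-allele character at SNP row %d (strain %s)",
                 bad[1, 2], strains[bad[1, 1]]))
  }
  genotype_matrix(df$chrom, as.integer(df$pos), al)
}

#' Write a genotype table
#'
#' Inverse of [read_genotypes]; untyped calls are written as
#' `missing_symbol`.
#'
#' @param geno a [genotype_matrix].
#' @param path output path.
#' @param missing_symbol character to write for untyped genotypes.
#' @export
write_genotypes <- function(geno, path, missing_symbol = "=") {
  al <- t(geno$alleles)
  al[is.na(al)] <- missing_symbol
  df <- data.frame(chrom = geno$chrom, pos = geno$pos, al,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_commented(df, path)
  invisible(path)
}

#' Read a CNVR table
#'
#' TSV with columns `cnvr_id`, `chrom`, `start`, `end`, then one integer
#' copy-number column per strain (`NA` allowed).
#'
#' @param path path to the TSV file.
#' @return A [cnvr_set].
#' @export
read_cnvrs <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("cnvr_id", "chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop("CNVR file must have columns ", paste(need, collapse = ", "), ": ", path)
  }
  strains <- setdiff(names(df), need)
  gt <- t(as.matrix(df[, strains, drop = FALSE]))
  mode(gt) <- "integer"
  rownames(gt) <- strains
  cnvr_set(df[, need], gt)
}

#' Write a CNVR table
#' @param cnvrs a [cnvr_set].
#' @param path output path.
#' @export
write_cnvrs <- function(cnvrs, path) {
  df <- cbind(cnvrs$regions, as.data.frame(t(cnvrs$genotype)))
  write_tsv_commented(df, path)
  invisible(path)
}

#' Read an expression matrix with detection calls
#'
#' `path` is a probe x array TSV (first column `probe_id`); `detection_path`
#' an optional parallel 0/1 TSV of the same shape; `map_path` a two-column
#' TSV (`array_id`, `strain`). Detection calls are taken as provided in the
#' input: the negative-control rule that generates them on real arrays needs
#' raw array internals that are not modelled here.
#'
#' @param path expression values TSV.
#' @param detection_path optional detection-call TSV (0/1).
#' @param map_path array-to-strain map TSV.
#' @return An [expression_matrix].
#' @export
read_expression <- function(path, map_path, detection_path = NULL) {
  df <- read_tsv_commented(path)
  if (names(df)[1] != "probe_id") stop("first column must be 'probe_id': ", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$probe_id
  det <- NULL
  if (!is.null(detection_path)) {
    dd <- read_tsv_commented(detection_path)
    det <- as.matrix(dd[, -1, drop = FALSE]) != 0
    rownames(det) <- dd$probe_id
    det <- det[rownames(vals), colnames(vals), drop = FALSE]
  }
  map <- read_tsv_commented(map_path)
  expression_matrix(vals, det,
                    stats::setNames(as.character(map$strain), map$array_id))
}

#' Write an expression matrix, its detection calls and array map
#' @param expr an [expression_matrix].
#' @param path expression values TSV path.
#' @param detection_path detection-call TSV path (0/1).
#' @param map_path array-to-strain map TSV path.
#' @export
write_expression <- function(expr, path, map_path, detection_path = NULL) {
  df <- data.frame(probe_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  write_tsv_commented(df, path)
  if (!is.null(detection_path)) {
    dd <- data.frame(probe_id = rownames(expr$values), expr$detected + 0L,
                     check.names = FALSE)
    write_tsv_commented(dd, detection_path)
  }
  write_tsv_commented(data.frame(array_id = colnames(expr$values),
                                 strain = unname(expr$array_to_strain)),
                      map_path)
  invisible(path)
}

#' Read a strain phenotype table
#'
#' Two-column TSV (`strain`, `phenotype`) with phenotype in
#' susceptible/resistant/unknown.
#'
#' @param path path to the TSV file.
#' @return A [strain_panel].
#' @export
read_phenotype <- function(path) {
  df <- read_tsv_commented(path)
  strain_panel(df$strain, df$phenotype)
}

#' Write a strain phenotype table
#' @param panel a [strain_panel].
#' @param path output path.
#' @export
write_phenotype <- function(panel, path) {
  write_tsv_commented(data.frame(strain = panel$strain_ids,
                                 phenotype = unname(panel$phenotype)),
                      path)
  invisible(path)
}

#' Write a haplotype block table
#'
#' One row per block: `block_id`, `chrom`, `start_pos`, `end_pos` (first and
#' last member SNP positions), `n_snps`, `n_haplotypes`, `error_count`, then
#' one column per strain with the integer haplotype label (`NA` = strain
#' untyped across the whole block).
#'
#' @param blocks list of haplotype blocks from [build_blocks].
#' @param strains character vector of strain ids (column order).
#' @param path output path.
#' @export
write_block_table <- function(blocks, strains, path) {
  lab <- if (length(blocks)) {
    do.call(rbind, lapply(blocks, function(b) b$labels[strains]))
  } else {
    matrix(integer(), 0L, length(strains), dimnames = list(NULL, strains))
  }
  colnames(lab) <- strains
  meta <- data.frame(
    block_id = vapply(blocks, `[[`, integer(1), "block_id"),
    chrom = vapply(blocks, `[[`, character(1), "chrom"),
    start_pos = vapply(blocks, `[[`, integer(1), "start_pos"),
    end_pos = vapply(blocks, `[[`, integer(1), "end_pos"),
    n_snps = vapply(blocks, `[[`, integer(1), "n_snps"),
    n_haplotypes = vapply(blocks, `[[`, integer(1), "k"),
    error_count = vapply(blocks, `[[`, integer(1), "error_count"))
  write_tsv_commented(cbind(meta, as.data.frame(lab, check.names = FALSE)), path)
  invisible(path)
}

#' Read a haplotype block table written by [write_block_table]
#' @param path path to the TSV file.
#' @return data.frame with block metadata and per-strain label columns.
#' @export
read_block_table <- function(path) {
  read_tsv_commented(path)
}
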