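#' Case-control genotype dataset
#'
#' Bundles an `n_samples x n_snps` genotype matrix coded by minor-allele
#' count (0 = homozygous major, 1 = heterozygous, 2 = homozygous minor)
#' with a binary phenotype vector (1 = case, 0 = control), locus
#' identifiers, and an optional list of ground-truth pathogenic SNP
#' index tuples carried along from a simulation.
#'
#' @param genotypes integer matrix with values in `{0, 1, 2}`, one row
#'   per sample and one column per SNP.
#' @param phenotype integer vector of 0/1 disease states, one per row of
#'   `genotypes`.
#' @param snp_names character vector of unique locus identifiers;
#'   defaults to the column names of `genotypes` or `N0, N1, ...`.
#' @param truth optional list of integer vectors, each a tuple of
#'   column indices of an embedded pathogenic interaction.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, phenotype, snp_names = NULL,
                             truth = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  phenotype <- as.integer(phenotype)
  if (is.null(snp_names)) {
    snp_names <- colnames(genotypes)
    if (is.null(snp_names)) {
      snp_names <- paste0("N", seq_len(ncol(genotypes)) - 1L)
    }
  }
  bad <- which(!(genotypes %in% c(0L, 1L, 2L)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(genotypes)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(genotypes)) + 1L
    stop(sprintf("genotype value '%s' at row %d, column %d (%s) is not 0/1/2",
                 genotypes[bad[1]], i, j, snp_names[j]))
  }
  if (length(phenotype) != nrow(genotypes)) {
    stop("phenotype length must equal the number of genotype rows")
  }
  if (anyNA(phenotype) || !all(phenotype %in% c(0L, 1L))) {
    stop("phenotype values must all be 0 (control) or 1 (case)")
  }
  if (length(snp_names) != ncol(genotypes)) {
    stop("snp_names length must equal the number of SNP columns")
  }
  if (anyDuplicated(snp_names)) {
    stop("snp_names must be unique")
  }
  if (!is.null(truth)) {
    truth <- lapply(truth, function(t) sort(as.integer(t)))
    ok <- vapply(truth, function(t) {
      all(t >= 1L & t <= ncol(genotypes)) && !anyDuplicated(t)
    }, logical(1))
    if (!all(ok)) stop("truth indices must be distinct valid column indices")
  }
  colnames(genotypes) <- snp_names
  structure(list(genotypes = genotypes, phenotype = phenotype,
                 snp_names = snp_names, truth = truth),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples (%d cases / %d controls) x %d SNPs\n",
              nrow(x$genotypes), sum(x$phenotype == 1L),
              sum(x$phenotype == 0L), ncol(x$genotypes)))
  if (!is.null(x$truth)) {
    for (t in x$truth) {
      cat("  embedded interaction:", paste(x$snp_names[t], collapse = ", "), "\n")
    }
  }
  invisible(x)
}

n_snps <- function(dataset) ncol(dataset$genotypes)
n_samples <- function(dataset) nrow(dataset$genotypes)
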