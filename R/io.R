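#' Read a case-control genotype file
#'
#' Reads a GAMETES-style tab-delimited genotype file (header row of SNP
#' names, genotypes coded 0/1/2, trailing class column with the 0/1
#' phenotype) or the equivalent comma-separated layout.  If a truth
#' sidecar file (`<path>.truth`) written by [write_genotypes()] is
#' present, the embedded pathogenic tuples are attached to the returned
#' dataset.
#'
#' @param path path to the genotype file.
#' @param dialect `"gametes"` (tab-delimited, default) or `"csv"`.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, dialect = c("gametes", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "gametes") "\t" else ","
  dt <- tryCatch(
    data.table::fread(path, sep = sep, header = TRUE, colClasses = "integer",
                      data.table = FALSE),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(dt) < 2L) stop("format error: need at least one SNP column plus a class column")
  cls <- dt[[ncol(dt)]]
  if (anyNA(cls) || !all(cls %in% c(0L, 1L))) {
    bad <- which(anyNA(cls) | !(cls %in% c(0L, 1L)))[1]
    stop(sprintf("format error: class column value '%s' at row %d is not 0/1",
                 cls[bad], bad))
  }
  geno <- as.matrix(dt[, -ncol(dt), drop = FALSE])
  if (anyNA(geno)) {
    bad <- which(is.na(geno))[1]
    stop(sprintf("format error: missing or ragged entry at row %d, column %d",
                 ((bad - 1L) %% nrow(geno)) + 1L, ((bad - 1L) %/% nrow(geno)) + 1L))
  }
  snp_names <- colnames(dt)[-ncol(dt)]
  truth <- NULL
  sidecar <- paste0(path, ".truth")
  if (file.exists(sidecar)) {
    truth <- read_truth(sidecar, snp_names)
  }
  genotype_dataset(geno, cls, snp_names, truth)
}

#' Write a case-control genotype file
#'
#' Writes the GAMETES-style tab-delimited layout read back by
#' [read_genotypes()]: header of SNP names plus a final `Class` column.
#' When the dataset carries ground-truth tuples they are serialized to a
#' plain-text sidecar file `<path>.truth` (one tab-separated tuple of
#' SNP names per line).
#'
#' @param dataset a [genotype_dataset()].
#' @param path output file path.
#' @param dialect `"gametes"` (tab) or `"csv"` (comma).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(dataset, path, dialect = c("gametes", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "gametes") "\t" else ","
  df <- as.data.frame(dataset$genotypes)
  df$Class <- dataset$phenotype
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  if (!is.null(dataset$truth)) {
    lines <- vapply(dataset$truth, function(t) {
      paste(dataset$snp_names[t], collapse = "\t")
    }, character(1))
    writeLines(lines, paste0(path, ".truth"))
  }
  invisible(path)
}

#' Read a truth sidecar file
#'
#' @param path path to a `.truth` file (tab-separated SNP names, one
#'   interaction tuple per line).
#' @param snp_names locus identifiers used to map names back to column
#'   indices.
#' @return list of sorted integer index tuples.
#' @export
read_truth <- function(path, snp_names) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    nm <- strsplit(l, "\t", fixed = TRUE)[[1]]
    idx <- match(nm, snp_names)
    if (anyNA(idx)) stop("truth SNP name(s) not present in dataset: ",
                         paste(nm[is.na(idx)], collapse = ", "))
    sort(idx)
  })
}

#' Export an interaction network in SIF format
#'
#' Each k-locus combination contributes all `k*(k-1)/2` pairwise edges
#' with interaction type `epistasis`; duplicated pairs are merged.  The
#' resulting file loads directly into Cytoscape.
#'
#' @param results a detection result (or list of them), or a list of
#'   character vectors of SNP names (each of length >= 2).
#' @param path output `.sif` path.
#' @return Invisibly, a data.frame of the unique edges written.
#' @export
write_interaction_network <- function(results, path) {
  combos <- extract_name_tuples(results)
  if (!length(combos)) {
    writeLines(character(0), path)
    message("interaction network: 0 nodes, 0 edges")
    return(invisible(data.frame(a = character(0), b = character(0))))
  }
  if (any(vapply(combos, length, integer(1)) < 2L)) {
    stop("every combination must contain at least 2 SNP names")
  }
  edges <- do.call(rbind, lapply(combos, function(nm) {
    nm <- sort(nm)
    t(utils::combn(nm, 2L))
  }))
  edges <- unique(data.frame(a = edges[, 1], b = edges[, 2],
                             stringsAsFactors = FALSE))
  writeLines(sprintf("%s\tepistasis\t%s", edges$a, edges$b), path)
  message(sprintf("interaction network: %d nodes, %d edges",
                  length(unique(c(edges$a, edges$b))), nrow(edges)))
  invisible(edges)
}

extract_name_tuples <- function(results) {
  if (inherits(results, "detection_result")) results <- list(results)
  if (is.data.frame(results)) results <- list(results)
  out <- list()
  for (r in results) {
    if (is.data.frame(r)) {
      out <- c(out, strsplit(r$snp_names, ",", fixed = TRUE))
    } else {
      out <- c(out, list(as.character(r)))
    }
  }
  out
}

#' Write a detection results table
#'
#' Tab-delimited table with one reported SNP combination per row:
#' comma-joined `snp_names`, both objective values, validation
#' statistics and the overall validation flag.
#'
#' @param results a `detection_result` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  data.table::fwrite(as.data.frame(results), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a detection results table written by [write_results()]
#'
#' @param path path to the results table.
#' @return data.frame of class `detection_result`.
#' @export
read_results <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  class(df) <- c("detection_result", class(df))
  df
}
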