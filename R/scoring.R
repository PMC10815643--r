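#' Build a genotype-combination by phenotype contingency table
#'
#' Cross-tabulates the joint genotype of a k-SNP set against the binary
#' phenotype.  Only genotype combinations actually observed appear as
#' rows, so the table has at most `3^k` rows; column 1 holds controls
#' and column 2 holds cases.
#'
#' @param dataset a [genotype_dataset()].
#' @param snp_indices integer vector of k distinct column indices.
#' @return Object of class `contingency_table`: a list with `counts`
#'   (I x 2 integer matrix), `row_labels` (joint genotypes as
#'   slash-separated strings), and grand total `N`.
#' @export
build_contingency <- function(dataset, snp_indices) {
  snp_indices <- as.integer(snp_indices)
  if (anyDuplicated(snp_indices)) stop("snp_indices must be distinct")
  if (any(snp_indices < 1L | snp_indices > n_snps(dataset))) {
    stop("snp_indices out of range")
  }
  G <- dataset$genotypes[, snp_indices, drop = FALSE]
  k <- length(snp_indices)
  code <- integer(nrow(G))
  for (l in seq_len(k)) code <- code * 3L + G[, l]
  tab <- table(code, factor(dataset$phenotype, levels = c(0L, 1L)))
  counts <- matrix(as.integer(tab), ncol = 2L,
                   dimnames = list(NULL, c("control", "case")))
  codes <- as.integer(rownames(tab))
  labels <- vapply(codes, function(cd) {
    g <- integer(k)
    for (l in rev(seq_len(k))) { g[l] <- cd %% 3L; cd <- cd %/% 3L }
    paste(g, collapse = "/")
  }, character(1))
  new_contingency(counts, labels)
}

new_contingency <- function(counts, row_labels = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("contingency table has no observations")
  if (is.null(row_labels)) row_labels <- as.character(seq_len(nrow(counts)))
  structure(list(counts = counts, row_labels = row_labels,
                 N = sum(counts)),
            class = "contingency_table")
}

as_table <- function(x) {
  if (inherits(x, "contingency_table")) return(x)
  new_contingency(x)
}

#' K2 Bayesian network score (negative-log form)
#'
#' Evaluates the Dirichlet-multinomial marginal likelihood of the
#' phenotype given a joint-genotype partition,
#' `prod_i (J-1)! prod_j N_ij! / (N_i + J - 1)!`, and returns its
#' negative natural log, computed with log-gamma arithmetic so that
#' sample sizes in the thousands cannot overflow.  Lower values mean a
#' stronger genotype-phenotype association; the negative log preserves
#' that ordering.
#'
#' @param table a `contingency_table` (or plain count matrix).
#' @return non-negative scalar, `-ln` of the K2 product.
#' @export
k2_score <- function(table) {
  tab <- as_table(table)
  counts <- tab$counts
  J <- ncol(counts)
  Ni <- rowSums(counts)
  sum(lfactorial(Ni + J - 1) - lfactorial(J - 1) - rowSums(lfactorial(counts)))
}

#' Expected cell counts under no association
#'
#' The default expectation is the classical two-way independence
#' expectation `E_ij = row_i total * column_j total / N`.  The
#' `"hwe"` method instead derives row probabilities from Hardy-Weinberg
#' genotype frequencies at allele frequencies estimated from the
#' table's own genotype margins, splitting each row by the observed
#' phenotype margin.
#'
#' @param table a `contingency_table`.
#' @param method `"margin"` (default) or `"hwe"`.
#' @return real matrix of expected counts, same shape as the table.
#' @export
expected_counts <- function(table, method = c("margin", "hwe")) {
  method <- match.arg(method)
  tab <- as_table(table)
  counts <- tab$counts
  if (tab$N == 0) stop("zero grand total")
  colp <- colSums(counts) / tab$N
  if (method == "margin") {
    return(outer(rowSums(counts), colSums(counts)) / tab$N)
  }
  parts <- strsplit(tab$row_labels, "/", fixed = TRUE)
  k <- length(parts[[1]])
  geno <- matrix(as.integer(unlist(parts)), ncol = k, byrow = TRUE)
  Ni <- rowSums(counts)
  rowp <- rep(1, nrow(counts))
  for (l in seq_len(k)) {
    q <- sum(Ni * geno[, l]) / (2 * tab$N)
    rowp <- rowp * genotype_prob(geno[, l], q)
  }
  outer(tab$N * rowp, colp)
}

#' Likelihood-ratio (G) statistic of a contingency table
#'
#' `G = 2 * sum_ij N_ij * ln(N_ij / E_ij)` with empty cells
#' contributing zero.  This is the raw goodness-of-fit statistic; the
#' search engine minimizes its negation so that stronger associations
#' score lower on both objectives.
#'
#' @inheritParams expected_counts
#' @return non-negative scalar G.
#' @export
lr_score <- function(table, method = c("margin", "hwe")) {
  tab <- as_table(table)
  counts <- tab$counts
  E <- expected_counts(tab, method)
  nz <- counts > 0L
  2 * sum(counts[nz] * log(counts[nz] / E[nz]))
}

#' Pearson chi-square test of a contingency table
#'
#' `X^2 = sum (N_ij - E_ij)^2 / E_ij` over cells with positive
#' expectation, with `df = (I - 1)(J - 1)` and an upper-tail p-value.
#'
#' @inheritParams expected_counts
#' @return list with `statistic`, `df`, `p`.
#' @export
pearson_chi2 <- function(table, method = c("margin", "hwe")) {
  tab <- as_table(table)
  counts <- tab$counts
  E <- expected_counts(tab, method)
  pos <- E > 0
  stat <- sum((counts[pos] - E[pos])^2 / E[pos])
  chi2_tail(stat, tab)
}

#' G-test of independence
#'
#' Uses the [lr_score()] statistic with the chi-square reference
#' distribution, `df = (I - 1)(J - 1)`.
#'
#' @inheritParams expected_counts
#' @return list with `statistic`, `df`, `p`.
#' @export
g_test <- function(table, method = c("margin", "hwe")) {
  tab <- as_table(table)
  chi2_tail(lr_score(tab, method), tab)
}

chi2_tail <- function(stat, tab) {
  df <- (nrow(tab$counts) - 1L) * (ncol(tab$counts) - 1L)
  if (df <= 0L) {
    warning("degenerate table (df <= 0); p set to 1")
    return(list(statistic = stat, df = df, p = 1))
  }
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Score a batch of SNP combinations
#'
#' Vectorized computation of the K2 score and G statistic for many
#' k-SNP combinations at once; this is the engine's evaluation path.
#' The minimization-oriented LR objective is `-G` by default (config
#' `lr_direction = "negate"`), so that minimizing both objectives
#' favours strong associations; `"raw"` keeps the G statistic itself as
#' the second objective.
#'
#' @param dataset a [genotype_dataset()].
#' @param idx matrix of combinations, one row per combination, k
#'   columns of distinct SNP indices.
#' @param lr_direction `"negate"` (default) or `"raw"`.
#' @return data.frame with columns `k2`, `g` (raw statistic), `lr`
#'   (minimization objective) and `i_rows` (number of observed joint
#'   genotypes, giving `df = i_rows - 1` for the G-test), one row per
#'   combination.
#' @export
score_combinations <- function(dataset, idx, lr_direction = c("negate", "raw")) {
  lr_direction <- match.arg(lr_direction)
  idx <- matrix(as.integer(idx), ncol = if (is.matrix(idx)) ncol(idx) else length(idx))
  k <- ncol(idx)
  m <- nrow(idx)
  y <- dataset$phenotype
  n <- length(y)
  ncell <- 3L^k
  code <- matrix(0L, n, m)
  for (l in seq_len(k)) {
    code <- code * 3L + dataset$genotypes[, idx[, l], drop = FALSE]
  }
  # cell index: phenotype-major within combination, combinations stacked
  flat <- as.integer(code) * 2L + rep(y, m) +
    rep.int((seq_len(m) - 1L) * (2L * ncell), rep.int(n, m))
  cnt <- tabulate(flat + 1L, nbins = m * 2L * ncell)
  cnt <- matrix(cnt, nrow = 2L * ncell)          # per-combination columns
  ctrl <- cnt[seq(1L, 2L * ncell, by = 2L), , drop = FALSE]
  case <- cnt[seq(2L, 2L * ncell, by = 2L), , drop = FALSE]
  Ni <- ctrl + case
  k2 <- colSums(lfactorial(Ni + 1L) - lfactorial(ctrl) - lfactorial(case))
  n_ctrl <- sum(y == 0L)
  n_case <- n - n_ctrl
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  g <- 2 * (colSums(xlogx(ctrl)) + colSums(xlogx(case)) - colSums(xlogx(Ni)) -
              xlogx(n_ctrl) - xlogx(n_case) + xlogx(n))
  g <- pmax(g, 0)
  data.frame(k2 = k2, g = g,
             lr = if (lr_direction == "negate") -g else g,
             i_rows = colSums(Ni > 0L))
}
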