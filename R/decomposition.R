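#' Weight vectors and neighborhoods for bi-objective decomposition
#'
#' Builds the uniform two-objective simplex lattice
#' `w_i = (i/(NP-1), 1 - i/(NP-1))` and, for each weight, the indices
#' of its `K` nearest weights by Euclidean distance (ties broken by
#' lower index).  Each subproblem of the decomposition owns one weight.
#'
#' @param NP number of weight vectors (= population size), >= 2.
#' @param K neighborhood size, defaults to `max(2, round(NP / 10))`.
#' @return Object of class `weight_scheme`: list with `weights`
#'   (NP x 2 matrix), `neighborhoods` (list of integer vectors of
#'   length K, each containing its own index), and `K`.
#' @export
generate_weights <- function(NP, K = max(2L, round(NP / 10))) {
  NP <- as.integer(NP)
  if (NP < 2L) stop("NP must be >= 2")
  K <- as.integer(min(K, NP))
  a <- (seq_len(NP) - 1L) / (NP - 1L)
  W <- cbind(a, 1 - a)
  dimnames(W) <- NULL
  nb <- lapply(seq_len(NP), function(i) {
    d <- sqrt((W[, 1] - W[i, 1])^2 + (W[, 2] - W[i, 2])^2)
    order(d, seq_len(NP))[seq_len(K)]
  })
  structure(list(weights = W, neighborhoods = nb, K = K),
            class = "weight_scheme")
}

#' Min-max normalization of raw objective pairs
#'
#' Scales each objective over the supplied pool (typically the union of
#' the current population and its trial offspring) to `[0, 1]`.  A
#' constant objective maps to all zeros.  The K2 score (log scale) and
#' the LR objective live on incommensurate scales; normalization makes
#' them commensurate before scalarization.
#'
#' @param pairs m x 2 matrix (or data.frame) of raw `(k2, lr)` values.
#' @return m x 2 matrix with entries in `[0, 1]`.
#' @export
normalize_objectives <- function(pairs) {
  M <- as.matrix(pairs)
  if (nrow(M) < 1L) stop("need at least one objective pair")
  lo <- apply(M, 2, min)
  hi <- apply(M, 2, max)
  span <- hi - lo
  out <- sweep(M, 2, lo)
  for (j in seq_len(ncol(M))) {
    out[, j] <- if (span[j] > 0) out[, j] / span[j] else 0
  }
  out
}

#' Penalty-based boundary intersection (PBI) scalarization
#'
#' `D(x | w, r) = d1 + theta * d2`, where `d1` is the length of the
#' projection of `Fx - r` onto the ray through `r` with direction `w`,
#' and `d2` is the perpendicular distance from `Fx` to that ray.
#'
#' @param fx normalized objective vector (length 2).
#' @param w weight vector (nonzero).
#' @param r reference point (componentwise minimum of normalized
#'   objectives).
#' @param theta penalty parameter, >= 0.
#' @return non-negative scalar.
#' @export
pbi_aggregate <- function(fx, w, r, theta) {
  if (theta < 0) stop("theta must be >= 0")
  wn <- sqrt(sum(w^2))
  if (wn == 0) stop("weight vector must be nonzero")
  d1 <- abs(sum((fx - r) * w)) / wn
  d2 <- sqrt(sum((fx - (r + d1 * w / wn))^2))
  d1 + theta * d2
}

# Vectorized PBI: rows of FX against the matching rows of W.
pbi_rows <- function(FX, W, r, theta) {
  wn <- sqrt(rowSums(W^2))
  diff <- sweep(FX, 2, r)
  d1 <- abs(rowSums(diff * W)) / wn
  proj <- (d1 / wn) * W
  d2 <- sqrt(rowSums((diff - proj)^2))
  d1 + theta * d2
}

#' Update the reference point with a new objective vector
#'
#' Maintains the componentwise minimum of all normalized objective
#' vectors seen so far.
#'
#' @param r current reference point.
#' @param fx newly observed normalized objective vector.
#' @return updated reference point.
#' @export
update_reference <- function(r, fx) pmin(r, fx)

#' Champion candidate of every subproblem
#'
#' For each weight vector, finds the candidate minimizing the PBI
#' scalarization; ties are broken by lower K2 score, then by
#' lexicographically smaller SNP tuple.
#'
#' @param candidates m x 2 matrix of normalized objective vectors.
#' @param scheme a [generate_weights()] scheme.
#' @param r reference point.
#' @param theta PBI penalty.
#' @param k2 optional raw K2 values for tie-breaking.
#' @param tuples optional character keys of SNP tuples for the final
#'   tie-break.
#' @return integer vector: the winning candidate index per subproblem.
#' @export
best_by_subproblem <- function(candidates, scheme, r, theta,
                               k2 = NULL, tuples = NULL) {
  C <- as.matrix(candidates)
  if (nrow(C) < 1L) stop("empty candidate list")
  m <- nrow(C)
  if (is.null(k2)) k2 <- numeric(m)
  if (is.null(tuples)) tuples <- rep("", m)
  ord <- order(k2, tuples)  # pre-rank for tie-breaking
  rank2 <- integer(m); rank2[ord] <- seq_len(m)
  W <- scheme$weights
  vapply(seq_len(nrow(W)), function(i) {
    d <- pbi_rows(C, matrix(W[i, ], m, 2, byrow = TRUE), r, theta)
    j <- order(d, rank2)[1L]
    j
  }, integer(1))
}
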