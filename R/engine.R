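#' Decode a continuous position into a SNP index tuple
#'
#' The search operates on real vectors; each coordinate is floored and
#' clipped into the index range, and colliding coordinates are repaired
#' by advancing the later coordinate to the nearest unused index
#' (cyclically).  The tuple is returned sorted, so decoding is
#' idempotent.
#'
#' @param position finite numeric vector of length k.
#' @param n_snps number of SNP columns.
#' @return sorted integer vector of k distinct indices in
#'   `[1, n_snps]`.
#' @export
decode_position <- function(position, n_snps) {
  j <- pmin.int(pmax.int(floor(position), 1L), n_snps)
  j <- as.integer(j)
  used <- logical(n_snps)
  for (l in seq_along(j)) {
    v <- j[l]
    while (used[v]) {
      v <- if (v >= n_snps) 1L else v + 1L
    }
    used[v] <- TRUE
    j[l] <- v
  }
  sort(j)
}

decode_rows <- function(P, n_snps) {
  J <- pmin(pmax(floor(P), 1), n_snps)
  storage.mode(J) <- "integer"
  k <- ncol(J)
  if (k == 2L) {
    fix <- J[, 1L] == J[, 2L]
    out <- cbind(pmin.int(J[, 1L], J[, 2L]), pmax.int(J[, 1L], J[, 2L]))
  } else {
    fix <- apply(J, 1L, anyDuplicated) > 0
    out <- t(apply(J, 1L, sort.int))
  }
  for (i in which(fix)) out[i, ] <- decode_position(J[i, ], n_snps)
  out
}

#' Random displacement on a hypersphere
#'
#' Returns `F * ||A - B|| * u(theta)` where `u` is the unit vector of
#' the hyperspherical coordinate system with angles drawn uniformly
#' from `[0, 2*pi)`; for one dimension the direction is a random sign.
#' The displacement norm is exactly `F * ||A - B||`.
#'
#' @param a,b numeric vectors of equal length (the radius is their
#'   Euclidean distance).
#' @param f scale factor in `(0, 1]`.
#' @return numeric displacement vector.
#' @export
spherical_step <- function(a, b, f) {
  d <- length(a)
  r <- f * sqrt(sum((a - b)^2))
  if (r == 0) return(numeric(d))
  if (d == 1L) return(r * sample(c(-1, 1), 1L))
  theta <- stats::runif(d - 1L, 0, 2 * pi)
  r * unit_from_angles(theta)
}

unit_from_angles <- function(theta) {
  d <- length(theta) + 1L
  s <- sin(theta)
  # suffix products of sines: suf[j] = prod(s[j..d-1])
  suf <- rev(cumprod(rev(s)))
  u <- numeric(d)
  u[1L] <- suf[1L]
  if (d > 2L) {
    for (j in 2:(d - 1L)) u[j] <- cos(theta[j - 1L]) * suf[j]
  }
  u[d] <- cos(theta[d - 1L])
  u
}

# Batch spherical steps: one displacement per row of A, B.
spherical_step_rows <- function(A, B, f) {
  k <- ncol(A)
  r <- f * sqrt(rowSums((A - B)^2))
  m <- nrow(A)
  if (k == 1L) {
    return(matrix(r * sample(c(-1, 1), m, replace = TRUE), m, 1L))
  }
  theta <- matrix(stats::runif(m * (k - 1L), 0, 2 * pi), m, k - 1L)
  S <- sin(theta)
  U <- matrix(0, m, k)
  suf <- matrix(1, m, k - 1L)
  suf[, k - 1L] <- S[, k - 1L]
  if (k > 2L) {
    for (j in (k - 2L):1L) suf[, j] <- suf[, j + 1L] * S[, j]
  }
  U[, 1L] <- suf[, 1L]
  if (k > 2L) {
    for (j in 2:(k - 1L)) U[, j] <- cos(theta[, j - 1L]) * suf[, j]
  }
  U[, k] <- cos(theta[, k - 1L])
  U * r
}

reflect_bounds <- function(x, lo, hi) {
  L <- hi - lo
  y <- (x - lo) %% (2 * L)
  y <- ifelse(y > L, 2 * L - y, y)
  lo + y
}

#' Spherical mutation of one individual
#'
#' `T = X + step(X, X_pbest) + step(X_r1, X_r2)` with both
#' displacements drawn by [spherical_step()] at the same scale factor;
#' out-of-bound coordinates are reflected back into range.
#'
#' @param xi parent position.
#' @param pbest position of an elite individual.
#' @param xr1 position drawn from the population.
#' @param xr2 position drawn from the union of population and archive.
#' @param f scale factor in `(0, 1]`.
#' @param lower,upper search bounds.
#' @return mutated base vector.
#' @export
spherical_mutate <- function(xi, pbest, xr1, xr2, f, lower, upper) {
  t <- xi + spherical_step(xi, pbest, f) + spherical_step(xr1, xr2, f)
  reflect_bounds(t, lower, upper)
}

#' Binomial crossover
#'
#' Each coordinate of the trial comes from the mutant with probability
#' `cr`, otherwise from the parent; one randomly chosen coordinate is
#' always taken from the mutant.
#'
#' @param xi parent position.
#' @param ti mutant position.
#' @param cr crossover rate in `[0, 1]`.
#' @return trial vector.
#' @export
crossover <- function(xi, ti, cr) {
  k <- length(xi)
  take <- stats::runif(k) < cr
  take[sample.int(k, 1L)] <- TRUE
  ifelse(take, ti, xi)
}

#' Append a losing parent to the bounded archive
#'
#' While over capacity, a uniformly random member other than the newest
#' is removed.
#'
#' @param archive matrix of archived positions (possibly 0 rows).
#' @param loser position vector to append.
#' @param capacity maximum number of members.
#' @return updated archive matrix.
#' @export
update_archive <- function(archive, loser, capacity) {
  archive <- rbind(archive, loser)
  rownames(archive) <- NULL
  while (nrow(archive) > capacity) {
    drop <- sample.int(nrow(archive) - 1L, 1L)
    archive <- archive[-drop, , drop = FALSE]
  }
  archive
}

#' Success-history memory of scale factors
#'
#' `H` slots, all initialized to 0.5; a cyclic index marks the next
#' slot to overwrite.
#'
#' @param H number of memory slots.
#' @return object of class `history_memory`.
#' @export
history_memory <- function(H) {
  structure(list(mF = rep(0.5, H), k_index = 1L, H = as.integer(H)),
            class = "history_memory")
}

#' Sample a scale factor from the success-history memory
#'
#' Picks a memory slot uniformly, draws from a Cauchy distribution with
#' that location and scale 0.1, truncates values above 1 to 1 and
#' redraws non-positive values.
#'
#' @param memory a [history_memory()].
#' @return scale factor in `(0, 1]`.
#' @export
sample_scale_factor <- function(memory) {
  loc <- memory$mF[sample.int(memory$H, 1L)]
  repeat {
    f <- stats::rcauchy(1L, loc, 0.1)
    if (f > 0) return(min(f, 1))
  }
}

sample_scale_factors <- function(memory, n) {
  loc <- memory$mF[sample.int(memory$H, n, replace = TRUE)]
  f <- stats::rcauchy(n, loc, 0.1)
  while (any(bad <- f <= 0)) {
    f[bad] <- stats::rcauchy(sum(bad), loc[bad], 0.1)
  }
  pmin(f, 1)
}

#' Update the success-history memory after a generation
#'
#' With successes, the next slot receives the weighted Lehmer mean
#' `sum(w F^2) / sum(w F)` with weights proportional to the fitness
#' improvements; with an empty success set the slot copies the previous
#' slot's value.  The cyclic index then advances.
#'
#' @param memory a [history_memory()].
#' @param f_success scale factors of winning trials this generation.
#' @param delta corresponding absolute fitness improvements.
#' @return updated memory.
#' @export
update_memory <- function(memory, f_success, delta = rep(1, length(f_success))) {
  k <- memory$k_index
  if (length(f_success)) {
    if (sum(delta) <= 0) delta <- rep(1, length(f_success))
    w <- delta / sum(delta)
    memory$mF[k] <- sum(w * f_success^2) / sum(w * f_success)
  } else {
    prev <- if (k == 1L) memory$H else k - 1L
    memory$mF[k] <- memory$mF[prev]
  }
  memory$k_index <- if (k >= memory$H) 1L else k + 1L
  memory
}

#' Initialize a population of continuous positions
#'
#' Positions are uniform over the box `[1, n_snps + 1)^k`, so floored
#' coordinates are uniform over the SNP indices.
#'
#' @param NP population size.
#' @param k interaction order.
#' @param n_snps number of SNPs.
#' @return NP x k numeric matrix.
#' @export
initialize_population <- function(NP, k, n_snps) {
  if (n_snps < k) stop("n_snps must be >= k")
  matrix(stats::runif(NP * k, 1, n_snps + 1), NP, k)
}

# Merge new (idx, k2, lr, g) rows into the running nondominated set.
update_front <- function(front, idx, k2, lr, g) {
  key <- apply(idx, 1L, paste, collapse = "_")
  all_idx <- rbind(front$idx, idx)
  all_k2 <- c(front$k2, k2)
  all_lr <- c(front$lr, lr)
  all_g <- c(front$g, g)
  all_key <- c(front$key, key)
  keep1 <- !duplicated(all_key)
  all_idx <- all_idx[keep1, , drop = FALSE]
  all_k2 <- all_k2[keep1]; all_lr <- all_lr[keep1]
  all_g <- all_g[keep1]; all_key <- all_key[keep1]
  ord <- order(all_k2, all_lr)
  keep <- logical(length(ord))
  min_lr <- Inf; min_k2 <- Inf
  for (p in ord) {
    if (all_lr[p] < min_lr ||
        (all_lr[p] == min_lr && all_k2[p] == min_k2)) {
      keep[p] <- TRUE
      if (all_lr[p] < min_lr) { min_lr <- all_lr[p]; min_k2 <- all_k2[p] }
    }
  }
  list(idx = all_idx[keep, , drop = FALSE], k2 = all_k2[keep],
       lr = all_lr[keep], g = all_g[keep], key = all_key[keep])
}

#' Run the spherical evolutionary multi-objective search
#'
#' Evolves a population of continuous positions decoded to k-SNP
#' combinations, scoring each combination with the K2 score and the
#' (negated) G statistic, scalarizing the two objectives per subproblem
#' with PBI over a fixed weight lattice, adapting the spherical scale
#' factor from a success-history memory, and keeping losing parents in
#' a bounded archive that feeds back into mutation.  A running
#' nondominated set over every distinct combination evaluated is
#' returned.
#'
#' @param dataset a [genotype_dataset()].
#' @param config a [run_config()]; `NULL` for defaults.
#' @param verbose print one progress line per generation.
#' @return Object of class `detection_result`: a data.frame with
#'   columns `snp_names` (comma-joined), `K2`, `LR` and `G`, sorted by
#'   `K2`, with the integer index tuples in `attr(, "indices")` and the
#'   evaluation budget spent in `attr(, "evaluations")`.
#' @export
run_search <- function(dataset, config = NULL, verbose = FALSE) {
  if (is.null(config)) config <- run_config()
  n <- n_snps(dataset)
  cfg <- resolve_config(config, n)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  NP <- cfg$population_size
  k <- cfg$order_k
  lo <- 1; hi <- n + 1
  theta <- cfg$pbi_theta

  scheme <- generate_weights(NP, cfg$neighborhood_size)
  NB <- do.call(rbind, scheme$neighborhoods)
  memory <- history_memory(cfg$memory_size)
  capacity <- as.integer(ceiling(cfg$archive_capacity_factor * NP))
  archive <- matrix(numeric(0), 0L, k)

  cache <- new.env(parent = emptyenv(), size = 4096L)
  eval_batch <- function(idx) {
    keys <- apply(idx, 1L, paste, collapse = "_")
    miss <- !vapply(keys, exists, logical(1), envir = cache,
                    inherits = FALSE, USE.NAMES = FALSE)
    new_keys <- unique(keys[miss])
    if (length(new_keys)) {
      new_idx <- do.call(rbind, lapply(strsplit(new_keys, "_", fixed = TRUE),
                                       as.integer))
      sc <- score_combinations(dataset, new_idx, cfg$lr_direction)
      for (ii in seq_along(new_keys)) {
        cache[[new_keys[ii]]] <- c(sc$k2[ii], sc$g[ii], sc$lr[ii])
      }
      front <<- update_front(front, new_idx, sc$k2, sc$lr, sc$g)
    }
    vals <- matrix(0, length(keys), 3L)
    for (ii in seq_along(keys)) {
      vals[ii, ] <- get(keys[ii], envir = cache, inherits = FALSE)
    }
    list(k2 = vals[, 1L], g = vals[, 2L], lr = vals[, 3L], keys = keys)
  }

  front <- list(idx = matrix(integer(0), 0L, k), k2 = numeric(0),
                lr = numeric(0), g = numeric(0), key = character(0))

  pos <- initialize_population(NP, k, n)
  dec <- decode_rows(pos, n)
  ev <- eval_batch(dec)
  obj <- cbind(ev$k2, ev$lr)
  evals <- NP
  # scalar fitness for pbest ranking (current-generation normalization)
  z <- normalize_objectives(obj)
  fitness <- pbi_rows(z, scheme$weights, c(0, 0), theta)

  gen <- 0L
  while (evals + NP <= cfg$max_evaluations) {
    gen <- gen + 1L
    f <- sample_scale_factors(memory, NP)
    elite <- order(fitness)[seq_len(ceiling(cfg$pbest_fraction * NP))]
    pb <- elite[sample.int(length(elite), NP, replace = TRUE)]
    r1 <- NB[cbind(seq_len(NP), sample.int(ncol(NB), NP, replace = TRUE))]
    clash <- r1 == seq_len(NP)
    while (any(clash)) {
      r1[clash] <- NB[cbind(which(clash),
                            sample.int(ncol(NB), sum(clash), replace = TRUE))]
      clash <- r1 == seq_len(NP) & ncol(NB) > 1L
      if (ncol(NB) == 1L) break
    }
    pool <- rbind(pos, archive)
    r2 <- sample.int(nrow(pool), NP, replace = TRUE)
    clash <- r2 == r1 | r2 == seq_len(NP)
    while (any(clash)) {
      r2[clash] <- sample.int(nrow(pool), sum(clash), replace = TRUE)
      clash <- r2 == r1 | r2 == seq_len(NP)
      if (nrow(pool) <= 2L) break
    }
    Tm <- pos + spherical_step_rows(pos, pos[pb, , drop = FALSE], f) +
      spherical_step_rows(pos[r1, , drop = FALSE],
                          pool[r2, , drop = FALSE], f)
    Tm <- reflect_bounds(Tm, lo, hi)
    take <- matrix(stats::runif(NP * k) < cfg$crossover_rate, NP, k)
    take[cbind(seq_len(NP), sample.int(k, NP, replace = TRUE))] <- TRUE
    U <- ifelse(take, Tm, pos)
    decU <- decode_rows(U, n)
    evU <- eval_batch(decU)
    objU <- cbind(evU$k2, evU$lr)
    evals <- evals + NP

    zz <- normalize_objectives(rbind(obj, objU))
    r_ref <- c(0, 0)
    fit_p <- pbi_rows(zz[seq_len(NP), , drop = FALSE], scheme$weights,
                      r_ref, theta)
    fit_t <- pbi_rows(zz[NP + seq_len(NP), , drop = FALSE], scheme$weights,
                      r_ref, theta)
    wins <- fit_t < fit_p
    if (any(wins)) {
      for (i in which(wins)) {
        archive <- update_archive(archive, pos[i, ], capacity)
      }
      memory <- update_memory(memory, f[wins], abs(fit_t[wins] - fit_p[wins]))
      pos[wins, ] <- U[wins, ]
      dec[wins, ] <- decU[wins, ]
      obj[wins, ] <- objU[wins, ]
      fitness <- ifelse(wins, fit_t, fit_p)
    } else {
      memory <- update_memory(memory, numeric(0))
      fitness <- fit_p
    }
    if (verbose) {
      message(sprintf(
        "generation %d: evals=%d best K2=%.3f best G=%.3f archive=%d mean F=%.3f",
        gen, evals, min(front$k2), max(front$g), nrow(archive), mean(f)))
    }
  }

  ord <- order(front$k2)
  idx_list <- lapply(ord, function(i) front$idx[i, ])
  res <- data.frame(
    snp_names = vapply(idx_list, function(t) {
      paste(dataset$snp_names[t], collapse = ",")
    }, character(1)),
    K2 = front$k2[ord],
    LR = front$lr[ord],
    G = front$g[ord],
    stringsAsFactors = FALSE)
  attr(res, "indices") <- idx_list
  attr(res, "evaluations") <- evals
  attr(res, "distinct_evaluated") <- length(ls(cache))
  class(res) <- c("detection_result", class(res))
  res
}
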