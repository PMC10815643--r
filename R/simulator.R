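#' Specification of a simulated epistatic disease model
#'
#' Describes a k-locus penetrance model by its disease-locus minor
#' allele frequency, target (broad-sense) heritability, population
#' prevalence, and whether single-locus marginal effects are allowed.
#' With `marginal_effects = FALSE` the model is purely epistatic: every
#' single-locus marginal penetrance equals the prevalence.
#'
#' @param maf minor allele frequency of the disease loci, in (0, 0.5].
#' @param h2 target heritability, in \[0, 1).
#' @param prevalence target disease prevalence P(D), in (0, 1).
#' @param order number of interacting loci k.
#' @param marginal_effects logical; `FALSE` builds a no-marginal-effect
#'   (DNME) model, `TRUE` a marginal-effect (DME) model.
#' @param tolerance accepted deviation of the achieved heritability.
#' @param name optional model label.
#' @return object of class `disease_model_spec`.
#' @export
disease_model_spec <- function(maf, h2, prevalence = 0.2, order = 2L,
                               marginal_effects = FALSE, tolerance = 0.02,
                               name = NULL) {
  stopifnot(maf > 0, maf <= 0.5, h2 >= 0, h2 < 1,
            prevalence > 0, prevalence < 1, order >= 2L)
  structure(list(maf = maf, h2 = h2, prevalence = prevalence,
                 order = as.integer(order),
                 marginal_effects = isTRUE(marginal_effects),
                 tolerance = tolerance,
                 name = if (is.null(name)) {
                   sprintf("%s_maf%g_h2%g",
                           if (isTRUE(marginal_effects)) "DME" else "DNME",
                           maf, h2)
                 } else name),
            class = "disease_model_spec")
}

#' Hardy-Weinberg genotype probabilities
#'
#' `(1-q)^2`, `2q(1-q)`, `q^2` for genotypes 0, 1, 2 at minor allele
#' frequency `q`.
#'
#' @param genotype vector of genotypes in `{0, 1, 2}`.
#' @param maf minor allele frequency.
#' @return vector of probabilities.
#' @export
genotype_prob <- function(genotype, maf) {
  q <- maf
  p <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  p[genotype + 1L]
}

# All joint genotypes of k loci in row-code order (locus 1 most
# significant), plus their HWE probabilities.
genotype_grid <- function(k) {
  g <- as.matrix(expand.grid(rev(replicate(k, 0:2, simplify = FALSE)),
                             KEEP.OUT.ATTRS = FALSE))[, k:1, drop = FALSE]
  colnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

joint_genotype_probs <- function(mafs) {
  k <- length(mafs)
  g <- genotype_grid(k)
  p <- rep(1, nrow(g))
  for (l in seq_len(k)) p <- p * genotype_prob(g[, l], mafs[l])
  p
}

#' Penetrance table of a k-locus disease model
#'
#' @param probs vector of `3^k` penetrances in `[0, 1]`, indexed by
#'   joint genotype (locus 1 most significant, genotype order 0,1,2).
#' @param mafs per-locus minor allele frequencies (recycled).
#' @param spec optional originating [disease_model_spec()].
#' @return object of class `penetrance_table` with achieved
#'   prevalence, heritability and maximum marginal deviation attached.
#' @export
penetrance_table <- function(probs, mafs, spec = NULL) {
  k <- as.integer(round(log(length(probs), 3)))
  if (3L^k != length(probs)) stop("probs must have length 3^k")
  if (any(probs < -1e-12 | probs > 1 + 1e-12)) {
    stop("penetrances must lie in [0, 1]")
  }
  probs <- pmin(pmax(probs, 0), 1)
  mafs <- rep_len(mafs, k)
  p <- joint_genotype_probs(mafs)
  prev <- sum(p * probs)
  tab <- structure(list(probs = probs, mafs = mafs, k = k, spec = spec),
                   class = "penetrance_table")
  tab$achieved_prevalence <- prev
  tab$achieved_h2 <- table_heritability(tab)
  marg <- marginal_penetrances(tab)
  tab$marginal_deviation <- max(abs(unlist(marg) - prev))
  tab
}

#' Heritability of a penetrance table
#'
#' Variance-explained definition:
#' `h2 = sum_g P(g) (f_g - K)^2 / (K (1 - K))` with `K` the prevalence
#' implied by the table under HWE genotype frequencies.  Zero for a
#' constant table.
#'
#' @param table a [penetrance_table()], or a penetrance vector.
#' @param mafs allele frequencies (needed when `table` is a plain
#'   vector).
#' @return heritability in `[0, 1]`.
#' @export
table_heritability <- function(table, mafs = NULL) {
  if (!inherits(table, "penetrance_table")) {
    table <- penetrance_table(table, mafs)
    return(table$achieved_h2)
  }
  p <- joint_genotype_probs(table$mafs)
  K <- sum(p * table$probs)
  v <- sum(p * (table$probs - K)^2)
  if (v == 0) return(0)
  v / (K * (1 - K))
}

#' Single-locus marginal penetrances
#'
#' For each locus, the probability of disease given that locus's
#' genotype, averaging the other loci over their HWE frequencies.  A
#' purely epistatic model has every marginal equal to the prevalence.
#'
#' @inheritParams table_heritability
#' @return list of length-3 numeric vectors, one per locus.
#' @export
marginal_penetrances <- function(table, mafs = NULL) {
  if (!inherits(table, "penetrance_table")) {
    table <- penetrance_table(table, mafs)
  }
  g <- genotype_grid(table$k)
  p <- joint_genotype_probs(table$mafs)
  lapply(seq_len(table$k), function(l) {
    vapply(0:2, function(gt) {
      sel <- g[, l] == gt
      sum(p[sel] * table$probs[sel]) / sum(p[sel])
    }, numeric(1))
  })
}

# Basis of the per-locus zero-mean space {x : sum_g P(g) x_g = 0}.
null_basis <- function(maf) {
  p <- genotype_prob(0:2, maf)
  cbind(c(1, -p[1] / p[2], 0), c(0, 1, -p[2] / p[3]))
}

#' Draw a random penetrance table matching a disease model spec
#'
#' Rejection sampling of random table architectures.  For purely
#' epistatic (DNME) models a random direction is drawn in the subspace
#' of tables whose single-locus marginals are exactly flat (spanned by
#' tensor products of per-locus zero-mean contrasts) and scaled so the
#' target heritability and prevalence hold exactly; draws whose
#' penetrances leave `[0, 1]` are rejected.  Marginal-effect (DME)
#' models rescale a uniformly random table instead.  The spec is
#' declared infeasible after `max_restarts` rejections.
#'
#' @param spec a [disease_model_spec()].
#' @param max_restarts rejection cap.
#' @return a [penetrance_table()].
#' @export
random_penetrance_table <- function(spec, max_restarts = 1e5) {
  k <- spec$order
  mafs <- rep(spec$maf, k)
  P <- joint_genotype_probs(mafs)
  K <- spec$prevalence
  target_var <- spec$h2 * K * (1 - K)
  if (spec$h2 == 0) {
    return(penetrance_table(rep(K, 3L^k), mafs, spec))
  }
  B <- null_basis(spec$maf)
  g <- genotype_grid(k)
  # tensor-product basis of the no-single-locus-effect space: factor 0 is
  # the all-ones vector, factors 1-2 the zero-mean contrasts; a term with
  # fewer than two zero-mean factors would leak a main effect
  sel <- as.matrix(expand.grid(replicate(k, 0:2, simplify = FALSE),
                               KEEP.OUT.ATTRS = FALSE))
  sel <- sel[rowSums(sel > 0L) >= 2L, , drop = FALSE]
  ncoef <- nrow(sel)
  for (attempt in seq_len(max_restarts)) {
    if (!spec$marginal_effects) {
      cf <- stats::rnorm(ncoef)
      D <- numeric(3L^k)
      for (cc in seq_len(ncoef)) {
        term <- rep(cf[cc], 3L^k)
        for (l in seq_len(k)) {
          if (sel[cc, l] > 0L) term <- term * B[g[, l] + 1L, sel[cc, l]]
        }
        D <- D + term
      }
    } else {
      f0 <- stats::runif(3L^k)
      D <- f0 - sum(P * f0)
    }
    v <- sum(P * D^2)
    if (v <= 0) next
    f <- K + sqrt(target_var / v) * D
    if (all(f >= 0 & f <= 1)) {
      tab <- penetrance_table(f, mafs, spec)
      if (abs(tab$achieved_h2 - spec$h2) <= spec$tolerance &&
          (spec$marginal_effects || tab$marginal_deviation < 1e-3)) {
        return(tab)
      }
    }
  }
  stop(sprintf(
    "infeasible disease model after %d restarts: maf=%g h2=%g prevalence=%g %s",
    max_restarts, spec$maf, spec$h2, spec$prevalence,
    if (spec$marginal_effects) "DME" else "DNME"))
}

#' Simulate a case-control dataset with one embedded interaction
#'
#' Disease-locus genotypes are sampled under HWE at the model MAF and
#' phenotypes by Bernoulli draws from the penetrance table; sampling
#' continues until exactly `n_cases` cases and `n_controls` controls
#' accumulate.  Background SNPs are HWE draws at locus-specific MAFs
#' uniform on (0.01, 0.5), independent of phenotype.  The disease loci
#' are placed at random columns, named `M0P0, M1P1, ...` in the GAMETES
#' convention, and recorded in the returned truth record.
#'
#' @param spec a [disease_model_spec()].
#' @param n_cases,n_controls exact case/control counts.
#' @param n_snps total number of SNP columns.
#' @param table optional pre-built [penetrance_table()]; drawn from
#'   `spec` when omitted.
#' @param max_batches sampling-timeout guard for pathological specs.
#' @return list with `dataset` (a [genotype_dataset()] whose `truth`
#'   holds the embedded tuple) and `truth` (list with `indices`,
#'   `labels`, `spec`, `table`).
#' @export
generate_dataset <- function(spec, n_cases = 800L, n_controls = 800L,
                             n_snps = 1000L, table = NULL,
                             max_batches = 2000L) {
  k <- spec$order
  if (n_snps <= k) stop("n_snps must exceed the interaction order")
  if (is.null(table)) table <- random_penetrance_table(spec)
  P <- joint_genotype_probs(table$mafs)
  f <- table$probs
  ncell <- length(P)
  case_codes <- integer(0)
  ctrl_codes <- integer(0)
  batch <- max(1000L, 2L * (n_cases + n_controls))
  for (b in seq_len(max_batches)) {
    gcode <- sample.int(ncell, batch, replace = TRUE, prob = P)
    y <- stats::rbinom(batch, 1L, f[gcode])
    case_codes <- c(case_codes, gcode[y == 1L])
    ctrl_codes <- c(ctrl_codes, gcode[y == 0L])
    if (length(case_codes) >= n_cases && length(ctrl_codes) >= n_controls) break
  }
  if (length(case_codes) < n_cases || length(ctrl_codes) < n_controls) {
    stop("generation timeout: prevalence too extreme to reach requested counts")
  }
  codes <- c(case_codes[seq_len(n_cases)], ctrl_codes[seq_len(n_controls)])
  pheno <- c(rep(1L, n_cases), rep(0L, n_controls))
  ord <- sample.int(length(codes))
  codes <- codes[ord]; pheno <- pheno[ord]
  gg <- genotype_grid(k)
  disease_geno <- gg[codes, , drop = FALSE]

  n_bg <- n_snps - k
  bg_mafs <- stats::runif(n_bg, 0.01, 0.5)
  n <- n_cases + n_controls
  bg <- matrix(stats::rbinom(n * n_bg, 2L, rep(bg_mafs, each = n)), n, n_bg)

  positions <- sort(sample.int(n_snps, k))
  G <- matrix(0L, n, n_snps)
  G[, positions] <- disease_geno
  G[, setdiff(seq_len(n_snps), positions)] <- bg
  labels <- paste0("M", seq_len(k) - 1L, "P", seq_len(k) - 1L)
  nm <- character(n_snps)
  nm[positions] <- labels
  nm[setdiff(seq_len(n_snps), positions)] <- paste0("N", seq_len(n_bg) - 1L)
  truth <- list(indices = positions, labels = labels, spec = spec,
                table = table)
  ds <- genotype_dataset(G, pheno, nm, truth = list(positions))
  list(dataset = ds, truth = truth)
}

#' Standard disease-model suites
#'
#' The no-marginal-effect (DNME) suite holds 10 two-locus models: the
#' cross of disease-locus MAF in {0.2, 0.4} with heritability in
#' {0.01, 0.05, 0.2, 0.4}, plus the two h2 = 0.1 fill-ins.  The
#' marginal-effect (DME) suite holds 12 models: MAF in
#' {0.05, 0.1, 0.2, 0.5} crossed with h2 in {0.005, 0.05, 0.2}.
#' Prevalence grows with the heritability target (0.2 up to h2 = 0.1,
#' 0.3 at 0.2, 0.35 at 0.4) because bounded penetrances with flat
#' marginals cannot carry large epistatic variance at low prevalence.
#'
#' @param kind `"dnme"` or `"dme"`.
#' @return list of [disease_model_spec()] objects.
#' @export
model_suite <- function(kind = c("dnme", "dme")) {
  kind <- match.arg(kind)
  prev_for <- function(h2) if (h2 >= 0.4) 0.35 else if (h2 >= 0.2) 0.3 else 0.2
  if (kind == "dnme") {
    grid <- expand.grid(maf = c(0.2, 0.4), h2 = c(0.01, 0.05, 0.1, 0.2, 0.4))
    specs <- lapply(seq_len(nrow(grid)), function(i) {
      disease_model_spec(grid$maf[i], grid$h2[i],
                         prevalence = prev_for(grid$h2[i]),
                         marginal_effects = FALSE)
    })
  } else {
    grid <- expand.grid(maf = c(0.05, 0.1, 0.2, 0.5),
                        h2 = c(0.005, 0.05, 0.2))
    specs <- lapply(seq_len(nrow(grid)), function(i) {
      disease_model_spec(grid$maf[i], grid$h2[i],
                         prevalence = prev_for(grid$h2[i]),
                         marginal_effects = TRUE)
    })
  }
  for (i in seq_along(specs)) {
    specs[[i]]$name <- sprintf("%s%d", toupper(kind), i)
  }
  specs
}
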