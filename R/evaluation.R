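#' Detection power over a collection of simulated datasets
#'
#' The fraction of datasets whose embedded pathogenic combination
#' appears (as an exact unordered tuple) among that dataset's detected
#' combinations.
#'
#' @param detections list (one element per dataset) of lists of integer
#'   index tuples, or of `detection_result` objects.
#' @param truths list of integer tuples, one per dataset.
#' @return scalar power in `[0, 1]`.
#' @export
detection_power <- function(detections, truths) {
  if (length(detections) != length(truths)) {
    stop("detections and truths must have equal length")
  }
  if (!length(truths)) stop("no datasets (#T = 0)")
  hits <- mapply(function(d, t) truth_detected(d, t), detections, truths)
  sum(hits) / length(truths)
}

truth_detected <- function(detection, truth) {
  tuples <- extract_index_tuples(detection)
  key <- paste(sort(as.integer(truth)), collapse = "_")
  any(vapply(tuples, function(x) {
    paste(sort(as.integer(x)), collapse = "_") == key
  }, logical(1)))
}

extract_index_tuples <- function(detection) {
  if (inherits(detection, "detection_result")) {
    return(attr(detection, "indices"))
  }
  if (is.list(detection)) return(detection)
  list(detection)
}

#' Classification metrics from confusion counts
#'
#' TPR = TP/(TP+FN), PPV = TP/(TP+FP), ACC = (TP+TN)/total,
#' FDR = FP/(TP+FP) and F1 the harmonic mean of TPR and PPV.  A metric
#' whose denominator is zero is reported as `NA` (undefined) rather
#' than propagated silently; F1 is 0 when nothing true was recovered
#' but errors exist.
#'
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @return named numeric vector `TPR, PPV, ACC, FDR, F1` (with `NA`
#'   for undefined entries).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  tpr <- div(tp, tp + fn)
  ppv <- div(tp, tp + fp)
  acc <- div(tp + tn, tp + tn + fp + fn)
  fdr <- div(fp, tp + fp)
  f1 <- if (tp + fp + fn == 0) NA_real_
        else if (tp == 0) 0
        else 2 / (1 / tpr + 1 / ppv)
  c(TPR = tpr, PPV = ppv, ACC = acc, FDR = fdr, F1 = f1)
}

#' Filter candidate combinations by the G-test
#'
#' Keeps candidates whose G-test p-value is below `alpha`, Bonferroni
#' corrected over the number of candidates tested (the default) or
#' uncorrected.
#'
#' @param candidates list of integer index tuples or a
#'   `detection_result`.
#' @param dataset the [genotype_dataset()] the candidates were found
#'   in.
#' @param alpha significance level.
#' @param correction `"bonferroni"` or `"none"`.
#' @param method expectation model passed to [g_test()].
#' @return list with `kept` (the surviving tuples), `p` (all
#'   p-values), and `pass` (logical vector).
#' @export
gtest_validate <- function(candidates, dataset, alpha = 0.05,
                           correction = c("bonferroni", "none"),
                           method = "margin") {
  correction <- match.arg(correction)
  tuples <- extract_index_tuples(candidates)
  if (!length(tuples)) {
    return(list(kept = list(), p = numeric(0), pass = logical(0)))
  }
  p <- vapply(tuples, function(t) {
    g_test(build_contingency(dataset, t), method)$p
  }, numeric(1))
  thr <- if (correction == "bonferroni") alpha / length(tuples) else alpha
  pass <- p < thr
  list(kept = tuples[pass], p = p, pass = pass)
}

#' MDR balanced accuracy of one SNP combination
#'
#' Multifactor dimensionality reduction: within each training fold a
#' joint-genotype cell is labelled high-risk when its case:control
#' ratio exceeds the overall training ratio; held-out samples are
#' classified by their cell label (cells unseen in training count as
#' low-risk) and scored by balanced accuracy.  Folds are stratified by
#' phenotype; a fold missing a class is skipped with a warning.
#'
#' @param combination integer tuple of SNP indices.
#' @param dataset a [genotype_dataset()].
#' @param folds number of cross-validation folds.
#' @return mean balanced accuracy over folds, in `[0, 1]`.
#' @export
mdr_classify <- function(combination, dataset, folds = 10L) {
  if (folds < 2L) stop("folds must be >= 2")
  y <- dataset$phenotype
  G <- dataset$genotypes[, combination, drop = FALSE]
  code <- integer(nrow(G))
  for (l in seq_len(ncol(G))) code <- code * 3L + G[, l]
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    i <- which(y == cls)
    fold[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  accs <- numeric(0)
  for (fd in seq_len(folds)) {
    test <- fold == fd
    ytr <- y[!test]; ctr <- code[!test]
    yte <- y[test]; cte <- code[test]
    if (length(unique(yte)) < 2L || length(unique(ytr)) < 2L) {
      warning("fold with a single class skipped")
      next
    }
    ratio_all <- sum(ytr == 1L) / sum(ytr == 0L)
    cases <- tapply(ytr == 1L, ctr, sum)
    ctrls <- tapply(ytr == 0L, ctr, sum)
    high <- as.integer(names(cases))[cases > ratio_all * ctrls]
    pred <- as.integer(cte %in% high)
    sens <- mean(pred[yte == 1L] == 1L)
    spec <- mean(pred[yte == 0L] == 0L)
    accs <- c(accs, (sens + spec) / 2)
  }
  if (!length(accs)) return(NA_real_)
  mean(accs)
}

#' Filter candidate combinations by MDR cross-validated accuracy
#'
#' @inheritParams gtest_validate
#' @param accuracy_min balanced-accuracy acceptance threshold.
#' @param folds cross-validation folds.
#' @return list with `kept`, `accuracy`, `pass`.
#' @export
mdr_validate <- function(candidates, dataset, accuracy_min = 0.55,
                         folds = 10L) {
  tuples <- extract_index_tuples(candidates)
  if (!length(tuples)) {
    return(list(kept = list(), accuracy = numeric(0), pass = logical(0)))
  }
  acc <- vapply(tuples, mdr_classify, numeric(1), dataset = dataset,
                folds = folds)
  pass <- !is.na(acc) & acc >= accuracy_min
  list(kept = tuples[pass], accuracy = acc, pass = pass)
}

#' Detect and validate SNP interactions in one dataset
#'
#' Runs the spherical evolutionary search and annotates the reported
#' nondominated combinations with the G-test p-value (Bonferroni over
#' the candidates), the MDR balanced accuracy, and the individual and
#' combined validation flags.
#'
#' @param dataset a [genotype_dataset()].
#' @param config a [run_config()].
#' @param verbose passed to [run_search()].
#' @return a `detection_result` data.frame with validation columns
#'   `g_test_p`, `mdr_accuracy`, `passed_g`, `passed_mdr`,
#'   `passed_validation`.
#' @export
detect_interactions <- function(dataset, config = NULL, verbose = FALSE) {
  if (is.null(config)) config <- run_config()
  res <- run_search(dataset, config, verbose = verbose)
  tuples <- attr(res, "indices")
  gv <- gtest_validate(tuples, dataset, alpha = config$g_test_alpha,
                       correction = config$g_test_correction,
                       method = config$expected_method)
  mv <- mdr_validate(tuples, dataset, accuracy_min = config$mdr_accuracy_min,
                     folds = config$mdr_folds)
  res$g_test_p <- if (length(tuples)) gv$p else numeric(0)
  res$mdr_accuracy <- if (length(tuples)) mv$accuracy else numeric(0)
  res$passed_g <- if (length(tuples)) gv$pass else logical(0)
  res$passed_mdr <- if (length(tuples)) mv$pass else logical(0)
  res$passed_validation <- res$passed_g & res$passed_mdr
  res
}

#' Aggregate powers and confusion metrics over an experiment
#'
#' Computes `power1` (raw detections), `power2` (G-test validated) and
#' `power3` (MDR validated), plus confusion counts where, per dataset,
#' the candidate universe is the detector's reported nondominated set:
#' TP counts truth combinations present after full validation, FP the
#' validated non-truth combinations, FN the missed truths, and TN the
#' non-truth candidates that validation correctly discarded.
#'
#' @param results list of validated `detection_result` objects (from
#'   [detect_interactions()] or [read_results()]).
#' @param truths list of integer truth tuples, one per dataset.
#' @return object of class `power_report`: list with `power`
#'   (power1/2/3), `counts` (TP/FP/TN/FN) and `metrics`
#'   (via [confusion_metrics()]).
#' @export
evaluate_experiment <- function(results, truths) {
  if (length(results) != length(truths)) stop("mismatched result/truth counts")
  tp <- fp <- tn <- fn <- 0L
  det1 <- det2 <- det3 <- vector("list", length(results))
  for (i in seq_along(results)) {
    r <- results[[i]]
    tuples <- result_tuples(r)
    key <- vapply(tuples, function(x) paste(sort(x), collapse = "_"),
                  character(1))
    tkey <- paste(sort(as.integer(truths[[i]])), collapse = "_")
    pg <- as.logical(r$passed_g)
    pm <- as.logical(r$passed_mdr)
    pv <- as.logical(r$passed_validation)
    det1[[i]] <- tuples
    det2[[i]] <- tuples[pg]
    det3[[i]] <- tuples[pm]
    is_truth <- key == tkey
    tp <- tp + as.integer(any(is_truth & pv))
    fn <- fn + as.integer(!any(is_truth & pv))
    fp <- fp + sum(!is_truth & pv)
    tn <- tn + sum(!is_truth & !pv)
  }
  power <- c(power1 = detection_power(det1, truths),
             power2 = detection_power(det2, truths),
             power3 = detection_power(det3, truths))
  structure(list(power = power,
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 metrics = confusion_metrics(tp, fp, tn, fn),
                 n_datasets = length(results)),
            class = "power_report")
}

result_tuples <- function(r) {
  idx <- attr(r, "indices")
  if (!is.null(idx)) return(idx)
  # results read back from file carry names, not indices
  stop("detection_result lacks index tuples; re-attach with match() against snp_names")
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("power report over %d datasets\n", x$n_datasets))
  cat(sprintf("  power1=%.3f power2=%.3f power3=%.3f\n",
              x$power["power1"], x$power["power2"], x$power["power3"]))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", x$counts["TP"], x$counts["FP"],
              x$counts["TN"], x$counts["FN"]))
  m <- x$metrics
  cat(sprintf("  TPR=%.3f PPV=%.3f ACC=%.3f FDR=%.3f F1=%.3f\n",
              m["TPR"], m["PPV"], m["ACC"], m["FDR"], m["F1"]))
  invisible(x)
}

#' Run one disease model end to end
#'
#' Generates `n_datasets` replicate panels from a model spec, runs the
#' detector with validation on each, and aggregates powers and
#' confusion metrics.
#'
#' @param spec a [disease_model_spec()].
#' @param n_datasets replicate datasets to simulate.
#' @param n_cases,n_controls,n_snps panel dimensions.
#' @param config a [run_config()]; its `seed` (plus the replicate
#'   index) seeds each replicate, keeping the experiment reproducible.
#' @return a `power_report` with the per-dataset results attached as
#'   `attr(, "results")`.
#' @export
run_model_experiment <- function(spec, n_datasets = 5L, n_cases = 800L,
                                 n_controls = 800L, n_snps = 1000L,
                                 config = NULL) {
  if (is.null(config)) config <- run_config()
  results <- vector("list", n_datasets)
  truths <- vector("list", n_datasets)
  base_seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  for (i in seq_len(n_datasets)) {
    set.seed((base_seed + 7919L * i) %% .Machine$integer.max)
    sim <- generate_dataset(spec, n_cases, n_controls, n_snps)
    cfg_i <- config
    cfg_i$seed <- (base_seed + 104729L * i) %% .Machine$integer.max
    results[[i]] <- detect_interactions(sim$dataset, cfg_i)
    truths[[i]] <- sim$truth$indices
  }
  rep <- evaluate_experiment(results, truths)
  attr(rep, "results") <- results
  attr(rep, "truths") <- truths
  attr(rep, "spec") <- spec
  rep
}
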