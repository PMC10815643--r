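#' Search and validation configuration
#'
#' Collects every tunable parameter of the spherical evolutionary
#' search and of the validation stage.  Fields left `NULL` are resolved
#' against the dataset at run time: the population defaults to one
#' individual per SNP (floor 100), the neighborhood to a tenth of the
#' population, and the evaluation budget to 100 generations.
#'
#' @param order_k interaction order k (>= 2).
#' @param population_size number of individuals NP (>= 4); `NULL` for
#'   `max(100, n_snps)`.
#' @param max_evaluations total objective-evaluation budget; `NULL` for
#'   `100 * NP`.
#' @param archive_capacity_factor archive capacity as a multiple of NP.
#' @param memory_size H, number of success-history slots.
#' @param pbest_fraction p in (0, 1]; the mutation's elite pool is the
#'   top `ceil(p * NP)` individuals (smaller is greedier).
#' @param crossover_rate CR in \[0, 1\] for binomial crossover.
#' @param pbi_theta PBI penalty parameter theta >= 0.
#' @param neighborhood_size K, weights per neighborhood; `NULL` for
#'   `max(2, NP / 10)`.
#' @param seed integer seed driving all randomness of a run.
#' @param g_test_alpha significance level of the G-test validation.
#' @param g_test_correction `"bonferroni"` (over the candidates tested)
#'   or `"none"`.
#' @param mdr_accuracy_min balanced-accuracy threshold of the MDR
#'   validation.
#' @param mdr_folds cross-validation folds for MDR.
#' @param lr_direction `"negate"` (minimize -G; default) or `"raw"`.
#' @param expected_method expectation used inside the LR statistic:
#'   `"margin"` (two-way independence, default) or `"hwe"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(order_k = 2L,
                       population_size = NULL,
                       max_evaluations = NULL,
                       archive_capacity_factor = 2,
                       memory_size = 5L,
                       pbest_fraction = 0.1,
                       crossover_rate = 0.5,
                       pbi_theta = 5,
                       neighborhood_size = NULL,
                       seed = NULL,
                       g_test_alpha = 0.05,
                       g_test_correction = "bonferroni",
                       mdr_accuracy_min = 0.55,
                       mdr_folds = 10L,
                       lr_direction = "negate",
                       expected_method = "margin") {
  cfg <- list(order_k = as.integer(order_k),
              population_size = population_size,
              max_evaluations = max_evaluations,
              archive_capacity_factor = archive_capacity_factor,
              memory_size = as.integer(memory_size),
              pbest_fraction = pbest_fraction,
              crossover_rate = crossover_rate,
              pbi_theta = pbi_theta,
              neighborhood_size = neighborhood_size,
              seed = seed,
              g_test_alpha = g_test_alpha,
              g_test_correction = g_test_correction,
              mdr_accuracy_min = mdr_accuracy_min,
              mdr_folds = as.integer(mdr_folds),
              lr_direction = lr_direction,
              expected_method = expected_method)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$order_k >= 2L,
            cfg$memory_size >= 1L,
            cfg$pbest_fraction > 0, cfg$pbest_fraction <= 1,
            cfg$crossover_rate >= 0, cfg$crossover_rate <= 1,
            cfg$pbi_theta >= 0,
            cfg$archive_capacity_factor > 0,
            cfg$mdr_folds >= 2L,
            cfg$g_test_alpha > 0, cfg$g_test_alpha < 1,
            cfg$lr_direction %in% c("negate", "raw"),
            cfg$expected_method %in% c("margin", "hwe"),
            cfg$g_test_correction %in% c("bonferroni", "none"))
  if (!is.null(cfg$population_size) && cfg$population_size < 4L) {
    stop("population_size must be >= 4 (mutation needs distinct r1, r2, pbest, self)")
  }
  invisible(cfg)
}

# Fill NULL fields against a concrete dataset.
resolve_config <- function(cfg, n_snps) {
  if (cfg$order_k >= n_snps) stop("order_k must be < n_snps")
  if (is.null(cfg$population_size)) {
    cfg$population_size <- max(100L, n_snps)
  }
  cfg$population_size <- as.integer(cfg$population_size)
  if (is.null(cfg$neighborhood_size)) {
    cfg$neighborhood_size <- max(2L, as.integer(round(cfg$population_size / 10)))
  }
  cfg$neighborhood_size <- as.integer(min(cfg$neighborhood_size,
                                          cfg$population_size))
  if (is.null(cfg$max_evaluations)) {
    cfg$max_evaluations <- 100L * cfg$population_size
  }
  cfg$max_evaluations <- as.integer(cfg$max_evaluations)
  validate_config(cfg)
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an
#' error.
#'
#' @param path path to a YAML file.
#' @return a [run_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}
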