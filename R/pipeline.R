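#' Per-column descriptive statistics
#'
#' Minimum, maximum, mean, SD, skewness and excess kurtosis per score column.
#' Skewness is the adjusted Fisher-Pearson (sample) coefficient and kurtosis
#' the sample-adjusted excess kurtosis (e1071 type 2, the convention of the
#' major commercial statistics packages).
#'
#' @param data scores.
#' @return data frame, one row per column.
#' @export
descriptives <- function(data) {
  X <- as_score_matrix(data)
  v <- apply(X, 2, var)
  if (any(v == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[v == 0], collapse = ", "))
  data.frame(
    node = colnames(X),
    min = apply(X, 2, min), max = apply(X, 2, max),
    mean = colMeans(X), sd = apply(X, 2, sd),
    skewness = apply(X, 2, e1071::skewness, type = 2),
    kurtosis = apply(X, 2, e1071::kurtosis, type = 2),
    row.names = NULL)
}

#' Welch t-test with Cohen's d
#'
#' Two-sided Welch (unequal-variance) t-test plus Cohen's d with the
#' pooled-SD denominator.
#'
#' @param x_A,x_B numeric vectors (each of length at least 2).
#' @return list with `t`, `df`, `p`, `d`, `mean_A`, `mean_B`.
#' @export
welch_t_cohens_d <- function(x_A, x_B) {
  if (length(x_A) < 2 || length(x_B) < 2) stop("each group needs n >= 2")
  nA <- length(x_A); nB <- length(x_B)
  sp2 <- ((nA - 1) * var(x_A) + (nB - 1) * var(x_B)) / (nA + nB - 2)
  if (sp2 == 0) stop("zero pooled variance")
  tt <- t.test(x_A, x_B, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = (mean(x_A) - mean(x_B)) / sqrt(sp2),
       mean_A = mean(x_A), mean_B = mean(x_B))
}

#' Flag multivariate outliers by a per-column z-score rule
#'
#' Flags participants with `|z| > z_max` on any score column (default 3.29,
#' a two-sided 0.001 normal criterion); used by the optional
#' outlier-sensitivity re-run of [run_study()].
#'
#' @param data scores.
#' @param z_max threshold (default 3.29).
#' @return logical vector, `TRUE` = flagged.
#' @export
flag_outliers <- function(data, z_max = 3.29) {
  X <- as_score_matrix(data)
  Z <- zscore_columns(X)
  apply(abs(Z) > z_max, 1, any)
}

#' Analysis configuration with study defaults
#'
#' Collects every tunable of the pipeline, with defaults matching the
#' package-wide conventions: EBIC gamma 0.5 over a 100-point penalty path,
#' 1000 bootstrap replicates, case-drop grid 0.10-0.75, 10 000 permutations,
#' hill climbing with 5 restarts and 10 perturbations over 1000 bootstraps,
#' bridge cutoff at the 80th percentile, consensus thresholds 0.85/0.50, and
#' CS rule 0.7/0.95.
#'
#' @param input a [questionnaire_dataset()], a CSV path readable by
#'   [read_questionnaire_csv()], or `NULL` when `synthetic` is given.
#' @param synthetic optional list describing a synthetic input: fields
#'   `n` (default 1019), `edges` (partial-correlation edge list for
#'   [precision_spec()]), `use_marginals` (default `TRUE`).
#' @param seed master seed; every stage draws from a fixed substream of it.
#' @param gamma,n_lambda,lambda_min_ratio network estimator settings.
#' @param bootstrap_B,casedrop_B,casedrop_grid stability settings.
#' @param n_perm permutation count for comparison tests.
#' @param dag_B,dag_restarts,dag_perturbations DAG settings.
#' @param bridge_percentile,edge_threshold,direction_threshold,cs_threshold,
#'   cs_confidence thresholds.
#' @param gender_column,age_column,median_split_total group definitions;
#'   `median_split_total = "SPQ"` sums the SPQ-community columns.
#' @param stages which stages to run.
#' @param outlier_sensitivity re-run descriptives/network excluding
#'   [flag_outliers()] rows.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, synthetic = NULL, seed = 1,
                            gamma = 0.5, n_lambda = 100,
                            lambda_min_ratio = 0.01,
                            bootstrap_B = 1000, casedrop_B = 1000,
                            casedrop_grid = c(seq(0.1, 0.7, 0.1), 0.75),
                            n_perm = 10000,
                            dag_B = 1000, dag_restarts = 5,
                            dag_perturbations = 10,
                            bridge_percentile = 80,
                            edge_threshold = 0.85, direction_threshold = 0.5,
                            cs_threshold = 0.7, cs_confidence = 0.95,
                            gender_column = "gender",
                            age_column = "age_band",
                            median_split_total = "SPQ",
                            stages = c("descriptives", "network",
                                       "stability", "nct", "dag"),
                            outlier_sensitivity = FALSE) {
  thr <- c(edge_threshold, direction_threshold, cs_threshold, cs_confidence)
  if (any(thr <= 0) || any(thr >= 1)) stop("thresholds must lie in (0, 1)")
  if (is.null(seed)) stop("a master seed is required")
  cfg <- as.list(environment())
  structure(cfg, class = "analysis_config")
}

# Fixed stage offsets for seed substreams: reconfiguring or disabling one
# stage must never change another stage's draws.
STAGE_STREAMS <- c(simulate = 1L, bootstrap = 20L, casedrop = 21L,
                   nct_gender = 41L, nct_age = 42L, nct_schizotypy = 43L,
                   dag_whole = 60L, dag_low = 61L, dag_high = 62L,
                   dag_age_young = 63L, dag_age_old = 64L)

#' @noRd
resolve_input <- function(config) {
  if (!is.null(config$input)) {
    if (inherits(config$input, "questionnaire_dataset")) return(config$input)
    return(read_questionnaire_csv(config$input))
  }
  syn <- config$synthetic %||% list()
  n <- syn$n %||% 1019
  t1 <- table1_marginals()
  marg <- if (isTRUE(syn$use_marginals %||% TRUE)) t1$marginals else NULL
  spec <- precision_spec(8, syn$edges)
  K <- build_precision(spec)
  seed <- substream_seed(config$seed, STAGE_STREAMS[["simulate"]])
  ds <- sample_copula(n, K, marginals = marg, seed = seed,
                      communities = t1$communities,
                      node_names = names(t1$communities))
  # demographic labels drawn independently of the scores
  ds$groups <- withr::with_seed(substream_seed(seed, 2L), data.frame(
    gender = ifelse(runif(n) < 540 / 1019, "boy", "girl"),
    age_band = ifelse(runif(n) < 544 / 1019, "9-10", "11-12"),
    stringsAsFactors = FALSE))
  ds
}

#' @noRd
subset_dataset <- function(data, keep) {
  questionnaire_dataset(
    data$scores[keep, , drop = FALSE], communities = data$communities,
    groups = if (!is.null(data$groups)) data$groups[keep, , drop = FALSE]
             else NULL)
}

#' @noRd
split_total <- function(data, config) {
  if (config$median_split_total %in% colnames(data$scores))
    return(data$scores[, config$median_split_total])
  comm <- data$communities
  cols <- names(comm)[comm == config$median_split_total]
  if (!length(cols))
    stop("median_split_total matches neither a column nor a community")
  rowSums(data$scores[, cols, drop = FALSE])
}

#' Run the full study pipeline
#'
#' Executes, in order: descriptives (with gender t-tests when a gender column
#' is present), the whole-sample regularized network with centrality, bridge
#' and predictability tables, bootstrap stability (edge CIs, difference
#' tests, case-dropping CS coefficients), permutation comparison tests for
#' the gender, age-band and median-split contrasts, and consensus DAGs for
#' the whole sample and subgroups. Deterministic given the master seed; each
#' stage draws from a fixed seed substream.
#'
#' @param config an [analysis_config()].
#' @param out_dir optional directory; when given, every stage's outputs are
#'   written (JSON/CSV) as soon as the stage completes.
#' @return an object of class `study_report` (nested list).
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  data <- resolve_input(config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  report <- list(provenance = list(
    seed = config$seed,
    config = config[setdiff(names(config), c("input"))],
    package_version = as.character(utils::packageVersion("psynet")),
    n = nrow(data$scores), nodes = data$node_names))
  emit <- function(name, obj) {
    if (!is.null(out_dir))
      jsonlite::write_json(obj, file.path(out_dir, paste0(name, ".json")),
                           auto_unbox = TRUE, digits = NA, force = TRUE,
                           null = "null")
    obj
  }
  emit_csv <- function(name, df) {
    if (!is.null(out_dir) && NROW(df))
      write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                row.names = FALSE)
    df
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }

  if ("descriptives" %in% config$stages) {
    report$descriptives <- stage("descriptives", {
      out <- list(table = descriptives(data))
      gc <- config$gender_column
      if (!is.null(data$groups) && gc %in% names(data$groups)) {
        g <- data$groups[[gc]]
        lv <- unique(g)
        if (length(lv) == 2) {
          out$gender_tests <- do.call(rbind, lapply(
            colnames(data$scores), function(cn) {
              r <- welch_t_cohens_d(data$scores[g == lv[1], cn],
                                    data$scores[g == lv[2], cn])
              data.frame(node = cn, group_A = lv[1], group_B = lv[2],
                         t = r$t, df = r$df, p = r$p, d = r$d)
            }))
        }
      }
      emit("descriptives", out)
    })
  }

  sel <- NULL
  if (any(c("network", "stability", "nct", "dag") %in% config$stages)) {
    report$network <- stage("network", {
      sel <- estimate_network(data, gamma = config$gamma,
                               n_lambda = config$n_lambda,
                               lambda_min_ratio = config$lambda_min_ratio)
      ct <- centrality_table(sel$network, data = data)
      out <- list(edges = network_edge_list(sel$network),
                  lambda = sel$fit$lambda, ebic = sel$fit$ebic,
                  n_edges = sel$fit$E,
                  global_strength = global_strength(sel$network),
                  centrality = ct,
                  bridge_nodes = select_bridge_nodes(
                    ct, config$bridge_percentile))
      emit_csv("edges", out$edges)
      # tidy long format: node, index, raw_value, z_value
      raw_cols <- setdiff(names(ct)[!startsWith(names(ct), "z_")], "node")
      emit_csv("centrality", do.call(rbind, lapply(raw_cols, function(v)
        data.frame(node = ct$node, index = v, raw_value = ct[[v]],
                   z_value = ct[[paste0("z_", v)]]))))
      emit("network", out)
    })
  }

  if ("stability" %in% config$stages) {
    report$stability <- stage("stability", {
      boot <- bootstrap_edges(
        data, B = config$bootstrap_B,
        seed = substream_seed(config$seed, STAGE_STREAMS[["bootstrap"]]),
        gamma = config$gamma, n_lambda = config$n_lambda,
        lambda_min_ratio = config$lambda_min_ratio)
      cd <- casedrop_bootstrap(
        data, proportions = config$casedrop_grid, B = config$casedrop_B,
        seed = substream_seed(config$seed, STAGE_STREAMS[["casedrop"]]),
        gamma = config$gamma, n_lambda = config$n_lambda,
        lambda_min_ratio = config$lambda_min_ratio)
      cs <- cs_coefficient(cd, config$cs_threshold, config$cs_confidence)
      dt <- lapply(c(edge = "edge", strength = "strength", EI = "EI"),
                   function(k) {
                     s <- difference_test(boot, k)$significant
                     sum(s[upper.tri(s)])
                   })
      out <- list(edge_ci = boot$ci, cs_coefficients = as.list(cs),
                  n_significant_differences = dt)
      emit_csv("edge_ci", boot$ci)
      emit("stability", out)
    })
  }

  if ("nct" %in% config$stages) {
    report$nct <- stage("nct", {
      out <- list()
      contrasts <- list()
      if (!is.null(data$groups)) {
        for (col in c(config$gender_column, config$age_column)) {
          if (col %in% names(data$groups) &&
              length(unique(data$groups[[col]])) == 2) {
            g <- data$groups[[col]]
            lv <- sort(unique(g))
            contrasts[[col]] <- list(A = subset_dataset(data, g == lv[1]),
                                     B = subset_dataset(data, g == lv[2]),
                                     labels = lv)
          }
        }
      }
      ms <- tryCatch(median_split(data, split_total(data, config)),
                     error = function(e) NULL)
      if (!is.null(ms))
        contrasts$schizotypy <- list(A = ms$low, B = ms$high,
                                     labels = c("low", "high"),
                                     n_excluded = ms$n_excluded)
      streams <- c(STAGE_STREAMS[["nct_gender"]], STAGE_STREAMS[["nct_age"]],
                   STAGE_STREAMS[["nct_schizotypy"]])
      for (i in seq_along(contrasts)) {
        con <- contrasts[[i]]
        res <- nct_run(con$A, con$B, n_perm = config$n_perm,
                       seed = substream_seed(config$seed, streams[i]),
                       gamma = config$gamma, n_lambda = config$n_lambda,
                       lambda_min_ratio = config$lambda_min_ratio)
        out[[names(contrasts)[i]]] <- list(
          groups = con$labels, n_A = res$n_A, n_B = res$n_B,
          n_excluded = con$n_excluded,
          M = res$M_observed, p_M = res$p_M,
          S = res$S_observed, p_S = res$p_S,
          global_strength_A = res$global_strength_A,
          global_strength_B = res$global_strength_B,
          significant_edges = res$edge_tests$edge[res$edge_tests$p_fdr < 0.05],
          centrality_tests = res$centrality_tests)
        emit_csv(paste0("nct_edges_", names(contrasts)[i]), res$edge_tests)
      }
      emit("nct", out)
    })
  }

  if ("dag" %in% config$stages) {
    report$dag <- stage("dag", {
      run_dag <- function(ds, stream) {
        tab <- bootstrap_arcs(ds, B = config$dag_B,
                              restarts = config$dag_restarts,
                              perturbations = config$dag_perturbations,
                              seed = substream_seed(config$seed,
                                                    STAGE_STREAMS[[stream]]))
        cn <- consensus_network(tab, config$edge_threshold,
                                config$direction_threshold)
        list(consensus = cn$arcs, listing_50 = cn$listing_50)
      }
      out <- list(whole_sample = run_dag(data, "dag_whole"))
      ms <- tryCatch(median_split(data, split_total(data, config)),
                     error = function(e) NULL)
      if (!is.null(ms)) {
        out$low_schizotypy <- run_dag(ms$low, "dag_low")
        out$high_schizotypy <- run_dag(ms$high, "dag_high")
      }
      if (!is.null(data$groups) && config$age_column %in% names(data$groups) &&
          length(unique(data$groups[[config$age_column]])) == 2) {
        g <- data$groups[[config$age_column]]
        lv <- sort(unique(g))
        out$age_A <- run_dag(subset_dataset(data, g == lv[1]),
                             "dag_age_young")
        out$age_B <- run_dag(subset_dataset(data, g == lv[2]), "dag_age_old")
      }
      emit("dag", out)
    })
  }

  if (isTRUE(config$outlier_sensitivity) &&
      "descriptives" %in% config$stages) {
    report$outlier_sensitivity <- stage("outlier_sensitivity", {
      keep <- !flag_outliers(data)
      sub <- subset_dataset(data, keep)
      sel2 <- estimate_network(sub, gamma = config$gamma,
                               n_lambda = config$n_lambda,
                               lambda_min_ratio = config$lambda_min_ratio)
      emit("outlier_sensitivity", list(
        n_excluded = sum(!keep),
        descriptives = descriptives(sub),
        edges = network_edge_list(sel2$network)))
    })
  }

  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  structure(report, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report: stages", paste(setdiff(names(x), "provenance"),
                                    collapse = ", "), "\n")
  invisible(x)
}
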