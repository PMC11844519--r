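#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis with validated
#' types and ranges; unknown keys are rejected. Input data come either from
#' a [simulation_config()] (\code{simulate}) or from files
#' (\code{counts_path}, \code{samples_path}).
#'
#' @param simulate a \code{simulation_config}, or NULL to read counts and
#'   covariates from \code{counts_path}/\code{samples_path}.
#' @param counts_path,samples_path input files used when \code{simulate}
#'   is NULL (counts TSV as written by [write_counts_tsv()]; covariate
#'   CSV).
#' @param min_count,min_fraction prevalence filter parameters (default
#'   10 and 0.8).
#' @param cv_cutoff coefficient-of-variation cutoff, or NULL to skip the
#'   CV filter (the filter is intended for transcript-resolution runs;
#'   0.36 is the reference value there).
#' @param residualize_covariates character vector of numeric columns of
#'   the sample table to regress out of the transformed expression.
#' @param mca_min_var,mca_cum_var MCA dimension-selection rules (defaults
#'   0.05 and 0.75).
#' @param beta,signed,cut_height,min_module_size co-expression network
#'   parameters (defaults 3, FALSE, 0.980, 40).
#' @param use_true_modules in simulated runs, use the planted modules as
#'   the grouping vector instead of the recovered assignment.
#' @param lambda feature penalty; NULL applies the \code{1 - 1/p} rule.
#' @param mu group penalty (default 0.1).
#' @param grid variance-fraction search grid (default 0.1 to 1 by 0.1).
#' @param n_perm permutations per grid point (default 1000).
#' @param n_boot bootstrap replicates (default 1000).
#' @param z_thresh,fdr dual significance criteria (defaults 2 and 0.05).
#' @param gmt optional GMT file of additional gene sets for enrichment.
#' @param gsea_n_perm gene-sampling permutations for GSEA (default 1000).
#' @param seed global seed; stage seeds are derived as
#'   \code{seed + 1000 * stage_index}.
#' @return validated list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(simulate = NULL, counts_path = NULL, samples_path = NULL,
                            min_count = 10, min_fraction = 0.8, cv_cutoff = NULL,
                            residualize_covariates = character(0),
                            mca_min_var = 0.05, mca_cum_var = 0.75,
                            beta = 3, signed = FALSE, cut_height = 0.980,
                            min_module_size = 40, use_true_modules = FALSE,
                            lambda = NULL, mu = 0.1,
                            grid = seq(0.1, 1, by = 0.1),
                            n_perm = 1000, n_boot = 1000,
                            z_thresh = 2, fdr = 0.05,
                            gmt = NULL, gsea_n_perm = 1000, seed = 1L) {
  stop_if(is.null(simulate) && (is.null(counts_path) || is.null(samples_path)),
          "either simulate or counts_path + samples_path must be given")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "simulation_config"))
  stop_if(min_fraction <= 0 || min_fraction > 1, "min_fraction must lie in (0, 1]")
  stop_if(!is.null(cv_cutoff) && cv_cutoff < 0, "cv_cutoff must be non-negative")
  stop_if(mu <= 0, "mu must be positive")
  stop_if(any(grid <= 0 | grid > 1), "grid fractions must lie in (0, 1]")
  stop_if(n_perm < 1 || n_boot < 1, "n_perm and n_boot must be >= 1")
  network_params(beta, signed, cut_height, min_module_size)  # range checks
  cfg <- list(simulate = simulate, counts_path = counts_path,
              samples_path = samples_path, min_count = min_count,
              min_fraction = min_fraction, cv_cutoff = cv_cutoff,
              residualize_covariates = residualize_covariates,
              mca_min_var = mca_min_var, mca_cum_var = mca_cum_var,
              beta = beta, signed = signed, cut_height = cut_height,
              min_module_size = min_module_size,
              use_true_modules = use_true_modules,
              lambda = lambda, mu = mu, grid = grid,
              n_perm = n_perm, n_boot = n_boot,
              z_thresh = z_thresh, fdr = fdr,
              gmt = gmt, gsea_n_perm = gsea_n_perm, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate/ingest, preprocess, toxicology
#' MCA, co-expression modules, GRCCA (model selection, fit, bootstrap),
#' DGE, enrichment — writing every intermediate artifact to \code{outdir}
#' plus a machine-readable \code{manifest.json} (parameters, per-stage
#' seeds, output checksums, wall times). Re-running with the same
#' configuration and seed reproduces all outputs bitwise.
#'
#' With \code{resume = TRUE}, a stage whose output files all exist and
#' whose upstream stages were not recomputed is loaded from disk instead of
#' recomputed; deleting any intermediate therefore regenerates that stage
#' and everything downstream of it.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @param resume reuse existing stage outputs where valid.
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env(parent = emptyenv())
  manifest <- list(parameters = config_to_manifest(config), stages = list())
  dirty <- FALSE

  stages <- pipeline_stages()
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    paths <- file.path(outdir, st$outputs)
    stage_seed <- config$seed + 1000L * i
    reusable <- resume && !dirty && all(file.exists(paths))
    t0 <- proc.time()[["elapsed"]]
    if (reusable) {
      st$load(env, paths, config)
      ran <- FALSE
    } else {
      ok <- tryCatch({ st$run(env, paths, config, stage_seed); TRUE },
                     error = function(e) {
                       stop(sprintf("stage '%s' failed: %s", st$name, conditionMessage(e)),
                            call. = FALSE)
                     })
      dirty <- TRUE
      ran <- TRUE
    }
    manifest$stages[[st$name]] <- list(
      name = st$name, seed = stage_seed, ran = ran,
      outputs = as.list(stats::setNames(unname(tools::md5sum(paths)), st$outputs)),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = as.list(env), manifest = manifest))
}

config_to_manifest <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulate)) cfg$simulate <- unclass(cfg$simulate)
  cfg
}

tox_columns <- function(samples) {
  setdiff(names(samples)[vapply(samples, function(col)
    is.character(col) && all(col %in% c("present", "absent", "unknown")), TRUE)],
    c("sample_id", "diagnosis"))
}

#' Diagnosis indicator columns
#'
#' Expands a diagnosis factor into 0/1 indicator columns against the first
#' (control) level — the Y-side encoding of diagnosis used throughout.
#'
#' @param diagnosis factor (or coercible) of diagnosis labels; the first
#'   level is the baseline.
#' @return numeric matrix, samples x (levels - 1).
#' @export
diagnosis_indicators <- function(diagnosis) {
  diagnosis <- droplevels(as.factor(diagnosis))
  mm <- stats::model.matrix(~diagnosis)[, -1, drop = FALSE]
  colnames(mm) <- sub("^diagnosis", "", colnames(mm))
  mm
}

# ordered stage table: each stage declares its output files and how to
# compute or reload them; state is passed through `env`
pipeline_stages <- function() {
  list(
    list(name = "ingest",
         outputs = c("counts.tsv", "samples.csv", "truth.tsv"),
         run = function(env, paths, cfg, seed) {
           if (!is.null(cfg$simulate)) {
             sim <- simulate_dataset(cfg$simulate)
             env$counts <- sim$counts; env$samples <- sim$samples
             env$truth <- sim$truth
             truth_tab <- data.frame(feature_id = names(sim$truth$true_modules),
                                     module_id = unname(sim$truth$true_modules),
                                     true_effect = unname(sim$truth$true_effect))
           } else {
             env$counts <- read_counts_tsv(cfg$counts_path)
             env$samples <- read_samples_csv(cfg$samples_path)
             env$truth <- NULL
             truth_tab <- data.frame(feature_id = rownames(env$counts),
                                     module_id = NA_integer_, true_effect = NA_real_)
           }
           write_counts_tsv(env$counts, paths[1])
           write_samples_csv(env$samples, paths[2])
           write_result_tsv(truth_tab, paths[3])
         },
         load = function(env, paths, cfg) {
           env$counts <- read_counts_tsv(paths[1])
           env$samples <- read_samples_csv(paths[2])
           tr <- utils::read.delim(paths[3], stringsAsFactors = FALSE)
           env$truth <- if (all(is.na(tr$module_id))) NULL else
             list(true_modules = stats::setNames(tr$module_id, tr$feature_id),
                  true_effect = stats::setNames(tr$true_effect, tr$feature_id))
         }),
    list(name = "preprocess",
         outputs = c("expression.tsv", "pc_screen.tsv"),
         run = function(env, paths, cfg, seed) {
           counts <- filter_min_counts(env$counts, cfg$min_count, cfg$min_fraction)
           if (!is.null(cfg$cv_cutoff)) counts <- filter_by_cv(counts, cfg$cv_cutoff)$matrix
           expr <- normalize_transform(counts)
           screen <- data.frame()
           if (length(cfg$residualize_covariates)) {
             covs <- as.matrix(env$samples[, cfg$residualize_covariates, drop = FALSE])
             expr <- residualize(expr, covs)
             screen <- pc_covariate_screen(expr, covs)$table
           }
           env$expr <- expr
           write_counts_tsv(round(expr, 8), paths[1])
           write_result_tsv(screen, paths[2])
         },
         load = function(env, paths, cfg) env$expr <- read_counts_tsv(paths[1])),
    list(name = "mca",
         outputs = c("mca_scores.tsv", "mca_loadings.tsv"),
         run = function(env, paths, cfg, seed) {
           tox <- env$samples[, tox_columns(env$samples), drop = FALSE]
           res <- select_dimensions(mca(impute_unknown(tox)),
                                    cfg$mca_min_var, cfg$mca_cum_var)
           env$mca_scores <- mca_scores(res)
           write_result_tsv(data.frame(sample_id = env$samples$sample_id,
                                       env$mca_scores), paths[1])
           write_result_tsv(data.frame(category = rownames(res$category_loadings),
                                       res$category_loadings), paths[2])
         },
         load = function(env, paths, cfg) {
           sc <- utils::read.delim(paths[1], stringsAsFactors = FALSE)
           env$mca_scores <- as.matrix(sc[, -1, drop = FALSE])
         }),
    list(name = "modules",
         outputs = c("modules.tsv"),
         run = function(env, paths, cfg, seed) {
           if (cfg$use_true_modules && !is.null(env$truth)) {
             mods <- env$truth$true_modules[rownames(env$expr)]
           } else {
             A <- adjacency(env$expr, network_params(cfg$beta, cfg$signed,
                                                     cfg$cut_height, cfg$min_module_size))
             mods <- cluster_modules(topological_overlap(A),
                                     network_params(cfg$beta, cfg$signed,
                                                    cfg$cut_height, cfg$min_module_size))
           }
           env$modules <- mods
           write_result_tsv(data.frame(feature_id = names(mods),
                                       module_id = unname(mods)), paths[1])
         },
         load = function(env, paths, cfg) {
           df <- utils::read.delim(paths[1], stringsAsFactors = FALSE)
           env$modules <- stats::setNames(df$module_id, df$feature_id)
         }),
    list(name = "grcca",
         outputs = c("grcca_features.tsv", "grcca_covariates.tsv",
                     "model_selection.tsv", "perm_null.tsv"),
         run = function(env, paths, cfg, seed) {
           X <- t(env$expr)
           Y <- cbind(diagnosis_indicators(env$samples$diagnosis), env$mca_scores)
           groups <- env$modules[colnames(X)]
           design <- grcca_design(X, Y, groups, cfg$lambda, cfg$mu)
           sel <- optimize_variance_fraction(design = design, grid = cfg$grid,
                                             n_perm = cfg$n_perm, seed = seed,
                                             X = NULL, Y = NULL, groups = NULL)
           fit <- fit_grcca(design = design, f = sel$chosen_f,
                            X = NULL, Y = NULL, groups = NULL)
           pt <- permutation_test(design = design, f = sel$chosen_f,
                                  n_perm = cfg$n_perm, seed = seed,
                                  X = NULL, Y = NULL, groups = NULL)
           fit$perm_p <- pt$perm_p
           fit <- bootstrap_z(X, Y, groups, fit, n_boot = cfg$n_boot,
                              seed = seed + 1L, lambda = cfg$lambda, mu = cfg$mu)
           env$fit <- fit
           sig <- significant_features(fit, cfg$z_thresh, cfg$fdr)
           feats <- data.frame(feature_id = sig$feature_id,
                               weight = unname(fit$w_x[sig$feature_id]),
                               Z = sig$Z, r = sig$r, p = sig$p, fdr = sig$fdr,
                               significant = sig$significant)
           env$sig <- feats
           covs <- data.frame(covariate_id = fit$r_y$covariate_id,
                              weight = unname(fit$w_y), Z = unname(fit$Z_y),
                              r = fit$r_y$r, p = fit$r_y$p, fdr = fit$r_y$fdr)
           write_result_tsv(feats, paths[1])
           write_result_tsv(covs, paths[2])
           write_result_tsv(cbind(sel$table,
                                  chosen = sel$table$f == sel$chosen_f), paths[3])
           write_result_tsv(data.frame(null_correlation = pt$null), paths[4])
         },
         load = function(env, paths, cfg) {
           env$sig <- utils::read.delim(paths[1], stringsAsFactors = FALSE)
           env$fit <- NULL  # full fit only available when the stage runs
         }),
    list(name = "dge",
         outputs = c("dge.tsv"),
         run = function(env, paths, cfg, seed) {
           env$dge <- fit_dge(env$expr, env$samples, env$mca_scores)
           write_result_tsv(as.data.frame(env$dge), paths[1])
         },
         load = function(env, paths, cfg) {
           df <- utils::read.delim(paths[1], stringsAsFactors = FALSE)
           class(df) <- c("dge_result", "data.frame")
           env$dge <- df
         }),
    list(name = "enrichment",
         outputs = c("gsea.tsv", "overlap.tsv"),
         run = function(env, paths, cfg, seed) {
           sets <- module_gene_sets(env$modules)
           if (!is.null(cfg$gmt)) sets <- c(sets, read_gmt(cfg$gmt))
           scores <- stats::setNames(env$sig$r, env$sig$feature_id)
           env$gsea <- gsea_preranked(scores, sets, n_perm = cfg$gsea_n_perm,
                                      seed = seed)
           query <- env$sig$feature_id[env$sig$significant]
           env$overlap <- if (length(query)) {
             hypergeom_overlap(query, sets, universe = env$sig$feature_id)
           } else {
             data.frame()
           }
           write_result_tsv(as.data.frame(env$gsea), paths[1])
           write_result_tsv(as.data.frame(env$overlap), paths[2])
         },
         load = function(env, paths, cfg) {
           env$gsea <- utils::read.delim(paths[1], stringsAsFactors = FALSE)
           env$overlap <- utils::read.delim(paths[2], stringsAsFactors = FALSE)
         })
  )
}

#' Gene sets from a module assignment
#'
#' @param modules named integer vector (feature -> module id).
#' @param include_gray include module 0 as a set.
#' @return named list of feature-id vectors, \code{module<k>}.
#' @export
module_gene_sets <- function(modules, include_gray = FALSE) {
  ids <- sort(unique(modules))
  if (!include_gray) ids <- setdiff(ids, 0L)
  stats::setNames(lapply(ids, function(k) names(modules)[modules == k]),
                  paste0("module", ids))
}
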