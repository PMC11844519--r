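#' Simulation configuration for synthetic case-control RNA-seq data
#'
#' Defines the data-generating model used throughout validation: a
#' feature-by-sample negative-binomial count matrix with block-structured
#' co-expression modules, a small diagnosis effect carried on the latent
#' module factors of a subset of modules, library-size variation, and
#' diagnosis-correlated ternary toxicology exposures
#' (present/absent/unknown).
#'
#' The latent model per sample \code{s}: each module \code{m} has a factor
#' \code{f_m(s) ~ N(0,1)}; gene \code{i} in module \code{m} has
#' \code{z_i(s) = sqrt(rho) f_m(s) + sqrt(1-rho) e_i(s)} with
#' \code{rho = within_module_cor} and iid standard-normal noise \code{e};
#' unassigned (gray) genes are pure noise. If \code{m} is an effect module
#' and the sample's diagnosis equals \code{effect_group},
#' \code{effect_size * sign_m} is added to \code{z_i(s)}. Counts are drawn
#' negative binomial with mean \code{L_s * exp(b_i + latent_scale * z_i(s))}
#' (per-gene baseline \code{b_i} log-uniform, library size \code{L_s}
#' log-uniform) and variance \code{mu + nb_dispersion * mu^2}.
#'
#' @param n_per_group named integer vector of samples per diagnostic group;
#'   names are the diagnosis labels, first entry is the control/baseline
#'   group. Default \code{c(Control=55, SCZ=44, BD=35, MDD=51)}, the design
#'   of a typical postmortem psychiatric cohort.
#' @param n_genes total number of features.
#' @param module_sizes integer vector of planted module sizes; genes beyond
#'   \code{sum(module_sizes)} are unassigned (module 0).
#' @param within_module_cor target latent correlation \code{rho} within a
#'   module, in [0,1).
#' @param effect_modules integer ids of modules carrying the diagnosis
#'   effect.
#' @param effect_size standardized shift added to the latent variable of
#'   effect-module genes in the affected group. May be a vector (one signed
#'   value per effect module).
#' @param effect_group diagnosis label carrying the effect.
#' @param n_tox number of ternary toxicology exposure variables.
#' @param tox_assoc matrix of Bernoulli exposure probabilities, groups x
#'   n_tox. Default: 0.15 in the control group and 0.30 in each case group,
#'   giving diagnosis-correlated exposures.
#' @param unknown_prob probability that an exposure entry is relabeled
#'   "unknown".
#' @param nb_dispersion negative-binomial dispersion (var = mu + disp*mu^2).
#' @param libsize_range multiplicative library-size interval (log-uniform).
#' @param baseline_range per-gene mean count interval (log-uniform).
#' @param latent_scale scale applied to the latent variable on the log-mean
#'   scale.
#' @param seed integer RNG seed; the simulation is deterministic given the
#'   full configuration.
#' @return an object of class \code{"simulation_config"}.
#' @seealso [simulate_dataset()], [null_config()]
#' @export
simulation_config <- function(n_per_group = c(Control = 55, SCZ = 44, BD = 35, MDD = 51),
                              n_genes = 2000,
                              n_modules = 20,
                              module_sizes = NULL,
                              within_module_cor = 0.7,
                              effect_modules = 1:3,
                              effect_size = 0.4,
                              effect_group = "SCZ",
                              n_tox = 17,
                              tox_assoc = NULL,
                              unknown_prob = 0.05,
                              nb_dispersion = 0.05,
                              libsize_range = c(0.7, 1.4),
                              baseline_range = c(50, 5000),
                              latent_scale = 0.3,
                              seed = 1L) {
  if (is.null(names(n_per_group))) {
    names(n_per_group) <- c("Control", "SCZ", "BD", "MDD")[seq_along(n_per_group)]
  }
  if (is.null(module_sizes)) module_sizes <- rep(floor(0.8 * n_genes / n_modules), n_modules)
  n_modules <- length(module_sizes)
  stop_if(sum(module_sizes) > n_genes, "sum(module_sizes) exceeds n_genes")
  stop_if(within_module_cor < 0 || within_module_cor >= 1,
          "within_module_cor must lie in [0, 1)")
  stop_if(nb_dispersion <= 0, "nb_dispersion must be positive")
  stop_if(any(effect_modules > n_modules) || any(effect_modules < 1 & length(effect_modules)),
          "effect_modules must index module_sizes")
  stop_if(!effect_group %in% names(n_per_group), "effect_group not among group labels")
  stop_if(unknown_prob < 0 || unknown_prob > 1, "unknown_prob must lie in [0, 1]")
  if (is.null(tox_assoc)) {
    tox_assoc <- matrix(0.30, nrow = length(n_per_group), ncol = n_tox,
                        dimnames = list(names(n_per_group), sprintf("tox%02d", seq_len(n_tox))))
    tox_assoc[1L, ] <- 0.15
  }
  stop_if(nrow(tox_assoc) != length(n_per_group) || ncol(tox_assoc) != n_tox,
          "tox_assoc must be groups x n_tox")
  stop_if(any(tox_assoc < 0 | tox_assoc > 1), "tox_assoc entries must be probabilities")
  stop_if(length(effect_size) != 1 && length(effect_size) != length(effect_modules),
          "effect_size must be scalar or one value per effect module")
  structure(list(n_per_group = n_per_group, n_genes = as.integer(n_genes),
                 module_sizes = as.integer(module_sizes),
                 within_module_cor = within_module_cor,
                 effect_modules = as.integer(effect_modules),
                 effect_size = effect_size, effect_group = effect_group,
                 n_tox = as.integer(n_tox), tox_assoc = tox_assoc,
                 unknown_prob = unknown_prob, nb_dispersion = nb_dispersion,
                 libsize_range = libsize_range, baseline_range = baseline_range,
                 latent_scale = latent_scale, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Null counterpart of a simulation configuration
#'
#' Removes the diagnosis effect (\code{effect_size = 0}) and equalizes the
#' toxicology exposure probabilities across diagnostic groups (each column
#' set to its across-group mean), so that group labels are exchangeable and
#' downstream permutation p-values are calibrated.
#'
#' @param base a \code{simulation_config}.
#' @return a \code{simulation_config}; idempotent.
#' @export
null_config <- function(base) {
  stopifnot(inherits(base, "simulation_config"))
  base$effect_size <- if (length(base$effect_size) > 1) rep(0, length(base$effect_size)) else 0
  base$tox_assoc[] <- rep(colMeans(base$tox_assoc), each = nrow(base$tox_assoc))
  base
}

#' Simulate a synthetic case-control expression dataset
#'
#' Draws a count matrix, a sample covariate table, and the ground-truth
#' record from the latent-factor negative-binomial model described in
#' [simulation_config()].
#'
#' @param config a \code{simulation_config}.
#' @return a list with components
#'   \describe{
#'     \item{counts}{integer matrix, features x samples, with gene and
#'       sample ids in dimnames.}
#'     \item{samples}{data.frame with \code{sample_id}, \code{diagnosis}
#'       (factor, control level first) and one character column per
#'       toxicology variable with values present/absent/unknown.}
#'     \item{truth}{list: \code{true_modules} (named integer, 0 =
#'       unassigned), \code{true_effect} (named numeric, zero outside effect
#'       modules), \code{affected_group}, \code{tox_assoc_used}.}
#'   }
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  set.seed(cf$seed)
  n <- sum(cf$n_per_group)
  groups <- names(cf$n_per_group)
  diagnosis <- factor(rep(groups, cf$n_per_group), levels = groups)
  sample_ids <- sprintf("S%03d", seq_len(n))
  gene_ids <- sprintf("g%04d", seq_len(cf$n_genes))

  modules <- integer(cf$n_genes)
  idx <- 1L
  for (m in seq_along(cf$module_sizes)) {
    modules[idx:(idx + cf$module_sizes[m] - 1L)] <- m
    idx <- idx + cf$module_sizes[m]
  }
  names(modules) <- gene_ids

  eff <- rep(0, length(cf$module_sizes))
  eff[cf$effect_modules] <- if (length(cf$effect_size) == 1)
    rep(cf$effect_size, length(cf$effect_modules)) else cf$effect_size
  true_effect <- ifelse(modules > 0, eff[pmax(modules, 1L)], 0)
  names(true_effect) <- gene_ids

  rho <- cf$within_module_cor
  K <- length(cf$module_sizes)
  fac <- matrix(stats::rnorm(K * n), K, n)                 # module factors, K x samples
  e <- matrix(stats::rnorm(cf$n_genes * n), cf$n_genes, n) # idiosyncratic noise
  z <- sqrt(1 - rho) * e
  assigned <- modules > 0
  z[assigned, ] <- z[assigned, ] + sqrt(rho) * fac[modules[assigned], , drop = FALSE]
  # genes with rho applying only to assigned genes; gray genes keep unit variance
  z[!assigned, ] <- e[!assigned, ]
  affected <- diagnosis == cf$effect_group
  if (any(true_effect != 0) && any(affected)) {
    z[, affected] <- z[, affected] + true_effect
  }

  b <- stats::runif(cf$n_genes, log(cf$baseline_range[1]), log(cf$baseline_range[2]))
  L <- exp(stats::runif(n, log(cf$libsize_range[1]), log(cf$libsize_range[2])))
  mu <- exp(b + cf$latent_scale * z)          # features x samples
  mu <- sweep(mu, 2, L, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cf$nb_dispersion),
                   nrow = cf$n_genes, dimnames = list(gene_ids, sample_ids))

  tox <- matrix("absent", n, cf$n_tox,
                dimnames = list(sample_ids, colnames(cf$tox_assoc)))
  for (j in seq_len(cf$n_tox)) {
    pr <- cf$tox_assoc[as.integer(diagnosis), j]
    tox[stats::runif(n) < pr, j] <- "present"
  }
  if (cf$unknown_prob > 0) {
    tox[matrix(stats::runif(length(tox)) < cf$unknown_prob, n)] <- "unknown"
  }

  samples <- data.frame(sample_id = sample_ids, diagnosis = diagnosis,
                        stringsAsFactors = FALSE)
  samples <- cbind(samples, as.data.frame(tox, stringsAsFactors = FALSE))

  list(counts = counts, samples = samples,
       truth = list(true_modules = modules, true_effect = true_effect,
                    affected_group = cf$effect_group, tox_assoc_used = cf$tox_assoc))
}
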