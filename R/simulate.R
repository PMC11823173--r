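#' Configuration for the synthetic-cohort generator
#'
#' The generator plants correlated gene blocks driven by one latent factor
#' per module, a designated anchor gene inside one module, cohort covariates,
#' and survival times whose hazard is tied to the anchor module's factor.
#'
#' @param n_genes total genes (background genes are pure noise).
#' @param n_samples cohort size.
#' @param module_sizes integer vector of planted block sizes; their sum must
#'   not exceed \code{n_genes}.
#' @param loading_range c(low, high) in (0, 1]: per-gene factor loadings are
#'   uniform on this interval. \code{c(0, 0)} disables loadings (pure noise).
#' @param noise_sd gaussian noise standard deviation.
#' @param anchor_gene_id id of the anchor gene (default "COL10A1").
#' @param anchor_module_index which planted module contains the anchor.
#' @param factor_mixture optional \code{c(delta, weight)}: the anchor module's
#'   factor becomes a two-component gaussian mixture with means +/- delta/2
#'   and mixing weight \code{weight} for the lower component. Produces the
#'   bimodal module-expression distribution the stratification stage assumes.
#' @param survival list: \code{baseline_rate} (exponential baseline hazard),
#'   \code{beta_signal} (log hazard per SD of the anchor factor),
#'   \code{beta_age} (per year, centered), \code{beta_stage} (stage 3-4 vs
#'   1-2), \code{censor_horizon} (uniform censoring upper bound).
#' @param celltypes list: \code{k_types}, \code{n_reps} (replicates per
#'   type, >= 2), \code{nb_dispersion} (negative-binomial dispersion > 0),
#'   \code{marker_fold} (planted marker fold change, >= 4),
#'   \code{markers_per_type}.
#' @param gender_preset "balanced" (50/50) or "brca_like" (1 percent male).
#' @param seed integer seed; one seed drives every stage of one simulation.
#' @return a validated \code{SimConfig} list.
#' @export
sim_config <- function(n_genes = 300, n_samples = 200,
                       module_sizes = c(60, 40),
                       loading_range = c(0.6, 0.9),
                       noise_sd = 1,
                       anchor_gene_id = "COL10A1",
                       anchor_module_index = 1,
                       factor_mixture = NULL,
                       survival = list(baseline_rate = 0.1, beta_signal = log(2),
                                       beta_age = 0.02, beta_stage = 0.3,
                                       censor_horizon = 30),
                       celltypes = list(k_types = 4, n_reps = 3, nb_dispersion = 0.1,
                                        marker_fold = 16, markers_per_type = 25),
                       gender_preset = c("balanced", "brca_like"),
                       seed = 1L) {
  gender_preset <- match.arg(gender_preset)
  stopifnot(n_genes >= 1, n_samples >= 2)
  if (sum(module_sizes) > n_genes)
    stop("sum(module_sizes) exceeds n_genes")
  if (length(loading_range) != 2 || loading_range[1] > loading_range[2] ||
      loading_range[1] < 0 || loading_range[2] > 1)
    stop("loading_range must be (low, high) within [0, 1]")
  if (anchor_module_index < 1 || anchor_module_index > length(module_sizes))
    stop("anchor_module_index out of range (", length(module_sizes), " modules)")
  if (!is.null(factor_mixture)) {
    stopifnot(length(factor_mixture) == 2)
    if (factor_mixture[2] <= 0 || factor_mixture[2] >= 1)
      stop("mixture weight must be in (0, 1)")
  }
  if (celltypes$n_reps < 2) stop("celltypes$n_reps must be >= 2")
  if (celltypes$nb_dispersion <= 0) stop("celltypes$nb_dispersion must be > 0")
  if (celltypes$marker_fold < 4) stop("celltypes$marker_fold must be >= 4")
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 module_sizes = module_sizes, loading_range = loading_range,
                 noise_sd = noise_sd, anchor_gene_id = anchor_gene_id,
                 anchor_module_index = anchor_module_index,
                 factor_mixture = factor_mixture, survival = survival,
                 celltypes = celltypes, gender_preset = gender_preset,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate an expression cohort with planted modules, covariates and survival
#'
#' Module genes follow \code{x_gs = lambda_g * z_m(g),s + eps_gs} with
#' loadings uniform on \code{loading_range}, one standard-normal latent
#' factor per module (the anchor module's factor optionally a two-gaussian
#' mixture) and gaussian noise. Background genes are pure noise. Survival
#' times are exponential with hazard
#' \code{baseline_rate * exp(beta_signal * z_anchor_sd + beta_age * (age-60)
#' + beta_stage * stage34)}, independently censored at uniform times up to
#' \code{censor_horizon}. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()] object.
#' @return list with \code{expression} (ExpressionMatrix, unit "log2"),
#'   \code{clinical} (ClinicalTable) and \code{truth} (true module labels,
#'   per-sample latent factors, loadings, survival coefficients).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n_g <- config$n_genes; n_s <- config$n_samples
  sizes <- config$module_sizes
  k_mod <- length(sizes)

  gene_ids <- sprintf("G%04d", seq_len(n_g))
  # anchor gene replaces one id inside its module block
  labels <- integer(n_g)
  idx <- 1L
  for (m in seq_len(k_mod)) {
    labels[idx:(idx + sizes[m] - 1L)] <- m
    idx <- idx + sizes[m]
  }
  anchor_pos <- which(labels == config$anchor_module_index)[1]
  gene_ids[anchor_pos] <- config$anchor_gene_id
  sample_ids <- sprintf("S%04d", seq_len(n_s))

  # latent factors: one per module
  Z <- matrix(stats::rnorm(k_mod * n_s), nrow = k_mod)
  if (!is.null(config$factor_mixture)) {
    delta <- config$factor_mixture[1]; w <- config$factor_mixture[2]
    comp <- stats::rbinom(n_s, 1, 1 - w)              # 1 = upper component
    Z[config$anchor_module_index, ] <-
      stats::rnorm(n_s) + ifelse(comp == 1, delta / 2, -delta / 2)
  }

  loadings <- numeric(n_g)
  in_mod <- labels > 0
  loadings[in_mod] <- stats::runif(sum(in_mod), config$loading_range[1],
                                   config$loading_range[2])
  X <- matrix(stats::rnorm(n_g * n_s, sd = config$noise_sd), nrow = n_g)
  if (any(in_mod))
    X[in_mod, ] <- X[in_mod, ] + loadings[in_mod] * Z[labels[in_mod], , drop = FALSE]
  dimnames(X) <- list(gene_ids, sample_ids)

  # clinical covariates
  age <- rnorm_trunc(n_s, 60, 10, 18, 90)
  p_male <- if (config$gender_preset == "brca_like") 0.01 else 0.5
  gender <- ifelse(stats::rbinom(n_s, 1, p_male) == 1, "male", "female")
  stage34 <- stats::rbinom(n_s, 1, 0.5)

  sv <- config$survival
  z_anchor <- Z[config$anchor_module_index, ]
  z_sd <- (z_anchor - mean(z_anchor)) / stats::sd(z_anchor)
  hazard <- sv$baseline_rate *
    exp(sv$beta_signal * z_sd + sv$beta_age * (age - 60) + sv$beta_stage * stage34)
  t_event <- stats::rexp(n_s, rate = hazard)
  c_time <- stats::runif(n_s, 0, sv$censor_horizon)
  os_time <- pmin(t_event, c_time)
  os_event <- as.numeric(t_event <= c_time)
  # disease-free interval: a second, shorter-horizon draw from the same hazard
  t_dfi <- stats::rexp(n_s, rate = hazard)
  c_dfi <- stats::runif(n_s, 0, sv$censor_horizon / 2)
  clinical <- as_clinical_table(data.frame(
    sample_id = sample_ids, age = age, gender = gender,
    stage_binary = ifelse(stage34 == 1, "3-4", "1-2"),
    os_time = os_time, os_event = os_event,
    dfi_time = pmin(t_dfi, c_dfi), dfi_event = as.numeric(t_dfi <= c_dfi),
    stringsAsFactors = FALSE))

  truth <- list(module_labels = stats::setNames(labels, gene_ids),
                factors = Z, anchor_factor = z_anchor,
                loadings = stats::setNames(loadings, gene_ids),
                survival_coefficients = sv, stage34 = stage34)
  list(expression = expression_matrix(X, unit = "log2",
                                      cohort_label = sprintf("synthetic-seed%d", config$seed)),
       clinical = clinical, truth = truth)
}

#' Simulate an independent cohort of the same synthetic biology
#'
#' Draws a new patient cohort from the generative model of an existing
#' simulation: gene module memberships and per-gene factor loadings are
#' reused (they encode the "biology"), while latent factors, noise,
#' covariates and survival are redrawn. This is the synthetic analogue of
#' profiling a second, independent cohort of the same disease, and is the
#' appropriate test cohort for module preservation.
#'
#' @param config the [sim_config()] used for the original cohort.
#' @param truth the original simulation's \code{truth} element.
#' @param seed new integer seed for the replicate draws.
#' @return same structure as [simulate_cohort()].
#' @export
replicate_cohort <- function(config, truth, seed) {
  stopifnot(inherits(config, "SimConfig"))
  cfg2 <- config
  cfg2$seed <- as.integer(seed)
  out <- simulate_cohort(cfg2)
  # rebuild expression with the original loadings on the replicate factors;
  # the RNG stream continues from the simulate_cohort draws, so the fresh
  # noise is independent of the factors yet still seed-deterministic
  labels <- truth$module_labels
  n_s <- config$n_samples
  k_mod <- length(config$module_sizes)
  Z <- out$truth$factors
  X <- matrix(stats::rnorm(length(labels) * n_s, sd = config$noise_sd),
              nrow = length(labels),
              dimnames = list(names(labels), colnames(out$expression$values)))
  in_mod <- labels > 0
  X[in_mod, ] <- X[in_mod, ] +
    truth$loadings[in_mod] * Z[labels[in_mod], , drop = FALSE]
  out$expression <- expression_matrix(X, unit = "log2",
                                      cohort_label = sprintf("replicate-seed%d", seed))
  out$truth$module_labels <- labels
  out$truth$loadings <- truth$loadings
  out
}

#' Simulate replicate cell-type count profiles with planted markers
#'
#' Draws negative-binomial counts for \code{k_types} cell types with
#' \code{n_reps} replicates each. Baseline gene means are log-normal; each
#' planted marker's mean is multiplied by \code{marker_fold} in its own type,
#' so its expected fold versus every other type equals \code{marker_fold}.
#' The anchor gene is planted as a marker of the last type.
#'
#' @param config a [sim_config()] object (fields under \code{celltypes}).
#' @return list with \code{counts} (ExpressionMatrix, unit "counts"),
#'   \code{labels} (cell type per column) and \code{truth} (marker sets per
#'   type).
#' @export
simulate_celltype_counts <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  ct <- config$celltypes
  if (ct$k_types < 2) stop("k_types must be >= 2")
  set.seed(config$seed + 1L)
  k <- ct$k_types; reps <- ct$n_reps
  n_g <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(n_g))
  types <- paste0("type", seq_len(k))
  labels <- rep(types, each = reps)
  sample_ids <- paste0(labels, "_r", rep(seq_len(reps), times = k))

  base_mu <- exp(stats::rnorm(n_g, log(100), 0.8))
  mu <- matrix(rep(base_mu, k), nrow = n_g,
               dimnames = list(gene_ids, types))
  marker_sets <- stats::setNames(vector("list", k), types)
  n_mark <- ct$markers_per_type
  if (n_mark * k > n_g) stop("markers_per_type * k_types exceeds n_genes")
  if (n_mark > 0) {
    pool <- sample(gene_ids, n_mark * k)
    for (t in seq_len(k)) {
      mg <- pool[((t - 1) * n_mark + 1):(t * n_mark)]
      marker_sets[[t]] <- mg
      mu[mg, t] <- mu[mg, t] * ct$marker_fold
    }
    # anchor gene planted as a marker of the last type
    last <- types[k]
    if (!config$anchor_gene_id %in% unlist(marker_sets)) {
      swap <- marker_sets[[last]][1]
      gene_ids[gene_ids == swap] <- config$anchor_gene_id
      rownames(mu) <- gene_ids
      marker_sets[[last]][1] <- config$anchor_gene_id
    }
  }
  size <- 1 / ct$nb_dispersion
  counts <- matrix(stats::rnbinom(n_g * k * reps, mu = mu[, rep(seq_len(k), each = reps)],
                                  size = size),
                   nrow = n_g, dimnames = list(gene_ids, sample_ids))
  list(counts = expression_matrix(counts, unit = "counts",
                                  cohort_label = sprintf("celltypes-seed%d", config$seed)),
       labels = stats::setNames(labels, sample_ids),
       truth = list(marker_sets = marker_sets, mean_matrix = mu))
}

#' Simulate bulk samples as noisy convex mixtures of cell-type profiles
#'
#' Sample j is \code{sum_t fractions[j, t] * profile_t} plus gaussian noise.
#'
#' @param profiles ExpressionMatrix or matrix, genes x cell types.
#' @param fractions samples x cell types matrix of non-negative weights.
#' @param noise_sd gaussian noise sd added to every entry.
#' @param seed integer seed.
#' @return list with \code{bulk} (ExpressionMatrix, unit "log2") and
#'   \code{fractions} (the truth, row-normalized copies included).
#' @export
simulate_mixtures <- function(profiles, fractions, noise_sd = 0, seed = 1L) {
  P <- expr_values(profiles)
  fractions <- as.matrix(fractions)
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (ncol(fractions) != ncol(P))
    stop("fractions columns must match profile cell types")
  set.seed(as.integer(seed))
  bulk <- P %*% t(fractions)
  if (noise_sd > 0)
    bulk <- bulk + matrix(stats::rnorm(length(bulk), sd = noise_sd), nrow = nrow(bulk))
  colnames(bulk) <- if (!is.null(rownames(fractions))) rownames(fractions) else
    sprintf("mix%03d", seq_len(nrow(fractions)))
  rel <- fractions / ifelse(rowSums(fractions) > 0, rowSums(fractions), NA)
  list(bulk = expression_matrix(bulk, unit = "log2", cohort_label = "mixtures"),
       fractions = list(absolute = fractions, relative = rel))
}
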