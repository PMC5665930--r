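#' Cohort specification for the turnover simulator
#'
#' Describes a cohort of individuals whose fecal communities convert SN-38G
#' to SN-38 ex vivo. Each individual belongs to a "low" or "high" metabolizer
#' group and is assigned a final percent-formation value drawn uniformly from
#' that group's range. Defaults reproduce the study design this package
#' emulates: 20 individuals split 16/4, low turnover in 0.04--8.72%, high in
#' 26.46--77.11%, sampled at 0, 1.5 and 3 minutes in triplicate.
#'
#' @param n_low,n_high Number of low and high metabolizer individuals.
#' @param low_range,high_range Percent-formation ranges `(min, max)` for each
#'   group. Must not overlap: `max(low_range) < min(high_range)`.
#' @param timepoints Sampling times in minutes; must include 0.
#' @param replicates Technical replicates per (individual, timepoint).
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   measurement noise applied independently to every peak area.
#' @param seed Integer seed; the simulation is a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_low = 16L, n_high = 4L,
                        low_range = c(0.04, 8.72),
                        high_range = c(26.46, 77.11),
                        timepoints = c(0, 1.5, 3),
                        replicates = 3L,
                        noise_cv = 0.05,
                        seed = 1L) {
  stopifnot(n_low >= 0, n_high >= 0, n_low + n_high >= 1)
  if (length(timepoints) == 0) stop("timepoints must be non-empty")
  if (!0 %in% timepoints) stop("timepoints must include 0")
  if (length(low_range) != 2 || length(high_range) != 2 ||
      low_range[1] > low_range[2] || high_range[1] > high_range[2])
    stop("ranges must be (min, max) pairs")
  if (n_low > 0 && n_high > 0 && low_range[2] >= high_range[1])
    stop("low and high percent-formation ranges overlap")
  if (replicates < 1) stop("replicates must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(n_individuals = n_low + n_high, n_low = as.integer(n_low),
                 n_high = as.integer(n_high), low_range = low_range,
                 high_range = high_range, timepoints = sort(timepoints),
                 replicates = as.integer(replicates), noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate an ex vivo SN-38G turnover time course
#'
#' Generates per-replicate peak areas for SN-38 (analyte), SN-38G (substrate)
#' and the internal standard. Each individual's final percent formation `f`
#' is drawn uniformly from their group's range; in expectation the analyte
#' signal rises linearly from 0 at t = 0 to `f`% of the initial substrate
#' signal at the final timepoint, the substrate declines by the same amount,
#' and the internal standard is constant. Every area is multiplied by
#' independent log-normal noise with mean 1 and CV `noise_cv`.
#'
#' Peak areas are tied to concentrations through a known "true" response
#' curve (area ratio = `response` x concentration), recorded in the truth
#' sidecar so quantitation can be round-trip tested.
#'
#' @param spec A [cohort_spec()].
#' @param substrate0_uM Initial SN-38G concentration (default 100 uM).
#' @param istd_uM Internal standard concentration (metadata only).
#' @param response Named response factors (area-ratio per uM) for `sn38`
#'   and `sn38g`.
#' @param istd_area Expected internal-standard peak area (arbitrary units).
#' @return A list with `table` (data.frame: individual, timepoint_min,
#'   replicate, area_sn38, area_sn38g, area_istd) and `truth` (group labels,
#'   planted percent formation per individual, the true calibration curves,
#'   and the assay constants).
#' @export
simulate_turnover <- function(spec, substrate0_uM = 100, istd_uM = 100,
                              response = c(sn38 = 0.01, sn38g = 0.01),
                              istd_area = 1e5) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_individuals
  ids <- sprintf("S%02d", seq_len(n))
  labels <- c(rep("low", spec$n_low), rep("high", spec$n_high))
  f <- numeric(n)
  if (spec$n_low > 0)
    f[labels == "low"] <- runif(spec$n_low, spec$low_range[1], spec$low_range[2])
  if (spec$n_high > 0)
    f[labels == "high"] <- runif(spec$n_high, spec$high_range[1], spec$high_range[2])

  t_final <- max(spec$timepoints)
  grid <- expand.grid(replicate = seq_len(spec$replicates),
                      timepoint_min = spec$timepoints,
                      individual = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("individual", "timepoint_min", "replicate")]
  frac <- if (t_final > 0) grid$timepoint_min / t_final else 0
  f_row <- f[match(grid$individual, ids)]
  conc_sn38 <- (f_row / 100) * substrate0_uM * frac
  conc_sn38g <- substrate0_uM - conc_sn38
  m <- nrow(grid)
  grid$area_sn38 <- response[["sn38"]] * conc_sn38 * istd_area * rlnorm_cv(m, spec$noise_cv)
  grid$area_sn38g <- response[["sn38g"]] * conc_sn38g * istd_area * rlnorm_cv(m, spec$noise_cv)
  grid$area_istd <- istd_area * rlnorm_cv(m, spec$noise_cv)
  rownames(grid) <- NULL

  truth <- list(
    labels = data.frame(individual = ids, metabotype = labels,
                        percent_formation = f, stringsAsFactors = FALSE),
    curves = list(
      sn38 = list(metabolite = "sn38", slope = response[["sn38"]], intercept = 0),
      sn38g = list(metabolite = "sn38g", slope = response[["sn38g"]], intercept = 0)),
    substrate0_uM = substrate0_uM, istd_uM = istd_uM, istd_area = istd_area)
  list(table = grid, truth = truth)
}

#' Simulate a calibration table
#'
#' Peak-area ratios at known concentration levels under a linear response
#' with additive Gaussian noise: `ratio = slope * conc + intercept + N(0, noise_sd)`.
#'
#' @param levels Concentration levels (uM); at least two distinct values.
#' @param slope,intercept True response line.
#' @param noise_sd Additive Gaussian noise SD on the area ratio.
#' @param replicates Replicates per level.
#' @param seed Integer seed.
#' @param metabolite Metabolite name recorded in the table.
#' @return data.frame with columns metabolite, concentration_uM, area_ratio.
#' @export
simulate_calibration <- function(levels, slope, intercept = 0, noise_sd = 0,
                                 replicates = 1L, seed = 1L,
                                 metabolite = "sn38") {
  if (length(unique(levels)) < 2)
    stop("calibration needs at least two distinct concentration levels")
  stopifnot(noise_sd >= 0, replicates >= 1)
  set.seed(seed)
  conc <- rep(levels, each = replicates)
  ratio <- slope * conc + intercept + rnorm(length(conc), 0, noise_sd)
  data.frame(metabolite = metabolite, concentration_uM = conc,
             area_ratio = ratio, stringsAsFactors = FALSE)
}

#' Feature-table specification
#'
#' Log-normal feature abundances with optional planted fold changes in the
#' high-metabotype samples, emulating mapped relative-abundance tables
#' (taxa, beta-glucuronidases, transporters or KEGG orthologous groups).
#'
#' @param n_features,n_samples Table dimensions.
#' @param group_labels Character vector of per-sample labels ("low"/"high"),
#'   length `n_samples`.
#' @param baseline_log_mean,baseline_log_sd Parameters of the per-entry
#'   log-normal abundance model. The default log-SD of 0.15 (CV ~15%, the
#'   scale of technical variation in mapped abundances) is fixed by a power
#'   requirement: at the emulated 16 vs 4 design a planted fold-4 effect
#'   must be recoverable through the q < 0.05 + effect >= 2 rule. Real
#'   between-subject biological spreads are several-fold larger (log-SD >=
#'   0.5) and make such effects undetectable with 4 high samples; see the
#'   package vignette.
#' @param planted data.frame with columns `feature_id` (1-based integer
#'   index) and `fold_change` (> 0), applied multiplicatively in high-group
#'   samples. Empty by default.
#' @param feature_prefix Prefix for generated feature IDs.
#' @param seed Integer seed.
#' @return An object of class `feature_table_spec`.
#' @export
feature_table_spec <- function(n_features, n_samples, group_labels,
                               baseline_log_mean = 5,
                               baseline_log_sd = 0.15,
                               planted = data.frame(feature_id = integer(),
                                                    fold_change = numeric()),
                               feature_prefix = "F",
                               seed = 1L) {
  stopifnot(n_features >= 1, n_samples >= 1)
  if (length(group_labels) != n_samples)
    stop("group_labels must have one entry per sample")
  if (!all(group_labels %in% c("low", "high")))
    stop("group_labels must be 'low' or 'high'")
  planted <- as.data.frame(planted)
  if (nrow(planted)) {
    if (any(planted$fold_change <= 0)) stop("fold_change must be > 0")
    if (any(planted$feature_id < 1 | planted$feature_id > n_features))
      stop("planted feature_id out of range")
  }
  structure(list(n_features = as.integer(n_features),
                 n_samples = as.integer(n_samples),
                 group_labels = group_labels,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 planted = planted, feature_prefix = feature_prefix,
                 seed = as.integer(seed)),
            class = "feature_table_spec")
}

#' Simulate a feature abundance table
#'
#' `abundance[f, s] = exp(N(baseline_log_mean, baseline_log_sd))`, with
#' planted features multiplied by their fold change in high-group samples.
#' All values are strictly positive.
#'
#' @param spec A [feature_table_spec()].
#' @return List with `table` (features x samples matrix), `labels` (named
#'   character vector of sample metabotypes), `truth` (the planted effects).
#' @export
simulate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "feature_table_spec"))
  set.seed(spec$seed)
  mat <- matrix(exp(rnorm(spec$n_features * spec$n_samples,
                          spec$baseline_log_mean, spec$baseline_log_sd)),
                nrow = spec$n_features, ncol = spec$n_samples)
  rownames(mat) <- sprintf("%s%04d", spec$feature_prefix, seq_len(spec$n_features))
  colnames(mat) <- sprintf("S%02d", seq_len(spec$n_samples))
  hi <- spec$group_labels == "high"
  if (nrow(spec$planted) && any(hi))
    mat[spec$planted$feature_id, hi] <-
      mat[spec$planted$feature_id, hi, drop = FALSE] * spec$planted$fold_change
  labels <- setNames(spec$group_labels, colnames(mat))
  truth <- spec$planted
  if (nrow(truth)) truth$feature <- rownames(mat)[truth$feature_id]
  list(table = mat, labels = labels, truth = truth)
}

#' Reaction-network specification
#'
#' Linear enzyme chains (enzyme i's product is enzyme i+1's substrate) with
#' optional random cross-links and ubiquitous currency compounds, emulating a
#' KEGG-style substrate/product annotation. Chain-end enzymes are recorded as
#' ground-truth peripheral nodes.
#'
#' @param n_chains Number of chains.
#' @param chain_length Enzymes per chain; >= 3 so central, intermediate and
#'   peripheral positions all exist.
#' @param cross_links Number of random extra product/substrate sharings.
#' @param currency_compounds Character IDs of compounds attached to every
#'   enzyme as both substrate and product (e.g. water, ATP analogues).
#' @param n_compounds Size of the compound pool; defaults to exactly what the
#'   topology requires.
#' @param seed Integer seed.
#' @return An object of class `reaction_spec`.
#' @export
reaction_spec <- function(n_chains, chain_length, cross_links = 0L,
                          currency_compounds = character(),
                          n_compounds = NULL, seed = 1L) {
  stopifnot(n_chains >= 1)
  if (chain_length < 3)
    stop("chain_length must be >= 3 so all centrality positions exist")
  needed <- n_chains * (chain_length + 1) + cross_links
  n_compounds <- n_compounds %||% needed
  if (n_compounds < needed)
    stop(sprintf("n_compounds must be >= %d for this topology", needed))
  structure(list(n_chains = as.integer(n_chains),
                 chain_length = as.integer(chain_length),
                 cross_links = as.integer(cross_links),
                 currency_compounds = currency_compounds,
                 n_compounds = as.integer(n_compounds),
                 seed = as.integer(seed)),
            class = "reaction_spec")
}

#' Simulate a reaction annotation
#'
#' @param spec A [reaction_spec()].
#' @return List with `annotation` (data.frame: enzyme_id, substrates,
#'   products; compound sets semicolon-joined) and `truth` (`peripheral`:
#'   chain-end enzyme IDs; `chain`: chain index per enzyme).
#' @export
simulate_reactions <- function(spec) {
  stopifnot(inherits(spec, "reaction_spec"))
  set.seed(spec$seed)
  n_enz <- spec$n_chains * spec$chain_length
  enzymes <- sprintf("K%04d", seq_len(n_enz))
  compounds <- sprintf("C%04d", seq_len(spec$n_compounds))
  subs <- vector("list", n_enz)
  prods <- vector("list", n_enz)
  chain_of <- integer(n_enz)
  peripheral <- character()
  cpd <- 0L
  e <- 0L
  for (ch in seq_len(spec$n_chains)) {
    backbone <- compounds[cpd + seq_len(spec$chain_length + 1)]
    cpd <- cpd + spec$chain_length + 1L
    for (j in seq_len(spec$chain_length)) {
      e <- e + 1L
      subs[[e]] <- backbone[j]
      prods[[e]] <- backbone[j + 1]
      chain_of[e] <- ch
      if (j == 1 || j == spec$chain_length)
        peripheral <- c(peripheral, enzymes[e])
    }
  }
  if (spec$cross_links > 0) {
    for (k in seq_len(spec$cross_links)) {
      uv <- sample.int(n_enz, 2)   # ordered pair, u != v
      cpd <- cpd + 1L
      link <- compounds[cpd]
      prods[[uv[1]]] <- c(prods[[uv[1]]], link)
      subs[[uv[2]]] <- c(subs[[uv[2]]], link)
    }
  }
  if (length(spec$currency_compounds)) {
    subs <- lapply(subs, c, spec$currency_compounds)
    prods <- lapply(prods, c, spec$currency_compounds)
  }
  annotation <- data.frame(
    enzyme_id = enzymes,
    substrates = vapply(subs, paste, "", collapse = ";"),
    products = vapply(prods, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  list(annotation = annotation,
       truth = list(peripheral = peripheral,
                    chain = setNames(chain_of, enzymes)))
}
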