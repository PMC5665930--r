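#' Default pipeline configuration
#'
#' A single config object drives the whole run. By default every input is
#' simulated at the emulated study design: 20 individuals (16 low / 4 high),
#' triplicate time courses at 0/1.5/3 min, 100 uM substrate, feature tables
#' with planted fold-4 effects, and a chain-structured reaction network with
#' enriched enzymes planted at chain ends. Thresholds mirror the analysis
#' defaults: q < 0.05, effect ratio >= 2, minimum metabotype gap 10 points,
#' Storey lambda 0.5.
#'
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param outdir Output directory.
#' @return A `run_config` list; fields can be overridden before
#'   [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L, outdir = tempfile("metabotyper_run_")) {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    cohort = list(n_low = 16L, n_high = 4L,
                  low_range = c(0.04, 8.72), high_range = c(26.46, 77.11),
                  timepoints = c(0, 1.5, 3), replicates = 3L,
                  noise_cv = 0.05),
    calibration = list(levels = c(0.5, 1, 5, 10, 25, 50, 100),
                       noise_sd = 0.005, replicates = 3L),
    features = list(n_features = 200L, baseline_log_mean = 5,
                    baseline_log_sd = 0.15, n_planted = 10L,
                    fold_change = 4, category = "BG"),
    reactions = list(n_chains = 8L, chain_length = 6L, cross_links = 6L,
                     currency_compounds = character(),
                     blacklist = character(), ko_fold_change = 4,
                     ko_baseline_log_mean = 5, ko_baseline_log_sd = 0.15),
    thresholds = list(q = 0.05, effect = 2.0, min_gap = 10, lambda = 0.5,
                      substrate_initial = 100),
    inputs = NULL,
    stages = list(enrichment = TRUE)),
    class = "run_config")
}

validate_run_config <- function(config) {
  th <- config$thresholds
  if (any(unlist(th) <= 0))
    stop("configuration error: all thresholds must be positive")
  if (!is.null(config$inputs)) {
    needed <- c("timecourse", "calibration_sn38", "calibration_sn38g",
                "features")
    if (isTRUE(config$stages$enrichment)) needed <- c(needed, "reactions")
    missing <- setdiff(needed, names(config$inputs))
    if (length(missing))
      stop("configuration error: missing input path(s): ",
           paste(missing, collapse = ", "))
    absent <- unlist(config$inputs[needed])
    absent <- absent[!file.exists(absent)]
    if (length(absent))
      stop("configuration error: input file(s) not found: ",
           paste(absent, collapse = ", "))
  }
  invisible(config)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full metabotyping pipeline
#'
#' Stage order: simulate (or load) inputs, fit calibration curves, quantify
#' the time course, compute percent formation, classify metabotypes, test
#' differential feature abundance, compute per-feature evenness, then the
#' enzyme odds-ratio / metabolic-network analysis. All per-stage outputs are
#' written under `config$outdir`; `report.json` summarises counts and is
#' byte-identical when re-run with the same config and seed.
#'
#' @param config A [default_run_config()]-style list.
#' @return The run report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config = default_run_config()) {
  validate_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  log_msg <- function(...) message(sprintf("[metabotyper] %s", sprintf(...)))
  seed <- config$seed
  th <- config$thresholds

  # --- inputs: simulate or load ------------------------------------------
  if (is.null(config$inputs)) {
    sim <- run_stage("simulate_turnover", {
      spec <- do.call(cohort_spec, c(config$cohort, list(seed = seed)))
      simulate_turnover(spec)
    })
    tc <- sim$table
    true_curves <- sim$truth$curves
    calib <- run_stage("simulate_calibration", {
      lapply(c(sn38 = "sn38", sn38g = "sn38g"), function(mb)
        simulate_calibration(config$calibration$levels,
                             slope = true_curves[[mb]]$slope,
                             intercept = true_curves[[mb]]$intercept,
                             noise_sd = config$calibration$noise_sd,
                             replicates = config$calibration$replicates,
                             seed = seed + 1L, metabolite = mb))
    })
    write_tsv(tc, out("timecourse.tsv"))
    write_tsv(calib$sn38, out("calibration_sn38.tsv"))
    write_tsv(calib$sn38g, out("calibration_sn38g.tsv"))
  } else {
    tc <- read_tsv(config$inputs$timecourse)
    calib <- list(sn38 = read_tsv(config$inputs$calibration_sn38),
                  sn38g = read_tsv(config$inputs$calibration_sn38g))
    sim <- NULL
  }

  # --- quantitation and metabotype classification ------------------------
  curves <- run_stage("fit_calibration",
                      lapply(calib, fit_calibration))
  quant <- run_stage("quantify", quantify(tc, curves))
  percents <- run_stage("percent_formation",
                        percent_formation(quant, th$substrate_initial))
  assign <- run_stage("classify_metabotype",
                      classify_metabotype(percents, th$min_gap))
  labels <- setNames(assign$assignments$metabotype,
                     assign$assignments$individual)
  write_tsv(quant, out("quant.tsv"))
  write_tsv(assign$assignments, out("metabotypes.tsv"))
  log_msg("metabotypes: %d low / %d high (split gap %.2f)",
          sum(labels == "low"), sum(labels == "high"), assign$split_gap)

  # --- feature table and differential abundance --------------------------
  if (is.null(config$inputs)) {
    feat <- run_stage("simulate_feature_table", {
      fc <- config$features
      planted <- if (fc$n_planted > 0)
        data.frame(feature_id = seq_len(fc$n_planted),
                   fold_change = fc$fold_change)
      else data.frame(feature_id = integer(), fold_change = numeric())
      # planted effects follow the TRUE group membership; the differential
      # stage then uses the classified labels, as it would on real data
      fspec <- feature_table_spec(
        fc$n_features, length(labels),
        group_labels = sim$truth$labels$metabotype,
        baseline_log_mean = fc$baseline_log_mean,
        baseline_log_sd = fc$baseline_log_sd,
        planted = planted, seed = seed + 2L)
      ft <- simulate_feature_table(fspec)
      colnames(ft$table) <- sim$truth$labels$individual
      names(ft$labels) <- sim$truth$labels$individual
      ft
    })
    write_feature_tsv(feat$table, feat$labels, out("features.tsv"))
  } else {
    feat <- read_feature_tsv(config$inputs$features)
  }
  diffab <- run_stage("differential_features",
                      differential_features(feat$table, labels,
                                            q_threshold = th$q,
                                            effect_threshold = th$effect,
                                            lambda = th$lambda,
                                            category = rep(config$features$category,
                                                           nrow(feat$table))))
  write_tsv(diffab, out("diffab.tsv"))
  log_msg("differential features: %d of %d significant",
          sum(diffab$significant), nrow(diffab))

  # --- evenness -----------------------------------------------------------
  evenness <- run_stage("evenness", {
    eds <- apply(feat$table, 1, function(v) {
      r <- simpson_equitability(v)
      c(ed = r$ed, s = r$s, d = r$d)
    })
    data.frame(feature_id = rownames(feat$table), t(eds),
               stringsAsFactors = FALSE)
  })
  write_tsv(evenness, out("evenness.tsv"))

  # --- enzyme enrichment and metabolic network ---------------------------
  net_stats <- NULL
  if (isTRUE(config$stages$enrichment)) {
    rc <- config$reactions
    if (is.null(config$inputs)) {
      rx <- run_stage("simulate_reactions",
                      simulate_reactions(reaction_spec(
                        rc$n_chains, rc$chain_length, rc$cross_links,
                        rc$currency_compounds, seed = seed + 3L)))
      ko <- run_stage("simulate_ko_table", {
        enzymes <- rx$annotation$enzyme_id
        planted <- data.frame(
          feature_id = match(rx$truth$peripheral, enzymes),
          fold_change = rc$ko_fold_change)
        kspec <- feature_table_spec(
          length(enzymes), length(labels),
          group_labels = sim$truth$labels$metabotype,
          baseline_log_mean = rc$ko_baseline_log_mean,
          baseline_log_sd = rc$ko_baseline_log_sd,
          planted = planted, seed = seed + 4L)
        kt <- simulate_feature_table(kspec)
        rownames(kt$table) <- enzymes
        colnames(kt$table) <- sim$truth$labels$individual
        kt$table
      })
      write_tsv(rx$annotation, out("reactions.tsv"))
      write_feature_tsv(ko, labels, out("ko_table.tsv"))
    } else {
      rx <- list(annotation = read_tsv(config$inputs$reactions), truth = NULL)
      ko_path <- config$inputs$ko_features %||% config$inputs$features
      ko <- read_feature_tsv(ko_path)$table
    }
    if (!all(rownames(ko) %in% rx$annotation$enzyme_id))
      stop("pipeline stage 'enrichment' failed: KO table rows do not match ",
           "the reaction annotation's enzyme IDs")
    ors <- run_stage("metabotype_odds_ratios",
                     metabotype_odds_ratios(ko, labels))
    g <- run_stage("build_network", build_network(rx$annotation, rc$blacklist))
    btw <- betweenness_centrality(g)
    ors <- ors[match(names(btw), ors$enzyme_id), , drop = FALSE]
    tiers <- centrality_tiers(btw)
    wil <- run_stage("compare_centrality",
                     compare_centrality(btw, ors$associated))
    rho <- run_stage("score_topology_correlation",
                     score_topology_correlation(ors$da_score, btw))
    hyp <- tier_enrichment(tiers$tier[match(names(btw), tiers$enzyme_id)],
                           ors$associated)
    write_tsv(ors, out("enrichment.tsv"))
    write_tsv(tiers, out("tiers.tsv"))
    write_tsv(igraph::as_data_frame(g, what = "edges"),
              out("network_edges.tsv"))
    igraph::write_graph(g, out("network.graphml"), format = "graphml")
    net_stats <- list(
      n_enzymes = length(btw),
      n_edges = igraph::ecount(g),
      n_associated = sum(ors$associated),
      categories = as.list(table(ors$category)),
      wilcoxon = wil,
      spearman_betweenness = rho,
      tier_enrichment = hyp,
      median_betweenness_associated = median(btw[ors$associated]),
      median_betweenness_non_associated = median(btw[!ors$associated]))
    jsonlite::write_json(net_stats, out("stats.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    log_msg("network: %d enzymes, %d edges; Wilcoxon p = %.3g",
            net_stats$n_enzymes, net_stats$n_edges, wil$p)
  }

  # --- report -------------------------------------------------------------
  report <- list(
    package = "metabotyper",
    version = as.character(utils::packageVersion("metabotyper")),
    seed = seed,
    config = config[c("cohort", "calibration", "features", "reactions",
                      "thresholds")],
    metabotypes = list(n_low = sum(labels == "low"),
                       n_high = sum(labels == "high"),
                       split_gap = assign$split_gap,
                       threshold = assign$threshold),
    calibration = lapply(curves, function(cv)
      cv[c("metabolite", "slope", "intercept", "residual_sd", "llod", "lloq")]),
    differential = list(n_features = nrow(diffab),
                        n_significant = sum(diffab$significant),
                        significant = diffab$feature_id[diffab$significant]),
    evenness = list(min_ed = min(evenness$ed), max_ed = max(evenness$ed)),
    network = net_stats)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}

#' Validate pipeline input tables
#'
#' Schema, sign and ID-consistency checks over the documented TSV
#' interfaces. Problems are collected, not thrown; fatal schema issues are
#' `errors`, recoverable oddities are `warnings`.
#'
#' @param paths Named list of file paths; recognized names: `timecourse`,
#'   `calibration` (or `calibration_sn38`/`calibration_sn38g`), `features`,
#'   `labels`, `reactions`.
#' @return List with character vectors `errors` and `warnings` and logical
#'   `ok`.
#' @export
validate_tables <- function(paths) {
  errors <- character(); warnings <- character()
  err <- function(...) errors <<- c(errors, sprintf(...))
  wrn <- function(...) warnings <<- c(warnings, sprintf(...))
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) err("%s: file not found: %s", nm, paths[[nm]])
  }
  if (length(errors)) return(list(errors = errors, warnings = warnings,
                                  ok = FALSE))
  feat <- NULL
  if (!is.null(paths$timecourse)) {
    tc <- read_tsv(paths$timecourse)
    needed <- c("individual", "timepoint_min", "replicate",
                "area_sn38", "area_sn38g", "area_istd")
    miss <- setdiff(needed, names(tc))
    if (length(miss)) err("timecourse: missing column(s) %s",
                          paste(miss, collapse = ", "))
    else {
      for (col in c("area_sn38", "area_sn38g", "area_istd")) {
        neg <- which(tc[[col]] < 0)
        if (length(neg)) err("timecourse: negative %s at row(s) %s", col,
                             paste(neg, collapse = ", "))
      }
      if (!0 %in% tc$timepoint_min) err("timecourse: no timepoint 0 present")
      if (any(tc$area_istd == 0)) wrn("timecourse: zero ISTD area present")
    }
  }
  for (nm in intersect(c("calibration", "calibration_sn38",
                         "calibration_sn38g"), names(paths))) {
    cb <- read_tsv(paths[[nm]])
    miss <- setdiff(c("concentration_uM", "area_ratio"), names(cb))
    if (length(miss)) err("%s: missing column(s) %s", nm,
                          paste(miss, collapse = ", "))
    else if (length(unique(cb$concentration_uM)) < 2)
      err("%s: fewer than 2 distinct concentration levels", nm)
  }
  if (!is.null(paths$features)) {
    feat <- tryCatch(read_feature_tsv(paths$features), error = function(e) {
      err("features: %s", conditionMessage(e)); NULL
    })
    if (!is.null(feat)) {
      neg <- which(feat$table < 0, arr.ind = TRUE)
      if (nrow(neg)) err("features: negative abundance at [%s]",
                         paste(sprintf("%s,%s", rownames(feat$table)[neg[, 1]],
                                       colnames(feat$table)[neg[, 2]]),
                               collapse = "; "))
      if (anyDuplicated(rownames(feat$table)))
        err("features: duplicated feature IDs")
    }
  }
  if (!is.null(paths$labels)) {
    lab <- read_tsv(paths$labels)
    miss <- setdiff(c("individual", "metabotype"), names(lab))
    if (length(miss)) err("labels: missing column(s) %s",
                          paste(miss, collapse = ", "))
    else {
      if (!all(lab$metabotype %in% c("low", "high")))
        err("labels: metabotype values must be 'low' or 'high'")
      if (!is.null(feat)) {
        unlabeled <- setdiff(colnames(feat$table), lab$individual)
        if (length(unlabeled))
          err("labels: sample(s) in features missing from labels: %s",
              paste(unlabeled, collapse = ", "))
      }
    }
  }
  if (!is.null(paths$reactions)) {
    rx <- read_tsv(paths$reactions)
    miss <- setdiff(c("enzyme_id", "substrates", "products"), names(rx))
    if (length(miss)) err("reactions: missing column(s) %s",
                          paste(miss, collapse = ", "))
    else if (anyDuplicated(rx$enzyme_id)) err("reactions: duplicated enzyme IDs")
  }
  list(errors = errors, warnings = warnings, ok = length(errors) == 0)
}
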