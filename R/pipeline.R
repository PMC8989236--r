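# End-to-end orchestration: curate -> features -> select -> train ->
# predict -> estimate-size -> benchmark -> gsla, from a single config, with
# every filtered/dropped count logged and a manifest recording parameters,
# seeds and output checksums so a rerun with the same config reproduces
# identical artifacts.

pipeline_defaults <- function() {
  list(min_studies = 2, require_low_throughput = TRUE, cutoff_year = 2017,
       neg_ratio = 100, auc_threshold = 0.6, folds = 5,
       sigma_grid = 2^seq(-6, 4, by = 2), cost_grid = 2^seq(-2, 8, by = 2),
       imputation = "zero", density_cutoff = 0.01, p_cutoff = 0.001,
       n_null = 1000, n_background = 1000, seed = 1,
       fixture = NULL, inputs = NULL, gde_size = 50)
}

#' Resolve a pipeline run configuration
#'
#' Accepts a named list or a YAML file path; unknown keys are rejected;
#' defaults carry the standard analysis parameters (minimum 2 studies,
#' AUC threshold 0.6, 1:100 negative ratio, 5 folds, density cutoff 0.01,
#' Q2 p cutoff 0.001).
#'
#' @param config named list of overrides, or a YAML file path.
#' @return complete config list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(config)] <- config
  defaults
}

md5_of <- function(paths) {
  unname(vapply(paths, function(p) as.character(tools::md5sum(p)), ""))
}

#' Run the full inference and annotation pipeline
#'
#' Executes the eight stages (curate, features, select, train, predict,
#' estimate_size, benchmark, gsla) over either a synthetic fixture
#' (`config$fixture`, a list of [fixture_config()] arguments) or input
#' files (`config$inputs`: paths `records`, `evidence_dir`, `gmt`, `gde`,
#' `universe`). Stage outputs are written under `out_dir` and a
#' `manifest.json` records parameters, seeds and MD5 checksums.
#'
#' @param config see [run_config()].
#' @param out_dir run directory (created).
#' @return the manifest list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(params = cfg[setdiff(names(cfg), c("fixture", "inputs"))],
                   stages = list())
  note <- function(stage, files, extra = list()) {
    manifest$stages[[stage]] <<- c(list(
      outputs = basename(files), md5 = md5_of(files)), extra)
    message("[", stage, "] done: ", paste(basename(files), collapse = ", "))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- inputs --------------------------------------------------------------
  if (!is.null(cfg$fixture)) {
    fx <- do.call(fixture_config, cfg$fixture)
    truth <- generate_true_interactome(fx)
    bundle <- generate_evidence(truth, fx)
    records <- generate_interaction_records(truth, fx)
    ann <- generate_annotation_split(truth, fx)
    universe <- fixture_genes(fx)
    collection <- ann$collection
    set.seed(fx$seed + 4L)
    gde <- sample(truth$modules[[1]], min(cfg$gde_size,
                                          length(truth$modules[[1]])))
  } else if (!is.null(cfg$inputs)) {
    inp <- cfg$inputs
    records <- read_interaction_records(inp$records)
    bundle <- read_evidence_dir(inp$evidence_dir)
    collection <- read_gmt(inp$gmt)
    gde <- readLines(inp$gde, warn = FALSE)
    gde <- trimws(gde[nzchar(trimws(gde))])
    universe <- readLines(inp$universe, warn = FALSE)
    universe <- trimws(universe[nzchar(trimws(universe))])
    ann <- NULL
    truth <- NULL
  } else {
    stop("config must provide either 'fixture' or 'inputs'")
  }

  # ---- 1. curate -----------------------------------------------------------
  curated <- stage("curate", {
    hc <- filter_high_confidence(records, cfg$min_studies,
                                 cfg$require_low_throughput)
    message("curate: ", length(unique(pair_key(records))), " reported pairs -> ",
            nrow(hc), " high-confidence")
    sp <- temporal_split(records, cfg$cutoff_year)
    train_pos <- sp$train[pair_key(sp$train) %in% pair_key(hc), ,
                          drop = FALSE]
    eval_pos <- sp$eval[pair_key(sp$eval) %in% pair_key(hc), , drop = FALSE]
    message("curate: ", nrow(train_pos), " training / ", nrow(eval_pos),
            " evaluation positives (cutoff ", cfg$cutoff_year, ")")
    neg <- sample_negatives(universe, hc, ratio = cfg$neg_ratio,
                            seed = cfg$seed,
                            n_negatives = floor(cfg$neg_ratio *
                                                  nrow(train_pos)))
    list(hc = hc, train_pos = train_pos, eval_pos = eval_pos, neg = neg,
         labels = labeled_pairs(train_pos, neg))
  })
  f_cur <- file.path(out_dir, c("train_positives.tsv", "eval_positives.tsv",
                                "negatives.tsv"))
  write.table(curated$train_pos, f_cur[1], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(curated$eval_pos, f_cur[2], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(curated$neg, f_cur[3], sep = "\t", quote = FALSE,
              row.names = FALSE)
  note("curate", f_cur,
       list(n_high_confidence = nrow(curated$hc),
            n_train_pos = nrow(curated$train_pos),
            n_eval_pos = nrow(curated$eval_pos),
            n_negatives = nrow(curated$neg)))

  # ---- 2. features ---------------------------------------------------------
  fm <- stage("features", {
    pairs <- rbind(curated$train_pos, curated$eval_pos, curated$neg)
    suppressMessages(build_feature_matrix(pairs, bundle))
  })
  f_fm <- file.path(out_dir, "features.tsv")
  write_feature_matrix(fm, f_fm)
  note("features", f_fm, list(n_pairs = nrow(fm)))

  # ---- 3. select -----------------------------------------------------------
  selected <- stage("select", {
    evals <- evaluate_features(fm, curated$labels)
    sel <- select_informative_features(evals, cfg$auc_threshold)
    message("select: ", length(sel), "/", length(evals),
            " features pass AUC > ", cfg$auc_threshold)
    list(evals = evals, features = sel)
  })
  f_sel <- file.path(out_dir, "selected_features.tsv")
  auc_tab <- data.frame(
    feature = names(selected$evals),
    auc = vapply(selected$evals, function(e) e$auc, 0),
    selected = names(selected$evals) %in% selected$features)
  write.table(auc_tab, f_sel, sep = "\t", quote = FALSE, row.names = FALSE)
  note("select", f_sel, list(selected = selected$features))

  # ---- 4. train ------------------------------------------------------------
  trained <- stage("train", {
    if (length(selected$features) == 0) {
      stop("no informative features; cannot train")
    }
    cv <- grid_search_cv(fm, curated$labels,
                         svm_config(sigma_grid = cfg$sigma_grid,
                                    cost_grid = cfg$cost_grid,
                                    folds = cfg$folds, seed = cfg$seed,
                                    imputation = cfg$imputation),
                         features = selected$features)
    model <- train_final(fm, curated$labels, cv$chosen,
                         features = selected$features,
                         imputation = cfg$imputation)
    list(cv = cv, model = model)
  })
  f_cv <- file.path(out_dir, "cv_report.tsv")
  write.table(trained$cv$grid, f_cv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  f_model <- file.path(out_dir, "model.rds")
  saveRDS(trained$model, f_model)
  note("train", c(f_cv, f_model), list(chosen = trained$cv$chosen))

  # ---- 5. predict ----------------------------------------------------------
  predicted <- stage("predict", {
    net <- predict_all_pairs(trained$model, universe, bundle,
                             known_positives = curated$train_pos)
    message("predict: ", attr(net, "n_predicted"), " predicted + ",
            nrow(curated$hc), " known -> ", nrow(net$edges), " edges")
    net
  })
  f_net <- file.path(out_dir, "network.tsv")
  write_network(predicted, f_net)
  note("predict", f_net,
       list(n_predicted = attr(predicted, "n_predicted"),
            n_edges = nrow(predicted$edges)))

  # ---- 6. estimate_size ----------------------------------------------------
  size_est <- stage("estimate_size", {
    key <- pair_key(attr(predicted, "predicted_only"))
    eval_sens <- if (nrow(curated$eval_pos) > 0) {
      mean(pair_key(curated$eval_pos) %in% key)
    } else NA_real_
    fresh_neg <- sample_negatives(universe, curated$hc, seed = cfg$seed + 7L,
                                  n_negatives = min(5000, nrow(curated$neg)))
    eval_spec <- 1 - mean(pair_key(fresh_neg) %in% key)
    sens <- min(trained$cv$chosen$sensitivity, eval_sens, na.rm = TRUE)
    n_all <- length(universe) * (length(universe) - 1) / 2
    est <- estimate_interactome_size(attr(predicted, "n_predicted"), n_all,
                                     sens, eval_spec)
    rc <- reliability_and_coverage(est$n_interactome, sens,
                                   attr(predicted, "n_predicted"))
    c(unclass(est), rc[c("reliability")],
      list(eval_sensitivity = eval_sens, eval_specificity = eval_spec))
  })
  f_size <- file.path(out_dir, "size_estimate.json")
  jsonlite::write_json(size_est, f_size, auto_unbox = TRUE, digits = NA)
  note("estimate_size", f_size)

  # ---- 7. benchmark --------------------------------------------------------
  bench <- stage("benchmark", {
    if (is.null(ann)) {
      NULL
    } else {
      gba_benchmark(predicted, ann$split)
    }
  })
  f_pr <- file.path(out_dir, "pr_curve.tsv")
  if (!is.null(bench)) {
    write.table(bench$points, f_pr, sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("benchmark", f_pr, list(pr_auc = bench$pr_auc))
  } else {
    writeLines("# no annotation split provided; benchmark skipped", f_pr)
    note("benchmark", f_pr, list(pr_auc = NA))
  }

  # ---- 8. gsla -------------------------------------------------------------
  gsla_res <- stage("gsla", {
    suppressWarnings(run_gsla(gde, collection, predicted,
                              density_cutoff = cfg$density_cutoff,
                              p_cutoff = cfg$p_cutoff, n_null = cfg$n_null,
                              n_background = cfg$n_background,
                              seed = cfg$seed))
  })
  f_gsla <- file.path(out_dir, "gsla_report.tsv")
  write_gsla_report(gsla_res, f_gsla)
  note("gsla", f_gsla,
       list(n_reported = sum(gsla_res$reported)))

  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
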