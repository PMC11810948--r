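#' Pipeline configuration
#'
#' Bundles either input file paths or a synthetic-data config together
#' with the analysis knobs. Exactly one of `paths` and `synthetic` must
#' be supplied.
#'
#' @param traits,survey,env,tree Optional input file paths (trait CSV,
#'   survey CSV, environment CSV, Newick tree). A stage whose input is
#'   absent is skipped.
#' @param synthetic Optional `synthetic_config`; when given, the dataset
#'   (traits, tree, environment) is generated instead of read.
#' @param r_threshold,p_threshold Network binarization thresholds.
#' @param alpha Level for the normality gate and interaction gating.
#' @param n_perm Tip shuffles for the phylogenetic-signal test.
#' @param seed Integer seed recorded in every output.
#' @param stratify Character vector of network stratifications to run
#'   (subset of `"type"`, `"elevation"`).
#' @param out_dir Optional directory; when given, [run_pipeline()] writes
#'   `report.json` and CSV siblings there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(traits = NULL, survey = NULL, env = NULL,
                            tree = NULL, synthetic = NULL,
                            r_threshold = 0.2, p_threshold = 0.05,
                            alpha = 0.05, n_perm = 999L, seed = 42L,
                            stratify = c("type", "elevation"),
                            out_dir = NULL) {
  has_paths <- !is.null(traits)
  if (has_paths == !is.null(synthetic))
    stop("supply exactly one of a traits path or a synthetic config",
         call. = FALSE)
  structure(list(traits = traits, survey = survey, env = env, tree = tree,
                 synthetic = synthetic, r_threshold = r_threshold,
                 p_threshold = p_threshold, alpha = alpha,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 stratify = match.arg(stratify, c("type", "elevation"),
                                      several.ok = TRUE),
                 out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE,
                                           error = conditionMessage(e)))
  if (res$ok) {
    report$stages[[name]] <- list(status = "ok")
    report[[name]] <- res$value
  } else {
    report$stages[[name]] <- list(status = "failed", error = res$error)
    warning("stage '", name, "' failed: ", res$error)
  }
  report
}

#' Run the full trait-analysis pipeline
#'
#' Stages, in order: importance values from the survey (skipped when no
#' survey is given), two-group trait comparisons, PCA, trait ~ type x
#' elevation linear models, environment regressions, Blomberg's K with
#' permutation null (skipped without a tree), and per-stratum trait
#' networks. A failed stage is marked in the report and later independent
#' stages still run. The whole run is deterministic under a fixed seed.
#'
#' @param config A `pipeline_config`.
#' @return A list of class `pipeline_report` with one element per stage
#'   (`iv`, `comparison`, `pca`, `models`, `env_regressions`,
#'   `phylo_signal`, `networks`), a `stages` status block and a
#'   `provenance` block (seed, thresholds, package version, stage skip
#'   reasons). When `config$out_dir` is set the report is also written to
#'   disk ([write_report()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  report <- list(stages = list())

  env_tab <- NULL; tree <- NULL; survey <- NULL
  if (!is.null(config$synthetic)) {
    ds <- generate_dataset(config$synthetic)
    traits <- ds$traits; tree <- ds$tree; env_tab <- ds$environment
    report$provenance <- list(source = "synthetic",
                              synthetic_seed = config$synthetic$seed)
  } else {
    traits <- read_trait_table(config$traits)
    if (!is.null(config$tree)) tree <- read_newick(config$tree)
    if (!is.null(config$env))
      env_tab <- as.data.frame(data.table::fread(config$env))
    report$provenance <- list(source = "files", traits = config$traits)
  }
  if (!is.null(config$survey))
    survey <- as.data.frame(data.table::fread(config$survey))

  if (!is.null(survey)) {
    report <- run_stage(report, "iv", {
      iv <- importance_value(survey)
      iv$rank <- match(iv$species, rank_species(iv, top_k = nrow(iv)))
      iv
    })
  } else report$stages$iv <- list(status = "skipped")

  report <- run_stage(report, "comparison",
                      compare_all_traits(traits, alpha = config$alpha))
  report <- run_stage(report, "pca", {
    pc <- trait_pca(standardize_traits(traits))
    list(variance_explained = pc$variance_explained,
         loadings_pc1 = pc$loadings[, 1], loadings_pc2 = pc$loadings[, 2])
  })
  report <- run_stage(report, "models", {
    codes <- trait_codes(traits)
    do.call(rbind, lapply(codes, function(code) {
      an <- fit_trait_model(code, traits)$anova
      data.frame(trait = code,
                 F_type = an$F[1], p_type = an$p[1],
                 F_elevation = an$F[2], p_elevation = an$p[2],
                 F_interaction = an$F[3], p_interaction = an$p[3],
                 stringsAsFactors = FALSE)
    }))
  })
  if (!is.null(env_tab)) {
    report <- run_stage(report, "env_regressions",
                        env_regressions(traits, env_tab))
  } else report$stages$env_regressions <- list(status = "skipped")

  if (!is.null(tree)) {
    report <- run_stage(report, "phylo_signal",
                        phylo_signal_all(traits, tree,
                                         n_perm = config$n_perm,
                                         seed = config$seed))
  } else report$stages$phylo_signal <- list(status = "skipped")

  report <- run_stage(report, "networks", {
    strata <- list(all = traits)
    for (by in config$stratify)
      strata <- c(strata, split_strata(traits, by))
    nets <- lapply(strata, function(tab)
      tryCatch({
        net <- build_network(tab, config$r_threshold, config$p_threshold)
        met <- network_metrics(net, seed = config$seed)
        list(metrics = met,
             relative_importance = as.list(met$relative_importance))
      }, error = function(e) list(error = conditionMessage(e))))
    summary <- do.call(rbind, lapply(names(nets), function(s) {
      met <- nets[[s]]$metrics
      if (is.null(met)) return(NULL)
      data.frame(stratum = s, n_edges = met$n_edges,
                 edge_density = met$edge_density,
                 modularity = met$modularity,
                 average_path_length = met$average_path_length,
                 stringsAsFactors = FALSE)
    }))
    list(per_stratum = nets, summary = summary)
  })

  report$provenance <- c(report$provenance, list(
    seed = config$seed, r_threshold = config$r_threshold,
    p_threshold = config$p_threshold, alpha = config$alpha,
    n_perm = config$n_perm,
    package_version = as.character(utils::packageVersion("traitnet"))))
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (the full report, with matrices simplified) plus
#' CSV siblings for the tabular stages.
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("iv", "comparison", "models", "env_regressions",
               "phylo_signal")) {
    if (is.data.frame(report[[nm]]))
      data.table::fwrite(report[[nm]], file.path(out_dir,
                                                 paste0(nm, ".csv")))
  }
  if (!is.null(report$networks$summary))
    data.table::fwrite(report$networks$summary,
                       file.path(out_dir, "network_summary.csv"))
  json <- report
  class(json) <- NULL
  json$networks$per_stratum <- lapply(json$networks$per_stratum,
    function(x) {
      if (!is.null(x$error)) return(x)
      met <- x$metrics
      list(degree = as.list(met$degree), n_edges = met$n_edges,
           edge_density = met$edge_density,
           modularity = met$modularity,
           modules = as.list(met$modules),
           average_path_length = met$average_path_length,
           disconnected = met$disconnected,
           relative_importance = x$relative_importance)
    })
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null", na = "null")
  invisible(out_dir)
}
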