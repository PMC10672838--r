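#' Configuration of an end-to-end pipeline run
#'
#' Bundles everything one run needs: the input (a [synthetic_spec()], an
#' existing [presence_matrix()], a matrix TSV path, or a list of
#' [genome_record()]s), the experiment arm(s), thresholds, the CV geometry,
#' the feature-selection settings and the classifier list. Seeds are
#' mandatory and explicit -- nothing is seeded from the wall clock.
#'
#' @param input a `synthetic_spec`, `presence_matrix`, list of
#'   `genome_record`s, or path to a matrix TSV.
#' @param arm "all_genes", "differential", or "both". The differential arm
#'   restricts the matrix to families that disagree within at least one
#'   multipartite/closest-unipartite-relative pair and therefore needs a
#'   pairing (synthetic matrices carry one).
#' @param homology a [homology_thresholds()] (used when input is records).
#' @param segregation a [segregation_thresholds()].
#' @param outer_k,inner_k outer and nested inner fold counts (6 and 10).
#' @param selection list: `clf` (ranking classifier, default "RF"),
#'   `method` ("native"/"permutation"), `top_k` (default 50), `n_random`
#'   (default 10).
#' @param classifiers classifier ids to benchmark (default: all twelve).
#' @param seed master integer seed.
#' @param nested compute the nested inner-CV panel (default TRUE).
#' @return object of class `run_config`.
#' @export
run_config <- function(input, arm = c("all_genes", "differential", "both"),
                       homology = homology_thresholds(),
                       segregation = segregation_thresholds(),
                       outer_k = 6, inner_k = 10,
                       selection = list(),
                       classifiers = CLASSIFIER_IDS, seed = 1L,
                       nested = TRUE) {
  arm <- match.arg(arm)
  selection <- utils::modifyList(
    list(clf = "RF", method = "native", top_k = 50, n_random = 10),
    selection)
  classifiers <- match.arg(classifiers, CLASSIFIER_IDS, several.ok = TRUE)
  if (is.character(input) && !file.exists(input))
    stopf("input matrix file does not exist: %s", input)
  structure(list(input = input, arm = arm, homology = homology,
                 segregation = segregation, outer_k = outer_k,
                 inner_k = inner_k, selection = selection,
                 classifiers = classifiers, seed = as.integer(seed),
                 nested = isTRUE(nested)),
            class = "run_config")
}

#' Load a run configuration from a YAML or JSON file
#'
#' Recognised keys mirror the [run_config()] arguments; `input` is either
#' `synthetic: {<synthetic_spec fields>}` or `matrix_tsv: <path>`.
#'
#' @param path YAML (.yml/.yaml, requires the yaml package) or JSON file.
#' @return a [run_config()]
#' @export
load_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("YAML configs require the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  input <- if (!is.null(cfg$synthetic))
    do.call(synthetic_spec, cfg$synthetic)
  else if (!is.null(cfg$matrix_tsv)) cfg$matrix_tsv
  else stopf("config must provide 'synthetic' or 'matrix_tsv'")
  run_config(
    input = input,
    arm = cfg$arm %||% "all_genes",
    homology = do.call(homology_thresholds, cfg$homology %||% list()),
    segregation = do.call(segregation_thresholds, cfg$segregation %||% list()),
    outer_k = cfg$outer_k %||% 6, inner_k = cfg$inner_k %||% 10,
    selection = cfg$selection %||% list(),
    classifiers = cfg$classifiers %||% CLASSIFIER_IDS,
    seed = cfg$seed %||% stopf("config must set an explicit seed"),
    nested = cfg$nested %||% TRUE)
}

#' Run the full pipeline and write a result directory
#'
#' Stages: input resolution (simulate / load / build matrix), then per
#' experiment arm: outer-fold planning, per-fold importance ranking,
#' Intersection + Random set construction, the classifier benchmark on
#' All/Intersection/Random sets, presence-pattern segregation of the
#' Intersection genes, and the two-component PCA. Every output is a TSV or
#' JSON file; a manifest records the configuration, seeds and software
#' versions, and a structured log records stage timings. Re-running with an
#' identical configuration reproduces every numeric output bit-identically
#' (the log's wall times are the only non-reproducible bytes).
#'
#' Any stage failure aborts with an error naming the stage; partial outputs
#' are kept next to a `FAILED` marker file.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; must not already contain a
#'   manifest).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  cat("", file = log_path)
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = log_path, append = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      file.create(file.path(out_dir, "FAILED"))
      log_line("stage=%s status=failed error=%s", name, conditionMessage(e))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    log_line("stage=%s status=ok elapsed=%.2fs", name,
             proc.time()[["elapsed"]] - t0)
    res
  }

  inp <- stage("input", resolve_input(config))
  write_matrix_tsv(inp$matrix, file.path(out_dir, "matrix.tsv"))

  arms <- if (config$arm == "both") c("all_genes", "differential")
          else config$arm
  for (arm in arms) {
    arm_dir <- if (length(arms) > 1) file.path(out_dir, arm) else out_dir
    dir.create(arm_dir, showWarnings = FALSE)
    pm <- if (arm == "differential")
      stage("differential_filter", filter_differential(inp$matrix))
    else inp$matrix
    if (arm == "differential")
      write_matrix_tsv(pm, file.path(arm_dir, "matrix_differential.tsv"))

    plan <- stage(paste0(arm, ":cv_plan"),
                  make_outer_folds(pm, config$outer_k, config$seed,
                                   config$inner_k))
    jsonlite::write_json(list(fold = as.list(plan$fold), k = plan$k,
                              inner_folds = plan$inner_folds,
                              seed = plan$seed),
                         file.path(arm_dir, "cv_plan.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    sets <- stage(paste0(arm, ":feature_selection"),
                  build_feature_sets(pm, plan,
                                     clf = config$selection$clf,
                                     method = config$selection$method,
                                     top_k = config$selection$top_k,
                                     n_random = config$selection$n_random,
                                     seed = config$seed))
    write_feature_sets(sets, file.path(arm_dir, "rankings.tsv"),
                       file.path(arm_dir, "feature_sets.json"))

    bench <- stage(paste0(arm, ":benchmark"),
                   benchmark_feature_sets(pm, sets, plan,
                                          classifiers = config$classifiers,
                                          seed = config$seed,
                                          nested = config$nested))
    write_benchmark_tsv(bench, file.path(arm_dir, "metrics_long.tsv"),
                        file.path(arm_dir, "metrics_wide.tsv"))

    seg_fams <- if (length(sets$intersection_set)) sets$intersection_set
                else family_ids(pm)
    seg <- stage(paste0(arm, ":segregation"),
                 segregate_sets(pm, seg_fams, config$segregation))
    write_tsv(as.data.frame(seg), file.path(arm_dir, "segregation.tsv"))

    if (length(seg_fams) >= 2) {
      pca <- stage(paste0(arm, ":pca"), pca_ordination(pm, seg_fams))
      write_pca_tsv(pca, file.path(arm_dir, "pca.tsv"))
    } else {
      log_line("stage=%s:pca status=skipped reason=fewer-than-2-features", arm)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("panphen")),
    r_version = R.version.string,
    seed = config$seed, arm = config$arm,
    outer_k = config$outer_k, inner_k = config$inner_k,
    selection = config$selection, classifiers = config$classifiers,
    homology = unclass(config$homology),
    segregation = unclass(config$segregation),
    nested = config$nested,
    input = if (inherits(config$input, "synthetic_spec"))
      unclass(config$input) else
        if (is.character(config$input)) config$input else "in-memory")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line("stage=done status=ok")
  invisible(out_dir)
}

resolve_input <- function(config) {
  inp <- config$input
  if (inherits(inp, "synthetic_spec")) {
    gen <- generate_matrix(inp)
    list(matrix = gen$matrix, truth = gen$truth)
  } else if (inherits(inp, "presence_matrix")) {
    list(matrix = inp, truth = NULL)
  } else if (is.character(inp)) {
    list(matrix = read_matrix_tsv(inp), truth = NULL)
  } else if (is.list(inp) && all(vapply(inp, inherits, TRUE, "genome_record"))) {
    fams <- cluster_hypothetical(inp, config$homology)
    list(matrix = build_presence_matrix(inp, fams), truth = NULL)
  } else stopf("unsupported input type")
}
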