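#' Configuration for an end-to-end run
#'
#' Exactly one input source must be given: a [sim_config()] (synthetic run)
#' or the three file paths (marker CSV, record CSV, layout CSV).
#'
#' @param model preset name (`"GM1"`, `"GM2"`, `"RM1"`, `"RM2"`).
#' @param sim optional [sim_config()].
#' @param marker_path,record_path,layout_path real-data inputs: markers as
#'   in [load_markers()]; records with the columns [assemble_model()]
#'   expects; layout with columns `bed`, `row`, `line` (plus optional
#'   `pair`, `position`).
#' @param tube_beds bed ids with minirhizotron tubes (real root runs).
#' @param out_dir output directory (created if needed).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param reestimate_vcs re-estimate variance components per CV fold
#'   (default `FALSE` here: the plug-in mode keeps orchestrated runs fast).
#' @param run_cv run leave-one-line-out cross-validation (default `TRUE`).
#' @return A `run_config` list.
#' @export
run_config <- function(model, sim = NULL, marker_path = NULL,
                       record_path = NULL, layout_path = NULL,
                       tube_beds = NULL, out_dir, seed,
                       reestimate_vcs = FALSE, run_cv = TRUE) {
  have_files <- !is.null(marker_path)
  if (is.null(sim) == !have_files)
    stop_domain("give exactly one of `sim` or file inputs")
  structure(list(model = match.arg(model, c("GM1", "GM2", "RM1", "RM2")),
                 sim = sim, marker_path = marker_path,
                 record_path = record_path, layout_path = layout_path,
                 tube_beds = tube_beds, out_dir = out_dir,
                 seed = as.integer(seed), reestimate_vcs = reestimate_vcs,
                 run_cv = run_cv),
            class = "run_config")
}

#' Run the full analysis pipeline and write a manifest
#'
#' Orchestrates simulate/load, G matrix, model assembly, REML fit, variance
#' partition and (optionally) leave-one-line-out cross-validation, writing
#' each stage's report under `out_dir` (JSON for machines, CSV for tables)
#' plus `manifest.json` listing every artifact with an md5 checksum. Given
#' the same config and seed the artifacts are bit-identical.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly (list of file, md5).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(name) {
    paths[length(paths) + 1L] <<- file.path(config$out_dir, name)
    paths[length(paths)]
  }
  if (!is.null(config$sim)) {
    ds <- simulate_trait(config$sim)
    markers <- ds$markers; layout <- ds$layout; records <- ds$records
    G <- ds$G
    write_markers(markers, emit("markers.csv"))
    utils::write.csv(layout$rows, emit("layout.csv"), row.names = FALSE)
    utils::write.csv(records, emit("records.csv"), row.names = FALSE)
  } else {
    markers <- impute_and_filter(load_markers(config$marker_path))
    records <- utils::read.csv(config$record_path)
    layout <- build_layout(utils::read.csv(config$layout_path),
                           tube_beds = config$tube_beds)
    G <- vanraden_G(markers)
  }
  write_G(G, emit("G.csv"))
  spec <- model_spec(config$model)
  bundle <- assemble_model(spec, records, layout, G)
  fit <- reml_fit(bundle)
  ses <- vc_standard_errors(fit)
  jsonlite::write_json(
    list(model = config$model, vcs = as.list(fit$vcs), se = as.list(ses),
         loglik = fit$loglik, iterations = fit$iterations,
         converged = fit$converged),
    emit("fit.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(term = rep(names(fit$blups), lengths(fit$blups)),
               level = unlist(lapply(fit$blups, names)),
               blup = unlist(fit$blups, use.names = FALSE)),
    emit("blups.csv"), row.names = FALSE)
  counts <- replicate_counts(records, layout, spec)
  part <- partition_report(fit, counts, bundle$g_bar,
                           mean(bundle$y), spec)
  utils::write.csv(part$table, emit("partition.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(model = config$model, sigma2_P = as.list(part$sigma2_P),
         h2 = as.list(part$h2), h2_mean = part$h2_mean,
         H2 = as.list(part$H2), H2_mean = part$H2_mean,
         cv_pct = part$cv_pct),
    emit("partition.json"), auto_unbox = TRUE, digits = NA)
  if (config$run_cv) {
    cv <- loo_cv_gebv(records, layout, G, spec,
                      reestimate_vcs = config$reestimate_vcs,
                      full_fit = fit)
    yc <- correct_phenotypes(fit, bundle)
    gebv <- stats::setNames(cv$gebv, cv$line)
    acc <- prediction_accuracy(yc$line_means, gebv, part$h2_mean)
    infl <- prediction_inflation(yc$line_means, gebv)
    cv$ybar_c <- yc$line_means[cv$line]
    utils::write.csv(cv, emit("cv.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(model = config$model, acc = acc$acc, cor = acc$cor,
           h2_used = acc$h2_used, slope = infl$slope, slope_se = infl$se,
           t_vs_1 = infl$t_vs_1, p = infl$p),
      emit("cv_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  manifest <- data.frame(file = basename(paths),
                         md5 = as.character(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA)
  invisible(manifest)
}
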