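## Study orchestration: corpora -> networks -> metric panel -> degree
## distribution fits -> random baselines -> statistical battery, with all
## intermediates written as plain text (Pajek .net, TSV, JSON) and a run
## manifest for reproducibility.

#' Study configuration
#'
#' @param corpora List of corpus entries, each a list with `path`,
#'   `format` (`"dialect"` or `"conllu"`), `label`, `modality`, `level`.
#' @param out_dir Output directory.
#' @param l_mode,nc_form Metric options (see [average_path_length()],
#'   [density_centralization()]).
#' @param punct_tags POS tags treated as punctuation when reading.
#' @param k_min Power-law fit cut-off.
#' @param baseline_reps,baseline_seed,tau_C,tau_L Random-baseline options.
#' @param battery_plan Battery plan (see [default_battery_plan()]).
#' @return A `study_config` list.
#' @export
study_config <- function(corpora, out_dir,
                         l_mode = "reachable", nc_form = "exact",
                         punct_tags = PUNCT_TAGS, k_min = 1,
                         baseline_reps = 30, baseline_seed = 0,
                         tau_C = 5, tau_L = 1.2,
                         battery_plan = default_battery_plan()) {
  if (!length(corpora)) stop_validation("at least one corpus is required")
  labs <- vapply(corpora, function(e) e$label %||% NA_character_, "")
  if (anyNA(labs) || anyDuplicated(labs))
    stop_validation("corpus labels must be present and unique")
  structure(list(corpora = corpora, out_dir = out_dir, l_mode = l_mode,
                 nc_form = nc_form, punct_tags = punct_tags, k_min = k_min,
                 baseline_reps = baseline_reps, baseline_seed = baseline_seed,
                 tau_C = tau_C, tau_L = tau_L, battery_plan = battery_plan),
            class = "study_config")
}

#' Read a study configuration from JSON
#'
#' @param path JSON file whose keys mirror the [study_config()] arguments.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$corpora)) stop_validation("config lacks 'corpora'")
  if (is.null(raw$out_dir)) stop_validation("config lacks 'out_dir'")
  plan <- default_battery_plan()
  if (!is.null(raw$battery_plan$t_variant))
    plan$t_variant[names(raw$battery_plan$t_variant)] <-
      unlist(raw$battery_plan$t_variant)
  if (!is.null(raw$battery_plan$native_in_regression))
    plan$native_in_regression <- isTRUE(raw$battery_plan$native_in_regression)
  study_config(
    corpora = raw$corpora, out_dir = raw$out_dir,
    l_mode = raw$l_mode %||% "reachable",
    nc_form = raw$nc_form %||% "exact",
    punct_tags = unlist(raw$punct_tags) %||% PUNCT_TAGS,
    k_min = raw$k_min %||% 1,
    baseline_reps = raw$baseline_reps %||% 30,
    baseline_seed = raw$baseline_seed %||% 0,
    tau_C = raw$tau_C %||% 5, tau_L = raw$tau_L %||% 1.2,
    battery_plan = plan)
}

read_corpus_entry <- function(entry, punct_tags) {
  meta <- corpus_meta(entry$modality %||% NA_character_,
                      entry$level %||% NA, entry$label)
  fmt <- entry$format %||% "dialect"
  switch(fmt,
    dialect = read_dependency_table(entry$path, sep = entry$sep %||% "\t",
                                    punct_tags = punct_tags, meta = meta),
    conllu = read_conllu(entry$path, punct_tags = punct_tags, meta = meta),
    stop_validation("unknown corpus format '%s' (label %s)", fmt, entry$label))
}

#' Run the full study pipeline
#'
#' Per corpus: read, build the network, compute the metric panel row, fit
#' power-law and Poisson models to the cumulative degree distribution,
#' generate the matched G(N, M) baseline ensemble and assess small-world
#' status.  Across corpora: run the statistical battery when both
#' modalities at levels 1..4 plus native are present (skipped with a note
#' otherwise).  All outputs are written under `config$out_dir`; on any
#' stage failure the error names the stage and corpus label, and files
#' created by this run are removed.
#'
#' @param config A [study_config()].
#' @return Invisibly, a list with `metrics` (data.frame), `fits`,
#'   `baselines`, `battery` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "study_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "networks"), showWarnings = FALSE)
  created <- character(0)
  note <- function(p) { created <<- c(created, p); p }
  stage <- function(what, label, expr) {
    tryCatch(expr, error = function(e) {
      unlink(created)
      if (inherits(e, "syntnet_validation_error"))
        stop_validation("stage '%s' failed for corpus '%s': %s",
                        what, label, conditionMessage(e))
      stop_runtime("stage '%s' failed for corpus '%s': %s",
                   what, label, conditionMessage(e))
    })
  }

  rows <- list()
  fits <- list()
  baselines <- list()
  for (entry in config$corpora) {
    lab <- entry$label
    tb <- stage("read", lab, read_corpus_entry(entry, config$punct_tags))
    net <- stage("build", lab, build_network(tb))
    dist <- stage("fitdist", lab, degree_distribution(net))
    pf <- stage("fitdist", lab, fit_power_law(dist, k_min = config$k_min))
    qf <- stage("fitdist", lab, fit_poisson(dist, k_min = config$k_min))
    cmp <- compare_models(pf, qf)
    row <- stage("metrics", lab,
                 compute_metrics_row(net, tb$meta, fit = pf,
                                     token_count = n_tokens(tb),
                                     l_mode = config$l_mode,
                                     nc_form = config$nc_form))
    ens <- stage("baseline", lab,
                 ensemble_metrics(net$N, net$M, reps = config$baseline_reps,
                                  seed = config$baseline_seed,
                                  l_mode = config$l_mode))
    sw <- assess_small_world(row, ens, tau_C = config$tau_C,
                             tau_L = config$tau_L)
    write_pajek(net, note(file.path(out, "networks", paste0(lab, ".net"))))
    rows[[lab]] <- row
    fits[[lab]] <- list(power_law = unclass(pf), poisson = unclass(qf),
                        delta_aic = cmp$delta_aic, preferred = cmp$preferred)
    baselines[[lab]] <- list(
      ensemble = unclass(ens)[c("model", "N", "M", "reps", "seed",
                                "L_mean", "L_sd", "C_mean", "C_sd",
                                "L_closed_form", "C_closed_form")],
      assessment = sw)
    message(sprintf("[%s] tokens=%d N=%d M=%d small_world=%s preferred=%s",
                    lab, n_tokens(tb), net$N, net$M, sw$is_small_world,
                    cmp$preferred))
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL

  battery <- NULL
  complete <- tryCatch({
    run_battery(metrics, plan = config$battery_plan)
  }, syntnet_validation_error = function(e) {
    message("battery skipped: ", conditionMessage(e))
    NULL
  })
  battery <- complete

  write_metrics_table(metrics, note(file.path(out, "metrics.tsv")))
  jsonlite::write_json(metrics, note(file.path(out, "metrics.json")),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(fits, note(file.path(out, "fits.json")),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(baselines, note(file.path(out, "baselines.json")),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(battery)) {
    jsonlite::write_json(battery_report_as_list(battery),
                         note(file.path(out, "battery.json")),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(battery_as_table(battery),
                       note(file.path(out, "battery.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "syntnet",
    version = as.character(utils::packageVersion("syntnet")),
    config_hash = config_hash(config),
    corpora = vapply(config$corpora, `[[`, "", "label"),
    seeds = list(baseline_seed = config$baseline_seed))
  jsonlite::write_json(manifest, note(file.path(out, "manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(metrics = metrics, fits = fits, baselines = baselines,
                 battery = battery, manifest = manifest))
}

battery_report_as_list <- function(report) {
  lapply(report$metrics, function(e)
    list(regression = lapply(e$regression, unclass), t_test = e$t_test))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              force = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
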