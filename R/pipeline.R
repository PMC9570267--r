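## Pipeline driver wiring the analysis stages together:
## benchmark -> reactivity descriptors -> drug-likeness screening ->
## docking verification -> QSAR. Configured from an R list or a YAML file;
## each stage writes its report into the output directory and a combined
## summary JSON records what ran. Status codes follow a shell-style contract:
## 0 ok, 2 configuration error, 3 data validation error, 4 computation error.

#' Default pipeline configuration (bundled study tables)
#'
#' @param out_dir output directory for stage reports.
#' @return configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(out_dir = tempfile("deskqsar_run_")) {
  list(
    inputs = list(
      bondlengths = fixture_path("bondlengths_tu"),
      energies = fixture_path("energies_dipoles"),
      quantum = fixture_path("reactivity_inputs"),
      physchem = fixture_path("physchem"),
      activities = fixture_path("activities"),
      docking = list(fixture_path("docking_alpha"), fixture_path("docking_beta"))
    ),
    phase = "aqueous",   # the only phase with orbital data for all 4 compounds
    i_tce = 4.21,
    temperature = 298.15,
    docking_rel_tol = 0.01,
    triangle_vertices = default_triangle_vertices(),
    qsar = list(
      cell_line = "HCT",
      response = "reciprocal",
      descriptors = c("e_lumo", "chi", "s_soft", "logp", "n_rotb")
    ),
    out_dir = out_dir
  )
}

.load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop_config(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a list or a YAML path")
  base <- default_pipeline_config()
  config <- utils::modifyList(base, config)
  if (is.list(config$triangle_vertices)) {   # YAML gives a list of pairs
    config$triangle_vertices <-
      do.call(rbind, lapply(config$triangle_vertices, unlist))
  }
  for (nm in c("bondlengths", "quantum", "physchem", "activities")) {
    p <- config$inputs[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop_config(sprintf("input file for '%s' not found: %s", nm, p))
  }
  for (p in config$inputs$docking) {
    if (!file.exists(p)) stop_config(sprintf("docking file not found: %s", p))
  }
  config
}

#' Run the full analysis pipeline
#'
#' Executes, in order: method benchmarking over the bond-length table,
#' reactivity descriptor computation for the configured phase, drug-likeness
#' screening, docking-table verification, and a QSAR fit for the configured
#' cell line and descriptor set. Per-stage CSV/JSON reports and a combined
#' `summary.json` are written to `config$out_dir`. Outputs are deterministic:
#' two runs on identical inputs produce byte-identical report files.
#'
#' @param config a configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML file with the same structure.
#' @param dry_run if TRUE, validate the configuration and run nothing.
#' @return invisibly, a list with `status` (0 ok, 2 config error, 3 data
#'   validation error, 4 computation error), `out_dir`, and `summary`. On
#'   failure the error message names the failing stage.
#' @export
run_pipeline <- function(config = default_pipeline_config(), dry_run = FALSE) {
  status <- function(code, msg = NULL, summary = NULL, out_dir = NULL) {
    invisible(list(status = code, message = msg, summary = summary,
                   out_dir = out_dir))
  }
  config <- tryCatch(.load_pipeline_config(config), deskqsar_error = function(e) e)
  if (inherits(config, "deskqsar_error"))
    return(status(2, conditionMessage(config)))
  if (isTRUE(dry_run)) return(status(0, "dry run: configuration valid"))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list()
  run_stage <- function(stage, fun) {
    tryCatch(fun(), deskqsar_error = function(e) {
      code <- if (inherits(e, "deskqsar_validation_error") ||
                  inherits(e, "deskqsar_schema_error") ||
                  inherits(e, "deskqsar_parse_error")) 3 else 4
      stop_deskqsar("deskqsar_stage_error",
                    sprintf("[stage %s | status %d] %s",
                            stage, code, conditionMessage(e)))
    })
  }
  out <- tryCatch({
    ## stage 1: geometry benchmark
    ranking <- run_stage("benchmark", function() {
      tbl <- load_table(config$inputs$bondlengths, "bondlengths")
      rank_methods(tbl)
    })
    write_report(ranking, file.path(config$out_dir, "benchmark.csv"))
    summary$benchmark <- list(best_method = ranking$method[1],
                              best_a_percent = ranking$a_percent[1])

    ## stage 2: reactivity descriptors
    desc <- run_stage("descriptors", function() {
      q <- load_table(config$inputs$quantum, "quantum")
      descriptor_table(q, config$phase, config$i_tce)
    })
    write_report(desc, file.path(config$out_dir, "descriptors.csv"))
    summary$descriptors <- list(phase = config$phase, n_compounds = nrow(desc))

    ## stage 3: drug-likeness screening
    screen <- run_stage("screen", function() {
      pc <- load_table(config$inputs$physchem, "physchem")
      screen_compounds(pc, triangle_policy(config$triangle_vertices))
    })
    write_report(screen, file.path(config$out_dir, "screen.csv"))
    summary$screen <- list(n_compounds = nrow(screen),
                           n_lipinski_passed = sum(screen$lipinski_passed))

    ## stage 4: docking verification
    docking_reports <- run_stage("verify_docking", function() {
      lapply(config$inputs$docking, function(p) {
        verify_docking_table(load_table(p, "docking"),
                             thermo_config(config$temperature),
                             config$docking_rel_tol)
      })
    })
    for (i in seq_along(docking_reports)) {
      write_report(docking_reports[[i]],
                   file.path(config$out_dir, sprintf("docking_%d.csv", i)))
    }
    summary$docking <- list(
      n_tables = length(docking_reports),
      n_tables_verified = sum(vapply(docking_reports,
                                     function(r) all(r$pass), logical(1))))

    ## stage 5: QSAR
    qres <- run_stage("qsar", function() {
      q <- load_table(config$inputs$quantum, "quantum")
      pc <- load_table(config$inputs$physchem, "physchem")
      act <- load_table(config$inputs$activities, "activity")
      spec <- model_spec(config$qsar$descriptors, config$qsar$response,
                         config$phase)
      dm <- build_design_matrix(q, pc, spec, act, config$qsar$cell_line,
                                config$i_tce)
      fit <- fit_ols(dm$x, dm$y)
      list(fit = fit, pvo = predicted_vs_observed(fit, dm$x, dm$y, dm$compounds))
    })
    write_report(qres$pvo, file.path(config$out_dir, "qsar_predicted_vs_observed.csv"))
    summary$qsar <- list(cell_line = config$qsar$cell_line,
                         response = config$qsar$response,
                         n = qres$fit$n, p = qres$fit$p,
                         r2 = qres$fit$r2,
                         underdetermined = qres$fit$underdetermined)

    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    status(0, "pipeline complete", summary, config$out_dir)
  }, deskqsar_stage_error = function(e) {
    msg <- conditionMessage(e)
    code <- if (grepl("status 3", msg, fixed = TRUE)) 3 else 4
    status(code, msg, summary, config$out_dir)
  })
  out
}
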