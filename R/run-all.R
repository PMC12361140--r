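#' Run the full pipeline end to end
#'
#' Orchestrates simulate -> kinetics -> ddct -> context -> correlate, writing
#' every stage's table as a header-carrying TSV plus a structured YAML run
#' report (seed, parameter settings, input digests, per-stage row counts,
#' collected warnings). Deterministic given the config seed: two runs with
#' the same seed produce byte-identical outputs.
#'
#' `config` is either a [synth_config()] (e.g. [study_mimic_config()]), in
#' which case every input is simulated, or a named list of real input files:
#' `ct` (CSV), `plate` (CSV), `gff`, `bed`, `origins`, `sites`,
#' `genome_length`, and optionally `cfu` (TSV `strain_id,blue_cfu,total_cfu`).
#' A missing entry raises an error naming the gap.
#'
#' @param config A [synth_config()] or a named list of input file paths.
#' @param out_dir Output directory (created if needed).
#' @param control A [kinetics_control()].
#' @return The run report (list of class `run_report`), invisibly holding
#'   output paths, per-stage row counts, seed and warnings.
#' @export
run_all <- function(config, out_dir, control = kinetics_control()) {
  simulate <- inherits(config, "synth_config")
  if (!simulate) {
    stopifnot(is.list(config))
    needed <- c("ct", "plate", "gff", "bed", "origins", "sites",
                "genome_length")
    missing <- setdiff(needed, names(config))
    if (length(missing))
      stop(sprintf("run_all config is missing input(s): %s",
                   paste(missing, collapse = ", ")))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  report <- list(tool = "reporterpos",
                 version = as.character(utils::packageVersion("reporterpos")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 seed = if (simulate) config$seed else NA_integer_,
                 settings = unclass(control),
                 input_digests = list(),
                 stages = list(), warnings = character(),
                 outputs = list())
  note <- function(stage, rows_in, rows_out) {
    report$stages[[stage]] <<- list(rows_in = rows_in, rows_out = rows_out)
    message(sprintf("[%s] %d rows in -> %d rows out", stage, rows_in, rows_out))
  }
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(df, p)
    report$outputs[[name]] <<- p
    p
  }
  wcatch <- function(expr) withCallingHandlers(expr, warning = function(w) {
    report$warnings <<- c(report$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  if (simulate) {
    ct <- gen_ct_table(config)
    curves <- gen_kinetic_plate(config)
    fixture <- gen_genome_fixture(config, dir = file.path(out_dir, "inputs"))
    cfu <- gen_cfu_counts(config)
    write_ct_csv(ct, file.path(out_dir, "inputs", "ct.csv"))
    write_plate_csv(curves, file.path(out_dir, "inputs", "plate.csv"))
    readr::write_tsv(cfu, file.path(out_dir, "inputs", "cfu.tsv"))
    in_files <- list.files(file.path(out_dir, "inputs"), full.names = TRUE)
    report$input_digests <- as.list(tools::md5sum(in_files))
    note("simulate", nrow(config$strains),
         nrow(ct) + length(curves) + nrow(cfu))
  } else {
    ct <- read_ct_csv(config$ct)
    curves <- read_plate_csv(config$plate)
    ann <- read_genes_gff3(config$gff)
    fixture <- list(genes = ann$genes, terminators = ann$terminators,
                    origins = read_origins_tsv(config$origins),
                    compartments = read_compartments_bed(config$bed),
                    sites = read_sites_tsv(config$sites),
                    genome_length = config$genome_length)
    cfu <- if (!is.null(config$cfu))
      readr::read_tsv(config$cfu, show_col_types = FALSE) else NULL
    paths <- unlist(config[setdiff(names(config), "genome_length")])
    report$input_digests <- as.list(tools::md5sum(paths))
    note("read", length(paths), nrow(ct) + length(curves))
  }

  # kinetics
  slopes <- estimate_slopes(curves, control)
  activity <- wcatch(aggregate_activity(slopes))
  emit(slopes, "slopes.tsv")
  emit(activity, "activity.tsv")
  note("kinetics", length(curves), nrow(activity))

  # ddct
  dct <- delta_ct(wcatch(average_technical(ct)))
  ratios <- fold_change_ddct(dct, baseline = "auto",
                             condition = "reference_growth")
  other_conds <- setdiff(unique(dct$condition), "reference_growth")
  cond_ratios <- dplyr::bind_rows(lapply(unique(dct$strain_id), function(s) {
    measured <- unique(dct$condition[dct$strain_id == s])
    dplyr::bind_rows(lapply(intersect(other_conds, measured), function(cn)
      condition_fold_change(dct, s, cn, "reference_growth")))
  }))
  emit(dplyr::select(ratios, -"per_bio_rep_ratios"), "ratios.tsv")
  emit(cond_ratios, "condition_ratios.tsv")
  note("ddct", nrow(ct), nrow(ratios) + nrow(cond_ratios))

  # context
  contexts <- build_site_table(fixture$sites, fixture$genes, fixture$origins,
                               fixture$compartments, fixture$terminators,
                               fixture$genome_length)
  emit(contexts, "context.tsv")
  if (!is.null(cfu)) {
    fractions <- tibble::tibble(site = cfu$strain_id,
                                fraction = popin_fraction(cfu$blue_cfu,
                                                          cfu$total_cfu))
    comp_means <- wcatch(compartment_mean_fraction(fractions, contexts))
    emit(fractions, "popin_fractions.tsv")
    emit(comp_means, "compartment_popin.tsv")
  }
  note("context", nrow(fixture$sites), nrow(contexts))

  # correlate
  rep3 <- correlation_report(contexts, activity, ratios)
  emit(rep3$regressions, "regressions.tsv")
  emit(rep3$scatter, "scatter.tsv")
  note("correlate", nrow(rep3$scatter), nrow(rep3$regressions))

  class(report) <- "run_report"
  yaml::write_yaml(unclass(report), file.path(out_dir, "run_report.yaml"))
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s %s seed %d, %d stages, %d warning(s)\n",
              x$tool, x$version, x$seed, length(x$stages), length(x$warnings)))
  for (s in names(x$stages))
    cat(sprintf("  %-10s %6d -> %d\n", s, x$stages[[s]]$rows_in,
                x$stages[[s]]$rows_out))
  invisible(x)
}
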