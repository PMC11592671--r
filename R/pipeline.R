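PIPELINE_STAGES <- c("simulate", "ncratio", "frap", "fret", "scan",
                     "screen", "fractionation", "report")

#' Build a validated pipeline configuration
#'
#' Every parameter has a default; unknown keys are rejected before any
#' computation starts.
#'
#' @param stages character vector of stages to run, a subset of
#'   `"simulate"`, `"ncratio"`, `"frap"`, `"fret"`, `"scan"`, `"screen"`,
#'   `"fractionation"`, `"report"`.
#' @param seed integer seed driving all synthetic stages.
#' @param outdir output directory.
#' @param field named list of [field_spec()] overrides.
#' @param frap named list of [frap_spec()] overrides.
#' @param fret named list of [fret_spec()] overrides; the positive-control
#'   cohort is generated alongside with efficiency `fret_control_efficiency`.
#' @param fret_control_efficiency true efficiency of the simulated
#'   positive-control construct.
#' @param fasta path to a protein FASTA for the scan stage (defaults to the
#'   packaged synthetic scaffold).
#' @param variants character vector of variant strings applied during the
#'   scan stage.
#' @param genes path to a newline-delimited gene list (defaults to the
#'   packaged interactome example list).
#' @param nuclear_percent target percentage for the simulated fractionation
#'   lanes.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = PIPELINE_STAGES, seed = 1L,
                            outdir = tempfile("nucshuttle-run-"),
                            field = list(), frap = list(), fret = list(),
                            fret_control_efficiency = 0.35,
                            fasta = NULL, variants = character(),
                            genes = NULL, nuclear_percent = 70) {
  known <- names(formals(pipeline_config))
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  cfg <- list(stages = stages, seed = as.integer(seed), outdir = outdir,
              field = field, frap = frap, fret = fret,
              fret_control_efficiency = fret_control_efficiency,
              fasta = fasta, variants = variants, genes = genes,
              nuclear_percent = nuclear_percent)
  structure(cfg, class = "pipeline_config")
}

#' Validate a raw configuration list
#'
#' Rejects unknown keys, then builds a [pipeline_config()].
#'
#' @param x a named list (e.g. parsed from JSON).
#' @return A `pipeline_config`.
#' @export
as_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  known <- setdiff(names(formals(pipeline_config)), "...")
  bad <- setdiff(names(x), known)
  if (length(bad)) stopf("unknown configuration key(s): %s",
                         paste(bad, collapse = ", "))
  do.call(pipeline_config, x)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order (simulate, then the analysis
#' stages, then the report), writing tables as CSV, label masks and channels
#' as TIFF, and a JSON summary plus a log of versions, seed and parameters.
#' Stage failures abort with a stage-named error; outputs written so far are
#' preserved.
#'
#' @param config a [pipeline_config()] or a named list accepted by
#'   [as_pipeline_config()].
#' @return Invisibly, the report list (also written to `summary.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- as_pipeline_config(config)
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  report <- list(seed = cfg$seed, stages = cfg$stages,
                 package_version = as.character(utils::packageVersion("nucshuttle")),
                 r_version = R.version.string)
  log_path <- file.path(cfg$outdir, "run_log.json")
  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  sim <- NULL
  run_stage("simulate", function() {
    fs <- do.call(field_spec, utils::modifyList(list(seed = cfg$seed),
                                                cfg$field))
    sim <<- generate_field(fs)
    write_field_tiff(sim$field, cfg$outdir)
    utils::write.csv(sim$truth$cells,
                     file.path(cfg$outdir, "truth_cells.csv"),
                     row.names = FALSE)
    report$simulate <<- list(n_cells = fs$n_cells,
                             nuclear_fraction = fs$nuclear_fraction)
  })

  run_stage("ncratio", function() {
    if (is.null(sim)) stopf("requires the simulate stage")
    nuclei <- segment_nuclei(sim$field$dapi)
    cells <- segment_cells(sim$field, nuclei)
    rec <- measure_nc(sim$field, cells, nuclei)
    utils::write.csv(as.data.frame(rec),
                     file.path(cfg$outdir, "cell_records.csv"),
                     row.names = FALSE)
    s <- summarize_population(rec, min_cells = 1)
    report$ncratio <<- list(mean_fraction_nuclear = s$mean,
                            sd = s$sd, n_cells = s$n)
  })

  run_stage("frap", function() {
    fs <- do.call(frap_spec, utils::modifyList(
      list(seed = derive_seed(cfg$seed, "frap")), cfg$frap))
    g <- generate_frap_trace(fs)
    write_frap_csv(g$trace, file.path(cfg$outdir, "frap_trace.csv"))
    dn <- double_normalize(g$trace)
    fit <- fit_recovery(full_scale_normalize(dn), model = fs$model)
    mf <- mobile_fraction(fit_recovery(dn, model = fs$model))
    report$frap <<- list(model = fs$model, t_half_s = fit$t_half,
                         mobile_fraction = mf, true_t_half_s = g$truth$t_half)
  })

  run_stage("fret", function() {
    mk <- function(eff, label, stream) {
      sp <- do.call(fret_spec, utils::modifyList(
        list(true_efficiency = eff, seed = derive_seed(cfg$seed, stream)),
        cfg$fret[setdiff(names(cfg$fret), "true_efficiency")]))
      fret_cohort(generate_fret_cohort(sp)$rois, condition = label)
    }
    eff_sample <- cfg$fret$true_efficiency %||% 0.2
    cohorts <- list(positive_control = mk(cfg$fret_control_efficiency,
                                          "positive_control", "fret-pc"),
                    sample = mk(eff_sample, "sample", "fret-sample"))
    cohorts <- normalize_to_control(cohorts, "positive_control")
    tab <- do.call(rbind, lapply(cohorts, function(co)
      cbind(condition = co$condition, co$cells)))
    utils::write.csv(tab, file.path(cfg$outdir, "fret_cells.csv"),
                     row.names = FALSE)
    report$fret <<- list(
      positive_control_mean = mean(cohorts$positive_control$cells$corrected_eff),
      sample_normalized_mean = mean(cohorts$sample$cells$corrected_eff))
  })

  run_stage("scan", function() {
    fasta <- cfg$fasta %||% system.file("extdata",
                                        "sans_synthetic_scaffold.fasta",
                                        package = "nucshuttle", mustWork = TRUE)
    seqs <- read_protein_fasta(fasta)
    all_hits <- list()
    for (sq in seqs) {
      hits <- rbind(scan_nls(sq), scan_nes(sq))
      if (nrow(hits)) hits <- cbind(sequence_id = sq$id, hits)
      all_hits[[sq$id]] <- hits
      for (v in cfg$variants) {
        mut <- apply_variant(sq, v)
        d <- diff_motifs(rbind(scan_nls(sq), scan_nes(sq)),
                         rbind(scan_nls(mut), scan_nes(mut)))
        utils::write.csv(as.data.frame(d$lost),
                         file.path(cfg$outdir,
                                   sprintf("motifs_lost_%s_%s.csv", sq$id,
                                           gsub("[*:]", "_", v))),
                         row.names = FALSE)
      }
    }
    hits <- do.call(rbind, all_hits[!vapply(all_hits, is.null, logical(1))])
    utils::write.csv(hits, file.path(cfg$outdir, "motif_hits.csv"),
                     row.names = FALSE)
    report$scan <<- list(n_nls = sum(hits$kind == "NLS"),
                         n_nes = sum(hits$kind == "NES"))
  })

  run_stage("screen", function() {
    genes <- if (is.null(cfg$genes))
      read_gene_list(system.file("extdata", "interactome_genes_example.txt",
                                 package = "nucshuttle", mustWork = TRUE))
    else read_gene_list(cfg$genes)
    scr <- screen_karyopherins(genes)
    utils::write.csv(scr$matched,
                     file.path(cfg$outdir, "karyopherin_screen.csv"),
                     row.names = FALSE)
    report$screen <<- as.list(scr$counts)
  })

  run_stage("fractionation", function() {
    lanes <- generate_blot_lanes(cfg$nuclear_percent,
                                 seed = derive_seed(cfg$seed, "blot"))
    fr <- quantify_fractionation(lanes)
    report$fractionation <<- list(nuclear_percent = fr$nuclear_percent,
                                  purity_flags = fr$purity_flags)
  })

  jsonlite::write_json(report, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(
    list(seed = cfg$seed, stages = cfg$stages,
         parameters = cfg[setdiff(names(cfg), c("stages", "seed"))]),
    log_path, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(report)
}
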