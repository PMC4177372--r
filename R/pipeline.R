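# End-to-end orchestration: one validated configuration object drives
# simulate (or load) -> peak calling x2 -> dual-threshold screen ->
# annotation -> report, with every stage artifact writable and the whole
# run a deterministic function of the config.

#' Pipeline configuration
#'
#' Exactly one input source must be given: a \code{\link{sim_config}}
#' (simulated run) or real-input paths (\code{annotation} plus
#' \code{coverage}).
#'
#' The two confidence thresholds of the dual-threshold screen default to
#' 0.975 (high; the focal condition must clear it) and 0.950 (low; evidence
#' in the other condition at this level vetoes). Peaks feeding the screen
#' are called without gap bridging (\code{screen_merge_gap_bp = 0}) so the
#' veto cover contains only qualifying bins; the reported peak sets bridge
#' gaps below \code{report_merge_gap_bp} as usual.
#'
#' @param simulation Optional \code{\link{sim_config}}.
#' @param annotation Optional list with \code{gene_path}, \code{cgi_path},
#'   \code{genome_path}, optional \code{enhancer_path} and
#'   \code{gene_format}.
#' @param coverage Optional list with \code{case_path}, \code{control_path}
#'   and \code{bin_bp}.
#' @param high,low Dual thresholds, \code{0 < low <= high < 1}.
#' @param min_length_bp Minimum DMR length after subtraction (default 100).
#' @param subtraction \code{"base"} or \code{"whole_peak"}.
#' @param screen_merge_gap_bp Gap bridging for screen peak calls (default
#'   0).
#' @param report_merge_gap_bp Gap bridging for reported peak sets (default
#'   200).
#' @param min_peak_bins Minimum peak span in bins (default 2).
#' @param trim Trim fraction for background estimation (default 0.01).
#' @param yates Yates correction in the report chi-square (default FALSE).
#' @param params \code{\link{annotation_params}} (real-input runs; simulated
#'   runs take them from the sim config).
#' @param seed Integer seed recorded in every output; seeds the simulation.
#' @param out_dir Optional directory: when set, every stage writes its
#'   artifact there.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(simulation = NULL, annotation = NULL,
                            coverage = NULL, high = 0.975, low = 0.950,
                            min_length_bp = 100,
                            subtraction = c("base", "whole_peak"),
                            screen_merge_gap_bp = 0,
                            report_merge_gap_bp = 200, min_peak_bins = 2,
                            trim = 0.01, yates = FALSE,
                            params = annotation_params(), seed = 1,
                            out_dir = NULL) {
  subtraction <- match.arg(subtraction)
  has_sim <- !is.null(simulation)
  has_real <- !is.null(annotation) || !is.null(coverage)
  if (has_sim && has_real)
    stop("config error: give either a simulation block or real-input ",
         "paths, not both")
  if (!has_sim && !(is.list(annotation) && is.list(coverage)))
    stop("config error: need a simulation block, or both annotation and ",
         "coverage paths")
  if (has_sim && !is(simulation, "sim_config"))
    stop("config error: simulation must be a sim_config")
  if (!(low > 0 && low <= high && high < 1))
    stop("config error: thresholds must satisfy 0 < low <= high < 1")
  structure(list(simulation = simulation, annotation = annotation,
                 coverage = coverage, high = high, low = low,
                 min_length_bp = min_length_bp, subtraction = subtraction,
                 screen_merge_gap_bp = screen_merge_gap_bp,
                 report_merge_gap_bp = report_merge_gap_bp,
                 min_peak_bins = min_peak_bins, trim = trim, yates = yates,
                 params = params, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' File keys mirror the \code{\link{pipeline_config}} arguments; a
#' \code{simulation} block is passed to \code{\link{sim_config}} (its
#' \code{genome} key is a name-to-length map). YAML needs the yaml package.
#'
#' @param path Config file (\code{.json}, \code{.yaml} or \code{.yml}).
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the yaml package")
    yaml::read_yaml(path)
  } else {
    read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$simulation)) {
    sim <- raw$simulation
    if (!is.null(sim$genome)) sim$genome <- unlist(sim$genome)
    raw$simulation <- do.call(sim_config, sim)
  }
  if (!is.null(raw$params))
    raw$params <- do.call(annotation_params, as.list(raw$params))
  do.call(pipeline_config, raw)
}

#' Run the full differential-methylation pipeline
#'
#' Executes simulate (or load) -> background estimation -> peak calling for
#' both conditions -> dual-threshold screen -> context annotation ->
#' report. Re-running with the same config reproduces identical artifacts.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return A list of class \code{pipeline_run} with \code{bundle},
#'   \code{truth} (simulated runs), \code{tracks}, \code{lambda},
#'   \code{screen_peaks}, \code{report_peaks}, \code{extraction},
#'   \code{annotations}, \code{metaprofile}, \code{report}, \code{config}.
#' @export
run_pipeline <- function(config) {
  stopifnot(is(config, "pipeline_config"))
  set.seed(config$seed)
  log_line <- function(...) message(sprintf(...))

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    bundle <- make_toy_bundle(sim)
    simmed <- plant_and_simulate(bundle, sim)
    truth <- simmed$truth
    tracks <- list(case = simmed$case, control = simmed$control)
    log_line("simulate: %d genes, %d CGIs, %d+%d+%d planted regions",
             length(bundle$genes), length(bundle$cgis),
             length(truth$planted_case), length(truth$planted_control),
             length(truth$planted_common))
  } else {
    an <- config$annotation
    genome <- read_genome_sizes(an$genome_path)
    bundle <- read_annotation(
      an$gene_path, an$cgi_path, genome, params = config$params,
      enhancer_path = an$enhancer_path,
      gene_format = if (!is.null(an$gene_format)) an$gene_format
                    else "refflat")
    cv <- config$coverage
    tracks <- list(
      case = read_bedgraph(cv$case_path, genome, cv$bin_bp, "case"),
      control = read_bedgraph(cv$control_path, genome, cv$bin_bp,
                              "control"))
    truth <- NULL
    log_line("load: %d genes, %d CGIs", length(bundle$genes),
             length(bundle$cgis))
  }

  lambda <- lapply(tracks, estimate_background, trim = config$trim)
  log_line("background: case %.3f, control %.3f per bin",
           lambda$case, lambda$control)

  screen_peaks <- lapply(names(tracks), function(cond)
    call_peaks(tracks[[cond]], lambda[[cond]], min_confidence = config$low,
               merge_gap_bp = config$screen_merge_gap_bp,
               min_peak_bins = config$min_peak_bins))
  names(screen_peaks) <- names(tracks)
  report_peaks <- lapply(names(tracks), function(cond)
    call_peaks(tracks[[cond]], lambda[[cond]], min_confidence = config$low,
               merge_gap_bp = config$report_merge_gap_bp,
               min_peak_bins = config$min_peak_bins))
  names(report_peaks) <- names(tracks)
  log_line("peaks: %d case, %d control (screen calls)",
           length(screen_peaks$case$peaks),
           length(screen_peaks$control$peaks))

  extraction <- extract_specific(screen_peaks$case, screen_peaks$control,
                                 high = config$high, low = config$low,
                                 min_length_bp = config$min_length_bp,
                                 mode = config$subtraction)
  log_line("screen: %d case-specific, %d control-specific DMRs",
           extraction$log$case_dmrs_out, extraction$log$control_dmrs_out)

  annotations <- list(
    case = annotate_dmrs(extraction$case_specific, bundle),
    control = annotate_dmrs(extraction$control_specific, bundle))
  metaprofile <- tss_metaprofile(report_peaks$case, bundle,
                                 bin_bp = tracks$case$bin_bp)
  report <- build_report(extraction, bundle,
                         peaks_case = report_peaks$case,
                         peaks_control = report_peaks$control,
                         metaprofile = metaprofile, yates = config$yates)

  run <- structure(list(config = config, bundle = bundle, truth = truth,
                        tracks = tracks, lambda = lambda,
                        screen_peaks = screen_peaks,
                        report_peaks = report_peaks,
                        extraction = extraction, annotations = annotations,
                        metaprofile = metaprofile, report = report),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) write_pipeline_run(run, config$out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run (seed", x$config$seed, ")\n\n")
  print(x$bundle)
  cat("\n")
  print(x$extraction)
  cat("\n")
  print(x$report)
  invisible(x)
}

#' Write every stage artifact of a pipeline run
#'
#' BED/bedGraph/TSV/JSON artifacts per stage, all traceable to the config
#' seed.
#'
#' @param run A \code{\link{run_pipeline}} result.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_pipeline_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotation(run$bundle, dir)
  if (!is.null(run$truth))
    write_truth(run$truth, file.path(dir, "truth.bed"))
  for (cond in names(run$tracks))
    write_bedgraph(run$tracks[[cond]],
                   file.path(dir, paste0("coverage_", cond, ".bedgraph")))
  for (cond in names(run$report_peaks))
    write_peaks(run$report_peaks[[cond]],
                file.path(dir, paste0("peaks_", cond, ".bed")))
  write_dmrs(run$extraction, dir)
  for (cond in names(run$annotations))
    write.table(run$annotations[[cond]],
                file.path(dir, paste0("annotation_", cond, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write_report(run$report, dir, seed = run$config$seed)
  cfg <- run$config
  cfg$simulation <- if (!is.null(cfg$simulation)) {
    s <- unclass(cfg$simulation)
    s$genome <- as.list(s$genome)
    s$params <- unclass(s$params)
    s
  }
  cfg$params <- unclass(cfg$params)
  write_json(unclass(cfg), file.path(dir, "config.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(dir)
}
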