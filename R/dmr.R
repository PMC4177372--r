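# Dual-threshold screen with common-peak subtraction.
#
# Specificity in condition A demands strong evidence in A (confidence >= the
# high threshold, 0.975) together with absence of even weak evidence in B (a
# B peak at >= the low threshold, 0.950, vetoes those bases). The screen is
# therefore conservative by construction: the high gate limits false
# positives in the focal condition, the low veto limits false specificity.

#' Condition-specific DMR set
#'
#' @param condition \code{"case_specific"} or \code{"control_specific"}.
#' @param regions Sorted non-overlapping GRanges.
#' @param thresholds Named numeric \code{c(high=, low=)}.
#' @param min_length_bp Minimum retained region length.
#' @param provenance Character description of the source peak sets.
#' @return A list of class \code{dmr_set}.
#' @export
dmr_set <- function(condition = c("case_specific", "control_specific"),
                    regions, thresholds = c(high = 0.975, low = 0.950),
                    min_length_bp = 100, provenance = character(0)) {
  condition <- match.arg(condition)
  regions <- sort(.cover(regions))
  stopifnot(all(width(regions) >= min_length_bp))
  structure(list(condition = condition, regions = regions,
                 thresholds = thresholds, min_length_bp = min_length_bp,
                 provenance = provenance),
            class = "dmr_set")
}

#' @export
print.dmr_set <- function(x, ...) {
  cat(sprintf("dmr_set (%s): %d regions, %.4g bp (high=%.4g low=%.4g, min %d bp)\n",
              x$condition, length(x$regions), .sum_width(x$regions),
              x$thresholds[["high"]], x$thresholds[["low"]],
              x$min_length_bp))
  invisible(x)
}

#' Extract condition-specific DMRs by the dual-threshold screen
#'
#' Case-specific regions are the bases covered by case peaks at confidence
#' \code{>= high} minus the bases covered by control peaks at confidence
#' \code{>= low}; control-specific regions are the mirror image; common
#' regions are the intersection of the two low-confidence covers. In
#' \code{"whole_peak"} mode a high-confidence peak overlapping the other
#' condition's low-confidence cover by even one base is discarded whole
#' instead of trimmed. Fragments shorter than \code{min_length_bp} after
#' subtraction are dropped and counted in the run log.
#'
#' @param case,control \code{\link{peak_set}}s for the two conditions.
#' @param high,low Confidence thresholds, \code{0 < low <= high < 1}
#'   (defaults 0.975 / 0.950).
#' @param min_length_bp Minimum DMR length (default 100).
#' @param mode \code{"base"} (base-resolution subtraction, default) or
#'   \code{"whole_peak"}.
#' @return A list of class \code{dmr_extraction}: \code{case_specific} and
#'   \code{control_specific} (\code{\link{dmr_set}}s), \code{common}
#'   (GRanges), and a \code{log} of counts at each stage.
#' @export
extract_specific <- function(case, control, high = 0.975, low = 0.950,
                             min_length_bp = 100,
                             mode = c("base", "whole_peak")) {
  mode <- match.arg(mode)
  stopifnot(is(case, "peak_set"), is(control, "peak_set"))
  if (identical(case$condition, control$condition))
    stop("both peak sets come from condition '", case$condition,
         "'; the screen needs one peak set per condition")
  if (!(low > 0 && low <= high && high < 1))
    stop("thresholds must satisfy 0 < low <= high < 1")
  conf_a <- mcols(case$peaks)$confidence
  conf_b <- mcols(control$peaks)$confidence
  case_high <- .cover(case$peaks[conf_a >= high])
  case_low <- .cover(case$peaks[conf_a >= low])
  ctrl_high <- .cover(control$peaks[conf_b >= high])
  ctrl_low <- .cover(control$peaks[conf_b >= low])

  if (mode == "base") {
    cs_raw <- setdiff(case_high, ctrl_low, ignore.strand = TRUE)
    ct_raw <- setdiff(ctrl_high, case_low, ignore.strand = TRUE)
  } else {
    keep_a <- conf_a >= high &
      !overlapsAny(case$peaks, ctrl_low, ignore.strand = TRUE)
    keep_b <- conf_b >= high &
      !overlapsAny(control$peaks, case_low, ignore.strand = TRUE)
    cs_raw <- .cover(case$peaks[keep_a])
    ct_raw <- .cover(control$peaks[keep_b])
  }
  common <- intersect(case_low, ctrl_low, ignore.strand = TRUE)

  cs <- cs_raw[width(cs_raw) >= min_length_bp]
  ct <- ct_raw[width(ct_raw) >= min_length_bp]
  log <- list(
    mode = mode, high = high, low = low, min_length_bp = min_length_bp,
    case_peaks_in = length(case$peaks),
    control_peaks_in = length(control$peaks),
    case_high_conf_peaks = sum(conf_a >= high),
    control_high_conf_peaks = sum(conf_b >= high),
    case_bases_subtracted =
      .sum_width(intersect(case_high, ctrl_low, ignore.strand = TRUE)),
    control_bases_subtracted =
      .sum_width(intersect(ctrl_high, case_low, ignore.strand = TRUE)),
    case_slivers_dropped = length(cs_raw) - length(cs),
    control_slivers_dropped = length(ct_raw) - length(ct),
    case_dmrs_out = length(cs), control_dmrs_out = length(ct),
    common_regions = length(common))
  prov <- sprintf("%s peaks (n=%d) vs %s peaks (n=%d), mode=%s",
                  case$condition, length(case$peaks), control$condition,
                  length(control$peaks), mode)
  structure(list(
    case_specific = dmr_set("case_specific", cs,
                            c(high = high, low = low), min_length_bp, prov),
    control_specific = dmr_set("control_specific", ct,
                               c(high = high, low = low), min_length_bp,
                               prov),
    common = sort(common), log = log),
    class = "dmr_extraction")
}

#' @export
print.dmr_extraction <- function(x, ...) {
  cat("dmr_extraction (dual-threshold screen)\n")
  cat(sprintf("  case-specific:    %d regions (%d slivers dropped)\n",
              x$log$case_dmrs_out, x$log$case_slivers_dropped))
  cat(sprintf("  control-specific: %d regions (%d slivers dropped)\n",
              x$log$control_dmrs_out, x$log$control_slivers_dropped))
  cat(sprintf("  common cover:     %d regions\n", x$log$common_regions))
  invisible(x)
}

#' Write a DMR set as BED4 plus a JSON run log
#'
#' @param extraction A \code{\link{extract_specific}} result.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_dmrs <- function(extraction, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (set in list(extraction$case_specific, extraction$control_specific)) {
    gr <- set$regions
    mcols(gr)$name <- rep(set$condition, length(gr))
    f <- file.path(dir, paste0(set$condition, ".bed"))
    out <- data.frame(chrom = as.character(seqnames(gr)),
                      start = start(gr) - 1, end = end(gr),
                      name = mcols(gr)$name)
    write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    files <- c(files, f)
  }
  cm <- extraction$common
  out <- data.frame(chrom = as.character(seqnames(cm)),
                    start = start(cm) - 1, end = end(cm), name = "common")
  f <- file.path(dir, "common.bed")
  write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "dmr_log.json")
  write_json(extraction$log, f, auto_unbox = TRUE, pretty = TRUE,
             digits = NA)
  invisible(c(files, f))
}
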