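# Contingency statistics, fraction arithmetic, gene-set enrichment, and the
# aggregate report that mirrors the count hierarchy of a two-condition
# methylCap-seq comparison.

#' Pearson chi-square test on a 2x2 contingency table
#'
#' @param table 2x2 numeric matrix of non-negative counts (rows =
#'   condition, columns = category), or the first of four counts.
#' @param b,c,d Remaining cell counts when \code{table} is scalar.
#' @param yates Apply the Yates continuity correction (default off; plain
#'   Pearson).
#' @return List with \code{statistic}, \code{p}, \code{df}, \code{expected}
#'   and \code{yates}.
#' @export
chi_square_2x2 <- function(table, b = NULL, c = NULL, d = NULL,
                           yates = FALSE) {
  m <- if (is.matrix(table)) table else matrix(c(table, b, c, d), 2, 2,
                                               byrow = TRUE)
  if (!all(dim(m) == 2) || any(m < 0) || any(is.na(m)))
    stop("need a 2x2 table of non-negative counts")
  if (sum(m) == 0 || any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin: chi-square undefined; consider an exact test")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0))
    stop("zero expected cell; consider an exact test")
  ht <- suppressWarnings(chisq.test(m, correct = yates))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), expected = expected, yates = yates)
}

#' Labeled numerator/denominator report with display rounding
#'
#' Percentages are kept at full precision and displayed rounded to the
#' nearest whole percent, matching the usual presentation of count splits
#' (e.g. 133/1131 prints as \code{"12\%"}).
#'
#' @param numerator Named (or unnamed) vector of numerators.
#' @param denominator Matching denominators (> 0).
#' @param label Optional labels; defaults to the numerator names.
#' @return data.frame of class \code{fraction_report}: label, numerator,
#'   denominator, percent, display.
#' @export
fraction_report <- function(numerator, denominator, label = NULL) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  if (any(numerator < 0)) stop("numerator must be >= 0")
  if (is.null(label))
    label <- if (!is.null(names(numerator))) names(numerator)
             else sprintf("fraction_%d", seq_along(numerator))
  pct <- 100 * numerator / denominator
  structure(data.frame(label = label, numerator = numerator,
                       denominator = denominator, percent = pct,
                       display = sprintf("%d%%", round(pct)),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("fraction_report", "data.frame"))
}

#' One-sided hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric p-value per gene set (sets intersected with the
#' universe first), Benjamini-Hochberg adjusted across the tested sets. A
#' generic enrichment engine for user-supplied gene sets; no ontology
#' parsing is involved.
#'
#' @param hit_genes Character vector of hit gene ids (must lie in
#'   \code{universe}).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector of all assayable genes.
#' @return data.frame with set name, set size (in universe), overlap,
#'   \code{p} and BH-adjusted \code{q}, sorted by \code{p}.
#' @export
hypergeometric_enrichment <- function(hit_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  hit_genes <- unique(hit_genes)
  if (!all(hit_genes %in% universe))
    stop("hit_genes must be a subset of the universe")
  k <- length(hit_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    x <- length(intersect(hit_genes, s))
    p <- phyper(x - 1, length(s), length(universe) - length(s), k,
                lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = x, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

# percentage helper that suppresses division by zero (NA instead)
.safe_pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_

#' Build the aggregate differential-methylation report
#'
#' Emits the full count hierarchy for a two-condition comparison: peaks in,
#' condition-specific DMRs, gene-overlapping DMRs, primary-context
#' partition, affected CGIs with the orphan vs gene-associated split,
#' promoter DMRs split by promoter CGI content, the gene-level CGI/shore
#' Venn, and a chi-square comparison of CGI-affected vs shore-only gene
#' counts between the conditions (a declared table construction). Every
#' split carries its conservation identity (children sum to the parent) and
#' the identities are checked on construction.
#'
#' @param extraction A \code{\link{extract_specific}} result.
#' @param bundle An \code{\link{annotation_bundle}}.
#' @param peaks_case,peaks_control Optional \code{\link{peak_set}}s for the
#'   headline peak counts and metaprofile.
#' @param metaprofile Optional \code{\link{tss_metaprofile}} result.
#' @param yates Yates correction for the chi-square (default off).
#' @return A list of class \code{dmr_report}.
#' @export
build_report <- function(extraction, bundle, peaks_case = NULL,
                         peaks_control = NULL, metaprofile = NULL,
                         yates = FALSE) {
  stopifnot(is(extraction, "dmr_extraction"))
  sets <- list(case = extraction$case_specific,
               control = extraction$control_specific)
  per_condition <- lapply(sets, function(ds) {
    regions <- ds$regions
    primary <- classify_primary(regions, bundle)
    cgi_feat <- classify_cgi_feature(regions, bundle)
    pairs <- .gene_attribution(regions, bundle)
    affected_cgis <- unique(queryHits(
      findOverlaps(bundle$cgis, regions, ignore.strand = TRUE)))
    orphan_status <- classify_orphan(bundle = bundle)
    n_orphan_hit <- sum(orphan_status[affected_cgis] == "orphan")
    venn <- gene_venn(ds, bundle)
    split <- split_promoters(ds, bundle)
    sub <- suppressWarnings(classify_subcontexts(regions, bundle))
    sub_tab <- table(factor(unlist(sub),
                            levels = c("promoter", "five_prime_utr", "exon",
                                       "intron", "downstream", "enhancer",
                                       "miRNA")))
    list(n_dmrs = length(regions),
         dmr_bp = .sum_width(regions),
         n_gene_overlapping = sum(overlapsAny(regions, bundle$genes,
                                              ignore.strand = TRUE)),
         primary = as.list(table(factor(primary,
                                        levels = c("TSS", "intragenic",
                                                   "intergenic")))),
         subcontexts = as.list(sub_tab),
         cgi_feature = as.list(table(factor(cgi_feat,
                                            levels = c("cgi", "shore",
                                                       "cgi_and_shore",
                                                       "none")))),
         n_affected_cgis = length(affected_cgis),
         n_orphan_cgis_hit = n_orphan_hit,
         orphan_pct = .safe_pct(n_orphan_hit, length(affected_cgis)),
         promoter_split = split,
         promoter_cgi_pct = .safe_pct(split$with_cgi, split$total),
         venn = venn,
         n_affected_genes = length(venn$cgi_and_shore) +
           length(venn$cgi_only) + length(venn$shore_only))
  })

  # declared chi-square construction: genes hypermethylated via a CGI
  # (cgi_only + cgi_and_shore) vs via a shore alone, case vs control
  tab <- matrix(c(
    length(per_condition$case$venn$cgi_and_shore) +
      length(per_condition$case$venn$cgi_only),
    length(per_condition$case$venn$shore_only),
    length(per_condition$control$venn$cgi_and_shore) +
      length(per_condition$control$venn$cgi_only),
    length(per_condition$control$venn$shore_only)), 2, 2, byrow = TRUE,
    dimnames = list(c("case", "control"), c("cgi_affected", "shore_only")))
  chi <- tryCatch(chi_square_2x2(tab, yates = yates),
                  error = function(e) list(statistic = NA_real_,
                                           p = NA_real_, df = 1,
                                           expected = NULL, yates = yates,
                                           note = conditionMessage(e)))

  report <- structure(list(
    peaks = list(
      case = if (!is.null(peaks_case)) length(peaks_case$peaks),
      control = if (!is.null(peaks_control)) length(peaks_control$peaks)),
    extraction_log = extraction$log,
    conditions = per_condition,
    chi_square = c(list(table = tab), chi,
                   list(construction = paste(
                     "genes hypermethylated via CGI (cgi_only +",
                     "cgi_and_shore) vs via shore alone, case vs control;",
                     "declared construction, not a published table"))),
    metaprofile = metaprofile,
    caller_note = "peaks from a Poisson-binned stand-in caller"),
    class = "dmr_report")

  # conservation identities
  for (cond in names(per_condition)) {
    pc <- per_condition[[cond]]
    stopifnot(sum(unlist(pc$primary)) == pc$n_dmrs)
    stopifnot(pc$promoter_split$with_cgi + pc$promoter_split$without_cgi ==
                pc$promoter_split$total)
    stopifnot(sum(unlist(pc$cgi_feature)) == pc$n_dmrs)
    stopifnot(length(intersect(pc$venn$cgi_only, pc$venn$shore_only)) == 0,
              length(intersect(pc$venn$cgi_only, pc$venn$cgi_and_shore)) == 0,
              length(intersect(pc$venn$shore_only, pc$venn$cgi_and_shore)) == 0)
  }
  report
}

#' @export
print.dmr_report <- function(x, ...) {
  cat("dmr_report\n")
  if (!is.null(x$peaks$case))
    cat(sprintf("  peaks: %d case, %d control\n", x$peaks$case,
                x$peaks$control))
  for (cond in names(x$conditions)) {
    pc <- x$conditions[[cond]]
    cat(sprintf("  %s-specific DMRs: %d (%d gene-overlapping)\n", cond,
                pc$n_dmrs, pc$n_gene_overlapping))
    cat(sprintf("    TSS/intragenic/intergenic: %d/%d/%d\n",
                pc$primary$TSS, pc$primary$intragenic,
                pc$primary$intergenic))
    if (pc$n_affected_cgis > 0)
      cat(sprintf("    affected CGIs: %d (orphan %d, %.0f%%)\n",
                  pc$n_affected_cgis, pc$n_orphan_cgis_hit, pc$orphan_pct))
    if (pc$promoter_split$total > 0)
      cat(sprintf("    promoter DMRs: %d with CGI / %d without (%.0f%% with)\n",
                  pc$promoter_split$with_cgi,
                  pc$promoter_split$without_cgi, pc$promoter_cgi_pct))
    cat(sprintf("    gene Venn: %d CGI&shore, %d CGI only, %d shore only\n",
                length(pc$venn$cgi_and_shore), length(pc$venn$cgi_only),
                length(pc$venn$shore_only)))
  }
  if (!is.na(x$chi_square$p))
    cat(sprintf("  chi-square (CGI-affected vs shore-only genes): X2=%.3g, p=%.3g\n",
                x$chi_square$statistic, x$chi_square$p))
  cat("  note:", x$caller_note, "\n")
  invisible(x)
}

# flatten a report for JSON/TSV output
.report_json <- function(report, seed = NULL) {
  conds <- lapply(report$conditions, function(pc) {
    pc$venn <- list(cgi_and_shore_genes = length(pc$venn$cgi_and_shore),
                    cgi_only_genes = length(pc$venn$cgi_only),
                    shore_only_genes = length(pc$venn$shore_only),
                    dmr_counts = as.list(pc$venn$dmr_counts))
    pc
  })
  list(tool = paste0("capdmr ", as.character(utils::packageVersion("capdmr"))),
       seed = seed,
       peaks = report$peaks,
       extraction_log = report$extraction_log,
       conditions = conds,
       chi_square = list(
         table = as.list(as.data.frame(report$chi_square$table)),
         statistic = report$chi_square$statistic,
         p = report$chi_square$p, yates = report$chi_square$yates,
         construction = report$chi_square$construction),
       caller_note = report$caller_note)
}

#' Write a report as JSON and flat TSV tables
#'
#' @param report A \code{\link{build_report}} result.
#' @param dir Output directory.
#' @param seed Seed to record in the JSON.
#' @return Invisibly, the files written.
#' @export
write_report <- function(report, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, "report.json")
  write_json(.report_json(report, seed), f1, auto_unbox = TRUE,
             pretty = TRUE, digits = NA, null = "null")
  rows <- list()
  for (cond in names(report$conditions)) {
    pc <- report$conditions[[cond]]
    add <- function(metric, value)
      rows[[length(rows) + 1]] <<- data.frame(condition = cond,
                                              metric = metric,
                                              value = value)
    add("n_dmrs", pc$n_dmrs)
    add("n_gene_overlapping", pc$n_gene_overlapping)
    for (nm in names(pc$primary)) add(paste0("primary_", nm),
                                      pc$primary[[nm]])
    for (nm in names(pc$subcontexts)) add(paste0("subcontext_", nm),
                                          pc$subcontexts[[nm]])
    add("n_affected_cgis", pc$n_affected_cgis)
    add("n_orphan_cgis_hit", pc$n_orphan_cgis_hit)
    add("promoter_dmrs_with_cgi", pc$promoter_split$with_cgi)
    add("promoter_dmrs_without_cgi", pc$promoter_split$without_cgi)
    add("venn_cgi_and_shore_genes", length(pc$venn$cgi_and_shore))
    add("venn_cgi_only_genes", length(pc$venn$cgi_only))
    add("venn_shore_only_genes", length(pc$venn$shore_only))
  }
  f2 <- file.path(dir, "report.tsv")
  write.table(do.call(rbind, rows), f2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(f1, f2)
  if (!is.null(report$metaprofile)) {
    f3 <- file.path(dir, "metaprofile.tsv")
    write_metaprofile(report$metaprofile, f3)
    files <- c(files, f3)
  }
  invisible(files)
}
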