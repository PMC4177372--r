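# Annotation model: gene models, CpG islands, and the derived features the
# context classifiers need (island shores, promoter windows).

#' Annotation parameters
#'
#' Window sizes, all in bp, used to derive features from the raw tracks.
#'
#' @param promoter_upstream Bases upstream of the TSS in a promoter window
#'   (default 2000).
#' @param promoter_downstream Bases at and downstream of the TSS in a
#'   promoter window (default 500).
#' @param shore_width Width of the CpG-island shore flanking each island
#'   (2000 bp; the standard definition).
#' @param tss_window Half-width of the symmetric TSS window used by the
#'   primary TSS/intragenic/intergenic classification (default 2000).
#' @param metaprofile_halfwidth Half-width of the TSS metaprofile survey
#'   window (default 5000).
#' @param orphan_association_window Upstream reach used when deciding
#'   whether a CpG island is associated with a gene (defaults to
#'   \code{promoter_upstream}).
#' @param downstream_width Strand-aware window past the 3' end attached as
#'   the "downstream" subcontext (default 2000).
#' @return A list of class \code{annotation_params}.
#' @export
annotation_params <- function(promoter_upstream = 2000,
                              promoter_downstream = 500,
                              shore_width = 2000,
                              tss_window = 2000,
                              metaprofile_halfwidth = 5000,
                              orphan_association_window = promoter_upstream,
                              downstream_width = 2000) {
  p <- list(promoter_upstream = promoter_upstream,
            promoter_downstream = promoter_downstream,
            shore_width = shore_width,
            tss_window = tss_window,
            metaprofile_halfwidth = metaprofile_halfwidth,
            orphan_association_window = orphan_association_window,
            downstream_width = downstream_width)
  .assert_scalar_number(promoter_upstream, "promoter_upstream", lo = 0)
  .assert_scalar_number(promoter_downstream, "promoter_downstream", lo = 0)
  if (promoter_upstream + promoter_downstream < 1)
    stop("promoter window must span at least one base")
  .assert_scalar_number(orphan_association_window,
                        "orphan_association_window", lo = 0)
  for (nm in setdiff(names(p), c("promoter_upstream", "promoter_downstream",
                                 "orphan_association_window")))
    .assert_scalar_number(p[[nm]], nm, lo = 1)
  structure(p, class = "annotation_params")
}

#' Transcription start sites of gene models
#'
#' @param genes Stranded GRanges of gene bodies.
#' @return Integer vector: \code{start} for \code{+} genes, \code{end} for
#'   \code{-} genes.
#' @export
gene_tss <- function(genes) {
  st <- as.character(strand(genes))
  if (any(st == "*")) stop("TSS requires stranded gene models")
  ifelse(st == "+", start(genes), end(genes))
}

#' Derive CpG-island shores
#'
#' Shores are the \code{shore_width} bp regions flanking each island, with
#' all island bases excised (including bases of neighbouring islands) and
#' clipped to the chromosome bounds. Input islands are merged first, so
#' bookended or overlapping records cannot create overlapping shores.
#'
#' @param cgis GRanges of CpG islands.
#' @param genome Named vector of chromosome lengths.
#' @param shore_width Flank width in bp (default 2000).
#' @return Sorted, non-overlapping, unstranded GRanges of shore intervals.
#' @export
derive_shores <- function(cgis, genome, shore_width = 2000) {
  m <- .cover(cgis)
  if (length(m) == 0)
    return(.set_genome(GRanges(), genome))
  ch <- as.character(seqnames(m))
  left <- .gr(ch, start(m) - shore_width, start(m) - 1, genome = genome)
  right <- .gr(ch, end(m) + 1, end(m) + shore_width, genome = genome)
  shores <- setdiff(reduce(c(left, right)), m, ignore.strand = TRUE)
  sort(.set_genome(shores, genome))
}

#' Derive strand-aware promoter windows
#'
#' The window covers \code{promoter_upstream} bp upstream of the TSS and
#' \code{promoter_downstream} bp from the TSS onwards, mirrored on the
#' \code{-} strand, clipped to the chromosome.
#'
#' @param genes Stranded GRanges of gene bodies with a \code{gene_id}
#'   metadata column.
#' @param genome Named vector of chromosome lengths.
#' @param params \code{\link{annotation_params}}.
#' @return GRanges of promoter windows carrying \code{gene_id}.
#' @export
derive_promoters <- function(genes, genome, params = annotation_params()) {
  st <- as.character(strand(genes))
  if (any(st == "*"))
    stop("promoters require stranded gene models")
  tss <- gene_tss(genes)
  plus <- st == "+"
  s <- ifelse(plus, tss - params$promoter_upstream,
              tss - params$promoter_downstream + 1)
  e <- ifelse(plus, tss + params$promoter_downstream - 1,
              tss + params$promoter_upstream)
  out <- .gr(as.character(seqnames(genes)), s, e, strand = st,
             genome = genome,
             gene_id = if (!is.null(mcols(genes)$gene_id))
               mcols(genes)$gene_id else sprintf("gene_%d", seq_along(genes)))
  .set_genome(out, genome)
}

# symmetric TSS window (half-open, width 2*tss_window) for the primary
# classifier
.tss_windows <- function(bundle) {
  genes <- bundle$genes
  tss <- gene_tss(genes)
  w <- bundle$params$tss_window
  out <- .gr(as.character(seqnames(genes)), tss - w, tss + w - 1,
             strand = as.character(strand(genes)), genome = bundle$genome,
             gene_id = mcols(genes)$gene_id)
  .set_genome(out, bundle$genome)
}

# gene-association windows for orphan classification (upstream reach is the
# configurable association window)
.assoc_windows <- function(bundle) {
  p <- bundle$params
  derive_promoters(bundle$genes, bundle$genome,
                   annotation_params(
                     promoter_upstream = p$orphan_association_window,
                     promoter_downstream = p$promoter_downstream,
                     shore_width = p$shore_width,
                     tss_window = p$tss_window,
                     metaprofile_halfwidth = p$metaprofile_halfwidth,
                     downstream_width = p$downstream_width))
}

#' Assemble an annotation bundle
#'
#' Validates the component tracks, merges overlapping CpG islands, derives
#' shores and promoters, and indexes everything for overlap queries.
#'
#' @param genome Named vector of chromosome lengths.
#' @param genes Stranded GRanges of gene bodies with \code{gene_id} and
#'   optionally \code{category} (\code{"protein_coding"} or \code{"miRNA"})
#'   metadata.
#' @param cgis GRanges of CpG islands (strand ignored).
#' @param exons Optional GRanges of exons with \code{gene_id}; defaults to
#'   one exon spanning each gene body.
#' @param utr5 Optional GRanges of 5' UTRs with \code{gene_id}.
#' @param enhancers Optional GRanges of enhancers.
#' @param params \code{\link{annotation_params}}.
#' @return A list of class \code{annotation_bundle} with elements
#'   \code{genome}, \code{genes}, \code{exons}, \code{utr5}, \code{cgis},
#'   \code{shores}, \code{promoters}, \code{enhancers}, \code{params}.
#' @export
annotation_bundle <- function(genome, genes, cgis, exons = NULL,
                              utr5 = NULL, enhancers = NULL,
                              params = annotation_params()) {
  stopifnot(is.numeric(genome), !is.null(names(genome)))
  if (is.null(mcols(genes)$gene_id))
    mcols(genes)$gene_id <- sprintf("gene_%d", seq_along(genes))
  if (is.null(mcols(genes)$category))
    mcols(genes)$category <- ifelse(
      grepl("^(hsa-)?mir", mcols(genes)$gene_id, ignore.case = TRUE),
      "miRNA", "protein_coding")
  if (anyDuplicated(mcols(genes)$gene_id))
    stop("duplicated gene_id in gene models")
  if (is.null(exons)) {
    exons <- granges(genes)
    strand(exons) <- "*"
    mcols(exons)$gene_id <- mcols(genes)$gene_id
  }
  if (is.null(utr5)) utr5 <- GRanges(gene_id = character(0))
  # exons must lie inside their gene body
  gidx <- match(mcols(exons)$gene_id, mcols(genes)$gene_id)
  if (anyNA(gidx)) stop("exon with unknown gene_id")
  bad <- which(start(exons) < start(genes)[gidx] |
                 end(exons) > end(genes)[gidx])
  if (length(bad)) stop("exon outside its gene body (exon row ", bad[1], ")")
  for (tr in list(genes, cgis, exons, utr5, enhancers)) {
    if (is.null(tr) || length(tr) == 0) next
    if (!all(as.character(seqnames(tr)) %in% names(genome)))
      stop("annotation interval on unknown chromosome")
    if (any(end(tr) > unname(genome[as.character(seqnames(tr))])) ||
        any(start(tr) < 1))
      stop("annotation interval beyond chromosome length")
  }
  cgis_m <- sort(.cover(cgis))
  mcols(cgis_m)$cgi_id <- sprintf("cgi_%d", seq_along(cgis_m))
  bundle <- structure(
    list(genome = genome,
         genes = .set_genome(sort(genes), genome),
         exons = sort(.set_genome(exons, genome)),
         utr5 = if (length(utr5)) .set_genome(sort(utr5), genome) else utr5,
         cgis = .set_genome(cgis_m, genome),
         shores = NULL, promoters = NULL,
         enhancers = if (!is.null(enhancers))
           .set_genome(sort(.flat(enhancers)), genome) else NULL,
         params = params),
    class = "annotation_bundle")
  bundle$shores <- derive_shores(bundle$cgis, genome, params$shore_width)
  bundle$promoters <- derive_promoters(bundle$genes, genome, params)
  ov <- .sum_width(intersect(bundle$shores, .flat(bundle$cgis),
                             ignore.strand = TRUE))
  stopifnot(ov == 0)
  bundle
}

#' Read annotation tracks and build a bundle
#'
#' @param gene_path Gene table (refFlat 11-column, BED12, or BED6 dialect).
#' @param cgi_path CpG islands, BED3+.
#' @param genome Named vector of chromosome lengths, or a path to a
#'   two-column sizes TSV.
#' @param params \code{\link{annotation_params}}.
#' @param enhancer_path Optional enhancer BED.
#' @param gene_format One of \code{"refflat"}, \code{"bed12"},
#'   \code{"bed6"}.
#' @return An \code{\link{annotation_bundle}}.
#' @export
read_annotation <- function(gene_path, cgi_path, genome,
                            params = annotation_params(),
                            enhancer_path = NULL,
                            gene_format = c("refflat", "bed12", "bed6")) {
  gene_format <- match.arg(gene_format)
  if (is.character(genome)) genome <- read_genome_sizes(genome)
  g <- switch(gene_format,
              refflat = .read_refflat(gene_path, genome),
              bed12 = .read_bed12(gene_path, genome),
              bed6 = .read_bed6_genes(gene_path, genome))
  cgis <- read_bed(cgi_path, genome)
  enh <- if (!is.null(enhancer_path)) read_bed(enhancer_path, genome)
  annotation_bundle(genome, g$genes, cgis, exons = g$exons, utr5 = g$utr5,
                    enhancers = enh, params = params)
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat("annotation_bundle\n")
  cat(sprintf("  genome:    %d chromosome(s), %.3g bp\n",
              length(x$genome), sum(x$genome)))
  cat(sprintf("  genes:     %d (%d miRNA)\n", length(x$genes),
              sum(mcols(x$genes)$category == "miRNA")))
  cat(sprintf("  CGIs:      %d (merged)\n", length(x$cgis)))
  cat(sprintf("  shores:    %d segments, %.3g bp\n", length(x$shores),
              .sum_width(x$shores)))
  cat(sprintf("  promoters: %d windows (-%d/+%d around TSS)\n",
              length(x$promoters), x$params$promoter_upstream,
              x$params$promoter_downstream))
  if (!is.null(x$enhancers))
    cat(sprintf("  enhancers: %d\n", length(x$enhancers)))
  invisible(x)
}

#' Write the derived annotation features
#'
#' Writes shores and promoters as BED6 and a JSON summary of the bundle.
#'
#' @param bundle An \code{\link{annotation_bundle}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_annotation <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  shores <- bundle$shores
  mcols(shores)$name <- sprintf("shore_%d", seq_along(shores))
  f1 <- file.path(dir, "shores.bed")
  write_bed(shores, f1)
  prom <- bundle$promoters
  mcols(prom)$name <- mcols(prom)$gene_id
  f2 <- file.path(dir, "promoters.bed")
  write_bed(prom, f2)
  f3 <- file.path(dir, "annotation_summary.json")
  smry <- list(genome = as.list(bundle$genome),
               n_genes = length(bundle$genes),
               n_mirna = sum(mcols(bundle$genes)$category == "miRNA"),
               n_cgis = length(bundle$cgis),
               n_shore_segments = length(bundle$shores),
               shore_bp = .sum_width(bundle$shores),
               params = unclass(bundle$params))
  write_json(smry, f3, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(f1, f2, f3))
}
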