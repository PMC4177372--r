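# Hierarchical genomic-context classification of DMRs and CpG islands:
# the primary TSS/intragenic/intergenic partition, structural subcontexts,
# the CGI vs shore feature, orphan-CGI status, gene-level Venn tallies,
# promoter CGI splits and the TSS metaprofile.

# regions argument may be a dmr_set or a GRanges
.regions_of <- function(x) {
  if (is(x, "dmr_set")) x$regions else .flat(x)
}

#' Primary genomic context of regions
#'
#' A region is \code{TSS} if it overlaps any gene's symmetric TSS window
#' (half-width \code{tss_window}), else \code{intragenic} if it overlaps any
#' gene body, else \code{intergenic}. The priority TSS > intragenic >
#' intergenic makes the three labels a partition.
#'
#' @param regions GRanges or \code{\link{dmr_set}}.
#' @param bundle An \code{\link{annotation_bundle}}.
#' @return Character vector of labels, one per region.
#' @export
classify_primary <- function(regions, bundle) {
  regions <- .regions_of(regions)
  at_tss <- overlapsAny(regions, .tss_windows(bundle), ignore.strand = TRUE)
  in_gene <- overlapsAny(regions, bundle$genes, ignore.strand = TRUE)
  ifelse(at_tss, "TSS", ifelse(in_gene, "intragenic", "intergenic"))
}

# derived structural feature tracks; intron = gene-body union minus exons
.subcontext_features <- function(bundle) {
  genes <- bundle$genes
  list(
    promoter = .flat(bundle$promoters),
    five_prime_utr = .flat(bundle$utr5),
    exon = .flat(bundle$exons),
    intron = setdiff(.cover(genes), .cover(bundle$exons),
                     ignore.strand = TRUE),
    downstream = .flat(.clip(flank(genes, bundle$params$downstream_width,
                                   start = FALSE), bundle$genome)),
    enhancer = if (!is.null(bundle$enhancers)) .flat(bundle$enhancers),
    miRNA = .flat(genes[mcols(genes)$category == "miRNA"]))
}

#' Structural subcontexts of regions
#'
#' Each label attaches iff the region overlaps at least one base of the
#' corresponding derived feature: promoter window, 5' UTR, exon, intron
#' (gene body minus exons), downstream (strand-aware window past the 3'
#' end), enhancer (only when an enhancer track is loaded; otherwise the
#' label is silently absent and a warning is logged once per call), and
#' miRNA (miRNA gene body). Multiple labels are allowed.
#'
#' @param regions GRanges or \code{\link{dmr_set}}.
#' @param bundle An \code{\link{annotation_bundle}}.
#' @return List of character vectors, one per region.
#' @export
classify_subcontexts <- function(regions, bundle) {
  regions <- .regions_of(regions)
  feats <- .subcontext_features(bundle)
  if (is.null(feats$enhancer)) {
    warning("no enhancer track loaded; 'enhancer' labels unavailable",
            call. = FALSE)
    feats$enhancer <- NULL
  }
  hit <- lapply(feats, function(f)
    if (length(f)) overlapsAny(regions, f, ignore.strand = TRUE)
    else rep(FALSE, length(regions)))
  labs <- names(hit)
  lapply(seq_along(regions), function(i)
    labs[vapply(hit, `[`, logical(1), i)])
}

#' CGI / shore feature of regions
#'
#' @param regions GRanges or \code{\link{dmr_set}}.
#' @param bundle An \code{\link{annotation_bundle}}.
#' @return Character vector with values \code{"cgi"}, \code{"shore"},
#'   \code{"cgi_and_shore"} or \code{"none"} (>= 1 bp overlap each).
#' @export
classify_cgi_feature <- function(regions, bundle) {
  regions <- .regions_of(regions)
  in_cgi <- overlapsAny(regions, bundle$cgis, ignore.strand = TRUE)
  in_shore <- overlapsAny(regions, bundle$shores, ignore.strand = TRUE)
  ifelse(in_cgi & in_shore, "cgi_and_shore",
         ifelse(in_cgi, "cgi", ifelse(in_shore, "shore", "none")))
}

#' Orphan vs gene-associated classification of CpG islands
#'
#' An island is gene-associated iff it overlaps any gene body or any gene's
#' association window (promoter-like window whose upstream reach is
#' \code{orphan_association_window}); otherwise it is an orphan island.
#'
#' @param cgis GRanges of islands; defaults to the bundle's.
#' @param bundle An \code{\link{annotation_bundle}}.
#' @return Character vector \code{"orphan"} / \code{"gene_associated"}.
#' @export
classify_orphan <- function(cgis = NULL, bundle) {
  if (is.null(cgis)) cgis <- bundle$cgis
  assoc <- overlapsAny(cgis, bundle$genes, ignore.strand = TRUE) |
    overlapsAny(cgis, .assoc_windows(bundle), ignore.strand = TRUE)
  ifelse(assoc, "gene_associated", "orphan")
}

# (dmr index, gene index) attribution pairs: a DMR is attributed to every
# gene whose body or association window it overlaps (same rule as
# classify_orphan, applied to the DMR)
.gene_attribution <- function(regions, bundle) {
  aw <- .assoc_windows(bundle)
  h1 <- findOverlaps(regions, bundle$genes, ignore.strand = TRUE)
  h2 <- findOverlaps(regions, aw, ignore.strand = TRUE)
  pairs <- unique(rbind(
    data.frame(dmr = queryHits(h1), gene = subjectHits(h1)),
    data.frame(dmr = queryHits(h2),
               gene = match(mcols(aw)$gene_id[subjectHits(h2)],
                            mcols(bundle$genes)$gene_id))))
  pairs[order(pairs$dmr, pairs$gene), , drop = FALSE]
}

#' Annotate DMRs with their full context
#'
#' @param regions GRanges or \code{\link{dmr_set}}.
#' @param bundle An \code{\link{annotation_bundle}}.
#' @return data.frame with one row per region: coordinates, primary
#'   context, comma-collapsed subcontexts, CGI feature, and the gene and
#'   CGI identifiers hit.
#' @export
annotate_dmrs <- function(regions, bundle) {
  regions <- .regions_of(regions)
  sub <- suppressWarnings(classify_subcontexts(regions, bundle))
  pairs <- .gene_attribution(regions, bundle)
  genes_hit <- vapply(seq_along(regions), function(i) {
    g <- pairs$gene[pairs$dmr == i]
    paste(mcols(bundle$genes)$gene_id[g], collapse = ",")
  }, character(1))
  hc <- findOverlaps(regions, bundle$cgis, ignore.strand = TRUE)
  cgis_hit <- vapply(seq_along(regions), function(i) {
    paste(mcols(bundle$cgis)$cgi_id[subjectHits(hc)[queryHits(hc) == i]],
          collapse = ",")
  }, character(1))
  data.frame(
    chrom = as.character(seqnames(regions)),
    start = start(regions) - 1, end = end(regions),
    primary_context = classify_primary(regions, bundle),
    subcontexts = vapply(sub, paste, character(1), collapse = ","),
    cgi_feature = classify_cgi_feature(regions, bundle),
    genes_hit = genes_hit, cgis_hit = cgis_hit,
    stringsAsFactors = FALSE)
}

#' Gene-level CGI/shore Venn of hypermethylation sites
#'
#' Each DMR is attributed to every gene whose body or association window it
#' overlaps. A gene enters \code{cgi_and_shore} when its attributed DMRs
#' collectively hit both island and shore bases (one straddling DMR or
#' several DMRs), \code{cgi_only} / \code{shore_only} otherwise; genes with
#' no island- or shore-hitting DMR are absent. DMR tallies count distinct
#' DMRs per category (a DMR shared by genes of different categories counts
#' in each, mirroring the many-to-many gene/DMR attribution).
#'
#' @param dmrs \code{\link{dmr_set}} or GRanges.
#' @param bundle An \code{\link{annotation_bundle}}.
#' @return A list of class \code{gene_venn}: gene-id sets
#'   \code{cgi_and_shore}, \code{cgi_only}, \code{shore_only} and
#'   \code{dmr_counts}.
#' @export
gene_venn <- function(dmrs, bundle) {
  regions <- .regions_of(dmrs)
  pairs <- .gene_attribution(regions, bundle)
  hit_cgi <- overlapsAny(regions, bundle$cgis, ignore.strand = TRUE)
  hit_shore <- overlapsAny(regions, bundle$shores, ignore.strand = TRUE)
  rel <- pairs[hit_cgi[pairs$dmr] | hit_shore[pairs$dmr], , drop = FALSE]
  cat_of_gene <- tapply(seq_len(nrow(rel)), rel$gene, function(rows) {
    any_c <- any(hit_cgi[rel$dmr[rows]])
    any_s <- any(hit_shore[rel$dmr[rows]])
    if (any_c && any_s) "cgi_and_shore" else if (any_c) "cgi_only"
    else "shore_only"
  })
  gene_ids <- mcols(bundle$genes)$gene_id[as.integer(names(cat_of_gene))]
  sets <- split(gene_ids, factor(unlist(cat_of_gene),
                                 levels = c("cgi_and_shore", "cgi_only",
                                            "shore_only")))
  dmr_counts <- vapply(names(sets), function(cat) {
    g_idx <- as.integer(names(cat_of_gene))[unlist(cat_of_gene) == cat]
    length(unique(rel$dmr[rel$gene %in% g_idx]))
  }, integer(1))
  structure(list(cgi_and_shore = unname(sets$cgi_and_shore),
                 cgi_only = unname(sets$cgi_only),
                 shore_only = unname(sets$shore_only),
                 dmr_counts = dmr_counts),
            class = "gene_venn")
}

#' @export
print.gene_venn <- function(x, ...) {
  cat("gene_venn (sites of hypermethylation per gene)\n")
  cat(sprintf("  CGI and shore: %d genes (%d DMRs)\n",
              length(x$cgi_and_shore), x$dmr_counts[["cgi_and_shore"]]))
  cat(sprintf("  CGI only:      %d genes (%d DMRs)\n",
              length(x$cgi_only), x$dmr_counts[["cgi_only"]]))
  cat(sprintf("  shore only:    %d genes (%d DMRs)\n",
              length(x$shore_only), x$dmr_counts[["shore_only"]]))
  invisible(x)
}

#' Split promoter-overlapping DMRs by promoter CGI content
#'
#' Counts DMRs overlapping at least one promoter window, partitioned by
#' whether an overlapped promoter itself contains >= 1 bp of CpG island. A
#' DMR hitting promoters of discordant CGI status counts once, in the
#' with-CGI arm (declared tie rule).
#'
#' @param dmrs \code{\link{dmr_set}} or GRanges.
#' @param bundle An \code{\link{annotation_bundle}}.
#' @return List with \code{with_cgi}, \code{without_cgi}, \code{total}.
#' @export
split_promoters <- function(dmrs, bundle) {
  regions <- .regions_of(dmrs)
  prom <- bundle$promoters
  prom_cgi <- overlapsAny(prom, bundle$cgis, ignore.strand = TRUE)
  h <- findOverlaps(regions, prom, ignore.strand = TRUE)
  if (length(h) == 0)
    return(list(with_cgi = 0L, without_cgi = 0L, total = 0L))
  with_cgi <- tapply(prom_cgi[subjectHits(h)], queryHits(h), any)
  list(with_cgi = sum(with_cgi), without_cgi = sum(!with_cgi),
       total = length(with_cgi))
}

#' TSS metaprofile of peak coverage
#'
#' For every gene and every peak overlapping its strand-oriented window of
#' \code{halfwidth} bp on either side of the TSS, every profile bin the
#' peak covers is incremented; negative offsets are upstream for both
#' strands. The sum over bins equals the total number of (peak, gene, bin)
#' coverage events.
#'
#' @param peaks \code{\link{peak_set}} or GRanges.
#' @param bundle An \code{\link{annotation_bundle}}.
#' @param halfwidth Survey half-width in bp (default: bundle parameter,
#'   5000).
#' @param bin_bp Profile bin width; must divide \code{halfwidth} (default
#'   50).
#' @return A list of class \code{meta_profile} with bin-center
#'   \code{offset}s and \code{counts}.
#' @export
tss_metaprofile <- function(peaks, bundle, halfwidth = NULL, bin_bp = 50) {
  pk <- if (is(peaks, "peak_set")) .flat(peaks$peaks) else .flat(peaks)
  if (is.null(halfwidth)) halfwidth <- bundle$params$metaprofile_halfwidth
  if (halfwidth %% bin_bp != 0)
    stop("bin_bp must divide halfwidth")
  nb <- 2 * halfwidth / bin_bp
  counts <- integer(nb)
  genes <- bundle$genes
  tss <- gene_tss(genes)
  minus <- as.character(strand(genes)) == "-"
  win <- .gr(as.character(seqnames(genes)), tss - halfwidth,
             tss + halfwidth - 1, genome = bundle$genome)
  h <- findOverlaps(pk, win, ignore.strand = TRUE)
  for (k in seq_along(h)) {
    p <- queryHits(h)[k]; g <- subjectHits(h)[k]
    lo <- max(start(pk)[p], tss[g] - halfwidth)
    hi <- min(end(pk)[p], tss[g] + halfwidth - 1)
    if (minus[g]) {
      r <- c(tss[g] - hi, tss[g] - lo)
    } else {
      r <- c(lo - tss[g], hi - tss[g])
    }
    b0 <- floor((r[1] + halfwidth) / bin_bp) + 1
    b1 <- floor((r[2] + halfwidth) / bin_bp) + 1
    b1 <- min(b1, nb)
    counts[b0:b1] <- counts[b0:b1] + 1L
  }
  structure(list(bin_bp = bin_bp, halfwidth = halfwidth,
                 offset = -halfwidth + (seq_len(nb) - 0.5) * bin_bp,
                 counts = counts),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("meta_profile: +/-%d bp around TSS, %d bp bins, %d events\n",
              x$halfwidth, x$bin_bp, sum(x$counts)))
  invisible(x)
}

#' Write a metaprofile as two-column TSV
#'
#' @param profile A \code{meta_profile}.
#' @param path Output path (columns: bin-center offset, count).
#' @return Invisibly, the path.
#' @export
write_metaprofile <- function(profile, path) {
  write.table(data.frame(offset = profile$offset, count = profile$counts),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Composite context label of recovered regions
#'
#' Collapses the hierarchical annotation into the single label vocabulary
#' used for planted regions, applying the declared priorities: promoter
#' (split by promoter CGI content, with-CGI winning ties) > orphan CGI >
#' shore > intragenic > intergenic.
#'
#' @param regions GRanges or \code{\link{dmr_set}}.
#' @param bundle An \code{\link{annotation_bundle}}.
#' @return Character vector over \code{promoter_cgi}, \code{promoter_nocgi},
#'   \code{orphan_cgi}, \code{shore}, \code{intragenic}, \code{intergenic}.
#' @export
composite_context <- function(regions, bundle) {
  regions <- .regions_of(regions)
  prom <- bundle$promoters
  prom_cgi <- overlapsAny(prom, bundle$cgis, ignore.strand = TRUE)
  in_prom_cgi <- overlapsAny(regions, prom[prom_cgi], ignore.strand = TRUE)
  in_prom <- overlapsAny(regions, prom, ignore.strand = TRUE)
  orphan <- bundle$cgis[classify_orphan(bundle = bundle) == "orphan"]
  in_orphan <- overlapsAny(regions, orphan, ignore.strand = TRUE)
  in_shore <- overlapsAny(regions, bundle$shores, ignore.strand = TRUE)
  in_gene <- overlapsAny(regions, bundle$genes, ignore.strand = TRUE)
  ifelse(in_prom_cgi, "promoter_cgi",
         ifelse(in_prom, "promoter_nocgi",
                ifelse(in_orphan, "orphan_cgi",
                       ifelse(in_shore, "shore",
                              ifelse(in_gene, "intragenic",
                                     "intergenic")))))
}
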