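# Brute-force oracles and hand-built fixtures. Every oracle transcribes a
# definition base by base (or region by region) independently of the
# interval algebra used by the package.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

gr1 <- function(chrom, start, end, strand = "*", ...) {
  GRanges(chrom, IRanges(start, end), strand = strand, ...)
}

# per-base shore membership on a single chromosome: a base is shore iff it
# lies within `width` bp of some island and inside no island
oracle_shore_mask <- function(cgi_start, cgi_end, chrom_len, width = 2000) {
  in_cgi <- logical(chrom_len)
  near <- logical(chrom_len)
  for (i in seq_along(cgi_start)) {
    in_cgi[cgi_start[i]:cgi_end[i]] <- TRUE
    lo <- max(1, cgi_start[i] - width)
    hi <- min(chrom_len, cgi_end[i] + width)
    near[lo:hi] <- TRUE
  }
  near & !in_cgi
}

base_mask <- function(gr, chrom, chrom_len) {
  m <- logical(chrom_len)
  gr <- gr[as.character(seqnames(gr)) == chrom]
  for (i in seq_along(gr)) m[start(gr)[i]:min(end(gr)[i], chrom_len)] <- TRUE
  m
}

# base-level dual-threshold definition on one chromosome
oracle_dual_threshold <- function(case_df, ctrl_df, chrom_len,
                                  high = 0.975, low = 0.950) {
  cover <- function(df, thr) {
    m <- logical(chrom_len)
    keep <- df$conf >= thr
    for (i in which(keep)) m[df$start[i]:df$end[i]] <- TRUE
    m
  }
  list(case_specific = cover(case_df, high) & !cover(ctrl_df, low),
       control_specific = cover(ctrl_df, high) & !cover(case_df, low),
       common = cover(case_df, low) & cover(ctrl_df, low))
}

# region-level primary context by direct re-evaluation of the definition
oracle_primary <- function(regions, bundle) {
  genes <- bundle$genes
  tss <- gene_tss(genes)
  w <- bundle$params$tss_window
  vapply(seq_along(regions), function(i) {
    s <- start(regions)[i]; e <- end(regions)[i]
    ch <- as.character(seqnames(regions))[i]
    on_ch <- as.character(seqnames(genes)) == ch
    hit_tss <- any(on_ch & s <= tss + w - 1 & e >= tss - w)
    hit_body <- any(on_ch & s <= end(genes) & e >= start(genes))
    if (hit_tss) "TSS" else if (hit_body) "intragenic" else "intergenic"
  }, character(1))
}

oracle_cgi_feature <- function(regions, bundle) {
  hits <- function(feat) {
    vapply(seq_along(regions), function(i) {
      ch <- as.character(seqnames(regions))[i]
      on_ch <- as.character(seqnames(feat)) == ch
      any(on_ch & start(regions)[i] <= end(feat) &
            end(regions)[i] >= start(feat))
    }, logical(1))
  }
  c_hit <- hits(bundle$cgis)
  s_hit <- hits(bundle$shores)
  ifelse(c_hit & s_hit, "cgi_and_shore",
         ifelse(c_hit, "cgi", ifelse(s_hit, "shore", "none")))
}

oracle_orphan <- function(bundle) {
  genes <- bundle$genes
  tss <- gene_tss(genes)
  aw <- bundle$params$orphan_association_window
  dn <- bundle$params$promoter_downstream
  plus <- as.character(strand(genes)) == "+"
  win_s <- ifelse(plus, tss - aw, tss - dn + 1)
  win_e <- ifelse(plus, tss + dn - 1, tss + aw)
  vapply(seq_along(bundle$cgis), function(i) {
    s <- start(bundle$cgis)[i]; e <- end(bundle$cgis)[i]
    ch <- as.character(seqnames(bundle$cgis))[i]
    on_ch <- as.character(seqnames(genes)) == ch
    assoc <- any(on_ch & s <= end(genes) & e >= start(genes)) ||
      any(on_ch & s <= win_e & e >= win_s)
    if (assoc) "gene_associated" else "orphan"
  }, character(1))
}

# reflect a genome: position p -> L - p + 1, strands flipped
reflect_gr <- function(gr, genome) {
  L <- unname(genome[as.character(seqnames(gr))])
  out <- GRanges(seqnames(gr), IRanges(L - end(gr) + 1, L - start(gr) + 1),
                 strand = chartr("+-", "-+", as.character(strand(gr))))
  mcols(out) <- mcols(gr)
  out
}

reflect_bundle <- function(bundle) {
  annotation_bundle(bundle$genome,
                    reflect_gr(bundle$genes, bundle$genome),
                    reflect_gr(bundle$cgis, bundle$genome),
                    exons = reflect_gr(bundle$exons, bundle$genome),
                    utr5 = if (length(bundle$utr5))
                      reflect_gr(bundle$utr5, bundle$genome),
                    enhancers = if (!is.null(bundle$enhancers))
                      reflect_gr(bundle$enhancers, bundle$genome),
                    params = bundle$params)
}

# minimal peak_set construction for screen tests
make_peak_set <- function(df, condition = "case", lambda = 5,
                          genome = NULL) {
  peaks <- gr1(df$chrom, df$start, df$end)
  mcols(peaks)$confidence <- df$conf
  mcols(peaks)$max_count <- NA_integer_
  mcols(peaks)$mean_count <- NA_real_
  structure(list(condition = condition, peaks = sort(peaks),
                 background_lambda = lambda, min_confidence = min(df$conf),
                 merge_gap_bp = 0, min_peak_bins = 1, bin_bp = 50,
                 caller = "test fixture"),
            class = "peak_set")
}

# a small deterministic hand-built bundle used across context tests:
# geneA's promoter contains a CGI, geneD's promoter abuts it without
# touching the island, geneC's TSS window reaches into geneA's body, geneB
# is isolated, and one CGI is orphan; the miRNA gene carries the
# documented coordinates of a hypermethylated miRNA locus
tiny_bundle <- function() {
  genome <- c(chr1 = 100000, chr15 = 89950000)
  genes <- gr1(
    c("chr1", "chr1", "chr1", "chr1", "chr15"),
    c(20001, 30501, 50001, 8001, 89908728),
    c(30000, 40000, 60000, 16000, 89909052),
    strand = c("+", "+", "-", "-", "+"),
    gene_id = c("geneA", "geneC", "geneB", "geneD", "hsa-mir-9-3"),
    category = c(rep("protein_coding", 4), "miRNA"))
  exons <- gr1(
    c("chr1", "chr1", "chr1", "chr1", "chr1", "chr15"),
    c(20001, 25001, 30501, 50001, 8001, 89908728),
    c(21000, 30000, 40000, 60000, 16000, 89909052),
    gene_id = c("geneA", "geneA", "geneC", "geneB", "geneD",
                "hsa-mir-9-3"))
  utr5 <- gr1("chr1", 20001, 20200, strand = "+", gene_id = "geneA")
  cgis <- gr1(c("chr1", "chr1"), c(18401, 80001), c(19300, 80600))
  annotation_bundle(genome, genes, cgis, exons = exons, utr5 = utr5)
}
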