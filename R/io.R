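# Readers and writers for the plain-text formats the pipeline speaks:
# chromosome sizes (two-column TSV), BED3/4/6(+1), BED12 / refFlat gene
# tables, and bedGraph coverage. Parsing is done directly so malformed rows
# can be rejected by row number and so the extra full-precision confidence
# column of peak BED files survives a round trip.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
             comment.char = "#", quote = "", colClasses = NA)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns chromosome name and length (bp).
#' @return Named numeric vector of chromosome lengths.
#' @export
read_genome_sizes <- function(path) {
  tab <- .read_tsv(path)
  if (ncol(tab) < 2) stop("genome sizes file needs two columns: ", path)
  len <- suppressWarnings(as.numeric(tab[[2]]))
  bad <- which(is.na(len) | len <= 0)
  if (length(bad))
    stop("invalid chromosome length at row ", bad[1], " of ", path)
  if (anyDuplicated(tab[[1]]))
    stop("duplicated chromosome name in ", path)
  structure(len, names = as.character(tab[[1]]))
}

# core BED validation shared by all BED dialects; coords are converted from
# 0-based half-open to 1-based closed here and nowhere else
.bed_core <- function(tab, path, genome = NULL) {
  if (ncol(tab) < 3) stop("need at least 3 BED columns in ", path)
  s0 <- suppressWarnings(as.numeric(tab[[2]]))
  e0 <- suppressWarnings(as.numeric(tab[[3]]))
  bad <- which(is.na(s0) | is.na(e0) | s0 < 0 | s0 >= e0)
  if (length(bad))
    stop("malformed coordinates (need 0 <= start < end) at row ", bad[1],
         " of ", path, call. = FALSE)
  if (!is.null(genome)) {
    unk <- which(!tab[[1]] %in% names(genome))
    if (length(unk))
      stop("unknown chromosome '", tab[[1]][unk[1]], "' at row ", unk[1],
           " of ", path, call. = FALSE)
    over <- which(e0 > unname(genome[as.character(tab[[1]])]))
    if (length(over))
      stop("interval beyond chromosome length at row ", over[1], " of ",
           path, call. = FALSE)
  }
  list(chrom = as.character(tab[[1]]), start = s0 + 1, end = e0)
}

#' Read a BED file as a GRanges
#'
#' Accepts BED3 upward. Column 4 becomes \code{name}, column 5 \code{score},
#' column 6 strand (\code{.} maps to \code{*}); further columns can be kept
#' via \code{extra_cols}. Coordinates are validated row by row (0 <= start <
#' end, end within the chromosome when \code{genome} is given).
#'
#' @param path BED file path.
#' @param genome Optional named vector of chromosome lengths used for bounds
#'   checking and sequence info.
#' @param extra_cols Optional character vector naming columns 7, 8, ... to
#'   retain as metadata columns.
#' @return GRanges with any requested metadata columns.
#' @export
read_bed <- function(path, genome = NULL, extra_cols = NULL) {
  tab <- .read_tsv(path)
  core <- .bed_core(tab, path, genome)
  strand <- if (ncol(tab) >= 6) {
    st <- as.character(tab[[6]])
    st[!st %in% c("+", "-")] <- "*"
    st
  } else "*"
  gr <- GRanges(core$chrom, IRanges(core$start, core$end), strand = strand)
  if (ncol(tab) >= 4) mcols(gr)$name <- as.character(tab[[4]])
  if (ncol(tab) >= 5)
    mcols(gr)$score <- suppressWarnings(as.numeric(tab[[5]]))
  if (!is.null(extra_cols)) {
    for (i in seq_along(extra_cols)) {
      col <- 6 + i
      if (col <= ncol(tab)) mcols(gr)[[extra_cols[i]]] <- tab[[col]]
    }
  }
  if (!is.null(genome)) gr <- .set_genome(gr, genome)
  gr
}

#' Write a GRanges as BED
#'
#' Inverse of \code{\link{read_bed}}: 1-based closed GRanges coordinates are
#' written 0-based half-open. \code{name} and \code{score} metadata columns
#' populate BED columns 4-5 when present; \code{extra_cols} appends metadata
#' columns after the strand at full precision.
#'
#' @param gr GRanges to write.
#' @param path Output path.
#' @param extra_cols Optional character vector of metadata column names to
#'   append as columns 7+.
#' @return Invisibly, the path.
#' @export
write_bed <- function(gr, path, extra_cols = NULL) {
  n <- length(gr)
  nm <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name)
        else rep(".", n)
  sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else rep(0, n)
  st <- as.character(strand(gr))
  st[st == "*"] <- "."
  out <- data.frame(chrom = as.character(seqnames(gr)),
                    start = format(start(gr) - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(end(gr), scientific = FALSE, trim = TRUE),
                    name = nm, score = sc, strand = st,
                    stringsAsFactors = FALSE)
  for (col in extra_cols) out[[col]] <- mcols(gr)[[col]]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# refFlat-style gene table: geneName txName chrom strand txStart txEnd
# cdsStart cdsEnd exonCount exonStarts exonEnds (UCSC dump, 0-based starts)
.read_refflat <- function(path, genome) {
  tab <- .read_tsv(path)
  if (ncol(tab) < 11)
    stop("refFlat gene table needs 11 columns: ", path)
  chrom <- as.character(tab[[3]])
  strand <- as.character(tab[[4]])
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop("gene without strand at row ", bad[1], " of ", path, call. = FALSE)
  core <- .bed_core(tab[, c(3, 5, 6)], path, genome)
  gene_id <- make.unique(as.character(tab[[1]]), sep = "_")
  genes <- GRanges(chrom, IRanges(core$start, core$end), strand = strand)
  mcols(genes)$gene_id <- gene_id
  ex_list <- lapply(seq_len(nrow(tab)), function(i) {
    es <- as.numeric(strsplit(as.character(tab[[10]][i]), ",")[[1]]) + 1
    ee <- as.numeric(strsplit(as.character(tab[[11]][i]), ",")[[1]])
    if (length(es) != length(ee) || any(es > ee))
      stop("malformed exon list at row ", i, " of ", path, call. = FALSE)
    data.frame(chrom = chrom[i], start = es, end = ee,
               gene_id = gene_id[i], stringsAsFactors = FALSE)
  })
  ex <- do.call(rbind, ex_list)
  exons <- GRanges(ex$chrom, IRanges(ex$start, ex$end))
  mcols(exons)$gene_id <- ex$gene_id
  # 5' UTR: transcript span before the CDS on the sense strand; absent for
  # non-coding rows (cdsStart == cdsEnd)
  cs <- as.numeric(tab[[7]]) + 1
  ce <- as.numeric(tab[[8]])
  coding <- cs <= ce
  plus <- strand == "+"
  us <- ifelse(plus, core$start, ce + 1)
  ue <- ifelse(plus, cs - 1, core$end)
  keep <- coding & us <= ue
  utr5 <- GRanges(chrom[keep], IRanges(us[keep], ue[keep]),
                  strand = strand[keep])
  mcols(utr5)$gene_id <- gene_id[keep]
  list(genes = genes, exons = exons, utr5 = utr5)
}

# BED12: thickStart/thickEnd give the CDS, blocks give exons
.read_bed12 <- function(path, genome) {
  tab <- .read_tsv(path)
  if (ncol(tab) < 12) stop("BED12 gene table needs 12 columns: ", path)
  core <- .bed_core(tab, path, genome)
  strand <- as.character(tab[[6]])
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop("gene without strand at row ", bad[1], " of ", path, call. = FALSE)
  gene_id <- make.unique(as.character(tab[[4]]), sep = "_")
  genes <- GRanges(core$chrom, IRanges(core$start, core$end),
                   strand = strand)
  mcols(genes)$gene_id <- gene_id
  ex_list <- lapply(seq_len(nrow(tab)), function(i) {
    sizes <- as.numeric(strsplit(as.character(tab[[11]][i]), ",")[[1]])
    offs <- as.numeric(strsplit(as.character(tab[[12]][i]), ",")[[1]])
    if (length(sizes) != length(offs))
      stop("malformed block list at row ", i, " of ", path, call. = FALSE)
    data.frame(chrom = core$chrom[i], start = core$start[i] + offs,
               end = core$start[i] + offs + sizes - 1,
               gene_id = gene_id[i], stringsAsFactors = FALSE)
  })
  ex <- do.call(rbind, ex_list)
  exons <- GRanges(ex$chrom, IRanges(ex$start, ex$end))
  mcols(exons)$gene_id <- ex$gene_id
  ts <- as.numeric(tab[[7]]) + 1
  te <- as.numeric(tab[[8]])
  coding <- ts <= te
  plus <- strand == "+"
  us <- ifelse(plus, core$start, te + 1)
  ue <- ifelse(plus, ts - 1, core$end)
  keep <- coding & us <= ue
  utr5 <- GRanges(core$chrom[keep], IRanges(us[keep], ue[keep]),
                  strand = strand[keep])
  mcols(utr5)$gene_id <- gene_id[keep]
  list(genes = genes, exons = exons, utr5 = utr5)
}

# BED6 genes: single-exon models, no UTR
.read_bed6_genes <- function(path, genome) {
  gr <- read_bed(path, genome)
  bad <- which(as.character(strand(gr)) == "*")
  if (length(bad))
    stop("gene without strand at row ", bad[1], " of ", path, call. = FALSE)
  gene_id <- if (!is.null(mcols(gr)$name))
    make.unique(as.character(mcols(gr)$name), sep = "_")
  else sprintf("gene_%d", seq_along(gr))
  genes <- granges(gr)
  mcols(genes)$gene_id <- gene_id
  exons <- genes
  list(genes = genes, exons = exons,
       utr5 = GRanges(gene_id = character(0)))
}

#' Read coverage bins from a bedGraph file
#'
#' Expands run-length bedGraph records onto a fixed bin grid. Records must be
#' bin-aligned multiples of \code{bin_bp}; uncovered bins are zero.
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @param genome Named vector of chromosome lengths.
#' @param bin_bp Bin width in bp.
#' @param condition Condition label to attach (\code{"case"} or
#'   \code{"control"}).
#' @return A \code{coverage_track} object.
#' @export
read_bedgraph <- function(path, genome, bin_bp, condition = "case") {
  tab <- .read_tsv(path)
  if (ncol(tab) < 4) stop("bedGraph needs 4 columns: ", path)
  core <- .bed_core(tab, path, genome)
  val <- suppressWarnings(as.numeric(tab[[4]]))
  bad <- which(is.na(val) | val < 0)
  if (length(bad)) stop("invalid coverage value at row ", bad[1], " of ", path)
  s0 <- core$start - 1
  mis <- which(s0 %% bin_bp != 0 |
                 (core$end %% bin_bp != 0 &
                    core$end != unname(genome[core$chrom])))
  if (length(mis))
    stop("record not aligned to the ", bin_bp, " bp bin grid at row ",
         mis[1], " of ", path, call. = FALSE)
  bins <- lapply(names(genome), function(ch) {
    n <- ceiling(unname(genome[ch]) / bin_bp)
    v <- integer(n)
    rows <- which(core$chrom == ch)
    for (i in rows) {
      b0 <- s0[i] %/% bin_bp + 1
      b1 <- ceiling(core$end[i] / bin_bp)
      v[b0:b1] <- val[i]
    }
    v
  })
  names(bins) <- names(genome)
  coverage_track(condition, bins, bin_bp, genome)
}

#' Write a coverage track as bedGraph
#'
#' Consecutive equal-valued bins are collapsed into single records.
#'
#' @param track A \code{coverage_track}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$bins), function(ch) {
    v <- track$bins[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    data.frame(chrom = ch,
               start = (starts - 1) * track$bin_bp,
               end = pmin(ends * track$bin_bp, unname(track$genome[ch])),
               value = r$values, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$value != 0, , drop = FALSE]
  write.table(format(out, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
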