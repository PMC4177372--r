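# Internal interval helpers. All public coordinates follow BED files
# (0-based half-open) at the I/O boundary; in memory everything is a
# GRanges (1-based closed) so GenomicRanges does the set algebra.

# strip strand and metadata so set operations act on plain base space
.flat <- function(x) {
  x <- granges(x)
  strand(x) <- "*"
  mcols(x) <- NULL
  x
}

# union cover of x with gaps < gap bp bridged (gap = 0 bridges bookended
# ranges only, i.e. adjacent coverage bins)
.cover <- function(x, gap = 0L) {
  reduce(.flat(x), min.gapwidth = max(as.integer(gap), 1L))
}

.sum_width <- function(x) sum(as.numeric(width(x)))

# build a GRanges clipped to [1, genome[chrom]]; rows that vanish are dropped
.gr <- function(chrom, start, end, strand = "*", genome = NULL, ...) {
  chrom <- as.character(chrom)
  if (!is.null(genome)) {
    if (!all(chrom %in% names(genome)))
      stop("unknown chromosome(s): ",
           paste(unique(chrom[!chrom %in% names(genome)]), collapse = ", "))
    len <- unname(genome[chrom])
    start <- pmax(start, 1)
    end <- pmin(end, len)
  }
  keep <- start <= end
  strand <- rep(strand, length.out = length(chrom))
  gr <- GRanges(chrom[keep], IRanges(start[keep], end[keep]),
                strand = strand[keep])
  extra <- list(...)
  for (nm in names(extra)) {
    v <- rep(extra[[nm]], length.out = length(chrom))
    mcols(gr)[[nm]] <- v[keep]
  }
  if (!is.null(genome))
    seqlevels(gr) <- names(genome)
  gr
}

.set_genome <- function(gr, genome) {
  seqlevels(gr) <- names(genome)
  seqlengths(gr) <- unname(genome[seqlevels(gr)])
  gr
}

# clip to chromosome bounds without out-of-bound construction warnings
.clip <- function(gr, genome) {
  s <- pmax(start(gr), 1L)
  len <- unname(genome[as.character(seqnames(gr))])
  e <- pmin(end(gr), len)
  keep <- s <= e
  out <- .gr(as.character(seqnames(gr))[keep], s[keep], e[keep],
             strand = as.character(strand(gr))[keep])
  mcols(out) <- mcols(gr)[keep, , drop = FALSE]
  .set_genome(out, genome)
}

.assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
    stop(name, " must be a single number in [", lo, ", ", hi, "]",
         call. = FALSE)
  invisible(x)
}

#' Per-region Jaccard overlap between planted and recovered regions
#'
#' For each query region, the Jaccard index between the region and the union
#' of all recovered regions that touch it: shared bases divided by bases in
#' the union of the query with those recovered regions. Regions touched by
#' nothing score 0. Used to quantify how well called DMRs recover planted
#' (truth) regions in simulations.
#'
#' @param truth GRanges of reference (e.g. planted) regions.
#' @param recovered GRanges of called regions.
#' @return Numeric vector, one Jaccard index in \code{[0, 1]} per truth
#'   region.
#' @export
region_jaccard <- function(truth, recovered) {
  truth <- .flat(truth)
  recovered <- .cover(recovered)
  vapply(seq_along(truth), function(i) {
    t1 <- truth[i]
    hit <- recovered[overlapsAny(recovered, t1)]
    if (length(hit) == 0) return(0)
    inter <- .sum_width(intersect(t1, hit, ignore.strand = TRUE))
    uni <- .sum_width(union(t1, hit, ignore.strand = TRUE))
    inter / uni
  }, numeric(1))
}
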