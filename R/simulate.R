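# Synthetic methylCap-seq data: a toy annotated genome plus two-condition
# binned capture coverage with planted condition-specific hypermethylated
# regions, commonly methylated regions, and fully methylated / unmethylated
# spike-in fragments on a dedicated contig. Planted regions are placed
# deliberately inside chosen genomic contexts and bin-aligned, so both DMR
# recovery and context-label recovery are exactly checkable downstream.

#' Binned coverage track
#'
#' @param condition \code{"case"} or \code{"control"}.
#' @param bins Named list (one element per chromosome) of non-negative
#'   integer fragment counts per bin.
#' @param bin_bp Bin width in bp.
#' @param genome Named vector of chromosome lengths.
#' @return A list of class \code{coverage_track}; \code{n_fragments} records
#'   the total number of simulated/observed fragments.
#' @export
coverage_track <- function(condition = c("case", "control"), bins, bin_bp,
                           genome) {
  condition <- match.arg(condition)
  stopifnot(is.list(bins), !is.null(names(bins)),
            all(names(bins) %in% names(genome)))
  for (ch in names(bins)) {
    v <- bins[[ch]]
    if (any(v < 0) || any(v != floor(v)))
      stop("bin counts must be non-negative integers (", ch, ")")
    if (length(v) != ceiling(unname(genome[ch]) / bin_bp))
      stop("bin vector length mismatch on ", ch)
    bins[[ch]] <- as.integer(v)
  }
  structure(list(condition = condition, bins = bins, bin_bp = bin_bp,
                 genome = genome[names(bins)],
                 n_fragments = sum(vapply(bins, sum, numeric(1)))),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track (%s): %d chromosome(s), %d bp bins, %.4g fragments\n",
              x$condition, length(x$bins), x$bin_bp, x$n_fragments))
  invisible(x)
}

#' Simulation configuration
#'
#' Defaults describe the reference study condition used throughout the test
#' suite: one 2-Mb chromosome, Poisson background of 5 fragments per 50-bp
#' bin, six-fold capture enrichment inside hypermethylated regions, 20
#' planted case-specific, 20 control-specific and 20 commonly methylated
#' regions of 1 kb, and paired fully methylated / unmethylated spike-in
#' fragments on a dedicated contig.
#'
#' @param seed Integer RNG seed; the whole simulation is a deterministic
#'   function of the config.
#' @param genome Named vector of chromosome lengths.
#' @param n_genes,n_mirna Number of gene models and how many of them are
#'   miRNA genes.
#' @param n_cgis Number of CpG islands.
#' @param orphan_fraction Fraction of CGIs placed away from every gene.
#' @param n_planted_case,n_planted_control,n_planted_common Planted region
#'   counts per class.
#' @param planted_length_bp Planted region length (bin-aligned).
#' @param enrichment_factor Coverage multiplier inside hypermethylated
#'   regions (>= 1; 1 gives an exchangeable null).
#' @param background_rate Expected fragments per bin outside planted
#'   regions.
#' @param planted_rate Optional absolute Poisson mean inside planted
#'   regions; defaults to \code{background_rate * enrichment_factor}.
#' @param bin_bp Coverage bin width.
#' @param spike_in Add the spike-in contig and fragments?
#' @param n_spike_pairs Pairs of (methylated, unmethylated) spike fragments.
#' @param spike_length_bp Spike fragment length.
#' @param params \code{\link{annotation_params}} used for the toy bundle.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1, genome = c(chr1 = 2e6), n_genes = 44,
                       n_mirna = 2, n_cgis = 40, orphan_fraction = 0.25,
                       n_planted_case = 20, n_planted_control = 20,
                       n_planted_common = 20, planted_length_bp = 1000,
                       enrichment_factor = 6, background_rate = 5,
                       planted_rate = NULL, bin_bp = 50, spike_in = TRUE,
                       n_spike_pairs = 6, spike_length_bp = 400,
                       params = annotation_params()) {
  .assert_scalar_number(seed, "seed")
  .assert_scalar_number(orphan_fraction, "orphan_fraction", 0, 1)
  .assert_scalar_number(enrichment_factor, "enrichment_factor", 1)
  .assert_scalar_number(background_rate, "background_rate", 0)
  for (nm in c("n_genes", "n_mirna", "n_cgis", "n_planted_case",
               "n_planted_control", "n_planted_common", "n_spike_pairs"))
    .assert_scalar_number(get(nm), nm, 0)
  stopifnot(is.numeric(genome), !is.null(names(genome)), all(genome > 0))
  if ("spike" %in% names(genome))
    stop("'spike' is a reserved contig name")
  structure(list(seed = as.integer(seed), genome = genome,
                 n_genes = n_genes, n_mirna = min(n_mirna, n_genes),
                 n_cgis = n_cgis, orphan_fraction = orphan_fraction,
                 n_planted_case = n_planted_case,
                 n_planted_control = n_planted_control,
                 n_planted_common = n_planted_common,
                 planted_length_bp = planted_length_bp,
                 enrichment_factor = enrichment_factor,
                 background_rate = background_rate,
                 planted_rate = planted_rate, bin_bp = bin_bp,
                 spike_in = isTRUE(spike_in),
                 n_spike_pairs = n_spike_pairs,
                 spike_length_bp = spike_length_bp, params = params),
            class = "sim_config")
}

# full genome incl. spike contig, if enabled
.sim_genome <- function(config) {
  g <- config$genome
  if (config$spike_in && config$n_spike_pairs > 0) {
    slot <- config$spike_length_bp + 600
    g <- c(g, spike = 2 * config$n_spike_pairs * slot + 600)
  }
  g
}

# random partition of `slack` extra bases over k+1 gaps
.gap_slack <- function(slack, k) {
  if (k == 0) return(slack)
  cuts <- sort(runif(k))
  floor(slack * diff(c(0, cuts, 1)))
}

#' Generate a toy annotation bundle
#'
#' Places non-overlapping gene models (with exons and 5' UTRs) separated by
#' wide intergenic gaps, attaches CpG islands to the promoters of a random
#' subset of protein-coding genes, and drops the remaining (orphan) islands
#' into gap interiors far enough from every gene that the orphan
#' classification is true by construction. Deterministic for a fixed config.
#'
#' @param config A \code{\link{sim_config}}.
#' @return An \code{\link{annotation_bundle}}.
#' @export
make_toy_bundle <- function(config) {
  stopifnot(is(config, "sim_config"))
  set.seed(config$seed)
  genome <- .sim_genome(config)
  main <- config$genome
  min_gap <- 12000

  n_prot <- config$n_genes - config$n_mirna
  lens <- c(if (n_prot > 0) sample(6000:12000, n_prot, replace = TRUE),
            if (config$n_mirna > 0)
              sample(600:1200, config$n_mirna, replace = TRUE))
  cat_all <- c(rep("protein_coding", n_prot), rep("miRNA", config$n_mirna))
  if (config$n_genes > 0) {
    ord <- sample(config$n_genes)
    lens <- lens[ord]
    cat_all <- cat_all[ord]
  }

  # distribute genes over chromosomes proportionally to length, then place
  # each chromosome's genes left to right with randomised gaps >= min_gap
  chroms <- names(main)
  alloc <- rep(0L, length(chroms))
  if (config$n_genes > 0) {
    share <- main / sum(main)
    alloc <- as.integer(round(share * config$n_genes))
    while (sum(alloc) < config$n_genes)
      alloc[which.max(main)] <- alloc[which.max(main)] + 1L
    while (sum(alloc) > config$n_genes)
      alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  }
  g_chrom <- character(0); g_start <- numeric(0); g_len <- numeric(0)
  idx <- 1
  for (ci in seq_along(chroms)) {
    k <- alloc[ci]
    if (k == 0) next
    li <- lens[idx:(idx + k - 1)]
    idx <- idx + k
    slack <- main[ci] - sum(li) - (k + 1) * min_gap
    if (slack < 0)
      stop("capacity: chromosome ", chroms[ci],
           " too small for ", k, " gene models", call. = FALSE)
    gaps <- min_gap + .gap_slack(slack, k)
    starts <- cumsum(gaps[seq_len(k)]) + c(0, cumsum(li))[seq_len(k)] + 1
    g_chrom <- c(g_chrom, rep(chroms[ci], k))
    g_start <- c(g_start, starts)
    g_len <- c(g_len, li)
  }
  g_end <- g_start + g_len - 1
  g_strand <- if (config$n_genes > 0)
    sample(c("+", "-"), config$n_genes, replace = TRUE) else character(0)
  gene_id <- sprintf("%s_%03d",
                     ifelse(cat_all == "miRNA", "mir", "gene"),
                     seq_len(max(config$n_genes, 0)))

  genes <- GRanges(g_chrom, IRanges(g_start, g_end), strand = g_strand)
  if (config$n_genes > 0) {
    mcols(genes)$gene_id <- gene_id
    mcols(genes)$category <- cat_all
  } else {
    mcols(genes)$gene_id <- character(0)
    mcols(genes)$category <- character(0)
  }

  # exons: protein genes carry three exons at fixed body fractions (first
  # and last flush with the gene ends, so the TSS is exonic); miRNA genes
  # are single-exon
  exn <- list()
  ut <- list()
  for (i in seq_len(config$n_genes)) {
    L <- g_len[i]; s <- g_start[i]; e <- g_end[i]
    if (cat_all[i] == "miRNA") {
      exn[[length(exn) + 1]] <- data.frame(
        chrom = g_chrom[i], start = s, end = e, gene_id = gene_id[i])
      next
    }
    b <- s + floor(L * c(0.2, 0.4, 0.55, 0.8))
    exn[[length(exn) + 1]] <- data.frame(
      chrom = g_chrom[i],
      start = c(s, b[2], b[4]),
      end = c(b[1] - 1, b[3] - 1, e),
      gene_id = gene_id[i])
    u <- if (g_strand[i] == "+") c(s, s + 199) else c(e - 199, e)
    ut[[length(ut) + 1]] <- data.frame(
      chrom = g_chrom[i], start = u[1], end = u[2],
      strand = g_strand[i], gene_id = gene_id[i])
  }
  exons <- if (length(exn)) {
    ex <- do.call(rbind, exn)
    GRanges(ex$chrom, IRanges(ex$start, ex$end), gene_id = ex$gene_id)
  } else GRanges(gene_id = character(0))
  utr5 <- if (length(ut)) {
    uu <- do.call(rbind, ut)
    GRanges(uu$chrom, IRanges(uu$start, uu$end), strand = uu$strand,
            gene_id = uu$gene_id)
  } else GRanges(gene_id = character(0))

  # CpG islands: gene-associated ones straddle the TSS of distinct
  # protein-coding genes; orphans sit in gap interiors with enough margin
  # that neither the island nor its shores approach any gene
  n_orphan <- round(config$orphan_fraction * config$n_cgis)
  n_assoc <- config$n_cgis - n_orphan
  prot_idx <- which(cat_all == "protein_coding")
  if (n_assoc > length(prot_idx))
    stop("capacity: ", n_assoc, " gene-associated CGIs requested but only ",
         length(prot_idx), " protein-coding genes", call. = FALSE)
  assoc_genes <- if (n_assoc > 0) sample(prot_idx, n_assoc) else integer(0)
  c_chrom <- character(0); c_start <- numeric(0); c_end <- numeric(0)
  for (i in assoc_genes) {
    w <- sample(500:1200, 1)
    tss <- if (g_strand[i] == "+") g_start[i] else g_end[i]
    if (g_strand[i] == "+") {
      c_start <- c(c_start, tss - 200); c_end <- c(c_end, tss - 200 + w - 1)
    } else {
      c_start <- c(c_start, tss + 200 - w + 1); c_end <- c(c_end, tss + 200)
    }
    c_chrom <- c(c_chrom, g_chrom[i])
  }
  # gaps between consecutive genes (and chromosome ends)
  margin <- max(config$params$orphan_association_window,
                config$params$promoter_upstream) +
    config$params$shore_width + 500
  gap_list <- list()
  for (ci in seq_along(chroms)) {
    gi <- which(g_chrom == chroms[ci])
    bounds <- c(0, sort(g_end[gi]), main[ci] + 1)
    starts <- head(bounds, -1) + 1
    ends <- c(if (length(gi)) sort(g_start[gi]) - 1, main[ci])
    usable_s <- starts + margin
    usable_e <- ends - margin
    ok <- usable_e - usable_s + 1 >= 1500
    if (any(ok))
      gap_list[[length(gap_list) + 1]] <- data.frame(
        chrom = chroms[ci], start = usable_s[ok], end = usable_e[ok])
  }
  gaps_df <- if (length(gap_list)) do.call(rbind, gap_list) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  if (n_orphan > 0 && nrow(gaps_df) == 0)
    stop("capacity: not enough intergenic space for ", n_orphan,
         " orphan CGIs", call. = FALSE)
  # several orphans may share a wide gap; rejection sampling keeps them
  # >= 5 kb apart so each island and its shores stay isolated
  o_chrom <- character(0); o_start <- numeric(0); o_end <- numeric(0)
  gap_w <- gaps_df$end - gaps_df$start + 1
  for (i in seq_len(n_orphan)) {
    placed <- FALSE
    for (try in 1:200) {
      g <- sample.int(nrow(gaps_df), 1, prob = gap_w)
      w <- sample(500:1200, 1)
      hi <- gaps_df$end[g] - w + 1
      if (hi < gaps_df$start[g]) next
      s <- if (hi > gaps_df$start[g])
        sample(seq(gaps_df$start[g], hi), 1) else gaps_df$start[g]
      conflict <- o_chrom == gaps_df$chrom[g] &
        s - 5000 <= o_end & s + w - 1 + 5000 >= o_start
      if (any(conflict)) next
      o_chrom <- c(o_chrom, gaps_df$chrom[g])
      o_start <- c(o_start, s); o_end <- c(o_end, s + w - 1)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("capacity: not enough intergenic space for ", n_orphan,
           " orphan CGIs", call. = FALSE)
  }
  c_chrom <- c(c_chrom, o_chrom)
  c_start <- c(c_start, o_start)
  c_end <- c(c_end, o_end)
  cgis <- GRanges(c_chrom, IRanges(c_start, c_end))

  annotation_bundle(genome, genes, cgis, exons = exons, utr5 = utr5,
                    params = config$params)
}

# snap an interval outward/inward to the bin grid
.snap_start <- function(x, bin) floor((x - 1) / bin) * bin + 1
.snap_up <- function(x, bin) ceiling((x - 1) / bin) * bin + 1

# erode every range by m bp on both sides
.erode <- function(gr, m) {
  gr <- gr[width(gr) > 2 * m]
  if (length(gr) == 0) return(gr)
  narrow(gr, start = m + 1, end = -(m + 1))
}

#' Plant hypermethylated regions and simulate two-condition coverage
#'
#' Bin counts are Poisson with the background rate, multiplied by the
#' enrichment factor inside planted regions of the matching condition (both
#' conditions for commonly methylated regions and fully methylated spikes;
#' unmethylated spikes stay at background). Planted regions are bin-aligned
#' and placed inside eroded context masks so their intended context label
#' (promoter_cgi, promoter_nocgi, shore, orphan_cgi, intragenic,
#' intergenic) is recoverable exactly; the truth object records every
#' planted interval with its label.
#'
#' @param bundle An \code{\link{annotation_bundle}} from
#'   \code{\link{make_toy_bundle}}.
#' @param config The same \code{\link{sim_config}}.
#' @return List with elements \code{truth} (class \code{methylome_truth}:
#'   \code{planted_case}, \code{planted_control}, \code{planted_common},
#'   \code{spikes}), \code{case} and \code{control}
#'   (\code{\link{coverage_track}}s).
#' @export
plant_and_simulate <- function(bundle, config) {
  stopifnot(is(config, "sim_config"), is(bundle, "annotation_bundle"))
  set.seed((config$seed %% 1000000L) * 2L + 1L)
  genome <- bundle$genome
  bin <- config$bin_bp
  main <- genome[setdiff(names(genome), "spike")]

  need <- ceiling(config$planted_length_bp / bin) * bin
  labels <- c("promoter_cgi", "promoter_nocgi", "shore", "orphan_cgi",
              "intragenic", "intergenic")

  genesF <- .flat(bundle$genes)
  prom <- bundle$promoters
  tssw <- .flat(.tss_windows(bundle))
  down <- .clip(flank(bundle$genes, bundle$params$downstream_width,
                      start = FALSE), genome)
  cgisF <- .flat(bundle$cgis)
  shoresF <- .flat(bundle$shores)
  assoc <- .flat(.assoc_windows(bundle))
  gene_zone <- .cover(c(genesF, .flat(prom), tssw, .flat(down), .flat(assoc)))

  orphan_cgis <- bundle$cgis[!(overlapsAny(bundle$cgis, genesF,
                                           ignore.strand = TRUE) |
                                 overlapsAny(bundle$cgis, assoc,
                                             ignore.strand = TRUE))]
  prom_has_cgi <- overlapsAny(prom, cgisF, ignore.strand = TRUE)
  cgi_zone <- .cover(c(cgisF, shoresF))
  masks <- list(
    promoter_cgi = .erode(.cover(prom[prom_has_cgi]), 200),
    promoter_nocgi = .erode(.cover(prom[!prom_has_cgi]), 200),
    # shores minus promoter windows: composite labelling resolves these as
    # "shore" whether the island is orphan or promoter-associated
    shore = .erode(setdiff(shoresF, .cover(prom), ignore.strand = TRUE),
                   150),
    orphan_cgi = NULL,  # handled from the island list itself
    intragenic = .erode(setdiff(genesF,
                                .cover(c(.flat(prom), tssw, .flat(down),
                                         cgi_zone)),
                                ignore.strand = TRUE), 200),
    intergenic = .erode(setdiff(.gr(names(main), rep(1, length(main)),
                                    unname(main)),
                                .cover(c(gene_zone, cgi_zone)),
                                ignore.strand = TRUE), 500))

  # reserve the orphan islands that will carry orphan_cgi plants up front,
  # so shore/intergenic plants cannot crowd them out
  labs_case <- rep(labels, length.out = config$n_planted_case)
  labs_ctrl <- rep(labels, length.out = config$n_planted_control)
  n_orphan_needed <- sum(c(labs_case, labs_ctrl) == "orphan_cgi")
  if (n_orphan_needed > length(orphan_cgis))
    stop("capacity: ", n_orphan_needed, " orphan-CGI plants requested but ",
         "only ", length(orphan_cgis), " orphan islands", call. = FALSE)
  reserved_idx <- if (n_orphan_needed > 0)
    sample(length(orphan_cgis), n_orphan_needed) else integer(0)
  reserved_zone <- suppressWarnings(
    .flat(orphan_cgis[reserved_idx]) + 1300)

  used <- .flat(orphan_cgis[0])
  orphan_pool <- orphan_cgis[reserved_idx]
  place_one <- function(label) {
    if (label == "orphan_cgi") {
      ok <- !overlapsAny(orphan_pool, used, ignore.strand = TRUE)
      if (!any(ok))
        stop("capacity: no free orphan CGI left to plant in", call. = FALSE)
      i <- which(ok)[sample(sum(ok), 1)]
      cg <- orphan_pool[i]
      w <- max(width(cg), need)
      s <- .snap_start(start(cg) - floor((w - width(cg)) / 2), bin)
      reg <- GRanges(seqnames(cg), IRanges(s, s + ceiling(w / bin) * bin - 1))
      orphan_pool <<- orphan_pool[-i]
    } else {
      segs <- setdiff(masks[[label]], c(used, reserved_zone),
                      ignore.strand = TRUE)
      starts_by_seg <- lapply(seq_along(segs), function(j) {
        s0 <- .snap_up(start(segs)[j], bin)
        hi <- end(segs)[j] - need + 1
        if (s0 > hi) return(numeric(0))
        seq(s0, hi, by = bin)
      })
      nopt <- lengths(starts_by_seg)
      if (sum(nopt) == 0)
        stop("capacity: no room to plant a ", label, " region",
             call. = FALSE)
      j <- sample(length(segs), 1, prob = nopt)
      s <- starts_by_seg[[j]][sample(nopt[j], 1)]
      reg <- GRanges(seqnames(segs)[j], IRanges(s, s + need - 1))
    }
    used <<- suppressWarnings(c(used, reg + 1000))
    reg
  }
  plant_class <- function(n, labs) {
    if (n == 0)
      return(.set_genome(GRanges(label = character(0)), genome))
    labs <- rep(labs, length.out = n)
    regs <- do.call(c, lapply(labs, place_one))
    mcols(regs)$label <- labs
    .set_genome(sort(regs), genome)
  }
  planted_case <- plant_class(config$n_planted_case, labels)
  planted_control <- plant_class(config$n_planted_control, labels)
  planted_common <- plant_class(config$n_planted_common, "intergenic")
  mcols(planted_common)$label <- NULL

  spikes <- GRanges(methylated = logical(0))
  if (config$spike_in && config$n_spike_pairs > 0) {
    slot <- config$spike_length_bp + 600
    n <- 2 * config$n_spike_pairs
    s <- 600 + (seq_len(n) - 1) * slot + 1
    s <- .snap_up(s, bin)
    w <- ceiling(config$spike_length_bp / bin) * bin
    spikes <- GRanges("spike", IRanges(s, s + w - 1),
                      methylated = seq_len(n) %% 2 == 1)
    spikes <- .set_genome(spikes, genome)
  }

  truth <- structure(list(planted_case = planted_case,
                          planted_control = planted_control,
                          planted_common = planted_common,
                          spikes = spikes, seed = config$seed),
                     class = "methylome_truth")
  stopifnot(!any(overlapsAny(planted_case, planted_control,
                             ignore.strand = TRUE)))

  planted_rate <- if (is.null(config$planted_rate))
    config$background_rate * config$enrichment_factor else
      config$planted_rate
  simulate_track <- function(condition) {
    enriched <- c(.flat(planted_case[0]),
                  if (condition == "case") .flat(planted_case) else
                    .flat(planted_control),
                  .flat(planted_common),
                  .flat(spikes[mcols(spikes)$methylated]))
    bins <- lapply(names(genome), function(ch) {
      nb <- ceiling(unname(genome[ch]) / bin)
      lam <- rep(config$background_rate, nb)
      er <- enriched[as.character(seqnames(enriched)) == ch]
      for (i in seq_along(er)) {
        b0 <- (start(er)[i] - 1) %/% bin + 1
        b1 <- min(ceiling(end(er)[i] / bin), nb)
        lam[b0:b1] <- planted_rate
      }
      rpois(nb, lam)
    })
    names(bins) <- names(genome)
    coverage_track(condition, bins, bin, genome)
  }
  case <- simulate_track("case")
  control <- simulate_track("control")
  list(truth = truth, case = case, control = control)
}

#' @export
print.methylome_truth <- function(x, ...) {
  cat(sprintf(paste0("methylome_truth: %d case-specific, %d control-",
                     "specific, %d common planted regions; %d spikes\n"),
              length(x$planted_case), length(x$planted_control),
              length(x$planted_common), length(x$spikes)))
  invisible(x)
}

#' Write simulation truth as BED
#'
#' Planted intervals with their context label (and class) in the name field,
#' plus spike fragments flagged methylated/unmethylated.
#'
#' @param truth A \code{methylome_truth}.
#' @param path Output BED path.
#' @return Invisibly, the path.
#' @export
write_truth <- function(truth, path) {
  all <- c(truth$planted_case, truth$planted_control, truth$planted_common,
           granges(truth$spikes))
  nm <- c(paste0("case_", mcols(truth$planted_case)$label),
          paste0("control_", mcols(truth$planted_control)$label),
          rep("common", length(truth$planted_common)),
          ifelse(mcols(truth$spikes)$methylated, "spike_methylated",
                 "spike_unmethylated"))
  out <- granges(all)
  mcols(out)$name <- nm
  write_bed(out, path)
}
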