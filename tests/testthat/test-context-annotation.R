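test_that("primary classification follows the TSS > intragenic priority", {
  b <- tiny_bundle()
  regions <- gr1(rep("chr1", 3),
                 c(29501, 26001, 70001),
                 c(29800, 26400, 70500))
  # first region overlaps geneC's TSS window and geneA's body: TSS wins
  expect_equal(classify_primary(regions, b),
               c("TSS", "intragenic", "intergenic"))
  # labels always partition: counts sum to the number of regions
  expect_equal(sum(table(classify_primary(regions, b))), 3)
})

test_that("subcontext labels attach per overlapped feature", {
  b <- tiny_bundle()
  sub <- suppressWarnings(classify_subcontexts(
    gr1(c("chr1", "chr1", "chr15"),
        c(20301, 21201, 89908801),
        c(20600, 21400, 89908900)), b))
  # promoter window and first exon together
  expect_setequal(sub[[1]], c("promoter", "exon"))
  # gene body outside every exon is intron
  expect_equal(sub[[2]], "intron")
  # a region on the miRNA locus carries the miRNA label
  expect_true("miRNA" %in% sub[[3]])
  # no enhancer track: the label is absent and a warning is logged
  expect_warning(classify_subcontexts(gr1("chr1", 1, 100), b), "enhancer")

  with_enh <- annotation_bundle(b$genome, b$genes, b$cgis,
                                exons = b$exons, utr5 = b$utr5,
                                enhancers = gr1("chr1", 70001, 70800))
  sub_e <- classify_subcontexts(gr1("chr1", 70201, 70400), with_enh)
  expect_equal(sub_e[[1]], "enhancer")
})

test_that("CGI feature labels respect the island/shore partition", {
  b <- tiny_bundle()
  regions <- gr1(rep("chr1", 4),
                 c(19201, 18501, 19401, 95001),
                 c(19400, 18700, 19600, 95400))
  # straddling the island edge hits island and shore at once
  expect_equal(classify_cgi_feature(regions, b),
               c("cgi_and_shore", "cgi", "shore", "none"))
})

test_that("orphan islands are those beyond every gene and its window", {
  b <- tiny_bundle()
  status <- classify_orphan(bundle = b)
  # the promoter island is gene-associated; the distant island is orphan
  expect_equal(status[start(b$cgis) == 18401], "gene_associated")
  expect_equal(status[start(b$cgis) == 80001], "orphan")
})

test_that("classifiers agree with brute-force re-evaluation at random", {
  for (seed in c(101, 202)) {
    cfg <- sim_config(seed = seed)
    b <- make_toy_bundle(cfg)
    set.seed(seed + 1)
    n <- 300
    s <- sample(1.9e6, n)
    regions <- gr1("chr1", s, s + sample(100:3000, n, TRUE))
    expect_identical(classify_primary(regions, b),
                     oracle_primary(regions, b))
    expect_identical(classify_cgi_feature(regions, b),
                     oracle_cgi_feature(regions, b))
    expect_identical(classify_orphan(bundle = b), oracle_orphan(b))
  }
})

test_that("gene Venn pools each gene's DMRs before categorising", {
  b <- tiny_bundle()
  # one island-only DMR plus one shore-only DMR, both in geneA's promoter
  two <- gr1(c("chr1", "chr1"), c(18501, 19401), c(18700, 19600))
  v <- gene_venn(two, b)
  expect_equal(v$cgi_and_shore, "geneA")
  expect_length(v$cgi_only, 0)
  expect_length(v$shore_only, 0)
  expect_equal(unname(v$dmr_counts[["cgi_and_shore"]]), 2)

  # a single island-only DMR leaves the gene in the island-only set
  v1 <- gene_venn(two[1], b)
  expect_equal(v1$cgi_only, "geneA")
  expect_equal(unname(v1$dmr_counts[["cgi_only"]]), 1)

  # one straddling DMR hits both features by itself
  v2 <- gene_venn(gr1("chr1", 19201, 19400), b)
  expect_equal(v2$cgi_and_shore, "geneA")
  expect_equal(unname(v2$dmr_counts[["cgi_and_shore"]]), 1)

  # venn gene sets are always pairwise disjoint
  expect_length(intersect(v$cgi_and_shore, v$cgi_only), 0)
})

test_that("promoter split partitions DMRs by promoter CGI content", {
  b <- tiny_bundle()
  dmrs <- gr1(rep("chr1", 3),
              c(18501, 28601, 17951),
              c(18700, 28800, 18100))
  sp <- split_promoters(dmrs, b)
  # DMR 1: geneA's CGI promoter; DMR 2: geneC's CGI-free promoter;
  # DMR 3 straddles geneD (no CGI) and geneA (CGI): the tie goes with-CGI
  expect_equal(sp$with_cgi, 2)
  expect_equal(sp$without_cgi, 1)
  expect_equal(sp$total, 3)
  expect_equal(sp$with_cgi + sp$without_cgi, sp$total)
})

test_that("the TSS metaprofile is strand-oriented and conservative", {
  b <- tiny_bundle()
  # one single-bin peak exactly on the (isolated) TSS of the minus-strand
  # gene: one event in the first downstream bin, zeros elsewhere
  pk <- gr1("chr1", 59951, 60000)
  mp <- tss_metaprofile(pk, b, halfwidth = 5000, bin_bp = 50)
  expect_equal(sum(mp$counts), 1)
  expect_equal(which(mp$counts == 1), 101)
  expect_equal(mp$offset[101], 25)

  # upstream peaks land at negative offsets for minus-strand genes too
  pk_up <- gr1("chr1", 60501, 60550)
  mp_up <- tss_metaprofile(pk_up, b, halfwidth = 5000, bin_bp = 50)
  expect_equal(sum(mp_up$counts), 1)
  expect_lt(mp_up$offset[which(mp_up$counts == 1)], 0)

  # no peaks, no events
  expect_equal(sum(tss_metaprofile(GRanges(), b)$counts), 0)
  expect_error(tss_metaprofile(pk, b, halfwidth = 5000, bin_bp = 70),
               "divide")
})

test_that("category counts survive reflection of the whole genome", {
  cfg <- sim_config(seed = 17)
  b <- make_toy_bundle(cfg)
  set.seed(18)
  n <- 200
  s <- sample(1.9e6, n)
  regions <- gr1("chr1", s, s + sample(100:2000, n, TRUE))
  rb <- reflect_bundle(b)
  rregions <- reflect_gr(regions, b$genome)
  expect_equal(table(classify_primary(regions, b)),
               table(classify_primary(rregions, rb)))
  expect_equal(table(classify_cgi_feature(regions, b)),
               table(classify_cgi_feature(rregions, rb)))
  expect_equal(table(classify_orphan(bundle = b)),
               table(classify_orphan(bundle = rb)))
  expect_equal(table(composite_context(regions, b)),
               table(composite_context(rregions, rb)))
})

test_that("DMR annotation table carries the full hierarchy per region", {
  b <- tiny_bundle()
  regions <- gr1(c("chr1", "chr1"), c(18501, 70001), c(18700, 70500))
  ann <- annotate_dmrs(regions, b)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$primary_context, c("TSS", "intergenic"))
  expect_equal(ann$cgi_feature, c("cgi", "none"))
  expect_match(ann$genes_hit[1], "geneA")
  expect_equal(ann$genes_hit[2], "")
  expect_match(ann$cgis_hit[1], "cgi_")
})
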