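test_that("promoter windows are strand-aware, mirrored, and clipped", {
  genome <- c(chr1 = 100000)
  genes <- gr1(c("chr1", "chr1"), c(1001, 8001), c(5001, 10000),
               strand = c("+", "-"), gene_id = c("gplus", "gminus"))
  prom <- derive_promoters(genes, genome)
  # + gene: TSS at 1001 (0-based 1000); [TSS-2000, TSS+500) clips at the
  # chromosome start -> 0-based [0, 1500)
  expect_equal(start(prom)[1], 1)
  expect_equal(end(prom)[1], 1500)
  # - gene: TSS at 10000; mirrored window is 0-based [9500, 12000)
  expect_equal(start(prom)[2], 9501)
  expect_equal(end(prom)[2], 12000)

  # mirror symmetry: reflecting the genome and flipping strands reflects
  # the promoter
  refl <- reflect_gr(genes, genome)
  prom_r <- derive_promoters(refl, genome)
  back <- reflect_gr(prom_r, genome)
  expect_equal(start(back), start(prom))
  expect_equal(end(back), end(prom))

  # degenerate window: upstream 0, downstream 1 bp is the TSS base itself
  p1 <- derive_promoters(genes, genome,
                         annotation_params(promoter_upstream = 0,
                                           promoter_downstream = 1))
  expect_equal(start(p1), c(1001, 10000))
  expect_equal(end(p1), c(1001, 10000))

  # unstranded genes have no orientation, hence no promoter
  unstr <- gr1("chr1", 1001, 5001, gene_id = "g")
  expect_error(derive_promoters(unstr, genome), "strand")
})

test_that("shore derivation flanks islands, excises islands, clips bounds", {
  genome <- c(chr1 = 1000000)
  # single mid-chromosome island (0-based 10000-10500): two clean 2-kb
  # shores
  sh <- derive_shores(gr1("chr1", 10001, 10500), genome)
  expect_equal(start(sh), c(8001, 10501))
  expect_equal(end(sh), c(10000, 12500))
  expect_true(all(width(sh) == 2000))

  # island at the chromosome start (0-based 0-300): left shore empty
  sh <- derive_shores(gr1("chr1", 1, 300), genome)
  expect_equal(start(sh), 301)
  expect_equal(end(sh), 2300)

  # neighbouring island bases are excised from the shore of another island
  sh <- derive_shores(gr1(c("chr1", "chr1"), c(10001, 11001),
                          c(10500, 11400)), genome)
  mask <- base_mask(sh, "chr1", 20000)
  oracle <- oracle_shore_mask(c(10001, 11001), c(10500, 11400), 20000)
  expect_identical(mask, oracle)

  # empty island list is a valid (empty) shore set
  expect_length(derive_shores(GRanges(), genome), 0)
})

test_that("random shore sets agree base-by-base with the flank definition", {
  for (seed in 1:5) {
    set.seed(seed)
    L <- 200000
    n <- 30
    s <- sort(sample(L - 3000, n))
    e <- pmin(s + sample(200:1500, n, replace = TRUE), L)
    genome <- c(chrZ = L)
    sh <- derive_shores(gr1("chrZ", s, e), genome)
    expect_identical(base_mask(sh, "chrZ", L), oracle_shore_mask(s, e, L))
    # shores never intersect islands
    ov <- intersect(sh, reduce(gr1("chrZ", s, e)), ignore.strand = TRUE)
    expect_equal(sum(width(ov)), 0)
  }
})

test_that("BED round trip preserves coordinates exactly", {
  set.seed(42)
  genome <- c(chr1 = 50000, chr2 = 30000)
  s <- sample(49000, 50)
  gr <- gr1(sample(c("chr1", "chr2"), 50, TRUE, prob = c(0.6, 0.4)),
            pmin(s, 29000), pmin(s, 29000) + sample(100:900, 50, TRUE),
            strand = sample(c("+", "-", "*"), 50, TRUE))
  mcols(gr)$name <- sprintf("iv_%02d", 1:50)
  path <- tempfile(fileext = ".bed")
  write_bed(gr, path)
  back <- read_bed(path, genome)
  expect_equal(as.character(seqnames(back)), as.character(seqnames(gr)))
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(as.character(strand(back)), as.character(strand(gr)))
  expect_equal(mcols(back)$name, mcols(gr)$name)
})

test_that("malformed BED rows are rejected with their row number", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tok", "chr1\t500\t400\tbad"), path)
  expect_error(read_bed(path), "row 2")
  writeLines(c("chr1\t100\t200", "chr1\t900\t1200"), path)
  expect_error(read_bed(path, genome = c(chr1 = 1000)), "row 2")
  writeLines("chrX\t100\t200", path)
  expect_error(read_bed(path, genome = c(chr1 = 1000)), "chrX")
})

test_that("refFlat gene tables parse with exons, UTR and TSS intact", {
  path <- tempfile(fileext = ".txt")
  # +: tx 1000-9000, CDS 1500-8500, exons [1000,2000) [4000,9000)
  # -: tx 20000-30000, CDS 21000-29000, single exon
  writeLines(c(
    paste("GENEP", "NM_1", "chr1", "+", 1000, 9000, 1500, 8500, 2,
          "1000,4000,", "2000,9000,", sep = "\t"),
    paste("GENEM", "NM_2", "chr1", "-", 20000, 30000, 21000, 29000, 1,
          "20000,", "30000,", sep = "\t")), path)
  g <- capdmr:::.read_refflat(path, c(chr1 = 50000))
  expect_equal(mcols(g$genes)$gene_id, c("GENEP", "GENEM"))
  expect_equal(gene_tss(g$genes), c(1001, 30000))
  expect_equal(start(g$exons), c(1001, 4001, 20001))
  expect_equal(end(g$exons), c(2000, 9000, 30000))
  # 5' UTR: before the CDS on the sense strand
  expect_equal(start(g$utr5), c(1001, 29001))
  expect_equal(end(g$utr5), c(1500, 30000))

  bundle <- annotation_bundle(c(chr1 = 50000), g$genes,
                              gr1("chr1", 40001, 40400),
                              exons = g$exons, utr5 = g$utr5)
  expect_s3_class(bundle, "annotation_bundle")
})

test_that("bundle assembly merges islands and enforces its invariants", {
  genome <- c(chr1 = 100000)
  genes <- gr1("chr1", 20001, 30000, strand = "+", gene_id = "g1")
  # overlapping + bookended islands merge into one before shores derive
  cgis <- gr1(c("chr1", "chr1", "chr1"), c(40001, 40301, 40501),
              c(40400, 40500, 40900))
  b <- annotation_bundle(genome, genes, cgis)
  expect_length(b$cgis, 1)
  expect_equal(start(b$cgis), 40001)
  expect_equal(end(b$cgis), 40900)
  ov <- intersect(b$shores, capdmr:::.flat(b$cgis), ignore.strand = TRUE)
  expect_equal(sum(width(ov)), 0)

  # exons must sit inside their gene body
  bad_ex <- gr1("chr1", 19001, 21000, gene_id = "g1")
  expect_error(annotation_bundle(genome, genes, cgis, exons = bad_ex),
               "exon")
  # intervals beyond the chromosome are rejected
  expect_error(annotation_bundle(genome, genes,
                                 gr1("chr1", 99901, 100200)),
               "beyond")
})
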