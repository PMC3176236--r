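# Annotation IO, validation and circular spacers.

test_that("the printed annotation table parses into a consistent 37-gene genome", {
  ann <- read_fixture()
  expect_s3_class(ann, "mito_annotation")
  expect_equal(nrow(ann$genes), 37L)
  expect_equal(ann$genome_length, 14491L)
  cls <- table(ann$genes$gene_class)
  expect_equal(as.integer(cls[c("PCG", "tRNA", "rRNA")]), c(13L, 22L, 2L))
  expect_equal(sum(ann$genes$strand == "N"), 8L)
  expect_equal(ann$genes$label[ann$genes$name == "trnL-uaa"], "trnL2")
  expect_equal(ann$genes$label[ann$genes$name == "trnS-gcu"], "trnS1")
})

test_that("single-row tables, degenerate tables and bad cells behave as specified", {
  one <- read_annotation_tsv(paste(
    "gene\tstart\tend\tstrand\tstart_codon\tstop_codon\tsize\tintergenic",
    "cox1\t1\t1532\t+\tATG\tTA(A)\t1532\t0", sep = "\n"))
  expect_equal(nrow(one$genes), 1L)
  expect_equal(one$genome_length, 1532L)
  expect_equal(one$genes$gene_class, "PCG")

  hdr <- "gene\tstart\tend\tstrand\tstart_codon\tstop_codon\tsize\tintergenic"
  expect_error(read_annotation_tsv(paste0(hdr, "\n")), "no genes")
  expect_error(read_annotation_tsv(paste(
    hdr, "cox1\t1\t1532\t+\t\t\t1532\t0", "cox1\t2000\t2100\t+\t\t\t101\t0",
    sep = "\n")), "duplicate")
  expect_error(read_annotation_tsv(paste(
    hdr, "mystery9\t1\t100\t+\t\t\t100\t0", sep = "\n")), "unknown gene label")
  expect_error(read_annotation_tsv(paste(
    hdr, "cox1\t500\t100\t+\t\t\t100\t0", sep = "\n")), "start > end")
  expect_error(read_annotation_tsv(paste(
    hdr, "cox1\t1x\t100\t+\t\t\t100\t0", sep = "\n")), "unparseable")
})

test_that("write_annotation_tsv round-trips the printed table cell-identically", {
  lines_in <- readLines(fixture_path())
  ann <- read_fixture()
  lines_out <- write_annotation_tsv(ann)
  expect_identical(lines_out, lines_in)
})

test_that("circular spacers reproduce the intergenic column and find the control region", {
  ann <- read_fixture()
  sp <- compute_spacers(ann)
  expect_equal(nrow(sp), 37L)
  # largest spacer is the 993-nt A+T-rich region between nad6 and cob
  i <- which.max(sp$gap)
  expect_equal(sp$gene[i], "nad6")
  expect_equal(sp$next_gene[i], "cob")
  expect_equal(sp$gap[i], 993L)
  # every non-wrap row matches the declared intergenic cell
  decl <- ann$genes$declared_intergenic[match(sp$gene, ann$genes$name)]
  expect_equal(sp$gap[-37], decl[-37])
  # the wrap cell disagrees by the documented 1-vs-0 convention gap
  expect_equal(sp$gap[37], 0L)
  expect_equal(decl[37], 1L)
  # trnD -> atp8 gap of 1, abutting genes gap 0
  expect_equal(sp$gap[sp$gene == "trnD-uau"], 1L)
  expect_equal(sp$gap[sp$gene == "cox1"], 0L)
})

test_that("gene sizes plus positive gaps minus overlaps tile the circle", {
  tile_sum <- function(ann) {
    sp <- compute_spacers(ann)
    sum(ann$genes$end - ann$genes$start + 1L) + sum(sp$gap[sp$gap > 0]) +
      sum(sp$gap[sp$gap < 0])
  }
  expect_equal(tile_sum(read_fixture()), 14491L)
  for (seed in 1:3) {
    g <- emit_genome(genome_spec(seed = seed))
    expect_equal(tile_sum(g$annotation), g$annotation$genome_length)
  }
})

test_that("validation flags size, spacer, class and completeness violations", {
  ann <- read_fixture()
  v <- validate_annotation(ann)
  # the only inconsistencies in the printed table sit in the trnC row
  expect_true(all(v$gene == "trnC-gca"))
  expect_setequal(v$type, c("size_mismatch", "wrap_intergenic_mismatch"))
  # all other 36 rows have declared size == end - start + 1
  g <- ann$genes[ann$genes$name != "trnC-gca", ]
  expect_equal(g$declared_size, g$end - g$start + 1L)

  # off-by-one size
  one <- read_annotation_tsv(paste(
    "gene\tstart\tend\tstrand\tstart_codon\tstop_codon\tsize\tintergenic",
    "cox1\t1\t1532\t+\tATG\tTAA\t1531\t0", sep = "\n"))
  expect_equal(validate_annotation(one)$type, "size_mismatch")

  # completeness: drop trnK but declare complete
  g2 <- ann$genes[ann$genes$label != "trnK", ]
  ann2 <- mito_annotation(g2, genome_length = 14491, complete = TRUE)
  v2 <- validate_annotation(ann2)
  expect_true(any(v2$type == "missing_gene" & v2$gene == "trnK"))
  missing <- setdiff(mito_gene_labels(), g2$label)   # oracle: set difference
  expect_setequal(v2$gene[v2$type == "missing_gene"], missing)
})

test_that("GenBank-style features map locations, strands and product synonyms", {
  gb <- paste(
    "LOCUS       TEST14491  14491 bp  DNA  circular  INV",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..1532",
    "                     /gene=\"COX1\"",
    "     tRNA            complement(4434..4489)",
    "                     /product=\"tRNA-Phe\"",
    "     rRNA            10445..11134",
    "                     /product=\"12S ribosomal RNA\"",
    "     tRNA            12196..12250",
    "                     /product=\"tRNA-Leu(UUR)\"",
    "//", sep = "\n")
  ann <- read_genbank_lite(gb)
  expect_equal(ann$genome_length, 14491L)
  expect_true(ann$circular)
  g <- ann$genes
  expect_equal(g$label[g$start == 1], "cox1")
  expect_equal(g$strand[g$label == "cox1"], "J")
  expect_equal(g$label[g$start == 4434], "trnF")
  expect_equal(g$strand[g$label == "trnF"], "N")
  expect_equal(g$label[g$start == 10445], "rrnS")
  expect_equal(g$label[g$start == 12196], "trnL2")

  # unmappable products are skipped with a warning, not fatal
  gb2 <- paste(
    "LOCUS       T2  100 bp  DNA  linear",
    "FEATURES             Location/Qualifiers",
    "     tRNA            1..60",
    "                     /product=\"completely unknown RNA\"",
    "//", sep = "\n")
  expect_warning(ann2 <- read_genbank_lite(gb2), "cannot map")
  expect_equal(nrow(ann2$genes), 0L)

  # zero features is a valid (empty) annotation
  ann3 <- read_genbank_lite("LOCUS       T3  100 bp  DNA  linear\n//")
  expect_equal(nrow(ann3$genes), 0L)
  expect_equal(ann3$genome_length, 100L)
})
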