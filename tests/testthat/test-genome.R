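test_that("read_fasta parses records in order, uppercases, records lengths", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chr some description", "acgt", ">p1", "AATTGG"), fa)
  asm <- read_fasta(fa)
  expect_s3_class(asm, "genome_assembly")
  expect_identical(replicon_names(asm), c("chr", "p1"))
  expect_identical(unname(replicon_lengths(asm)), c(4L, 6L))
  expect_identical(asm$seq[["chr"]], "ACGT")
})

test_that("read_fasta rejects empty files and duplicate names", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), fa)
  expect_error(read_fasta(fa), "no records")
  writeLines(c(">chr", "ACGT", ">chr", "GGCC"), fa)
  expect_error(read_fasta(fa), "unique")
})

test_that("FASTA round trip preserves the assembly", {
  asm <- genome_assembly(c(chr = "ACGTNACGT", p1 = "TTTTAAAA"),
                         circular = c(TRUE, FALSE))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(asm, fa)
  back <- read_fasta(fa, circular = c(TRUE, FALSE))
  expect_identical(back$seq, asm$seq)
  expect_identical(back$circular, asm$circular)
})

test_that("annotation I/O converts GFF3 to 0-based half-open and back", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1;tu_id=TU1;is_is=false",
               "chr\tsrc\tgene\t21\t40\t.\t-\t.\tID=g2;tu_id=NA;is_is=true"),
             gff)
  ann <- read_annotations(gff, "gff3")
  expect_identical(ann$start, c(0L, 20L))   # 1-based inclusive -> 0-based
  expect_identical(ann$end, c(10L, 40L))
  expect_true(is.na(ann$tu_id[2]))
  expect_identical(ann$is_insertion_sequence, c(FALSE, TRUE))

  out <- withr::local_tempfile(fileext = ".gff3")
  write_annotations(ann, out, "gff3")
  back <- read_annotations(out, "gff3")
  expect_identical(back[names(ann)], ann[names(ann)])
})

test_that("BED6 annotations keep 0-based half-open coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr\t0\t10\tgeneA\t0\t+", bed)
  ann <- read_annotations(bed, "bed6")
  expect_identical(ann$start, 0L)
  expect_identical(ann$end, 10L)
  expect_identical(ann$gene_id, "geneA")
})

test_that("annotations beyond the replicon are rejected", {
  asm <- genome_assembly(c(chr = strrep("A", 100)))
  ann <- gene_annotations("g1", "chr", 90, 120)
  expect_error(validate_annotations(ann, asm), "beyond")
  expect_error(gene_annotations("g1", "chr", 10, 10), "start >= end")
})

test_that("normalize merges overlapping and bookended intervals", {
  expect_identical(
    normalize_intervals(interval_set("chr", c(0, 50), c(100, 150))),
    interval_set("chr", 0, 150))
  expect_identical(
    normalize_intervals(interval_set("chr", c(0, 100), c(100, 150))),
    interval_set("chr", 0, 150))
  disjoint <- interval_set("chr", c(0, 200), c(100, 300))
  expect_identical(normalize_intervals(disjoint), disjoint)
})

test_that("normalize is idempotent and never increases total length", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample.int(30, 1)
    s <- sample.int(5000, n)
    x <- interval_set(sample(c("chr", "p1"), n, TRUE), s,
                      s + sample.int(500, n))
    nx <- normalize_intervals(x)
    expect_identical(normalize_intervals(nx), nx)
    expect_lte(total_length(nx), sum(x$end - x$start))
    # total covered length is invariant under re-normalization
    expect_identical(total_length(nx), total_length(x))
  }
})

test_that("BED3 and bedGraph round trips reproduce identical objects", {
  x <- normalize_intervals(
    interval_set(c("chr", "chr", "p1"), c(0, 500, 10), c(100, 900, 50)))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed3(x, bed)
  expect_identical(read_bed3(bed), x)

  tr <- binned_track(list(chr = c(5, 0, 12), p1 = c(3, 7)),
                     bin_width = 100, lengths = c(chr = 250, p1 = 180),
                     total_count = 40, sample_id = "ip_rep1")
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph_track(tr, bg)
  back <- read_bedgraph_track(bg, bin_width = 100)
  expect_equal(back$counts, tr$counts)
  expect_identical(back$lengths, tr$lengths)
  expect_identical(back$total_count, tr$total_count)
  expect_identical(back$sample_id, tr$sample_id)
})

test_that("interval algebra: intersection, difference, complement, jaccard", {
  a <- interval_set("chr", c(100, 600), c(500, 700))
  b <- interval_set("chr", 300, 700)
  expect_identical(intersect_intervals(a, b),
                   interval_set("chr", c(300, 600), c(500, 700)))
  expect_identical(setdiff_intervals(a, b), interval_set("chr", 100, 300))
  asm <- genome_assembly(c(chr = strrep("A", 1000)))
  expect_identical(complement_intervals(interval_set("chr", 200, 800), asm),
                   interval_set("chr", c(0, 800), c(200, 1000)))
  expect_equal(interval_jaccard(interval_set("chr", 0, 100),
                                interval_set("chr", 50, 150)), 1 / 3)
  expect_equal(interval_jaccard(interval_set(), interval_set()), 1)
})
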