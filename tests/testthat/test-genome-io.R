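write_bed12_lines <- function(path, rows) {
  writeLines(vapply(rows, function(r) paste(r, collapse = "\t"),
                    character(1)), path)
}

test_that("BED12 coordinates map to the internal convention", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed12_lines(path, list(
    c("chrS", 1000, 5000, "geneA", 0, "+", 1000, 5000, "0,0,0", 1, 4000, 0),
    c("chrS", 9000, 13000, "geneB", 0, "-", 9000, 13000, "0,0,0", 1, 4000, 0)
  ))
  g <- read_gene_models(path, "bed12")
  expect_s3_class(g, "gene_models")
  expect_equal(g$start[g$gene_id == "geneA"], 1000)
  expect_equal(g$tss[g$gene_id == "geneA"], 1000)
  expect_equal(g$tes[g$gene_id == "geneA"], 4999)
  # strand symmetry: same interval on - strand
  expect_equal(g$tss[g$gene_id == "geneB"], 12999)
  expect_equal(g$tes[g$gene_id == "geneB"], 9000)
})

test_that("duplicate gene ids in BED are rejected", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed12_lines(path, list(
    c("chrS", 1000, 5000, "geneA", 0, "+", 1000, 5000, "0,0,0", 1, 4000, 0),
    c("chrS", 9000, 13000, "geneA", 0, "-", 9000, 13000, "0,0,0", 1, 4000, 0)
  ))
  expect_error(read_gene_models(path, "bed12"), "duplicate")
})

test_that("GTF mode unions exon spans per gene", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chrS", "test", "exon", 1001, 1500, ".", "+", ".",
          'gene_id "gA"; gene_biotype "protein_coding";', sep = "\t"),
    paste("chrS", "test", "exon", 4001, 6000, ".", "+", ".",
          'gene_id "gA"; gene_biotype "protein_coding";', sep = "\t"),
    paste("chrS", "test", "exon", 8001, 9000, ".", "-", ".",
          'gene_id "gB"; gene_biotype "lincRNA";', sep = "\t")
  ), path)
  g <- read_gene_models(path, "gtf")
  expect_equal(g$start[g$gene_id == "gA"], 1000)  # back to 0-based
  expect_equal(g$end[g$gene_id == "gA"], 6000)
  expect_equal(g$tss[g$gene_id == "gB"], 8999)
  expect_equal(g$biotype, c("protein_coding", "lincRNA"))
})

test_that("bedGraph intervals expand per base with zeros elsewhere", {
  plus <- withr::local_tempfile(fileext = ".bedgraph")
  minus <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chrS\t0\t3\t2", plus)
  writeLines(character(0), minus)
  tr <- read_bedgraph(plus, minus, contig_length = 10)
  expect_equal(as.numeric(tr$counts[["+"]]), c(2, 2, 2, rep(0, 7)))
  expect_equal(as.numeric(tr$counts[["-"]]), rep(0, 10))
  expect_equal(tr$library_size, 6)
})

test_that("an empty bedGraph pair is an all-zero track", {
  plus <- withr::local_tempfile(fileext = ".bedgraph")
  minus <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(character(0), plus); writeLines(character(0), minus)
  tr <- read_bedgraph(plus, minus, contig_length = 50)
  expect_equal(tr$library_size, 0)
  expect_equal(sum(tr$counts[["+"]] != 0), 0)
})

test_that("negative values and overlapping intervals are format errors", {
  plus <- withr::local_tempfile(fileext = ".bedgraph")
  minus <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(character(0), minus)
  writeLines("chrS\t0\t3\t-1", plus)
  expect_error(read_bedgraph(plus, minus), "negative")
  writeLines(c("chrS\t0\t5\t2", "chrS\t3\t8\t4"), plus)
  expect_error(read_bedgraph(plus, minus), "overlap")
})

test_that("bedGraph writing run-length encodes and omits zero runs", {
  tr <- make_track(plus = c(0, 5, 5, 0), minus = c(1, 1, 2, 0))
  dir <- withr::local_tempdir()
  paths <- write_bedgraph(tr, dir)
  expect_equal(readLines(paths[["plus"]]), "chrS\t1\t3\t5")
  expect_equal(readLines(paths[["minus"]]), c("chrS\t0\t2\t1", "chrS\t2\t3\t2"))
  # all-zero strand -> empty data section
  tr0 <- make_track(plus = numeric(4), minus = numeric(4))
  p0 <- write_bedgraph(tr0, dir)
  expect_equal(length(readLines(p0[["plus"]])), 0)
})

test_that("tracks round-trip exactly through bedGraph", {
  set.seed(42)
  tr <- make_track(plus = rpois(400, 0.7), minus = rpois(400, 1.3),
                   sample_id = "rt", spike_count = 123)
  dir <- withr::local_tempdir()
  write_bedgraph(tr, dir)
  back <- read_bedgraph(file.path(dir, "rt.plus.bedgraph"),
                        file.path(dir, "rt.minus.bedgraph"),
                        meta = list(sample_id = "rt", spike_count = 123),
                        contig_length = 400)
  expect_equal(as.numeric(back$counts[["+"]]), as.numeric(tr$counts[["+"]]))
  expect_equal(as.numeric(back$counts[["-"]]), as.numeric(tr$counts[["-"]]))
  expect_equal(back$library_size, tr$library_size)
})

test_that("fixtures round-trip and have stable checksums", {
  cfg <- sim_config(n_genes = 3, gene_length_range = c(4e3, 8e3),
                    intergenic_gap = 2e3, dispersion = 0.15, seed = 21,
                    timepoints_triptolide = c(0, 5), replicates = 1)
  sim <- simulate_genome(cfg)
  tracks <- simulate_triptolide_timecourse(sim$genes, sim$truth, cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(d1, sim$genes, sim$truth, tracks)
  write_fixture(d2, sim$genes, sim$truth, tracks)
  sums <- function(d) unname(tools::md5sum(sort(list.files(d, full.names = TRUE))))
  expect_identical(sums(d1), sums(d2))

  fx <- read_fixture(d1)
  expect_equal(fx$genes$gene_id, sim$genes$gene_id)
  expect_equal(fx$genes$tss, sim$genes$tss)
  expect_equal(fx$truth$half_life_min, sim$truth$half_life_min)
  for (id in names(tracks)) {
    got <- fx$tracks[[id]]$counts[["+"]]
    expect_equal(as.numeric(got),
                 as.numeric(S4Vectors::window(tracks[[id]]$counts[["+"]],
                                              1, length(got))))
    expect_equal(fx$tracks[[id]]$spike_count, tracks[[id]]$spike_count)
    expect_equal(fx$tracks[[id]]$library_size, tracks[[id]]$library_size)
  }

  # empty track list -> sample sheet with header only
  d3 <- withr::local_tempdir()
  write_fixture(d3, sim$genes, sim$truth, list())
  sheet <- read_sample_sheet(file.path(d3, "samples.tsv"))
  expect_equal(nrow(sheet), 0)
})
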