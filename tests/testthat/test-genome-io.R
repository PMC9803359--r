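test_that("FASTA reading normalises case, preserves order, flags ambiguity codes", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgt", ">chr2", "GGGG", ">chr3", "AARYKMTT"), fa)
  expect_message(g <- read_genome_fasta(fa), "ambiguity")
  expect_equal(names(g), c("chr1", "chr2", "chr3"))
  expect_equal(as.character(g[["chr1"]]), "ACGT")
  expect_equal(as.character(g[["chr3"]]), "AARYKMTT")

  fa2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">dup", "ACGT", ">dup", "TTTT"), fa2)
  expect_error(read_genome_fasta(fa2), "duplicate")

  fa3 <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), fa3)
  expect_error(suppressWarnings(read_genome_fasta(fa3)))
})

test_that("U in FASTA input is stored as T internally", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">rna", "ACGU"), fa)
  g <- read_genome_fasta(fa)
  expect_equal(as.character(g[["rna"]]), "ACGT")
})

test_that("strand-aware sequence lookup reverse-complements minus-strand queries", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AACCGGTT"))
  expect_equal(genome_seq(g, "chr1", 0, 4, "+"), "AACC")
  expect_equal(genome_seq(g, "chr1", 0, 4, "-"), "GGTT")
  expect_error(genome_seq(g, "chr1", 0, 9), "bounds")
  expect_error(genome_seq(g, "chrX", 0, 4), "not in genome")
})

test_that("GTF coordinates convert from 1-based inclusive to 0-based half-open", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", 1, 100, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", "src", "exon", 201, 300, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", "src", "exon", 1, 100, ".", "-", ".",
          'gene_id "g2"; transcript_id "t2";', sep = "\t"),
    paste("chr1", "src", "exon", 201, 300, ".", "-", ".",
          'gene_id "g2"; transcript_id "t2";', sep = "\t")
  ), gtf)
  ex <- read_annotation(gtf)
  t1 <- ex[ex$transcript_id == "t1", ]
  expect_equal(t1$start, c(0L, 200L))
  expect_equal(t1$end, c(100L, 300L))
  t2 <- ex[ex$transcript_id == "t2", ]
  expect_equal(t2$start, c(0L, 200L))  # identical stored intervals
  expect_equal(unique(t2$strand), "-")
})

test_that("GFF3 mRNA/exon hierarchies group transcripts under their genes", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t1000\t.\t+\t.\tID=geneX",
    "chr1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=mX.1;Parent=geneX",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=mX.1",
    "chr1\tsrc\texon\t201\t500\t.\t+\t.\tParent=mX.1",
    "chr1\tsrc\tmRNA\t1\t1000\t.\t+\t.\tID=mX.2;Parent=geneX",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=mX.2",
    "chr1\tsrc\texon\t301\t1000\t.\t+\t.\tParent=mX.2",
    "chr1\tsrc\tgene\t2001\t3000\t.\t-\t.\tID=geneY",
    "chr1\tsrc\tmRNA\t2001\t3000\t.\t-\t.\tID=mY.1;Parent=geneY",
    "chr1\tsrc\texon\t2001\t2400\t.\t-\t.\tParent=mY.1",
    "chr1\tsrc\texon\t2601\t3000\t.\t-\t.\tParent=mY.1"
  ), gff)
  ex <- read_annotation(gff)
  expect_setequal(unique(ex$transcript_id), c("mX.1", "mX.2", "mY.1"))
  expect_equal(unique(ex$gene_id[ex$transcript_id %in% c("mX.1", "mX.2")]),
               "geneX")
  expect_equal(unique(ex$gene_id[ex$transcript_id == "mY.1"]), "geneY")
  expect_equal(ex$start[ex$transcript_id == "mX.2"], c(0L, 300L))
})

test_that("mixed-strand transcripts are rejected", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "s", "exon", 1, 100, ".", "+", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t"),
    paste("chr1", "s", "exon", 201, 300, ".", "-", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t")
  ), gtf)
  expect_error(read_annotation(gtf), "strand")
})

test_that("introns derive from exon gaps with strand-correct junctions", {
  ex <- tibble(transcript_id = "t", gene_id = "g", chrom = "c", strand = "+",
               start = c(0L, 200L), end = c(100L, 300L))
  i <- extract_introns(ex)
  expect_equal(i$start, 100L)
  expect_equal(i$end, 200L)
  expect_equal(i$donor_pos, 100L)
  expect_equal(i$acceptor_pos, 199L)

  ex$strand <- "-"
  i2 <- extract_introns(ex)
  expect_equal(i2$donor_pos, 199L)
  expect_equal(i2$acceptor_pos, 100L)
})

test_that("intron deduplication collapses transcript-shared junctions", {
  ex <- bind_rows(
    tibble(transcript_id = "t1", gene_id = "g", chrom = "c", strand = "+",
           start = c(0L, 200L), end = c(100L, 300L)),
    tibble(transcript_id = "t2", gene_id = "g", chrom = "c", strand = "+",
           start = c(0L, 200L), end = c(100L, 350L))
  )
  expect_equal(nrow(extract_introns(ex, dedup = TRUE)), 1L)
  expect_equal(extract_introns(ex, dedup = TRUE)$n_transcripts, 2L)
  expect_equal(nrow(extract_introns(ex, dedup = FALSE)), 2L)
})

test_that("donor and acceptor windows carry the expected junction contexts", {
  fx <- make_fixture_genome()
  introns <- extract_introns(fx$exons)
  w5 <- suppressMessages(extract_windows(introns, fx$genome, "five_prime"))
  # exon ends ...TC | intron starts GTGAG: the near-constitutive UC//GUGAG
  a5 <- w5$seq[w5$strand == "+"]
  expect_equal(substr(a5, 2, 8), "UCGUGAG")
  # minus-strand twin gives the identical transcription-sense window
  b5 <- w5$seq[w5$strand == "-"]
  expect_equal(b5, a5)

  w3 <- suppressMessages(extract_windows(introns, fx$genome, "three_prime"))
  a3 <- w3$seq[w3$strand == "+"]
  # intron ends ...TAG | exon starts CA: UAG\CA acceptor context
  expect_equal(substr(a3, 3, 7), "UAGCA")
  expect_equal(w3$seq[w3$strand == "-"], a3)
})

test_that("windows running off chromosome ends are discarded, not padded", {
  g <- Biostrings::DNAStringSet(c(tiny = "AAGTAAGTTTTTTTTTTTTTTTTAGCC"))
  introns <- tibble(chrom = "tiny", strand = "+", start = 2L, end = 25L,
                    donor_pos = 2L, acceptor_pos = 24L, gene_id = "g")
  expect_message(w <- extract_windows(introns, g, "five_prime"), "discarded")
  expect_equal(nrow(w), 0L)
})

test_that("non-GU donors are retained and counted, never dropped", {
  g <- Biostrings::DNAStringSet(c(c1 = paste0(strrep("C", 10), "ATATAT",
                                              strrep("T", 14), "AGGG")))
  introns <- tibble(chrom = "c1", strand = "+", start = 10L, end = 32L,
                    donor_pos = 10L, acceptor_pos = 31L, gene_id = "g")
  expect_message(w <- extract_windows(introns, g, "five_prime"), "non-GU")
  expect_equal(nrow(w), 1L)
  expect_equal(substr(w$seq, 4, 5), "AU")
})

test_that("window tables round-trip through TSV", {
  fx <- make_fixture_genome()
  w <- suppressMessages(
    extract_windows(extract_introns(fx$exons), fx$genome, "five_prime"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_windows_tsv(w, tsv)
  w2 <- read_windows_tsv(tsv)
  cols <- c("chrom", "strand", "junction_pos", "site_kind", "seq")
  expect_equal(as.data.frame(w[cols]), as.data.frame(w2[cols]))
})

test_that("reverse-complementing the genome and flipping strands leaves windows unchanged", {
  fx <- make_fixture_genome()
  w1 <- suppressMessages(
    extract_windows(extract_introns(fx$exons), fx$genome, "five_prime"))
  fl <- flip_fixture(fx$genome, fx$exons)
  w2 <- suppressMessages(
    extract_windows(extract_introns(fl$exons), fl$genome, "five_prime"))
  expect_setequal(w1$seq, w2$seq)
  w3a <- suppressMessages(
    extract_windows(extract_introns(fx$exons), fx$genome, "three_prime"))
  w3b <- suppressMessages(
    extract_windows(extract_introns(fl$exons), fl$genome, "three_prime"))
  expect_setequal(w3a$seq, w3b$seq)
})
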