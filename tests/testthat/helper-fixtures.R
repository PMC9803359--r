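# Fixture builders shared across the suite. Everything is generated in code;
# no binary or downloaded data.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# A tiny two-gene genome whose donor and acceptor contexts are known by
# construction. Gene A (+ strand) carries the near-constitutive donor
# UC//GUGAG and a UAG|CA acceptor; gene B is its reverse-complement twin on
# the minus strand of a second chromosome.
make_fixture_genome <- function() {
  # exon1 = 20 nt ending ...TC ; intron = 30 nt GTGAG...TTTTAG ; exon2 = CA...
  exon1 <- "GGATCCGGATCCGGATCCTC"
  intron <- "GTGAGCCCCCCCCCCCCCCCCCCTTTTTAG"
  exon2 <- "CATGGATCCGGATCCGGATC"
  gene <- paste0(exon1, intron, exon2)
  plus <- Biostrings::DNAStringSet(gene)
  names(plus) <- "chrA"
  minus <- Biostrings::DNAStringSet(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(gene))))
  names(minus) <- "chrB"
  genome <- c(plus, minus)
  n <- nchar(gene)
  exons <- bind_rows(
    tibble(transcript_id = "tA.1", gene_id = "geneA", chrom = "chrA",
           strand = "+", start = c(0L, 50L), end = c(20L, 70L)),
    tibble(transcript_id = "tB.1", gene_id = "geneB", chrom = "chrB",
           strand = "-",
           start = c(n - 70L, n - 20L), end = c(n - 50L, n)) |>
      arrange(start)
  )
  list(genome = genome, exons = exons)
}

# Exon chains containing one planted event of each analysed type.
make_event_exons <- function(strand = "+") {
  bind_rows(
    # A5: donors 100 / 120, shared acceptor 200
    tibble(transcript_id = "T1", gene_id = "G1", chrom = "c", strand = strand,
           start = c(0L, 200L), end = c(100L, 300L)),
    tibble(transcript_id = "T2", gene_id = "G1", chrom = "c", strand = strand,
           start = c(0L, 200L), end = c(120L, 300L)),
    # RI: intron [100, 200)
    tibble(transcript_id = "T3", gene_id = "G2", chrom = "c", strand = strand,
           start = c(0L, 200L), end = c(100L, 300L)),
    tibble(transcript_id = "T4", gene_id = "G2", chrom = "c", strand = strand,
           start = 0L, end = 300L),
    # SE: exon [150, 180)
    tibble(transcript_id = "T5", gene_id = "G3", chrom = "c", strand = strand,
           start = c(0L, 150L, 200L), end = c(100L, 180L, 300L)),
    tibble(transcript_id = "T6", gene_id = "G3", chrom = "c", strand = strand,
           start = c(0L, 200L), end = c(100L, 300L)),
    # A3: acceptors 200 / 203 (NAGNAG geometry, 3 nt apart)
    tibble(transcript_id = "T7", gene_id = "G4", chrom = "c", strand = strand,
           start = c(0L, 200L), end = c(100L, 300L)),
    tibble(transcript_id = "T8", gene_id = "G4", chrom = "c", strand = strand,
           start = c(0L, 203L), end = c(100L, 300L))
  )
}

# Reverse-complement a genome and flip its annotation strand, for the
# strand-invariance property: transcription-sense windows must not change.
flip_fixture <- function(genome, exons) {
  lens <- Biostrings::width(genome)
  flipped <- Biostrings::reverseComplement(genome)
  names(flipped) <- names(genome)
  len <- lens[match(exons$chrom, names(genome))]
  ex2 <- exons |>
    mutate(new_start = len - .data$end, new_end = len - .data$start,
           strand = ifelse(.data$strand == "+", "-", "+")) |>
    mutate(start = .data$new_start, end = .data$new_end) |>
    select(-"new_start", -"new_end") |>
    arrange(.data$transcript_id, .data$start)
  list(genome = flipped, exons = ex2)
}

# Independent exhaustive PSSM oracle: hand-count frequencies and scores.
oracle_pssm_freq <- function(seqs, pseudocount) {
  seqs <- chartr("T", "U", toupper(seqs))
  L <- nchar(seqs[1])
  bases <- c("A", "C", "G", "U")
  sapply(seq_len(L), function(i) {
    ch <- substr(seqs, i, i)
    counts <- vapply(bases, function(b) sum(ch == b), numeric(1))
    (counts + pseudocount) / (sum(counts) + 4 * pseudocount)
  })
}

oracle_score <- function(seqs, freqs_by_pos) {
  vapply(seqs, function(s) {
    s <- chartr("T", "U", toupper(s))
    total <- 0
    for (i in seq_len(nchar(s))) {
      b <- substr(s, i, i)
      j <- match(b, c("A", "C", "G", "U"))
      if (is.na(j)) return(NA_real_)
      total <- total + log2(freqs_by_pos[j, i])
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

# Independent 2xk G-test oracle on two character vectors of bases.
oracle_g <- function(a, b) {
  bases <- sort(unique(c(a, b)))
  obs <- rbind(table(factor(a, levels = bases)),
               table(factor(b, levels = bases)))
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  terms <- ifelse(obs == 0, 0, obs * log(obs / expd))
  list(g = 2 * sum(terms), df = (nrow(obs) - 1) * (ncol(obs) - 1))
}

random_windows <- function(n, len = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  apply(matrix(sample(c("A", "C", "G", "U"), n * len, replace = TRUE),
               nrow = n), 1, paste, collapse = "")
}
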