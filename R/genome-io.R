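#' Read a genome FASTA file
#'
#' Loads chromosome sequences with [Biostrings::readDNAStringSet()], uppercases
#' them, and converts any U to T so all internal arithmetic is on the DNA
#' alphabet. Ambiguity codes (IUPAC letters other than ACGTN) are retained
#' verbatim and reported via a message.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  # read as plain strings first so RNA-alphabet (U) input survives the trip
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate FASTA headers: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(toupper(chartr("Uu", "Tt", as.character(seqs))))
  amb <- Biostrings::letterFrequency(seqs, letters = "RYSWKMBDHV")
  n_amb <- sum(amb)
  if (n_amb > 0) {
    message(n_amb, " ambiguity-code bases (non-ACGTN) retained verbatim")
  }
  seqs
}

#' Fetch genomic sequence, strand-aware
#'
#' Coordinates are 0-based half-open. Minus-strand queries return the reverse
#' complement, i.e. the transcription-sense sequence.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param chrom Chromosome name(s).
#' @param start,end 0-based half-open interval(s).
#' @param strand `"+"` or `"-"` (recycled).
#' @return Character vector of sequences.
#' @export
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  n <- max(length(chrom), length(start), length(end), length(strand))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n)
  end <- rep_len(end, n); strand <- rep_len(strand, n)
  missing_chrom <- setdiff(unique(chrom), names(genome))
  if (length(missing_chrom) > 0) {
    stop("chromosome(s) not in genome: ", paste(missing_chrom, collapse = ", "),
         call. = FALSE)
  }
  lens <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(start < 0 | end > lens | start >= end)) {
    stop("interval outside chromosome bounds", call. = FALSE)
  }
  out <- as.character(Biostrings::subseq(genome[chrom], start = start + 1L,
                                         end = end))
  neg <- strand == "-"
  if (any(neg)) out[neg] <- revcomp(out[neg])
  unname(out)
}

detect_dialect <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("gtf")) return("gtf")
  if (ext %in% c("gff", "gff3")) return("gff3")
  # sniff attribute syntax: GFF3 uses key=value, GTF uses key "value"
  lines <- readLines(path, n = 100L)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) stop("cannot detect annotation dialect: ", path,
                               call. = FALSE)
  attrs <- vapply(strsplit(lines, "\t"), function(x) x[min(9, length(x))], "")
  if (any(grepl("=", attrs, fixed = TRUE)) && !any(grepl(" \"", attrs))) "gff3"
  else "gtf"
}

#' Read transcript models from GFF3/GTF
#'
#' Parses exon features with [rtracklayer::import()] and returns one row per
#' exon with coordinates converted from the 1-based inclusive file convention
#' to 0-based half-open. Exons are grouped per transcript and sorted by
#' genomic coordinate. Single-exon transcripts are retained (they simply
#' yield no introns downstream).
#'
#' @param path Path to a GFF3 or GTF file.
#' @param dialect `"auto"` (default, by extension then attribute syntax),
#'   `"gff3"`, or `"gtf"`.
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open exon intervals).
#' @export
read_annotation <- function(path, dialect = c("auto", "gff3", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  if (dialect == "auto") dialect <- detect_dialect(path)
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  feats <- as.character(gr$type)
  ex <- gr[feats == "exon"]
  if (length(ex) == 0) stop("no exon features in ", path, call. = FALSE)
  if (dialect == "gtf") {
    tx_id <- ex$transcript_id
    gene_id <- ex$gene_id %||% rep(NA_character_, length(ex))
    if (any(is.na(tx_id) | tx_id == "")) {
      stop("exon feature(s) without transcript_id attribute", call. = FALSE)
    }
    exons <- tibble(
      transcript_id = tx_id,
      gene_id = gene_id,
      chrom = as.character(GenomicRanges::seqnames(ex)),
      strand = as.character(GenomicRanges::strand(ex)),
      start = GenomicRanges::start(ex) - 1L,
      end = GenomicRanges::end(ex)
    )
  } else {
    parents <- ex$Parent
    np <- lengths(parents)
    if (any(np == 0)) {
      stop("exon feature(s) without Parent attribute", call. = FALSE)
    }
    idx <- rep(seq_along(ex), np)
    tx_id <- unlist(parents, use.names = FALSE)
    # map transcript-level features to their gene via their own Parent
    tx_feats <- gr[!is.na(gr$ID) & feats != "exon"]
    tx_gene <- setNames(
      vapply(as.list(tx_feats$Parent), function(p)
        if (length(p)) p[[1]] else NA_character_, ""),
      tx_feats$ID
    )
    exons <- tibble(
      transcript_id = tx_id,
      gene_id = unname(tx_gene[tx_id]),
      chrom = as.character(GenomicRanges::seqnames(ex))[idx],
      strand = as.character(GenomicRanges::strand(ex))[idx],
      start = GenomicRanges::start(ex)[idx] - 1L,
      end = GenomicRanges::end(ex)[idx]
    )
  }
  exons$gene_id <- ifelse(is.na(exons$gene_id), exons$transcript_id,
                          exons$gene_id)
  bad <- exons |>
    group_by(.data$transcript_id) |>
    summarise(mixed = dplyr::n_distinct(.data$strand) > 1 |
                dplyr::n_distinct(.data$chrom) > 1)
  if (any(bad$mixed)) {
    stop("transcript(s) with exons on multiple strands/chromosomes: ",
         paste(bad$transcript_id[bad$mixed], collapse = ", "), call. = FALSE)
  }
  exons |> arrange(.data$transcript_id, .data$start, .data$end)
}

#' Derive introns from transcript exon chains
#'
#' An intron spans the gap between each pair of consecutive exons. Donor and
#' acceptor coordinates are strand-correct: on `+` the donor is the intron
#' start and the acceptor the last intron base; on `-` the roles flip.
#'
#' @param exons Exon tibble as returned by [read_annotation()].
#' @param dedup If `TRUE` (default), introns are unique by
#'   `(chrom, strand, start, end)` with a transcript-support count; if
#'   `FALSE` one row per transcript occurrence.
#' @return Tibble with columns `chrom`, `strand`, `start`, `end` (0-based
#'   half-open), `donor_pos`, `acceptor_pos`, `gene_id`, `transcript_id`
#'   (first supporting transcript when deduplicated) and `n_transcripts`.
#' @export
extract_introns <- function(exons, dedup = TRUE) {
  introns <- exons |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(next_start = lead(.data$start)) |>
    ungroup() |>
    filter(!is.na(.data$next_start)) |>
    mutate(intron_start = .data$end, intron_end = .data$next_start) |>
    select("chrom", "strand", start = "intron_start", end = "intron_end",
           "gene_id", "transcript_id")
  if (any(introns$end - introns$start < 4)) {
    stop("intron(s) shorter than 4 nt (no room for GU..AG core)",
         call. = FALSE)
  }
  introns <- introns |>
    mutate(
      donor_pos = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
      acceptor_pos = ifelse(.data$strand == "+", .data$end - 1L, .data$start)
    )
  if (dedup) {
    introns <- introns |>
      group_by(.data$chrom, .data$strand, .data$start, .data$end,
               .data$donor_pos, .data$acceptor_pos) |>
      summarise(gene_id = .data$gene_id[1], transcript_id = .data$transcript_id[1],
                n_transcripts = n(), .groups = "drop")
  } else {
    introns$n_transcripts <- 1L
  }
  introns |> arrange(.data$chrom, .data$start, .data$end)
}

# Genomic slice [gstart, gend) holding a window, given junction geometry.
window_bounds <- function(site_kind, strand, donor_pos, acceptor_pos) {
  if (site_kind == "five_prime") {
    # -3..-1 exonic, +1..+5 intronic
    gstart <- ifelse(strand == "+", donor_pos - 3L, donor_pos - 4L)
    gend <- gstart + 8L
  } else {
    # -5..-1 intronic, +1..+2 exonic
    gstart <- ifelse(strand == "+", acceptor_pos - 4L, acceptor_pos - 2L)
    gend <- gstart + 7L
  }
  list(start = gstart, end = gend)
}

#' Extract splice-site windows around intron junctions
#'
#' Returns transcription-sense window sequences in the RNA alphabet: donor
#' windows are the last 3 exonic plus first 5 intronic nucleotides, acceptor
#' windows the last 5 intronic plus first 2 exonic nucleotides. Minus-strand
#' windows are reverse complemented. Windows that would run off a chromosome
#' end, or whose intronic span exceeds the intron length, are dropped with a
#' message (never padded), so downstream matrices contain no placeholder
#' bases. Non-GU donors are counted and reported, never dropped.
#'
#' @param introns Intron tibble from [extract_introns()].
#' @param genome A [Biostrings::DNAStringSet] from [read_genome_fasta()].
#' @param site_kind `"five_prime"` (donor) or `"three_prime"` (acceptor).
#' @return Tibble with columns `chrom`, `strand`, `junction_pos` (0-based
#'   genomic coordinate of intron base +1 for donors, -1 for acceptors),
#'   `site_kind`, `seq`, plus the intron `start`/`end` and `gene_id`.
#' @export
extract_windows <- function(introns, genome,
                            site_kind = c("five_prime", "three_prime")) {
  site_kind <- match.arg(site_kind)
  intron_span <- if (site_kind == "five_prime") 5L else 5L
  short <- introns$end - introns$start < intron_span
  if (any(short)) {
    message(sum(short), " intron(s) shorter than the intronic window span dropped")
    introns <- introns[!short, , drop = FALSE]
  }
  b <- window_bounds(site_kind, introns$strand, introns$donor_pos,
                     introns$acceptor_pos)
  lens <- Biostrings::width(genome)[match(introns$chrom, names(genome))]
  off <- b$start < 0 | b$end > lens | is.na(lens)
  if (any(off)) {
    message(sum(off), " window(s) overlapping chromosome ends discarded")
    introns <- introns[!off, , drop = FALSE]
    b <- lapply(b, function(x) x[!off])
  }
  if (nrow(introns) == 0) {
    return(tibble(chrom = character(), strand = character(),
                  junction_pos = integer(), site_kind = character(),
                  seq = character(), start = integer(), end = integer(),
                  gene_id = character()))
  }
  seqs <- to_rna(genome_seq(genome, introns$chrom, b$start, b$end,
                            introns$strand))
  out <- tibble(
    chrom = introns$chrom,
    strand = introns$strand,
    junction_pos = if (site_kind == "five_prime") introns$donor_pos
                   else introns$acceptor_pos,
    site_kind = site_kind,
    seq = seqs,
    start = introns$start,
    end = introns$end,
    gene_id = introns$gene_id %||% NA_character_
  )
  if (site_kind == "five_prime") {
    non_gu <- window_slice(out$seq, 1, 2, window_positions("five_prime")) != "GU"
    if (any(non_gu)) message(sum(non_gu), " non-GU donor window(s) retained")
  }
  out
}

#' Extract a donor/acceptor window directly from a junction coordinate
#'
#' Lower-level companion to [extract_windows()] for sites known only by their
#' junction position (e.g. alternative donors of an event pair).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param chrom,strand,junction_pos Site coordinates; `junction_pos` is the
#'   0-based genomic coordinate of intron base +1 (donors) or -1 (acceptors).
#' @param site_kind `"five_prime"` or `"three_prime"`.
#' @return Character vector of window sequences (RNA alphabet).
#' @export
junction_window <- function(genome, chrom, strand, junction_pos,
                            site_kind = c("five_prime", "three_prime")) {
  site_kind <- match.arg(site_kind)
  b <- window_bounds(site_kind, strand,
                     donor_pos = junction_pos, acceptor_pos = junction_pos)
  to_rna(genome_seq(genome, chrom, b$start, b$end, strand))
}

#' Write / read splice-site window tables
#'
#' Plain TSV with columns `chrom`, `strand`, `junction_pos` (0-based),
#' `site_kind`, `seq`; round-trips losslessly.
#'
#' @param windows Window tibble from [extract_windows()].
#' @param path Output/input TSV path.
#' @return `write_windows_tsv()` returns `path` invisibly;
#'   `read_windows_tsv()` returns the window tibble.
#' @export
write_windows_tsv <- function(windows, path) {
  cols <- intersect(c("chrom", "strand", "junction_pos", "site_kind", "seq"),
                    names(windows))
  utils::write.table(windows[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_tsv
#' @export
read_windows_tsv <- function(path) {
  as_tibble(utils::read.delim(path, colClasses = c(
    chrom = "character", strand = "character", junction_pos = "integer",
    site_kind = "character", seq = "character")))
}

#' Export windows as BED6
#'
#' @inheritParams write_windows_tsv
#' @export
write_windows_bed <- function(windows, path) {
  b <- window_bounds(windows$site_kind[1], windows$strand,
                     donor_pos = windows$junction_pos,
                     acceptor_pos = windows$junction_pos)
  bed <- data.frame(windows$chrom, b$start, b$end, windows$seq, 0L,
                    windows$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
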