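# Seed-deterministic simulators producing the inputs the analyses assume:
# a two-class 5'SS population realised as a toy genome (FASTA + GTF), PSI
# matrices under a genotype x temperature linear model, and pooled EMS
# variant counts with one causal locus (VCF). Every generator returns a
# machine-readable truth table alongside its data.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

sample_bases <- function(n, probs) {
  sample(PSSM_BASES, n, replace = TRUE, prob = probs)
}

consensus_probs <- function(base, p) {
  probs <- rep((1 - p) / 3, 4)
  names(probs) <- PSSM_BASES
  probs[base] <- p
  probs
}

#' Simulate a two-class 5' splice-site population
#'
#' Draws donor windows from a mixture of the two major 5'SS classes: an
#' AG//GU-like class with consensus AG at -2..-1 (per-position consensus
#' probability `consensus_prob`, near-uniform +3..+5) and a //GURAG-like
#' class with near-uniform -2..-1 and consensus RAG at +3..+5 (R split
#' evenly between A and G). Positions +1..+2 are GU with probability
#' `gu_prob` per position and -3 is near-uniform in both classes. The drawn
#' windows are realised as a toy genome - one single-intron, plus-strand
#' gene per site, exons and introns separated by fixed spacer sequence - so
#' that annotation-driven window extraction reproduces the drawn windows
#' exactly.
#'
#' @param n_sites Number of donors (default 10000).
#' @param mixture_aggu Mixture weight of the AG//GU-like class (default 0.5).
#' @param consensus_prob Per-position consensus emission probability
#'   (default 0.9).
#' @param gu_prob Per-position probability of the GU dinucleotide at +1..+2
#'   (default 0.98).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param dir Optional directory: when given, `genome.fa`, `annotation.gtf`,
#'   and `truth.tsv` are written there.
#' @return List with `sites` (truth tibble: `site_id`, `class`, `seq`),
#'   `genome` (a [Biostrings::DNAStringSet]), `exons` (annotation tibble as
#'   from [read_annotation()]), and `paths` (when `dir` is given).
#' @export
simulate_sites <- function(n_sites = 10000, mixture_aggu = 0.5,
                           consensus_prob = 0.9, gu_prob = 0.98,
                           seed = NULL, dir = NULL) {
  stopifnot(n_sites >= 1, mixture_aggu >= 0, mixture_aggu <= 1,
            consensus_prob > 0, consensus_prob <= 1,
            gu_prob > 0, gu_prob <= 1)
  with_seed(seed, {
    cls <- ifelse(runif(n_sites) < mixture_aggu, "aggu", "gurag")
    near_unif <- rep(0.25, 4)
    draw <- function(class_probs) {
      m <- matrix(NA_character_, nrow = n_sites, ncol = 8)
      for (k in 1:8) {
        pa <- class_probs$aggu[[k]]; pg <- class_probs$gurag[[k]]
        m[cls == "aggu", k] <- sample_bases(sum(cls == "aggu"), pa)
        m[cls == "gurag", k] <- sample_bases(sum(cls == "gurag"), pg)
      }
      apply(m, 1, paste, collapse = "")
    }
    gu1 <- consensus_probs("G", gu_prob)
    gu2 <- consensus_probs("U", gu_prob)
    r_probs <- c(A = consensus_prob / 2, C = (1 - consensus_prob) / 2,
                 G = consensus_prob / 2, U = (1 - consensus_prob) / 2)
    class_probs <- list(
      aggu = list(near_unif, consensus_probs("A", consensus_prob),
                  consensus_probs("G", consensus_prob), gu1, gu2,
                  near_unif, near_unif, near_unif),
      gurag = list(near_unif, near_unif, near_unif, gu1, gu2,
                   r_probs, consensus_probs("A", consensus_prob),
                   consensus_probs("G", consensus_prob))
    )
    seqs <- draw(class_probs)
    sites <- tibble(site_id = sprintf("site%05d", seq_len(n_sites)),
                    class = cls, seq = seqs)
    toy <- build_toy_genome(sites)
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(fasta = file.path(dir, "genome.fa"),
                    gtf = file.path(dir, "annotation.gtf"),
                    truth = file.path(dir, "truth.tsv"))
      Biostrings::writeXStringSet(toy$genome, paths$fasta)
      write_gtf(toy$exons, paths$gtf)
      utils::write.table(sites, paths$truth, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    list(sites = sites, genome = toy$genome, exons = toy$exons, paths = paths)
  })
}

# Lay each drawn window into a single-intron plus-strand gene. Exon 1 is 20
# nt ending with the window's exonic -3..-1; the 40 nt intron starts with
# the intronic +1..+5 and ends with a canonical pyrimidine-tract acceptor.
build_toy_genome <- function(sites) {
  exon1_pad <- "GCTAGCTAGCTAGCTAG"        # 17 nt
  intron_mid <- "CTCTCTCTCTCTCTCTCTCTCTCTCTCT"  # 28 nt
  acceptor <- "TTTTCAG"                   # 7 nt; intron ends ...AG
  exon2 <- "ATGGCTGCTGCTGCTGCTAA"         # 20 nt
  spacer <- "GCGCGCGCGC"                  # 10 nt between genes
  dna <- chartr("U", "T", sites$seq)
  exonic <- substr(dna, 1, 3)
  intronic <- substr(dna, 4, 8)
  gene_seq <- paste0(exon1_pad, exonic, intronic, intron_mid, acceptor, exon2)
  gene_len <- nchar(gene_seq[1])          # 20 + 40 + 20
  offsets <- (seq_len(nrow(sites)) - 1L) * (gene_len + nchar(spacer))
  chrom_seq <- paste0(paste0(gene_seq, spacer, collapse = ""), spacer)
  genome <- Biostrings::DNAStringSet(chrom_seq)
  names(genome) <- "chrS"
  exons <- tibble(
    transcript_id = rep(paste0(sites$site_id, ".1"), 2),
    gene_id = rep(sites$site_id, 2),
    chrom = "chrS",
    strand = "+",
    start = c(offsets, offsets + 60L),
    end = c(offsets + 20L, offsets + 80L)
  ) |> arrange(.data$transcript_id, .data$start)
  list(genome = genome, exons = exons)
}

write_gtf <- function(exons, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   exons$gene_id, exons$transcript_id)
  lines <- paste(exons$chrom, "splicegrammar", "exon",
                 exons$start + 1L, exons$end, ".", exons$strand, ".",
                 attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Simulate PSI matrices under a genotype x temperature model
#'
#' `PSI = baseline + genotype effect + per-temperature interaction profile +
#' N(0, sigma)`, clipped to \[0, 1\] (the clip rate is returned and is below
#' 1% under defaults). A fraction of events carries a planted genotype
#' effect of magnitude `delta` (random sign, baselines kept `4 * sigma`
#' clear of the boundaries); a further fraction of those carries a
#' temperature-dependent interaction added on top.
#'
#' @param n_events Number of events (default 1000).
#' @param frac_genotype Fraction of events with a genotype effect
#'   (default 0.2).
#' @param delta Planted genotype delta-PSI magnitude (default 0.2).
#' @param frac_interaction Fraction of effect events whose genotype effect
#'   additionally varies by temperature (default 0).
#' @param interaction_profile Named additive offsets per temperature applied
#'   to interaction events (default doubles the effect at 28 degrees,
#'   mimicking cryptic-site activation at elevated temperature).
#' @param sigma Gaussian noise standard deviation (default 0.05).
#' @param n_reps Replicates per genotype x temperature cell (default 6).
#' @param temperatures Temperature levels (default 4, 12, 20, 28).
#' @param seed Integer seed.
#' @return List with `psi` (wide tibble, events x samples), `design`
#'   (`sample_id`, `genotype`, `temperature`, `replicate`), `truth`
#'   (`event_id`, `genotype_effect`, `has_interaction`), and `clip_rate`.
#' @export
simulate_psi <- function(n_events = 1000, frac_genotype = 0.2, delta = 0.2,
                         frac_interaction = 0,
                         interaction_profile = c("4" = 0, "12" = 0,
                                                 "20" = 0, "28" = 1),
                         sigma = 0.05, n_reps = 6,
                         temperatures = c(4, 12, 20, 28), seed = NULL) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  stopifnot(n_events >= 1, frac_genotype >= 0, frac_genotype <= 1)
  with_seed(seed, {
    design <- tidyr::expand_grid(
      genotype = c("wt", "mutant"),
      temperature = temperatures,
      replicate = seq_len(n_reps)
    ) |>
      mutate(sample_id = paste(.data$genotype, .data$temperature,
                               .data$replicate, sep = "_"))
    n_eff <- round(n_events * frac_genotype)
    has_eff <- seq_len(n_events) <= n_eff
    sign <- ifelse(runif(n_events) < 0.5, -1, 1)
    effect <- ifelse(has_eff, sign * delta, 0)
    has_int <- has_eff & (runif(n_events) < frac_interaction)
    margin <- 4 * sigma
    lo <- margin + pmax(0, -effect) + ifelse(has_int, delta, 0)
    hi <- 1 - margin - pmax(0, effect) - ifelse(has_int, delta, 0)
    baseline <- runif(n_events, lo, hi)
    prof <- interaction_profile[as.character(design$temperature)]
    mu <- outer(baseline, rep(1, nrow(design))) +
      outer(effect, as.numeric(design$genotype == "mutant")) +
      outer(ifelse(has_int, sign * delta, 0),
            as.numeric(design$genotype == "mutant") * prof)
    noise <- matrix(rnorm(length(mu), 0, sigma), nrow = n_events)
    raw <- mu + noise
    clip_rate <- mean(raw < 0 | raw > 1)
    psi_mat <- pmin(pmax(raw, 0), 1)
    colnames(psi_mat) <- design$sample_id
    psi <- bind_cols(
      tibble(event_id = sprintf("event%05d", seq_len(n_events))),
      as_tibble(psi_mat)
    )
    truth <- tibble(event_id = psi$event_id, genotype_effect = effect,
                    has_interaction = has_int)
    list(psi = psi, design = design[c("sample_id", "genotype", "temperature",
                                      "replicate")],
         truth = truth, clip_rate = clip_rate)
  })
}

#' Simulate a bulked-segregant experiment with one causal locus
#'
#' Generates EMS-style SNPs along one chromosome and pooled allele depths
#' under recessive segregation of a single causal mutation in a
#' backcross-derived F2: the mutant pool is homozygous for the causal
#' allele, the phenotypically normal pool carries it at an expected fraction
#' of 1/3, and linkage to flanking SNPs decays with genetic distance via a
#' Haldane map (`rec_per_mb` Morgans per Mb). Each pool chromosome's causal
#' haplotype is sampled, the SNP allele follows it with probability `1 - r`,
#' and read depths are Poisson with binomial allele counts. Expected allele
#' fractions are `1 - r` (mutant pool) and `(1 - r)/3 + 2r/3` (normal pool);
#' far from the causal locus both approach 1/2.
#'
#' @param chrom_length Chromosome length in bases (default 20 Mb).
#' @param n_snps Number of EMS SNPs (default 2000).
#' @param causal_pos Causal position (default: drawn uniformly on the
#'   central half of the chromosome). Must lie on the chromosome.
#' @param pool_size Plants per pool (default 50).
#' @param mean_depth Mean sequencing depth per pool per SNP (default 50).
#' @param rec_per_mb Recombination rate in Morgans per megabase
#'   (default 0.05).
#' @param seed Integer seed.
#' @param vcf Optional path: write the variants as a two-sample VCF with AD
#'   fields (samples `normal`, `mutant`).
#' @return List with `variants` (tibble in [read_pool_vcf()] layout, with
#'   `g`-ready depth columns), `truth` (`causal_pos`, model parameters),
#'   and `vcf` (the path, when written).
#' @export
simulate_bsa <- function(chrom_length = 20e6, n_snps = 2000,
                         causal_pos = NULL, pool_size = 50, mean_depth = 50,
                         rec_per_mb = 0.05, seed = NULL, vcf = NULL) {
  with_seed(seed, {
    if (is.null(causal_pos)) {
      causal_pos <- round(runif(1, 0.25, 0.75) * chrom_length)
    }
    if (causal_pos < 1 || causal_pos > chrom_length) {
      stop("causal position outside the chromosome", call. = FALSE)
    }
    pos <- sort(sample.int(chrom_length, n_snps))
    d_mb <- abs(pos - causal_pos) / 1e6
    r <- 0.5 * (1 - exp(-2 * rec_per_mb * d_mb))   # Haldane
    n_chrom <- 2L * pool_size
    # mutant pool: every chromosome carries the causal allele
    p_mut <- 1 - r
    k_mut <- rbinom(n_snps, n_chrom, p_mut)
    f_mut <- k_mut / n_chrom
    # normal pool: a chromosome is causal-mutant with probability 1/3
    k_causal <- rbinom(n_snps, n_chrom, 1 / 3)
    k_norm <- rbinom(n_snps, k_causal, 1 - r) +
      rbinom(n_snps, n_chrom - k_causal, r)
    f_norm <- k_norm / n_chrom
    depth_n <- rpois(n_snps, mean_depth)
    depth_m <- rpois(n_snps, mean_depth)
    alt_n <- rbinom(n_snps, depth_n, f_norm)
    alt_m <- rbinom(n_snps, depth_m, f_mut)
    gc <- sample(c("G", "C"), n_snps, replace = TRUE)
    variants <- annotate_pool_variants(tibble(
      chrom = "chr2", pos = pos,
      ref = gc, alt = ifelse(gc == "G", "A", "T"),
      normal_ref = depth_n - alt_n, normal_alt = alt_n,
      mutant_ref = depth_m - alt_m, mutant_alt = alt_m
    ))
    vcf_path <- NULL
    if (!is.null(vcf)) {
      write_pool_vcf(variants, vcf)
      vcf_path <- vcf
    }
    list(variants = variants,
         truth = list(causal_pos = causal_pos, pool_size = pool_size,
                      mean_depth = mean_depth, rec_per_mb = rec_per_mb),
         vcf = vcf_path)
  })
}

#' Write pooled variants as a two-sample VCF with AD fields
#'
#' @param variants Variant tibble (see [simulate_bsa()]).
#' @param path Output VCF path.
#' @export
write_pool_vcf <- function(variants, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("##contig=<ID=", unique(variants$chrom), ">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "normal", "mutant", sep = "\t")
  )
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", ".", "AD",
                paste0(variants$normal_ref, ",", variants$normal_alt),
                paste0(variants$mutant_ref, ",", variants$mutant_alt),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
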