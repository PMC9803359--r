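# Bulked-segregant mapping of an EMS-induced causal locus: variant
# filtering, per-SNP pool-contrast G-tests on allele depths, tri-cube kernel
# smoothing along the chromosome, and candidate-interval calling.

#' Read pooled allele depths from a VCF
#'
#' Parses a VCF with per-sample AD (allelic depth) fields via
#' [vcfR::read.vcfR()] and returns one row per biallelic site with ref/alt
#' depths and allele fractions for the two named pools. Positions are kept
#' 1-based (VCF convention).
#'
#' @param path VCF path (plain text or bgzipped).
#' @param pool_normal,pool_mutant Sample names of the phenotypically normal
#'   pool and the mutant (phenotype-selected) pool.
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `normal_ref`, `normal_alt`,
#'   `mutant_ref`, `mutant_alt`, `normal_af`, `mutant_af`,
#'   `is_ems_transition`.
#' @export
read_pool_vcf <- function(path, pool_normal = "normal",
                          pool_mutant = "mutant") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  for (s in c(pool_normal, pool_mutant)) {
    if (!s %in% colnames(ad)) {
      stop("pool sample not in VCF: ", s, call. = FALSE)
    }
  }
  split_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    list(ref = as.integer(vapply(parts, `[`, "", 1)),
         alt = as.integer(vapply(parts, function(p) p[2] %||% NA_character_,
                                 "")))
  }
  adn <- split_ad(ad[, pool_normal])
  adm <- split_ad(ad[, pool_mutant])
  out <- tibble(
    chrom = as.character(v@fix[, "CHROM"]),
    pos = as.integer(v@fix[, "POS"]),
    ref = as.character(v@fix[, "REF"]),
    alt = as.character(v@fix[, "ALT"]),
    normal_ref = adn$ref, normal_alt = adn$alt,
    mutant_ref = adm$ref, mutant_alt = adm$alt
  )
  annotate_pool_variants(out)
}

annotate_pool_variants <- function(variants) {
  variants |>
    mutate(
      normal_af = ifelse(.data$normal_ref + .data$normal_alt > 0,
                         .data$normal_alt /
                           (.data$normal_ref + .data$normal_alt), NA_real_),
      mutant_af = ifelse(.data$mutant_ref + .data$mutant_alt > 0,
                         .data$mutant_alt /
                           (.data$mutant_ref + .data$mutant_alt), NA_real_),
      is_ems_transition = (.data$ref == "G" & .data$alt == "A") |
        (.data$ref == "C" & .data$alt == "T")
    )
}

#' Filter variants to EMS-induced transitions
#'
#' EMS alkylates guanine, inducing G:C -> A:T transitions. Keeps biallelic
#' SNVs with `G>A` changes and, by default, `C>T` changes (the reverse-strand
#' representation of the same transition); `strict = TRUE` keeps `G>A`
#' records only. Multi-allelic records and indels are dropped; counts are
#' reported via messages.
#'
#' @param variants Variant tibble from [read_pool_vcf()].
#' @param strict Keep only literal `G>A` records (default `FALSE`).
#' @return The filtered tibble.
#' @export
filter_ems <- function(variants, strict = FALSE) {
  snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    !grepl(",", variants$alt, fixed = TRUE)
  if (any(!snv)) {
    message(sum(!snv), " multi-allelic or indel record(s) dropped")
  }
  v <- variants[snv, , drop = FALSE]
  keep <- if (strict) v$ref == "G" & v$alt == "A" else v$is_ems_transition
  dropped <- sum(!keep)
  if (dropped > 0) message(dropped, " non-EMS substitution(s) dropped")
  out <- v[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no EMS-consistent variants remain")
  out
}

#' Pool-contrast G statistic per SNP
#'
#' 2x2 (pool x allele) G-test of the ref/alt depths, `G = 2 * sum(O *
#' log(O/E))` with expectations from the margins; zero cells contribute
#' zero. The statistic is symmetric under swapping pools or allele labels.
#' `NA` when either pool has zero depth.
#'
#' @param variants Variant tibble with per-pool ref/alt depth columns.
#' @return The tibble with an added numeric `g` column.
#' @export
pool_g_test <- function(variants) {
  g2x2 <- function(a, b, c, d) {
    obs <- c(a, b, c, d)
    n <- a + b + c + d
    expd <- c((a + b) * (a + c), (a + b) * (b + d),
              (c + d) * (a + c), (c + d) * (b + d)) / n
    terms <- ifelse(obs == 0, 0, obs * log(obs / expd))
    2 * sum(terms)
  }
  variants |>
    mutate(g = purrr::pmap_dbl(
      list(.data$normal_ref, .data$normal_alt,
           .data$mutant_ref, .data$mutant_alt),
      function(nr, na_, mr, ma) {
        if (is.na(nr) || is.na(na_) || is.na(mr) || is.na(ma) ||
            nr + na_ == 0 || mr + ma == 0) return(NA_real_)
        g2x2(nr, na_, mr, ma)
      }))
}

#' Tri-cube kernel weight
#'
#' `w(d) = (1 - (|d|/h)^3)^3` for `|d| <= h`, else 0.
#'
#' @param d Distance(s) in bases.
#' @param h Kernel half-width in bases.
#' @return Numeric weights in \[0, 1\].
#' @export
tricube_weight <- function(d, h) {
  u <- abs(d) / h
  ifelse(u <= 1, (1 - u^3)^3, 0)
}

#' Smooth per-SNP G statistics with a tri-cube kernel
#'
#' Evaluates, at every SNP position, the tri-cube-weighted mean of the raw G
#' statistics of all SNPs on the same chromosome within the kernel support.
#' `window` is the total kernel width (the default 2 Mb window means a 1 Mb
#' half-width `h`); set `half_width = TRUE` to reinterpret `window` as `h`.
#' An isolated SNP's smoothed value equals its raw G, and every smoothed
#' value is a convex combination of raw values within the window.
#'
#' @param variants Variant tibble with a `g` column ([pool_g_test()]),
#'   sorted by position within chromosome.
#' @param window Kernel span in bases (default 2e6).
#' @param half_width Interpret `window` as the half-width (default `FALSE`).
#' @return A `bsa_track` tibble: `chrom`, `pos`, `g_raw`, `g_smooth`.
#' @export
smooth_track <- function(variants, window = 2e6, half_width = FALSE) {
  h <- if (half_width) window else window / 2
  out <- variants |>
    filter(!is.na(.data$g)) |>
    arrange(.data$chrom, .data$pos) |>
    group_by(.data$chrom) |>
    mutate(g_smooth = {
      p <- .data$pos
      gv <- .data$g
      vapply(seq_along(p), function(i) {
        lo <- findInterval(p[i] - h, p) + 1L
        hi <- findInterval(p[i] + h, p)
        w <- tricube_weight(p[lo:hi] - p[i], h)
        sum(w * gv[lo:hi]) / sum(w)
      }, numeric(1))
    }) |>
    ungroup() |>
    select("chrom", "pos", g_raw = "g", g_smooth = "g_smooth",
           dplyr::any_of(c("normal_af", "mutant_af")))
  class(out) <- c("bsa_track", class(out))
  attr(out, "window") <- window
  attr(out, "half_width") <- half_width
  out
}

#' Call the candidate mapping interval
#'
#' Returns the contiguous run of SNPs around the global smoothed-G maximum
#' whose smoothed values stay at or above `peak_fraction` of that maximum.
#' With ties at the maximum the widest qualifying run is reported (with a
#' multi-peak warning); a flat track yields the whole chromosome with a
#' warning.
#'
#' @param track A `bsa_track` from [smooth_track()].
#' @param peak_fraction Threshold as a fraction of the maximum (default
#'   0.95); 1.0 degenerates to the argmax SNP(s).
#' @return One-row tibble `chrom`, `start`, `end` (1-based positions of the
#'   first and last SNP in the run), `peak_pos`, `peak_g`.
#' @export
call_interval <- function(track, peak_fraction = 0.95) {
  if (nrow(track) == 0) stop("empty track", call. = FALSE)
  gmax <- max(track$g_smooth)
  peak_chrom <- track$chrom[which.max(track$g_smooth)]
  tr <- track[track$chrom == peak_chrom, , drop = FALSE]
  tr <- tr[order(tr$pos), ]
  if (diff(range(tr$g_smooth)) < .Machine$double.eps^0.5) {
    warning("flat smoothed track; returning the whole chromosome")
    return(tibble(chrom = peak_chrom, start = min(tr$pos), end = max(tr$pos),
                  peak_pos = NA_integer_, peak_g = gmax))
  }
  above <- tr$g_smooth >= peak_fraction * gmax
  runs <- rle(above)
  run_id <- rep(seq_along(runs$lengths), runs$lengths)
  is_max <- tr$g_smooth >= gmax - .Machine$double.eps^0.5 * max(1, abs(gmax))
  cand <- unique(run_id[above & is_max])
  if (length(cand) > 1) warning("multiple tied peaks; reporting the widest region")
  widths <- vapply(cand, function(r) diff(range(tr$pos[run_id == r])) + 1,
                   numeric(1))
  r <- cand[which.max(widths)]
  sel <- run_id == r
  peak_i <- which(sel & is_max)[1]
  tibble(chrom = peak_chrom, start = min(tr$pos[sel]), end = max(tr$pos[sel]),
         peak_pos = tr$pos[peak_i], peak_g = gmax)
}

#' Write a smoothed track as TSV or bedGraph
#'
#' @param track A `bsa_track`.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"bedgraph"` (smoothed values).
#' @export
write_track <- function(track, path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    bg <- data.frame(track$chrom, track$pos - 1L, track$pos, track$g_smooth)
    utils::write.table(bg, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
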