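# Local alternative-splicing event detection from transcript exon chains.
#
# Events follow local-event (SUPPA-style) semantics but are detected directly
# from exon chains: alternative 5'SS (A5) pairs share an acceptor and differ
# in donor, alternative 3'SS (A3) pairs share a donor and differ in acceptor,
# retained introns (RI) oppose an intact intron-spanning exon to the spliced
# junction, and skipped exons (SE) oppose an exon with both flanking
# junctions to the direct junction between the flanking exons. Transcripts
# are assigned to event forms by containing the defining junction or exon.

transcript_introns <- function(exons) {
  extract_introns(exons, dedup = FALSE)
}

junction_key <- function(chrom, start, end) paste(chrom, start, end, sep = ":")

tx_with_junction <- function(introns, chrom, start, end) {
  sort(unique(introns$transcript_id[
    introns$chrom == chrom & introns$start == start & introns$end == end
  ]))
}

make_event <- function(gene_id, type, chrom, strand, coord_tag,
                       inclusion, exclusion, coords) {
  tibble(
    event_id = paste0(gene_id, ";", type, ";", chrom, ":", coord_tag, ":",
                      strand),
    event_type = type, gene_id = gene_id, chrom = chrom, strand = strand,
    coords = list(coords),
    inclusion_transcripts = list(inclusion),
    exclusion_transcripts = list(exclusion)
  )
}

find_events_one_gene <- function(exons) {
  gene_id <- exons$gene_id[1]
  chrom <- exons$chrom[1]
  strand <- exons$strand[1]
  tx_ids <- unique(exons$transcript_id)
  out <- list()
  if (length(tx_ids) < 2) return(NULL)
  introns <- transcript_introns(exons)
  uintrons <- distinct(introns, .data$chrom, .data$start, .data$end)

  # Exon intervals flanking a junction on its variable side, restricted to
  # the transcripts that actually contain the junction. Used to require that
  # alternative sites are alternative boundaries of one exonic region
  # (overlapping flanking exons), which keeps skipped-exon junction
  # configurations from being miscounted as A5/A3.
  flank_exons <- function(tx, s, e, var_col) {
    sel <- exons$transcript_id %in% tx &
      (if (var_col == "start") exons$end == s else exons$start == e)
    exons[sel, c("start", "end"), drop = FALSE]
  }
  any_overlap <- function(a, b) {
    if (nrow(a) == 0 || nrow(b) == 0) return(FALSE)
    any(outer(a$start, b$end, `<`) & outer(a$end, b$start, `>`))
  }

  # ---- A5 / A3: intron pairs sharing one boundary --------------------------
  # On '+' the donor is the intron start and the acceptor the end; alt donors
  # share `end`, alt acceptors share `start`. Roles flip on '-'.
  for (kind in c("A5", "A3")) {
    shared_col <- if ((kind == "A5") == (strand == "+")) "end" else "start"
    var_col <- setdiff(c("start", "end"), shared_col)
    grp <- split(uintrons, uintrons[[shared_col]])
    for (g in grp) {
      if (nrow(g) < 2) next
      g <- g[order(g[[var_col]]), ]
      combs <- utils::combn(nrow(g), 2)
      for (ci in seq_len(ncol(combs))) {
        i1 <- g[combs[1, ci], ]; i2 <- g[combs[2, ci], ]
        tx1 <- tx_with_junction(introns, chrom, i1$start, i1$end)
        tx2 <- tx_with_junction(introns, chrom, i2$start, i2$end)
        if (!any_overlap(flank_exons(tx1, i1$start, i1$end, var_col),
                         flank_exons(tx2, i2$start, i2$end, var_col))) next
        both <- intersect(tx1, tx2)
        tx1 <- setdiff(tx1, both); tx2 <- setdiff(tx2, both)
        if (length(tx1) == 0 || length(tx2) == 0) next
        # inclusion form = shorter intron (more exonic sequence retained)
        len1 <- i1$end - i1$start; len2 <- i2$end - i2$start
        if (len1 <= len2) { inc <- list(i1, tx1); exc <- list(i2, tx2) }
        else { inc <- list(i2, tx2); exc <- list(i1, tx1) }
        out[[length(out) + 1]] <- make_event(
          gene_id, kind, chrom, strand,
          paste0(inc[[1]]$start, "-", inc[[1]]$end, ":",
                 exc[[1]]$start, "-", exc[[1]]$end),
          inc[[2]], exc[[2]],
          coords = c(inc_start = inc[[1]]$start, inc_end = inc[[1]]$end,
                     exc_start = exc[[1]]$start, exc_end = exc[[1]]$end)
        )
      }
    }
  }

  # ---- RI: an exon spanning another transcript's intron --------------------
  for (r in seq_len(nrow(uintrons))) {
    s <- uintrons$start[r]; e <- uintrons$end[r]
    spanning <- exons[exons$start < s & exons$end > e, ]
    if (nrow(spanning) == 0) next
    inc <- sort(unique(spanning$transcript_id))  # intron retained
    exc <- tx_with_junction(introns, chrom, s, e)
    exc <- setdiff(exc, inc)
    if (length(exc) == 0) next
    out[[length(out) + 1]] <- make_event(
      gene_id, "RI", chrom, strand, paste0(s, "-", e), inc, exc,
      coords = c(intron_start = s, intron_end = e)
    )
  }

  # ---- SE: internal exon with both flanking junctions vs direct junction ---
  ex_by_tx <- split(exons, exons$transcript_id)
  se_seen <- character()
  for (tx in ex_by_tx) {
    tx <- tx[order(tx$start), ]
    if (nrow(tx) < 3) next
    for (k in 2:(nrow(tx) - 1)) {
      p <- tx$end[k - 1]; s <- tx$start[k]; e <- tx$end[k]; q <- tx$start[k + 1]
      key <- paste(p, s, e, q)
      if (key %in% se_seen) next
      exc <- tx_with_junction(introns, chrom, p, q)
      if (length(exc) == 0) next
      # inclusion form: transcripts containing both flanking junctions
      tx_up <- tx_with_junction(introns, chrom, p, s)
      tx_dn <- tx_with_junction(introns, chrom, e, q)
      inc <- intersect(tx_up, tx_dn)
      inc <- setdiff(inc, exc)
      if (length(inc) == 0) next
      se_seen <- c(se_seen, key)
      out[[length(out) + 1]] <- make_event(
        gene_id, "SE", chrom, strand,
        paste0(p, "-", s, ":", e, "-", q), inc, exc,
        coords = c(upstream_intron_start = p, exon_start = s,
                   exon_end = e, downstream_intron_start = e,
                   skip_start = p, skip_end = q)
      )
    }
  }
  if (length(out) == 0) NULL else bind_rows(out)
}

#' Detect local alternative-splicing events
#'
#' Scans each gene's transcript models for A5, A3, RI, and SE events,
#' deduplicated by defining coordinates. Multi-way alternative donors or
#' acceptors (more than two sites sharing a boundary) are decomposed into
#' all pairs. Genes with a single transcript yield no events.
#'
#' @param exons Exon tibble as returned by [read_annotation()].
#' @return Tibble with one row per event: `event_id`, `event_type`,
#'   `gene_id`, `chrom`, `strand`, a `coords` list-column of named defining
#'   coordinates, and list-columns `inclusion_transcripts` /
#'   `exclusion_transcripts` (disjoint, non-empty).
#' @export
find_events <- function(exons) {
  genes <- split(exons, exons$gene_id)
  res <- purrr::map(genes, find_events_one_gene)
  res <- purrr::compact(res)
  if (length(res) == 0) {
    return(tibble(event_id = character(), event_type = character(),
                  gene_id = character(), chrom = character(),
                  strand = character(), coords = list(),
                  inclusion_transcripts = list(),
                  exclusion_transcripts = list()))
  }
  bind_rows(res) |> distinct(.data$event_id, .keep_all = TRUE) |>
    arrange(.data$event_id)
}

#' Percent spliced in from transcript abundances
#'
#' `PSI = sum(TPM inclusion) / sum(TPM inclusion + exclusion)`, `NA` when the
#' denominator falls below `expression_floor` (events too weakly expressed to
#' quantify). For A5/A3 the inclusion form is the shorter-intron variant, for
#' RI the intron-retaining form, for SE the exon-including form.
#'
#' @param events Event tibble from [find_events()].
#' @param tpm Transcript abundances: either a wide data frame with a
#'   `transcript_id` column plus one numeric column per sample, or a long
#'   data frame with columns `transcript_id`, `sample`, `tpm`.
#' @param expression_floor Minimum total event-form TPM (default 1).
#' @return Long tibble `event_id`, `sample`, `psi`, `total_tpm`.
#' @export
compute_psi <- function(events, tpm, expression_floor = 1) {
  if (!all(c("transcript_id", "sample", "tpm") %in% names(tpm))) {
    tpm <- tidyr::pivot_longer(tpm, -"transcript_id",
                               names_to = "sample", values_to = "tpm")
  }
  if (any(tpm$tpm < 0, na.rm = TRUE)) {
    stop("negative transcript abundances", call. = FALSE)
  }
  samples <- unique(tpm$sample)
  abx <- tpm |>
    tidyr::pivot_wider(names_from = "sample", values_from = "tpm",
                       values_fill = 0)
  mat <- as.matrix(abx[samples])
  rownames(mat) <- abx$transcript_id
  sum_tpm <- function(tx) {
    tx <- intersect(tx, rownames(mat))
    if (length(tx) == 0) rep(0, ncol(mat))
    else colSums(mat[tx, , drop = FALSE])
  }
  purrr::map2(events$event_id,
              purrr::map2(events$inclusion_transcripts,
                          events$exclusion_transcripts, list),
              function(id, forms) {
                inc <- sum_tpm(forms[[1]])
                exc <- sum_tpm(forms[[2]])
                total <- unname(inc + exc)
                psi <- ifelse(total < expression_floor, NA_real_,
                              unname(inc) / total)
                tibble(event_id = id, sample = samples, psi = psi,
                       total_tpm = total)
              }) |>
    bind_rows()
}

#' Pivot long PSI values to an events-by-samples matrix-like tibble
#'
#' @param psi Long tibble from [compute_psi()].
#' @return Wide tibble, one row per event, one column per sample.
#' @export
psi_wide <- function(psi) {
  tidyr::pivot_wider(psi[c("event_id", "sample", "psi")],
                     names_from = "sample", values_from = "psi")
}

#' Orient alternative site pairs by strand
#'
#' Orders the two alternative sites of each A5/A3 event by genomic position
#' relative to the strand of the parent gene: on `+` the upstream site has
#' the smaller genomic coordinate, on `-` the larger. The distance is the
#' separation in nucleotides (always positive; direction-of-shift labels are
#' attached downstream from the sign of delta-PSI).
#'
#' @param events Event tibble from [find_events()] (A5/A3 rows are used).
#' @param genome Optional [Biostrings::DNAStringSet]; when supplied, full
#'   window sequences are attached as `upstream_seq` / `downstream_seq`.
#' @return Tibble with `pair_id`, `kind` (`alt5`/`alt3`), `chrom`, `strand`,
#'   `upstream_pos`, `downstream_pos` (junction coordinates), `distance`,
#'   `inclusion_site` (`"upstream"`/`"downstream"`: which site the inclusion
#'   form uses), and optionally the window sequences.
#' @export
orient_pair <- function(events, genome = NULL) {
  ev <- events |> filter(.data$event_type %in% c("A5", "A3"))
  if (nrow(ev) == 0) {
    return(tibble(pair_id = character(), kind = character(),
                  chrom = character(), strand = character(),
                  upstream_pos = integer(), downstream_pos = integer(),
                  distance = integer(), inclusion_site = character()))
  }
  rows <- purrr::pmap(list(ev$coords, ev$event_type, ev$strand),
                      function(co, ty, st) {
    # variable boundary: donor for A5, acceptor for A3.
    # '+' A5 donors and '-' A3 acceptors sit at the intron start; the
    # other two combinations sit at the last intron base (end - 1).
    if ((ty == "A5") == (st == "+")) {
      inc_j <- co[["inc_start"]]
      exc_j <- co[["exc_start"]]
    } else {
      inc_j <- co[["inc_end"]] - 1L
      exc_j <- co[["exc_end"]] - 1L
    }
    # transcription-sense order
    if (st == "+") {
      up <- min(inc_j, exc_j); dn <- max(inc_j, exc_j)
    } else {
      up <- max(inc_j, exc_j); dn <- min(inc_j, exc_j)
    }
    tibble(upstream_pos = up, downstream_pos = dn,
           distance = abs(dn - up),
           inclusion_site = ifelse(up == inc_j, "upstream", "downstream"))
  })
  out <- bind_rows(rows) |>
    mutate(pair_id = ev$event_id,
           kind = ifelse(ev$event_type == "A5", "alt5", "alt3"),
           chrom = ev$chrom, strand = ev$strand, .before = 1)
  if (!is.null(genome)) {
    sk <- ifelse(out$kind == "alt5", "five_prime", "three_prime")
    out$upstream_seq <- NA_character_
    out$downstream_seq <- NA_character_
    for (k in c("five_prime", "three_prime")) {
      i <- sk == k
      if (!any(i)) next
      out$upstream_seq[i] <- junction_window(genome, out$chrom[i],
                                             out$strand[i],
                                             out$upstream_pos[i], k)
      out$downstream_seq[i] <- junction_window(genome, out$chrom[i],
                                               out$strand[i],
                                               out$downstream_pos[i], k)
    }
  }
  out
}

#' Donor windows flanking a skipped exon
#'
#' For each SE event, returns the 5'SS of the intron upstream of the skipped
#' exon and the 5'SS at the exon's 3' end (the downstream intron's donor), in
#' transcription sense.
#'
#' @param events Event tibble (non-SE rows are rejected).
#' @param genome Optional genome to attach window sequences.
#' @return Tibble with `event_id`, `upstream_donor_pos`,
#'   `downstream_donor_pos`, and optionally `upstream_seq`/`downstream_seq`.
#' @export
flanking_donors <- function(events, genome = NULL) {
  if (any(events$event_type != "SE")) {
    stop("flanking_donors() applies to SE events only", call. = FALSE)
  }
  rows <- purrr::pmap(list(events$coords, events$strand), function(co, st) {
    p <- co[["upstream_intron_start"]]  # genomic: end of exon before the SE
    e <- co[["exon_end"]]               # genomic: end of the skipped exon
    s <- co[["exon_start"]]
    q <- co[["skip_end"]]
    if (st == "+") {
      tibble(upstream_donor_pos = p, downstream_donor_pos = e)
    } else {
      # transcription sense flips: upstream intron is the genomic-downstream
      # one (e, q), whose minus-strand donor sits at q - 1; the skipped
      # exon's own donor is at s - 1.
      tibble(upstream_donor_pos = q - 1L, downstream_donor_pos = s - 1L)
    }
  })
  out <- bind_rows(rows) |> mutate(event_id = events$event_id, .before = 1) |>
    mutate(chrom = events$chrom, strand = events$strand)
  if (!is.null(genome)) {
    out$upstream_seq <- junction_window(genome, out$chrom, out$strand,
                                        out$upstream_donor_pos, "five_prime")
    out$downstream_seq <- junction_window(genome, out$chrom, out$strand,
                                          out$downstream_donor_pos,
                                          "five_prime")
  }
  out
}

#' Write events as an ioe-style TSV
#'
#' @param events Event tibble from [find_events()].
#' @param path Output path.
#' @export
write_events_tsv <- function(events, path) {
  df <- events |>
    mutate(inclusion_transcripts =
             purrr::map_chr(.data$inclusion_transcripts, paste, collapse = ","),
           exclusion_transcripts =
             purrr::map_chr(.data$exclusion_transcripts, paste, collapse = ",")) |>
    select(-"coords")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
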