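# Position-specific scoring matrices over the RNA alphabet {A,C,G,U}.
# Frequencies are pseudocount-smoothed and stored as log2; a window's score
# is the summed log2 frequency of its observed bases.

PSSM_BASES <- c("A", "C", "G", "U")

resolve_windows <- function(windows, positions) {
  if (is.data.frame(windows)) {
    layout <- window_positions(windows$site_kind[1])
    seqs <- norm_seq(windows$seq)
  } else {
    seqs <- norm_seq(windows)
    layout <- positions %||%
      stop("positions must be given when windows is a character vector",
           call. = FALSE)
  }
  positions <- positions %||% layout
  if (!all(positions %in% layout)) {
    stop("requested positions not covered by the window span", call. = FALSE)
  }
  idx <- match(positions, layout)
  list(seqs = seqs, positions = positions, idx = idx)
}

#' Build a log-transformed position-specific scoring matrix
#'
#' Per position, `frequency(base) = (count + pseudocount) / (n + 4 *
#' pseudocount)`, stored as log2. Windows containing N at a counted position
#' contribute to the other positions only. Callers are expected to pass
#' junction-deduplicated windows (one count per unique genomic site) so that
#' isoform multiplicity does not weight the matrix; [extract_introns()] with
#' `dedup = TRUE` provides this.
#'
#' @param windows A window tibble (from [extract_windows()]) or a character
#'   vector of equal-length sequences.
#' @param positions Signed positions to model. Defaults to the window's full
#'   span for tibbles; required for character input (e.g. `-2:-1`).
#' @param pseudocount Additive count per base per position (default 1).
#' @return An object of class `pssm`.
#' @export
build_pssm <- function(windows, positions = NULL, pseudocount = 1) {
  w <- resolve_windows(windows, positions)
  if (length(w$seqs) == 0) stop("cannot build a PSSM from zero windows",
                                call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  mat <- matrix(NA_real_, nrow = length(w$positions), ncol = 4,
                dimnames = list(as.character(w$positions), PSSM_BASES))
  chars <- do.call(rbind, strsplit(w$seqs, ""))
  for (k in seq_along(w$positions)) {
    obs <- chars[, w$idx[k]]
    counts <- table(factor(obs[obs %in% PSSM_BASES], levels = PSSM_BASES))
    freq <- (as.numeric(counts) + pseudocount) /
      (sum(counts) + 4 * pseudocount)
    mat[k, ] <- log2(freq)
  }
  structure(
    list(positions = w$positions, log_freqs = mat, pseudocount = pseudocount,
         n_sites = length(w$seqs)),
    class = "pssm"
  )
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM over positions", paste(x$positions, collapse = ", "),
      "| n_sites =", x$n_sites, "| pseudocount =", x$pseudocount, "\n")
  print(round(x$log_freqs, 3))
  invisible(x)
}

#' @describeIn build_pssm Tidy a PSSM into a position/base/log2-frequency tibble.
#' @param x A `pssm` object.
#' @param ... Unused.
#' @method tidy pssm
#' @export
tidy.pssm <- function(x, ...) {
  tidyr::expand_grid(position = x$positions, base = PSSM_BASES) |>
    mutate(log2_freq = as.vector(t(x$log_freqs)),
           freq = 2^.data$log2_freq)
}

#' @describeIn build_pssm One-row summary of a PSSM.
#' @method glance pssm
#' @export
glance.pssm <- function(x, ...) {
  tibble(n_positions = length(x$positions), n_sites = x$n_sites,
         pseudocount = x$pseudocount)
}

#' Score windows against a PSSM
#'
#' The score is the sum over modelled positions of the log2 frequency of the
#' observed base. Any N (or other non-ACGU letter) at a scored position makes
#' the score `NA`.
#'
#' @param pssm A `pssm` from [build_pssm()].
#' @param windows Window tibble or character vector.
#' @param positions Signed position layout of `windows` when given as a
#'   character vector.
#' @return Numeric vector of log2 likelihood scores.
#' @export
score_pssm <- function(pssm, windows, positions = NULL) {
  if (is.data.frame(windows)) {
    layout <- window_positions(windows$site_kind[1])
    seqs <- norm_seq(windows$seq)
  } else {
    seqs <- norm_seq(windows)
    # bare sequences without a stated layout must span exactly the PSSM
    layout <- positions %||% pssm$positions
  }
  if (length(seqs) == 0) return(numeric(0))
  if (any(nchar(seqs) != length(layout))) {
    stop("window length does not match its position layout", call. = FALSE)
  }
  idx <- match(pssm$positions, layout)
  if (anyNA(idx)) stop("window span does not cover all PSSM positions",
                       call. = FALSE)
  chars <- do.call(rbind, strsplit(seqs, ""))
  scores <- rep(0, length(seqs))
  for (k in seq_along(pssm$positions)) {
    obs <- chars[, idx[k], drop = TRUE]
    col <- match(obs, PSSM_BASES)
    scores <- scores + pssm$log_freqs[k, ][col]
  }
  unname(scores)
}

#' U5 and U6 snRNA interaction scores for donor windows
#'
#' Scores each 5'SS window against a U5-side PSSM (exonic positions -2..-1,
#' the U5 snRNA loop 1 contact) and a U6-side PSSM (intronic positions
#' +3..+5, the U6 snRNA ACAGA box contact), following the convention that
#' both PSSMs are built from one reference donor set.
#'
#' @param windows 5'SS window tibble.
#' @param pssm_u5,pssm_u6 PSSMs over positions -2..-1 and +3..+5. If omitted,
#'   both are built from `windows` itself (the genome-wide reference case).
#' @param pseudocount Passed to [build_pssm()] when PSSMs are built here.
#' @return `windows` with added numeric columns `u5_ll` and `u6_ll`.
#' @export
score_sites <- function(windows, pssm_u5 = NULL, pssm_u6 = NULL,
                        pseudocount = 1) {
  if (is.null(pssm_u5)) pssm_u5 <- build_pssm(windows, positions = -2:-1,
                                              pseudocount = pseudocount)
  if (is.null(pssm_u6)) pssm_u6 <- build_pssm(windows, positions = 3:5,
                                              pseudocount = pseudocount)
  windows |>
    mutate(u5_ll = score_pssm(pssm_u5, windows),
           u6_ll = score_pssm(pssm_u6, windows))
}

#' Log-odds ratios for alternative donor pairs
#'
#' For each pair the log-odds ratio is the upstream site's log-likelihood
#' minus the downstream site's (downstream in the denominator), so a positive
#' value means the upstream 5'SS has the greater PSSM score. The ratio is
#' antisymmetric under swapping the two sites and `NA` whenever either score
#' is missing.
#'
#' @param pairs Tibble with `upstream_seq` and `downstream_seq` columns
#'   holding full 5'SS windows (-3..+5).
#' @param pssm_u5,pssm_u6 Reference PSSMs (positions -2..-1 and +3..+5).
#' @return `pairs` with added columns `u5_lor` and `u6_lor`.
#' @export
pair_log_odds <- function(pairs, pssm_u5, pssm_u6) {
  layout <- window_positions("five_prime")
  up <- pairs$upstream_seq
  dn <- pairs$downstream_seq
  pairs |>
    mutate(
      u5_lor = score_pssm(pssm_u5, up, positions = layout) -
        score_pssm(pssm_u5, dn, positions = layout),
      u6_lor = score_pssm(pssm_u6, up, positions = layout) -
        score_pssm(pssm_u6, dn, positions = layout)
    )
}

#' Serialize / load a PSSM as TSV
#'
#' Rows are positions, columns the log2 frequencies of A, C, G, U; header
#' comment lines record the pseudocount and number of sites.
#'
#' @param pssm A `pssm` object.
#' @param path TSV path.
#' @export
write_pssm_tsv <- function(pssm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# pseudocount=", pssm$pseudocount),
               paste0("# n_sites=", pssm$n_sites)), con)
  df <- data.frame(position = pssm$positions, pssm$log_freqs,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pssm_tsv
#' @export
read_pssm_tsv <- function(path) {
  hdr <- readLines(path, n = 2)
  pc <- as.numeric(sub("# pseudocount=", "", hdr[1], fixed = TRUE))
  ns <- as.integer(sub("# n_sites=", "", hdr[2], fixed = TRUE))
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  mat <- as.matrix(df[PSSM_BASES])
  rownames(mat) <- as.character(df$position)
  structure(list(positions = df$position, log_freqs = mat,
                 pseudocount = pc, n_sites = ns), class = "pssm")
}
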