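# Positional composition statistics: base-frequency matrices (logo inputs),
# G-tests of composition between site sets, class contingency tables, the
# +4-base direction table, and Spearman correlations of scores.

seqs_from <- function(sites, positions = NULL) {
  if (is.data.frame(sites)) {
    layout <- window_positions(sites$site_kind[1])
    seqs <- norm_seq(sites$seq)
  } else {
    seqs <- norm_seq(sites)
    layout <- positions %||% window_positions("five_prime")
  }
  positions <- positions %||% layout
  idx <- match(positions, layout)
  if (anyNA(idx)) stop("requested positions outside the window span",
                       call. = FALSE)
  list(chars = do.call(rbind, strsplit(seqs, "")), idx = idx,
       positions = positions, n = length(seqs))
}

#' Empirical positional base-frequency matrix
#'
#' Raw per-position base probabilities over A, C, G, U without pseudocount;
#' these are display statistics (sequence-logo input), not scoring
#' frequencies. Non-ACGU letters are excluded from the per-position
#' denominator. Sites should be junction-deduplicated.
#'
#' @param sites Window tibble or character vector of window sequences.
#' @param positions Signed positions to tabulate (default: the full span).
#' @return A `freq_matrix`: tibble with `position`, one probability column
#'   per base, and attribute `n_sites`.
#' @export
freq_matrix <- function(sites, positions = NULL) {
  w <- seqs_from(sites, positions)
  if (w$n == 0) stop("cannot tabulate an empty site set", call. = FALSE)
  rows <- purrr::map(seq_along(w$positions), function(k) {
    obs <- w$chars[, w$idx[k]]
    counts <- table(factor(obs[obs %in% PSSM_BASES], levels = PSSM_BASES))
    p <- as.numeric(counts) / sum(counts)
    tibble(position = w$positions[k], A = p[1], C = p[2], G = p[3], U = p[4])
  })
  out <- bind_rows(rows)
  attr(out, "n_sites") <- w$n
  class(out) <- c("freq_matrix", class(out))
  out
}

#' G-test of base composition between two splice-site sets
#'
#' Per position, a groups x observed-bases G statistic `2 * sum(O *
#' log(O/E))` with expectations from the pooled margins; zero observed cells
#' contribute 0 and bases unobserved in both sets are dropped from the
#' degrees of freedom. The total statistic and df are summed over positions
#' (per-position tests are additive); the p-value is the chi-square upper
#' tail. A Williams continuity correction is available for small fixtures.
#'
#' @param sites_a,sites_b Window tibbles or character vectors.
#' @param positions Signed positions to test (default -2..+5, the donor
#'   region contacted by U5 and U6 snRNA).
#' @param williams Apply the Williams correction (default `FALSE`; the
#'   intended use is large annotation-scale sets).
#' @return A `g_test` list with `g`, `df`, `p_value`, and a `by_position`
#'   tibble.
#' @export
g_test_composition <- function(sites_a, sites_b, positions = c(-2:-1, 1:5),
                               williams = FALSE) {
  wa <- seqs_from(sites_a, positions)
  wb <- seqs_from(sites_b, positions)
  if (wa$n == 0 || wb$n == 0) stop("both site sets must be non-empty",
                                   call. = FALSE)
  per_pos <- purrr::map(seq_along(positions), function(k) {
    oa <- wa$chars[, wa$idx[k]]
    ob <- wb$chars[, wb$idx[k]]
    ca <- table(factor(oa[oa %in% PSSM_BASES], levels = PSSM_BASES))
    cb <- table(factor(ob[ob %in% PSSM_BASES], levels = PSSM_BASES))
    if (sum(ca) == 0 || sum(cb) == 0) {
      message("position ", positions[k], " skipped (no scorable bases)")
      return(tibble(position = positions[k], g = NA_real_, df = NA_integer_))
    }
    obs <- rbind(as.numeric(ca), as.numeric(cb))
    observed_base <- colSums(obs) > 0
    obs <- obs[, observed_base, drop = FALSE]
    expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    terms <- obs * log(obs / expd)
    terms[obs == 0] <- 0
    g <- 2 * sum(terms)
    df <- (nrow(obs) - 1L) * (ncol(obs) - 1L)
    if (williams && df > 0) {
      n <- sum(obs)
      q <- 1 + ((n / sum(rowSums(obs) > 0) - 1) *
                  (n / sum(colSums(obs) > 0) - 1)) / (6 * n * df)
      g <- g / q
    }
    tibble(position = positions[k], g = g, df = df)
  }) |> bind_rows()
  g <- sum(per_pos$g, na.rm = TRUE)
  df <- sum(per_pos$df, na.rm = TRUE)
  structure(
    list(g = g, df = df,
         p_value = if (df > 0) pchisq(g, df, lower.tail = FALSE) else 1,
         by_position = per_pos),
    class = "g_test"
  )
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("G-test of base composition: G = %.4g, df = %d, p = %.3g\n",
              x$g, x$df, x$p_value))
  invisible(x)
}

#' @method tidy g_test
#' @export
tidy.g_test <- function(x, ...) {
  tibble(g = x$g, df = x$df, p.value = x$p_value)
}

#' U5 x U6 class contingency table
#'
#' Cross-tabulates 5'SS windows by their U5 (0..2) and U6 (0..3) classes.
#' Axis levels are ordered by the mean PSSM log-likelihood of class members
#' when reference PSSMs are supplied (strong classes first), with ties
#' broken by class index; otherwise by class index.
#'
#' @param sites Classified 5'SS window tibble (see [classify_sites()]);
#'   unclassified tibbles are classified on the fly.
#' @param pssm_u5,pssm_u6 Optional reference PSSMs for axis ordering.
#' @return A `class_contingency` list with a `counts` matrix (U5 classes x
#'   U6 classes) and a tidy `table` tibble.
#' @export
class_contingency <- function(sites, pssm_u5 = NULL, pssm_u6 = NULL) {
  if (!all(c("u5_class", "u6_class") %in% names(sites))) {
    sites <- classify_sites(sites)
  }
  order_levels <- function(cls, ll) {
    levs <- sort(unique(cls))
    if (is.null(ll)) return(levs)
    m <- tapply(ll, factor(cls, levels = levs), mean)
    levs[order(-m, levs)]
  }
  ll5 <- if (!is.null(pssm_u5)) score_pssm(pssm_u5, sites) else NULL
  ll6 <- if (!is.null(pssm_u6)) score_pssm(pssm_u6, sites) else NULL
  lev5 <- order_levels(sites$u5_class, ll5)
  lev6 <- order_levels(sites$u6_class, ll6)
  counts <- table(factor(sites$u5_class, levels = lev5),
                  factor(sites$u6_class, levels = lev6))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("u5_class", "u6_class")
  tidy_tbl <- as_tibble(as.data.frame.table(counts, responseName = "n")) |>
    mutate(across(c("u5_class", "u6_class"), ~ as.integer(as.character(.x))))
  structure(list(counts = counts, table = tidy_tbl, n_sites = nrow(sites)),
            class = "class_contingency")
}

#' @export
print.class_contingency <- function(x, ...) {
  cat("U5 x U6 class contingency (", x$n_sites, " sites)\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' +4 base versus direction-of-change table
#'
#' For lost/gained-labelled alternative donor pairs, cross-tabulates whether
#' the +4 base is A against the direction of usage change, and reports the
#' separation rate: the fraction of sites consistent with the rule that
#' A(+4) sites lose usage and non-A(+4) sites gain usage when U6 snRNA is
#' unmethylated.
#'
#' @param pairs Tibble with `lost_seq` and `gained_seq` 5'SS windows (see
#'   [label_pair_direction()]).
#' @return List with a 2x2 `counts` matrix (`direction` x `plus4_is_A`) and
#'   `separation_rate`.
#' @export
plus4_direction_table <- function(pairs) {
  ok <- !is.na(pairs$lost_seq) & !is.na(pairs$gained_seq)
  pairs <- pairs[ok, , drop = FALSE]
  lost_a <- plus4_base(pairs$lost_seq) == "A"
  gained_a <- plus4_base(pairs$gained_seq) == "A"
  counts <- matrix(
    c(sum(lost_a), sum(!lost_a), sum(gained_a), sum(!gained_a)),
    nrow = 2, byrow = TRUE,
    dimnames = list(direction = c("reduced_usage", "increased_usage"),
                    plus4 = c("A", "not_A"))
  )
  consistent <- sum(lost_a) + sum(!gained_a)
  list(counts = counts,
       separation_rate = consistent / (2 * nrow(pairs)))
}

#' Spearman correlation of paired site scores
#'
#' Tie-corrected Spearman rank correlation with the large-sample p-value
#' approximation, for U5 versus U6 log-likelihoods (or pair log-odds
#' ratios). Incomplete pairs are dropped.
#'
#' @param data Tibble holding the two score columns, or a numeric vector
#'   (with `y` the second vector).
#' @param x,y Column names (strings; default `"u5_ll"`, `"u6_ll"`) or, when
#'   `data` is numeric, the second score vector.
#' @return Tibble with `rho`, `p.value`, `n`.
#' @export
score_correlation <- function(data, x = "u5_ll", y = "u6_ll") {
  if (is.data.frame(data)) {
    xv <- data[[x]]
    yv <- data[[y]]
  } else {
    xv <- data
    yv <- x
  }
  ok <- !is.na(xv) & !is.na(yv)
  if (sum(ok) < 3) stop("need at least 3 complete score pairs", call. = FALSE)
  ct <- suppressWarnings(cor.test(xv[ok], yv[ok], method = "spearman",
                                  exact = FALSE))
  tibble(rho = unname(ct$estimate), p.value = ct$p.value, n = sum(ok))
}

#' Serialize a frequency matrix as logo-tool-compatible TSV
#'
#' @param fm A `freq_matrix`.
#' @param path Output path.
#' @export
write_freq_matrix_tsv <- function(fm, path) {
  utils::write.table(as.data.frame(fm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
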