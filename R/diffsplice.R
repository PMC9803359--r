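# Per-event linear models of PSI on genotype, temperature, and their
# interaction. Temperature is treated as categorical with the growth
# temperature (20 degrees C by default) as reference; per-term p-values come
# from partial F-tests on nested ordinary-least-squares fits (type II for the
# main effects, interaction against the additive model), and
# Benjamini-Hochberg correction is applied within term across events.

logit <- function(p, eps = 0.01) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

fit_one_event <- function(psi, design, ref_temperature, family, min_obs) {
  keep <- !is.na(psi)
  empty <- tibble(
    n_obs = sum(keep), degenerate = TRUE, coef_genotype = NA_real_,
    p_genotype = NA_real_, p_temperature = NA_real_, p_interaction = NA_real_,
    delta_psi = NA_real_, delta_psi_by_temp = list(NULL)
  )
  if (sum(keep) < 2 * min_obs) return(empty)
  d <- design[keep, , drop = FALSE]
  y <- psi[keep]
  if (family == "logit") y <- logit(y)
  d$genotype <- factor(d$genotype, levels = c("wt", "mutant"))
  d$temperature <- stats::relevel(factor(d$temperature),
                                  ref = as.character(ref_temperature))
  if (min(table(d$genotype)) < min_obs || dplyr::n_distinct(d$genotype) < 2) {
    return(empty)
  }
  multi_temp <- dplyr::n_distinct(d$temperature) > 1
  # delta-PSI effect sizes on the raw PSI scale, per temperature and pooled
  raw <- psi[keep]
  dpsi_t <- tapply(raw, list(d$temperature, d$genotype), mean)
  dpsi_by_temp <- dpsi_t[, "mutant"] - dpsi_t[, "wt"]
  dpsi <- mean(raw[d$genotype == "mutant"]) - mean(raw[d$genotype == "wt"])

  dd <- data.frame(y = y, genotype = d$genotype, temperature = d$temperature)
  if (multi_temp) {
    m_full <- lm(y ~ genotype * temperature, data = dd)
    m_add <- lm(y ~ genotype + temperature, data = dd)
    m_t <- lm(y ~ temperature, data = dd)
    m_g <- lm(y ~ genotype, data = dd)
  } else {
    m_add <- lm(y ~ genotype, data = dd)
    m_full <- m_add
    m_t <- lm(y ~ 1, data = dd)
    m_g <- m_add
  }
  rss <- sum(stats::residuals(m_full)^2)
  degenerate <- rss < 1e-12 * max(1, sum(y^2)) ||
    m_full$df.residual == 0
  pf_test <- function(reduced, full) {
    a <- anova(reduced, full)
    p <- a[["Pr(>F)"]][2]
    if (is.null(p) || is.na(p)) NA_real_ else p
  }
  if (degenerate) {
    p_g <- p_t <- p_i <- NA_real_
  } else {
    p_g <- pf_test(m_t, m_add)
    p_t <- if (multi_temp) pf_test(m_g, m_add) else NA_real_
    p_i <- if (multi_temp) pf_test(m_add, m_full) else NA_real_
  }
  tibble(
    n_obs = sum(keep), degenerate = degenerate,
    coef_genotype = unname(stats::coef(m_add)[["genotypemutant"]]),
    p_genotype = p_g, p_temperature = p_t, p_interaction = p_i,
    delta_psi = dpsi, delta_psi_by_temp = list(dpsi_by_temp)
  )
}

#' Fit per-event PSI models of genotype, temperature, and interaction
#'
#' For each splicing event, fits `PSI ~ genotype + temperature +
#' genotype:temperature` by ordinary least squares with temperature
#' categorical (reference level `ref_temperature`). Per-term p-values are
#' partial F-tests comparing nested models; the reported genotype
#' coefficient is the pooled mutant - wild-type effect from the additive
#' model, and delta-PSI columns are observed mean differences on the raw PSI
#' scale. Events with too few complete observations, fewer than `min_obs`
#' per genotype, or zero residual variance are flagged `degenerate` with
#' missing p-values. Missing PSIs are dropped (complete-case fitting, no
#' imputation). Q-values are Benjamini-Hochberg, applied within term across
#' events.
#'
#' @param psi PSI values: long tibble (`event_id`, `sample`, `psi`) from
#'   [compute_psi()] or a wide tibble from [psi_wide()].
#' @param design Tibble with columns `sample_id`, `genotype` (`"wt"` /
#'   `"mutant"`), `temperature`; duplicate sample ids are an error.
#' @param ref_temperature Reference temperature level (default `20`).
#' @param family `"gaussian"` (OLS on raw PSI, the default) or `"logit"`
#'   (OLS on logit-transformed PSI; effect sizes stay on the PSI scale).
#' @param min_obs Minimum non-missing PSIs per genotype (default 3).
#' @return A `diffsplice_fit` tibble: one row per event with coefficients,
#'   per-term `p_*` and `q_*` values, `delta_psi` (pooled mutant - wt),
#'   and a `delta_psi_by_temp` list-column.
#' @export
fit_diffsplice <- function(psi, design, ref_temperature = 20,
                           family = c("gaussian", "logit"), min_obs = 3) {
  family <- match.arg(family)
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design", call. = FALSE)
  }
  if (!"event_id" %in% names(psi)) stop("psi must carry event_id",
                                        call. = FALSE)
  if (all(c("sample", "psi") %in% names(psi))) {
    psi <- psi_wide(psi)
  }
  samples <- intersect(design$sample_id, names(psi))
  if (length(samples) < nrow(design)) {
    stop("design samples missing from the PSI table: ",
         paste(setdiff(design$sample_id, names(psi)), collapse = ", "),
         call. = FALSE)
  }
  design <- design[match(samples, design$sample_id), , drop = FALSE]
  mat <- as.matrix(psi[samples])
  bad <- mat[!is.na(mat)]
  if (any(bad < 0 | bad > 1)) stop("PSI values outside [0, 1]", call. = FALSE)
  res <- purrr::map(seq_len(nrow(mat)), function(i) {
    fit_one_event(mat[i, ], design, ref_temperature, family, min_obs)
  }) |> bind_rows()
  out <- bind_cols(tibble(event_id = psi$event_id), res)
  out$q_genotype <- bh_fdr(out$p_genotype)
  out$q_temperature <- bh_fdr(out$p_temperature)
  out$q_interaction <- bh_fdr(out$p_interaction)
  class(out) <- c("diffsplice_fit", class(out))
  attr(out, "alpha") <- NA_real_
  attr(out, "family") <- family
  attr(out, "ref_temperature") <- ref_temperature
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH correction via [stats::p.adjust()]; missing p-values are
#' excluded from the family and reinserted as `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values outside [0, 1]",
                                       call. = FALSE)
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Flag significant events and partition them by model term
#'
#' Adds per-term significance flags at FDR `alpha` and a `category` column
#' partitioning events into `interaction`, `genotype+temperature`,
#' `genotype`, `temperature`, or `ns` (interaction takes precedence: an
#' interaction-significant event responds to genotype differently across
#' temperatures regardless of its main-effect flags).
#'
#' @param fit A `diffsplice_fit` from [fit_diffsplice()].
#' @param alpha FDR threshold (default 0.05).
#' @return The fit tibble with `sig_genotype`, `sig_temperature`,
#'   `sig_interaction`, and `category` columns; `alpha` stored as attribute.
#' @export
call_significant <- function(fit, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  fit <- fit |>
    mutate(
      sig_genotype = !is.na(.data$q_genotype) & .data$q_genotype < alpha,
      sig_temperature = !is.na(.data$q_temperature) &
        .data$q_temperature < alpha,
      sig_interaction = !is.na(.data$q_interaction) &
        .data$q_interaction < alpha,
      category = dplyr::case_when(
        sig_interaction ~ "interaction",
        sig_genotype & sig_temperature ~ "genotype+temperature",
        sig_genotype ~ "genotype",
        sig_temperature ~ "temperature",
        TRUE ~ "ns"
      )
    )
  attr(fit, "alpha") <- alpha
  fit
}

#' Label lost and gained sites of alternative pairs from delta-PSI signs
#'
#' For A5/A3 events, the inclusion form's delta-PSI determines which donor or
#' acceptor lost usage in the mutant: a negative delta-PSI means the
#' inclusion-form site is `lost` (FIO1-sensitive in the motivating analysis)
#' and the alternative site `gained`, and vice versa. Pairs are returned
#' oriented lost -> gained with window sequences when present.
#'
#' @param pairs Oriented pair tibble from [orient_pair()] (pair ids must
#'   match event ids in `fit`).
#' @param fit A `diffsplice_fit`.
#' @return `pairs` joined with `delta_psi`, plus `lost_site`/`gained_site`
#'   (`"upstream"`/`"downstream"`) and, when sequences are present,
#'   `lost_seq`/`gained_seq`.
#' @export
label_pair_direction <- function(pairs, fit) {
  out <- pairs |>
    left_join(as_tibble(fit)[c("event_id", "delta_psi")],
              by = c(pair_id = "event_id")) |>
    mutate(
      lost_site = dplyr::case_when(
        is.na(.data$delta_psi) ~ NA_character_,
        .data$delta_psi < 0 ~ .data$inclusion_site,
        TRUE ~ ifelse(.data$inclusion_site == "upstream", "downstream",
                      "upstream")
      ),
      gained_site = ifelse(.data$lost_site == "upstream", "downstream",
                           "upstream")
    )
  if (all(c("upstream_seq", "downstream_seq") %in% names(out))) {
    out <- out |>
      mutate(
        lost_seq = ifelse(.data$lost_site == "upstream", .data$upstream_seq,
                          .data$downstream_seq),
        gained_seq = ifelse(.data$gained_site == "upstream",
                            .data$upstream_seq, .data$downstream_seq)
      )
  }
  out
}

#' Summarise |delta-PSI| by switch category or class
#'
#' Groups pair-level absolute effect sizes by a labelling column (for
#' example a +4 switch category or a U5 class) and reports n, median and
#' quartiles per group. Empty groups are omitted with a message.
#'
#' @param pairs Tibble carrying `delta_psi` and the grouping column.
#' @param category Name of the grouping column (string).
#' @return Tibble `category`, `n`, `median_abs_dpsi`, `q1`, `q3`.
#' @export
effect_size_by_category <- function(pairs, category = "group_label") {
  if (!category %in% names(pairs)) {
    stop("no column `", category, "` in pairs", call. = FALSE)
  }
  miss <- is.na(pairs[[category]]) | is.na(pairs$delta_psi)
  if (any(miss)) message(sum(miss), " pair(s) without category or effect size omitted")
  pairs[!miss, ] |>
    group_by(category = .data[[category]]) |>
    summarise(
      n = n(),
      median_abs_dpsi = median(abs(.data$delta_psi)),
      q1 = quantile(abs(.data$delta_psi), 0.25),
      q3 = quantile(abs(.data$delta_psi), 0.75),
      .groups = "drop"
    ) |>
    arrange(category)
}

#' @method tidy diffsplice_fit
#' @export
tidy.diffsplice_fit <- function(x, ...) {
  as_tibble(x) |>
    select("event_id", "coef_genotype", "delta_psi",
           dplyr::starts_with("p_"), dplyr::starts_with("q_")) |>
    tidyr::pivot_longer(cols = c(dplyr::starts_with("p_")),
                        names_to = "term", values_to = "p.value",
                        names_prefix = "p_") |>
    mutate(q.value = dplyr::case_when(
      .data$term == "genotype" ~ .data$q_genotype,
      .data$term == "temperature" ~ .data$q_temperature,
      .data$term == "interaction" ~ .data$q_interaction
    )) |>
    select("event_id", "term", estimate = "coef_genotype",
           "delta_psi", "p.value", "q.value")
}

#' @method glance diffsplice_fit
#' @export
glance.diffsplice_fit <- function(x, ...) {
  alpha <- attr(x, "alpha")
  thr <- if (is.na(alpha)) 0.05 else alpha
  tibble(
    n_events = nrow(x),
    n_tested = sum(!x$degenerate & !is.na(x$p_genotype)),
    n_sig_genotype = sum(x$q_genotype < thr, na.rm = TRUE),
    n_sig_temperature = sum(x$q_temperature < thr, na.rm = TRUE),
    n_sig_interaction = sum(x$q_interaction < thr, na.rm = TRUE),
    alpha = thr,
    family = attr(x, "family") %||% "gaussian"
  )
}
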