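#' Average technical replicates of quantification cycles
#'
#' Collapses a long CT table to the arithmetic mean CT per
#' (strain, condition, gene role, biological replicate) group, the standard
#' first step of relative quantification. Biological replicates for which the
#' target gene was measured but the reference gene was not (or vice versa)
#' cannot be normalised; they are flagged with a warning and excluded.
#'
#' @param records Tibble with columns `strain_id`, `condition`, `gene_role`
#'   (`"target"` or `"reference"`), `bio_rep`, `tech_rep`, `ct`.
#' @return Tibble keyed by (`strain_id`, `condition`, `gene_role`, `bio_rep`)
#'   with `mean_ct` and `n_tech`.
#' @export
average_technical <- function(records) {
  stopifnot(all(c("strain_id", "condition", "gene_role", "bio_rep", "ct")
                %in% names(records)))
  if (nrow(records) == 0) stop("empty CT table")
  bad_role <- setdiff(unique(records$gene_role), c("target", "reference"))
  if (length(bad_role))
    stop(sprintf("unknown gene_role: %s", paste(bad_role, collapse = ", ")))
  if (any(records$ct <= 0)) stop("CT values must be positive")

  means <- records |>
    dplyr::group_by(.data$strain_id, .data$condition, .data$gene_role,
                    .data$bio_rep) |>
    dplyr::summarise(mean_ct = mean(.data$ct), n_tech = dplyr::n(),
                     .groups = "drop")

  roles <- means |>
    dplyr::group_by(.data$strain_id, .data$condition, .data$bio_rep) |>
    dplyr::summarise(n_roles = dplyr::n_distinct(.data$gene_role),
                     .groups = "drop")
  incomplete <- dplyr::filter(roles, .data$n_roles < 2)
  if (nrow(incomplete) > 0) {
    warning(sprintf(
      "dropping %d biological replicate(s) lacking a paired target/reference measurement: %s",
      nrow(incomplete),
      paste(incomplete$strain_id, incomplete$condition, incomplete$bio_rep,
            sep = ":", collapse = ", ")))
    means <- dplyr::anti_join(means, incomplete,
                              by = c("strain_id", "condition", "bio_rep"))
  }
  means
}

#' Reference-gene normalisation (delta CT)
#'
#' For every (strain, condition, biological replicate) computes
#' `delta_ct = mean CT(target) - mean CT(reference)`. Larger delta CT means
#' lower target expression.
#'
#' @param mean_ct_table Output of [average_technical()].
#' @return Tibble with `strain_id`, `condition`, `bio_rep`, `delta_ct`.
#' @export
delta_ct <- function(mean_ct_table) {
  wide <- tidyr::pivot_wider(
    dplyr::select(mean_ct_table, "strain_id", "condition", "bio_rep",
                  "gene_role", "mean_ct"),
    names_from = "gene_role", values_from = "mean_ct")
  if (!all(c("target", "reference") %in% names(wide)) ||
      any(is.na(wide$target)) || any(is.na(wide$reference)))
    stop("each (strain, condition, bio_rep) needs both target and reference means")
  wide |>
    dplyr::mutate(delta_ct = .data$target - .data$reference) |>
    dplyr::select("strain_id", "condition", "bio_rep", "delta_ct")
}

#' Select the baseline strain for relative quantification
#'
#' The baseline is the strain with the lowest expression in the given
#' condition, i.e. the largest mean delta CT; ties are broken
#' lexicographically by strain id.
#'
#' @param delta_ct_table Output of [delta_ct()].
#' @param condition Condition identifier to evaluate.
#' @return The baseline strain id (character scalar).
#' @export
select_baseline <- function(delta_ct_table, condition) {
  tab <- dplyr::filter(delta_ct_table, .data$condition == !!condition)
  if (nrow(tab) == 0) stop(sprintf("no delta CT rows for condition '%s'", condition))
  if (dplyr::n_distinct(tab$strain_id) < 2)
    stop("baseline selection needs at least two strains")
  means <- tab |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(mean_dct = mean(.data$delta_ct), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_dct), .data$strain_id)
  means$strain_id[1]
}

#' Two-tailed one-sample test of log ratios against no change
#'
#' One-sample t test of `log2(ratios)` against 0 with `n - 1` degrees of
#' freedom. With fewer than two ratios, or a degenerate zero-variance sample,
#' no p-value is produced (`NA` with attribute `zero_variance` set in the
#' degenerate case).
#'
#' @param per_bio_rep_ratios Positive fold-change ratios, one per biological
#'   replicate.
#' @return Two-tailed p-value, or `NA` when untestable.
#' @export
one_sample_log_test <- function(per_bio_rep_ratios) {
  r <- per_bio_rep_ratios
  stopifnot(all(r > 0))
  if (length(r) < 2) return(NA_real_)
  lx <- log2(r)
  s <- stats::sd(lx)
  if (s == 0) return(structure(NA_real_, zero_variance = TRUE))
  tt <- mean(lx) / (s / sqrt(length(lx)))
  2 * stats::pt(-abs(tt), df = length(lx) - 1)
}

#' Relative expression by the delta-delta-CT method
#'
#' For each strain in `condition`, per-biological-replicate fold changes are
#' `eff^-(delta_ct - delta_ct_baseline)`, where the baseline delta CT is the
#' mean over the baseline strain's biological replicates and `eff` is the
#' amplification efficiency (2 = perfect doubling). The per-strain fold
#' change is the geometric mean of the per-replicate ratios; `sd_log2` is the
#' standard deviation of the log2 per-replicate ratios and the p-value a
#' two-tailed one-sample t test of those log2 ratios against 0.
#'
#' @param delta_ct_table Output of [delta_ct()].
#' @param baseline Baseline strain id, or `"auto"` to use [select_baseline()].
#' @param condition Condition identifier.
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return Tibble with `strain_id`, `condition`, `fold_change`,
#'   `per_bio_rep_ratios` (list column), `sd_log2`, `p_two_tailed`, `n_bio`.
#' @export
fold_change_ddct <- function(delta_ct_table, baseline = "auto", condition,
                             efficiency = 2) {
  stopifnot(efficiency > 1)
  tab <- dplyr::filter(delta_ct_table, .data$condition == !!condition)
  if (nrow(tab) == 0) stop(sprintf("no delta CT rows for condition '%s'", condition))
  if (identical(baseline, "auto")) baseline <- select_baseline(tab, condition)
  if (!baseline %in% tab$strain_id)
    stop(sprintf("baseline strain '%s' absent from condition '%s'",
                 baseline, condition))
  base_dct <- mean(tab$delta_ct[tab$strain_id == baseline])

  tab |>
    dplyr::mutate(ratio = efficiency^(-(.data$delta_ct - base_dct))) |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(
      condition = !!condition,
      fold_change = exp(mean(log(.data$ratio))),
      per_bio_rep_ratios = list(.data$ratio),
      sd_log2 = stats::sd(log2(.data$ratio)),
      p_two_tailed = as.numeric(one_sample_log_test(.data$ratio)),
      n_bio = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(baseline = !!baseline)
}

#' Within-strain fold change between conditions
#'
#' Compares a strain's normalised expression between two conditions:
#' `ratio = eff^-(mean delta CT(numerator) - mean delta CT(denominator))`.
#' Each condition is normalised against its own reference-gene CT, so the
#' ratio reflects condition regulation of the target.
#'
#' @inheritParams fold_change_ddct
#' @param strain Strain id.
#' @param cond_num,cond_den Numerator and denominator condition identifiers.
#' @return One-row tibble with `strain_id`, `numerator_condition`,
#'   `denominator_condition`, `ratio`.
#' @export
condition_fold_change <- function(delta_ct_table, strain, cond_num, cond_den,
                                  efficiency = 2) {
  pick <- function(cond) {
    x <- delta_ct_table$delta_ct[delta_ct_table$strain_id == strain &
                                   delta_ct_table$condition == cond]
    if (!length(x))
      stop(sprintf("strain '%s' not measured in condition '%s'", strain, cond))
    mean(x)
  }
  ratio <- efficiency^(-(pick(cond_num) - pick(cond_den)))
  tibble::tibble(strain_id = strain, numerator_condition = cond_num,
                 denominator_condition = cond_den, ratio = ratio)
}

#' Classify regulatory concordance between the reporter and a neighbour gene
#'
#' Compares log2 fold changes of the integrated reporter and of the
#' neighbouring gene expected to read through into it. Both below the
#' threshold in magnitude: `"neither_regulated"`. Both above with the same
#' sign: `"concordant"`. Anything else (opposite signs, or only one
#' regulated): `"discordant"`.
#'
#' @param lacS_log2fc,neighbor_log2fc Log2 fold changes (vectorised).
#' @param threshold Positive magnitude threshold on log2 scale (default 0.58,
#'   about 1.5-fold).
#' @return Character vector of classifications.
#' @export
regulation_concordance <- function(lacS_log2fc, neighbor_log2fc,
                                   threshold = 0.58) {
  stopifnot(threshold > 0)
  both <- abs(lacS_log2fc) > threshold & abs(neighbor_log2fc) > threshold
  neither <- abs(lacS_log2fc) < threshold & abs(neighbor_log2fc) < threshold
  dplyr::case_when(
    neither ~ "neither_regulated",
    both & sign(lacS_log2fc) == sign(neighbor_log2fc) ~ "concordant",
    .default = "discordant")
}
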