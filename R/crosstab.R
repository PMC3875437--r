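#' Cross-tabulate substitution outcomes against MSA frequencies
#'
#' Assigns each (position, amino acid) cell the outcome codes used to
#' compare parallel-mutagenesis results with natural sequence frequencies:
#'
#' * `A` — absent from the MSA subset (frequency exactly 0) yet tolerated
#'   (fold-change at least 0.5, i.e. near or better than parent) in two or
#'   more homologs;
#' * `P1` — present in the MSA, but in at least one homolog whose parent
#'   represses below the growth threshold the substitution pushed activity
#'   above that threshold;
#' * `P2` — present in the MSA, but in at least one such homolog the
#'   substitution fell to the DEL floor (`at_min`);
#' * `D` — disparate outcomes: log10 fold-changes span at least 2 orders of
#'   magnitude across homologs, or the substitution is enhancing in one
#'   homolog and at MIN in another;
#' * `L` — absent from the MSA, tolerated in the designated reference
#'   homolog only;
#' * `X` — the amino acid is the parent residue of at least one homolog at
#'   that position (recorded as background, not tallied);
#' * insufficient — fewer than two homologs carry the substitution.
#'
#' Codes are not mutually exclusive (except A versus P1/P2, which split on
#' zero versus non-zero frequency); the `codes` column concatenates all
#' fired codes, e.g. `"P2D"`.
#'
#' @inheritParams classify_behavior
#' @param msa_freqs Column frequencies of the comparison MSA subset, from
#'   [column_frequencies()]; must cover every scanned position.
#' @param reference_homolog Homolog used for code `L`; defaults to the
#'   first homolog of the context table.
#' @return A tibble with one row per (position, amino acid): logical
#'   columns `A`, `P1`, `P2`, `D`, `L`, `X`, `insufficient`, the combined
#'   `codes` string, `n_homologs`, and `f_msa`.
#' @export
assign_outcome_codes <- function(measurements, contexts, msa_freqs,
                                 reference_homolog = NULL) {
  contexts <- validate_contexts(contexts)
  if (is.null(reference_homolog)) reference_homolog <- contexts$homolog[1]
  scan_pos <- unique(measurements$position)
  missing_pos <- setdiff(scan_pos, unique(msa_freqs$position))
  if (length(missing_pos) > 0) {
    abort(sprintf("MSA frequency profile lacks position(s): %s",
                  paste(missing_pos, collapse = ", ")))
  }
  pos_act <- measurements$mean_miller
  pos_act <- pos_act[!is.na(pos_act) & pos_act > 0]
  clamp <- if (length(pos_act) > 0) min(pos_act) / 2 else 1e-6

  scored <- measurements %>%
    dplyr::inner_join(contexts, by = "homolog") %>%
    dplyr::filter(
      .data$condition == .data$active_condition,
      !.data$excluded,
      .data$sub_aa != .data$wt_aa
    ) %>%
    dplyr::mutate(
      act = ifelse(.data$mean_miller <= 0, clamp, .data$mean_miller),
      fold = ifelse(.data$parent_mean <= 0, clamp, .data$parent_mean) /
        .data$act,
      changed = is_changed(.data$parent_mean, .data$parent_sd,
                           .data$mean_miller, .data$sd_miller),
      at_min = !is_changed(.data$mean_miller, .data$sd_miller,
                           .data$del_mean, .data$del_sd),
      tight_parent = .data$parent_mean < .data$growth_threshold
    )
  parent_aa <- measurements %>%
    dplyr::distinct(.data$position, .data$wt_aa)

  scored <- scored %>%
    dplyr::left_join(
      dplyr::select(msa_freqs, "position", sub_aa = "symbol",
                    f_msa = "freq"),
      by = c("position", "sub_aa")
    )
  scored %>%
    dplyr::group_by(.data$position, .data$sub_aa) %>%
    dplyr::summarise(
      n_homologs = dplyr::n_distinct(.data$homolog),
      f_msa = .data$f_msa[1],
      A = .data$f_msa == 0 & sum(.data$fold >= 0.5) >= 2,
      P1 = .data$f_msa > 0 &
        any(.data$tight_parent &
              .data$mean_miller > .data$growth_threshold),
      P2 = .data$f_msa > 0 & any(.data$tight_parent & .data$at_min),
      D = (max(log10(.data$fold)) - min(log10(.data$fold)) >= 2) |
        (any(.data$fold > 2 & .data$changed) & any(.data$at_min)),
      L = .data$f_msa == 0 &
        any(.data$homolog == .env$reference_homolog & .data$fold >= 0.5) &
        sum(.data$homolog != .env$reference_homolog) >= 1 &
        all(.data$fold[.data$homolog != .env$reference_homolog] < 0.5),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      insufficient = .data$n_homologs < 2,
      dplyr::across(c("A", "P1", "P2", "D", "L"),
                    ~ .x & !.data$insufficient),
      X = purrr::map2_lgl(.data$position, .data$sub_aa, function(p, a) {
        any(parent_aa$position == p & parent_aa$wt_aa == a)
      }),
      codes = ifelse(
        .data$insufficient, "-",
        paste0(
          ifelse(.data$A, "A", ""), ifelse(.data$P1, "P1", ""),
          ifelse(.data$P2, "P2", ""), ifelse(.data$D, "D", ""),
          ifelse(.data$L, "L", "")
        )
      )
    ) %>%
    dplyr::rename(amino_acid = "sub_aa") %>%
    dplyr::arrange(.data$position, .data$amino_acid)
}

#' Screen substitution outcomes against physico-chemical scales
#'
#' For every (homolog, position) profile and every scale, computes the
#' tie-corrected Spearman rank correlation between the scale value of the
#' substituted amino acid and log10 of the (clamped) variant activity. The
#' correlation is undefined (`NA`) when fewer than `min_n` substitutions
#' have scale values or the scale is constant over the observed amino
#' acids.
#'
#' @inheritParams classify_behavior
#' @param scales A long scale table (`scale_name`, `aa`, `value`), e.g.
#'   [amino_acid_scales()].
#' @param min_n Minimum substitutions required for a defined correlation.
#' @return A tibble: `homolog`, `position`, `scale_name`,
#'   `rank_correlation`, `n`.
#' @export
scale_screen <- function(measurements, contexts,
                         scales = amino_acid_scales(), min_n = 4) {
  contexts <- validate_contexts(contexts)
  pos_act <- measurements$mean_miller
  pos_act <- pos_act[!is.na(pos_act) & pos_act > 0]
  clamp <- if (length(pos_act) > 0) min(pos_act) / 2 else 1e-6
  scored <- measurements %>%
    dplyr::inner_join(contexts, by = "homolog") %>%
    dplyr::filter(
      .data$condition == .data$active_condition,
      !.data$excluded,
      .data$sub_aa != .data$wt_aa
    ) %>%
    dplyr::mutate(
      log_act = log10(ifelse(.data$mean_miller <= 0, clamp,
                             .data$mean_miller))
    ) %>%
    dplyr::inner_join(scales, by = c("sub_aa" = "aa"),
                      relationship = "many-to-many")
  scored %>%
    dplyr::group_by(.data$homolog, .data$position, .data$scale_name) %>%
    dplyr::summarise(
      n = dplyr::n(),
      rank_correlation = if (.data$n[1] >= min_n &&
                             length(unique(.data$value)) > 1) {
        stats::cor(.data$value, .data$log_act, method = "spearman")
      } else {
        NA_real_
      },
      .groups = "drop"
    ) %>%
    dplyr::select(
      "homolog", "position", "scale_name", "rank_correlation", "n"
    )
}

#' Family-wide summary of a scale screen
#'
#' Per scale, the fraction of (homolog, position) cells whose absolute rank
#' correlation reaches `threshold`, among cells where the correlation is
#' defined.
#'
#' @param screen Output of [scale_screen()].
#' @param threshold Absolute correlation counted as strong (default 0.8).
#' @return A tibble: `scale_name`, `n_cells`, `n_defined`, `n_strong`,
#'   `frac_strong`.
#' @export
scale_screen_summary <- function(screen, threshold = 0.8) {
  screen %>%
    dplyr::group_by(.data$scale_name) %>%
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_defined = sum(!is.na(.data$rank_correlation)),
      n_strong = sum(abs(.data$rank_correlation) >= threshold,
                     na.rm = TRUE),
      frac_strong = ifelse(.data$n_defined > 0,
                           .data$n_strong / .data$n_defined, NA_real_),
      .groups = "drop"
    )
}
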