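#' The dual criterion for a repression change
#'
#' Two measurements differ ("changed") when both conditions hold: the
#' ratio of their means is strictly greater than 2-fold, and their standard
#' deviation intervals `[mean - sd, mean + sd]` do not overlap. The test is
#' symmetric in its arguments and reflexively false. Vectorized; recycling
#' follows the usual rules.
#'
#' @param mean_a,sd_a Mean and standard deviation of the first measurement
#'   (Miller units).
#' @param mean_b,sd_b Mean and standard deviation of the second measurement.
#' @return Logical vector.
#' @export
#' @examples
#' is_changed(15, 4, 0.7, 0.2)   # TRUE: 21-fold apart, disjoint sds
#' is_changed(0.12, 0.06, 0.06, 0.06)  # FALSE: exactly 2-fold, overlapping
is_changed <- function(mean_a, sd_a, mean_b, sd_b) {
  hi <- pmax(mean_a, mean_b)
  lo <- pmin(mean_a, mean_b)
  ratio_gt2 <- ifelse(lo > 0, hi / lo > 2, hi > 0)
  disjoint <- (mean_a + sd_a < mean_b - sd_b) |
    (mean_b + sd_b < mean_a - sd_a)
  ratio_gt2 & disjoint
}

#' Fold-change of a variant relative to its parent protein
#'
#' Normalizes variant repression against the starting protein:
#' `value = parent_mean / variant_mean`, so values above 1 indicate
#' enhanced repression (tighter than parent) and below 1 diminished
#' repression. Also evaluates the dual change criterion against the parent
#' and, when a DEL control is supplied, whether the variant is
#' indistinguishable from the no-repressor floor (`at_min`).
#'
#' Zero activities are clamped to `clamp` (typically half the smallest
#' positive activity in the dataset) before ratios are formed.
#'
#' @param parent_mean,parent_sd Parent activity (Miller units).
#' @param variant_mean,variant_sd Variant activity; vectorized.
#' @param del_mean,del_sd Optional DEL (no-repressor) control.
#' @param clamp Positive replacement for zero activities; defaults to half
#'   the smallest positive value among the supplied activities.
#' @return A tibble with columns `value`, `changed`, `at_min` (`at_min` is
#'   `NA` when no DEL control is given).
#' @export
#' @examples
#' fold_change(15, 4, 0.7, 0.2)   # ~21-fold enhanced
fold_change <- function(parent_mean, parent_sd, variant_mean, variant_sd,
                        del_mean = NULL, del_sd = NULL, clamp = NULL) {
  all_act <- c(parent_mean, variant_mean, del_mean)
  if (is.null(clamp)) {
    pos <- all_act[!is.na(all_act) & all_act > 0]
    if (length(pos) == 0) abort("All activities are zero; cannot clamp")
    clamp <- min(pos) / 2
  }
  if (clamp <= 0) abort("clamp must be positive")
  p <- ifelse(parent_mean <= 0, clamp, parent_mean)
  v <- ifelse(variant_mean <= 0, clamp, variant_mean)
  at_min <- if (is.null(del_mean)) {
    NA
  } else {
    !is_changed(variant_mean, variant_sd, del_mean,
                if (is.null(del_sd)) 0 else del_sd)
  }
  tibble(
    value = p / v,
    changed = is_changed(parent_mean, parent_sd, variant_mean, variant_sd),
    at_min = at_min
  )
}

#' Thresholds for behavior classification
#'
#' All tunable parameters of the rank-order decision procedure, with
#' defaults calibrated to the published behavior codes: the neutral band is
#' 2-fold, the near-neutral band 5-fold, a full rheostat spans more than 2
#' orders of magnitude, rheostat character starts beyond the 5-fold band
#' (`log10(5)`, about 0.7), clusters are separated by gaps of at least 0.7
#' log10 units, and progressivity requires that no single adjacent gap
#' exceed 0.62 of the span.
#'
#' @param min_substitutions Fewer scored substitutions than this yields the
#'   insufficient-data code `"#"`.
#' @param neutral_fold Fold-change band for a neutral substitution.
#' @param n_fold Fold-change band for the near-neutral code `"n"`.
#' @param rheostat_span Span (log10) above which a rheostat is `"R"`.
#' @param r_span_min Span (log10) above which a position has rheostat
#'   character at all.
#' @param nr_span_max Span (log10) at or below which a weak rheostat is the
#'   borderline code `"n/r"` (the ~5-9-fold window).
#' @param cluster_gap Minimum log10 gap separating occupied clusters.
#' @param gap_fraction Largest adjacent gap, as a fraction of the span,
#'   compatible with a progressive (`"R"`) call.
#' @param min_at_min_hybrid Minimum number of substitutions at the DEL floor
#'   for a toggle hybrid (`"R+T"`/`"r+T"`) call.
#' @return A named list of thresholds.
#' @export
behavior_config <- function(min_substitutions = 5,
                            neutral_fold = 2,
                            n_fold = 5,
                            rheostat_span = 2,
                            r_span_min = log10(5),
                            nr_span_max = 0.95,
                            cluster_gap = 0.7,
                            gap_fraction = 0.62,
                            min_at_min_hybrid = 3) {
  list(
    min_substitutions = min_substitutions,
    neutral_fold = neutral_fold,
    n_fold = n_fold,
    rheostat_span = rheostat_span,
    r_span_min = r_span_min,
    nr_span_max = nr_span_max,
    cluster_gap = cluster_gap,
    gap_fraction = gap_fraction,
    min_at_min_hybrid = min_at_min_hybrid
  )
}

# Split sorted log10 activities into clusters at gaps >= cluster_gap.
# Returns an integer cluster index per (sorted-order) element.
split_clusters <- function(log_act_sorted, cluster_gap) {
  if (length(log_act_sorted) == 1) return(1L)
  gaps <- diff(log_act_sorted)
  cumsum(c(TRUE, gaps >= cluster_gap))
}

#' Classify one (homolog, position) profile
#'
#' Applies the rank-order decision procedure to the substitution outcomes
#' at one position of one homolog: insufficient-data gate, all-at-MIN gate
#' (`"x"`), neutral gates (`"N"`, `"n"`), cluster detection (`"T"`, `"3"`),
#' toggle/neutral hybrids (`"R+T"`, `"r+T"`, `"N+r"`), then span measurement
#' (`"R"`, `"r"`, `"n/r"`). A substitution is "neutral" when it is within
#' 2-fold of the parent or not a change by the dual criterion, and "at MIN"
#' when it is not a change relative to the DEL control.
#'
#' @param activities,sds Variant mean activities and standard deviations
#'   (Miller units), one scored substitution each.
#' @param parent_mean,parent_sd Parent activity.
#' @param del_mean,del_sd DEL (no-repressor) control.
#' @param cfg A [behavior_config()].
#' @param clamp Replacement for zero activities (see [fold_change()]).
#' @return A one-row tibble: `code`, `n_substitutions`, `span_log10`,
#'   `max_gap_frac`, `n_clusters`, `n_at_min`, `n_neutral`.
#' @export
classify_position <- function(activities, sds, parent_mean, parent_sd,
                              del_mean, del_sd, cfg = behavior_config(),
                              clamp = NULL) {
  n <- length(activities)
  if (is.null(clamp)) {
    pos <- c(activities, parent_mean, del_mean)
    pos <- pos[pos > 0]
    clamp <- if (length(pos) > 0) min(pos) / 2 else 1e-6
  }
  act <- ifelse(activities <= 0, clamp, activities)
  res <- function(code, span = NA_real_, gap_frac = NA_real_,
                  n_clusters = NA_integer_, n_at_min = NA_integer_,
                  n_neutral = NA_integer_) {
    tibble(
      code = code, n_substitutions = n, span_log10 = span,
      max_gap_frac = gap_frac, n_clusters = n_clusters,
      n_at_min = n_at_min, n_neutral = n_neutral
    )
  }
  if (n < cfg$min_substitutions) return(res("#"))

  fc <- fold_change(parent_mean, parent_sd, activities, sds,
                    del_mean, del_sd, clamp = clamp)
  at_min <- fc$at_min
  neutral <- !at_min &
    ((fc$value >= 1 / cfg$neutral_fold & fc$value <= cfg$neutral_fold) |
       !fc$changed)
  nband <- neutral |
    (!at_min & fc$value >= 1 / cfg$n_fold & fc$value <= cfg$n_fold)
  n_min <- sum(at_min)
  n_neu <- sum(neutral)

  ord <- order(act)
  la <- log10(act)[ord]
  span <- la[n] - la[1]
  gaps <- if (n > 1) diff(la) else 0
  gap_frac <- if (span > 0) max(gaps) / span else 0
  cl <- split_clusters(la, cfg$cluster_gap)
  n_cl <- max(cl)
  finish <- function(code) res(code, span, gap_frac, n_cl, n_min, n_neu)

  if (n_min == n) return(finish("x"))
  if (n_neu == n) return(finish("N"))
  if (all(nband)) return(finish("n"))

  # cluster-structure codes: a toggle is two occupied levels (parent-like
  # and MIN) with an empty intermediate zone; three levels give "3"
  if (n_cl == 2) {
    upper <- ord[cl == 2]
    lower <- ord[cl == 1]
    if (all(at_min[upper]) && all(neutral[lower])) return(finish("T"))
  }
  if (n_cl == 3) return(finish("3"))

  # hybrids: a MIN subset plus a rheostatic remainder, or a neutral
  # majority plus a changed remainder
  if (n_min >= cfg$min_at_min_hybrid && n_min < n) {
    rem <- act[!at_min]
    if (length(rem) >= 2) {
      span_rem <- log10(max(rem) / min(rem))
      if (all(neutral[!at_min])) return(finish("T"))
      if (span_rem > cfg$rheostat_span) return(finish("R+T"))
      if (span_rem > cfg$r_span_min) return(finish("r+T"))
    }
  }
  if (n_neu >= n / 2 && sum(!neutral & !at_min) >= 2 && n_min == 0) {
    return(finish("N+r"))
  }

  if (span > cfg$rheostat_span && gap_frac <= cfg$gap_fraction) {
    return(finish("R"))
  }
  if (span > cfg$rheostat_span) return(finish("r"))
  if (span > cfg$nr_span_max) return(finish("r"))
  if (span > cfg$r_span_min) return(finish("n/r"))
  finish("n")
}

#' Classify every (homolog, position) in a dataset
#'
#' Runs [classify_position()] over all scored substitutions (active
#' condition only, exclusions removed, parent self-substitutions dropped)
#' and returns one behavior call per (homolog, position).
#'
#' @param measurements A measurement tibble (see [read_variant_table()]).
#' @param contexts A homolog context tibble (see [validate_contexts()]).
#' @param cfg A [behavior_config()].
#' @return A tibble with columns `homolog`, `position`, `code`,
#'   `n_substitutions`, `span_log10`, `max_gap_frac`, `n_clusters`,
#'   `n_at_min`, `n_neutral`.
#' @export
classify_behavior <- function(measurements, contexts,
                              cfg = behavior_config()) {
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
    )
  scored %>%
    dplyr::group_by(.data$homolog, .data$position) %>%
    dplyr::group_modify(function(d, key) {
      classify_position(
        d$mean_miller, d$sd_miller,
        d$parent_mean[1], d$parent_sd[1],
        d$del_mean[1], d$del_sd[1],
        cfg = cfg, clamp = clamp
      )
    }) %>%
    dplyr::ungroup()
}

#' Percentage of enhancing substitutions
#'
#' The published formula: `100 * enhanced / (total_variants -
#' parents_mutated)`, rounded half-up to an integer percent (each parent
#' protein is counted as one of the amino acids in the total, so the
#' denominator is the number of true substitutions). Undefined (NA) when
#' the denominator is zero.
#'
#' @param enhanced Count of substitutions enhancing repression beyond the
#'   fold threshold.
#' @param total_variants Total variants at the position, parents included.
#' @param parents_mutated Number of parent proteins mutated at the position.
#' @return Integer percent (vectorized).
#' @export
#' @examples
#' enhancement_percent(21, 126, 13)  # 19
enhancement_percent <- function(enhanced, total_variants, parents_mutated) {
  denom <- total_variants - parents_mutated
  out <- ifelse(denom > 0,
                round_half_up(100 * enhanced / denom),
                NA_real_)
  as.integer(out)
}

#' Per-position enhancement statistics
#'
#' Counts, per position across all homologs, the substitutions that enhance
#' repression more than `fold_threshold`-fold relative to their own parent,
#' and applies [enhancement_percent()]. Each parent protein is counted once
#' in `total_variants` at each position it was mutated.
#'
#' @inheritParams classify_behavior
#' @param fold_threshold Enhancement counts when `parent/variant` exceeds
#'   this ratio (default 10, the published choice).
#' @return A tibble with columns `position`, `total_variants`,
#'   `enhanced_gt10`, `pct_enhanced`, `parents_mutated`, `parents_enhanced`.
#' @export
enhancement_table <- function(measurements, contexts, fold_threshold = 10) {
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
      fold = ifelse(.data$parent_mean <= 0, clamp, .data$parent_mean) /
        ifelse(.data$mean_miller <= 0, clamp, .data$mean_miller),
      enhanced = .data$fold > fold_threshold
    )
  scored %>%
    dplyr::group_by(.data$position) %>%
    dplyr::summarise(
      parents_mutated = dplyr::n_distinct(.data$homolog),
      total_variants = dplyr::n() + .data$parents_mutated[1],
      enhanced_gt10 = sum(.data$enhanced),
      parents_enhanced = dplyr::n_distinct(.data$homolog[.data$enhanced]),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      pct_enhanced = enhancement_percent(
        .data$enhanced_gt10, .data$total_variants, .data$parents_mutated
      )
    ) %>%
    dplyr::select(
      "position", "total_variants", "enhanced_gt10", "pct_enhanced",
      "parents_mutated", "parents_enhanced"
    )
}

#' Flag variants with altered allosteric response
#'
#' A variant alters allosteric response when its relationship between the
#' effector conditions differs from its parent's by the dual change
#' criterion. When the parent fully induces (its non-readout-condition
#' activity is indistinguishable from the DEL control), the variant is
#' flagged if its non-readout activity *is* distinguishable from DEL.
#' Otherwise the parent's induced-state ratio is applied to the variant's
#' readout value and compared with its measured non-readout value. Variants
#' missing either condition get `NA` (undetermined), never `FALSE`.
#'
#' @inheritParams classify_behavior
#' @return A tibble with one row per (homolog, position, substitution):
#'   `homolog`, `position`, `wt_aa`, `sub_aa`, `allosteric_change`
#'   (logical, `NA` when undetermined).
#' @export
allosteric_change_flags <- function(measurements, contexts) {
  contexts <- validate_contexts(contexts)
  wide <- measurements %>%
    dplyr::filter(!.data$excluded, .data$sub_aa != .data$wt_aa) %>%
    dplyr::inner_join(contexts, by = "homolog") %>%
    dplyr::mutate(role = ifelse(.data$condition == .data$active_condition,
                                "active", "inactive")) %>%
    dplyr::select(
      "homolog", "position", "wt_aa", "sub_aa", "role",
      "mean_miller", "sd_miller",
      "parent_mean", "parent_sd", "parent_inactive_mean",
      "parent_inactive_sd", "del_mean", "del_sd"
    ) %>%
    tidyr::pivot_wider(
      names_from = "role",
      values_from = c("mean_miller", "sd_miller")
    )
  for (col in c("mean_miller_active", "sd_miller_active",
                "mean_miller_inactive", "sd_miller_inactive")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide %>%
    dplyr::mutate(
      parent_induces_to_del = !is_changed(
        .data$parent_inactive_mean, .data$parent_inactive_sd,
        .data$del_mean, .data$del_sd
      ),
      induction_ratio = .data$parent_inactive_mean / .data$parent_mean,
      allosteric_change = dplyr::case_when(
        is.na(.data$mean_miller_active) |
          is.na(.data$mean_miller_inactive) ~ NA,
        parent_induces_to_del ~ is_changed(
          .data$mean_miller_inactive, .data$sd_miller_inactive,
          .data$del_mean, .data$del_sd
        ),
        TRUE ~ is_changed(
          .data$mean_miller_inactive, .data$sd_miller_inactive,
          .data$mean_miller_active * .data$induction_ratio,
          .data$sd_miller_active * .data$induction_ratio
        )
      )
    ) %>%
    dplyr::select(
      "homolog", "position", "wt_aa", "sub_aa", "allosteric_change"
    )
}
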