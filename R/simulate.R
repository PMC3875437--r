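#' Default ground-truth position classes for simulation
#'
#' Twelve scanned linker positions with a class mixture echoing the
#' published behavior table: mostly rheostats, two toggles, two neutral
#' positions and one dead position. `span_log10` applies to rheostat
#' classes, `abolished_fraction` to toggles.
#'
#' @return A tibble: `position`, `true_class`, `span_log10`,
#'   `abolished_fraction`.
#' @export
default_positions <- function() {
  tibble(
    position = c("46", "48", "50", "51", "52", "54",
                 "55", "58", "59", "60", "61", "62"),
    true_class = c("R", "R", "T", "R", "R", "R",
                   "N", "T", "R", "N", "R", "x"),
    span_log10 = c(3, 3, NA, 3, 3, 3, NA, NA, 3, NA, 3, NA),
    abolished_fraction = c(NA, NA, 0.5, NA, NA, NA,
                           NA, 0.5, NA, NA, NA, NA)
  )
}

#' Simulation configuration
#'
#' Ground truth and noise parameters for [simulate_dataset()]. Defaults
#' emulate the published study conditions: 14 homolog parents with their
#' published repression values, 12 scanned positions, about 10 amino-acid
#' substitutions per position (the scans typically yielded 8-12), replicate
#' measurements with multiplicative lognormal noise, and ~30 planted
#' variants with altered allosteric response among the ~1700 variants.
#'
#' @param seed Integer seed; a fixed seed gives identical output.
#' @param homologs Homolog panel (see [default_homologs()]).
#' @param positions Position classes (see [default_positions()]); classes
#'   `R`, `r`, `T`, `N`, `n`, `x`, `three_state` are supported.
#' @param substitutions_per_position Substitutions simulated per
#'   (homolog, position).
#' @param noise_cv Coefficient of variation of replicate measurements
#'   (lognormal, multiplicative); 0 gives exact measurements.
#' @param n_replicates Replicates averaged per reported measurement.
#' @param n_allosteric Number of variants planted with an altered
#'   allosteric response (they fail to induce).
#' @param anti_met_bias If `TRUE`, methionine substitutions are sampled
#'   with reduced weight, mirroring the codon bias of NNN mutagenesis.
#' @return A validated config list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       homologs = default_homologs(),
                       positions = default_positions(),
                       substitutions_per_position = 10,
                       noise_cv = 0.2,
                       n_replicates = 4,
                       n_allosteric = 30,
                       anti_met_bias = FALSE) {
  cfg <- structure(
    list(
      seed = as.integer(seed), homologs = as_tibble(homologs),
      positions = as_tibble(positions),
      substitutions_per_position = as.integer(substitutions_per_position),
      noise_cv = noise_cv, n_replicates = as.integer(n_replicates),
      n_allosteric = as.integer(n_allosteric),
      anti_met_bias = isTRUE(anti_met_bias)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  known <- c("R", "r", "T", "N", "n", "x", "three_state")
  bad <- setdiff(cfg$positions$true_class, known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown true_class value(s): %s",
                  paste(bad, collapse = ", ")))
  }
  r_rows <- cfg$positions$true_class == "R"
  if (any(r_rows & (is.na(cfg$positions$span_log10) |
                    cfg$positions$span_log10 <= 2))) {
    abort("Class R requires span_log10 > 2")
  }
  if (any(cfg$homologs$parent_mean <= 0) ||
      any(cfg$homologs$del_mean <= 0)) {
    abort("All parent and DEL activities must be positive")
  }
  if (any(cfg$homologs$del_mean <= cfg$homologs$parent_mean)) {
    abort("del_mean must exceed parent_mean for every homolog")
  }
  if (cfg$noise_cv < 0) abort("noise_cv must be non-negative")
  if (cfg$substitutions_per_position < 1 || cfg$n_replicates < 1) {
    abort("substitutions_per_position and n_replicates must be >= 1")
  }
  invisible(cfg)
}

# Stratified log-uniform draw: one uniform per equal log-width stratum,
# returned in random order. Guarantees the realized range covers at least
# (n-2)/n of the interval and no adjacent gap exceeds 2/n of it.
stratified_log_uniform <- function(n, lo, hi) {
  llo <- log10(lo)
  lhi <- log10(hi)
  u <- (seq_len(n) - stats::runif(n)) / n
  sample(10^(llo + u * (lhi - llo)))
}

sample_true_activities <- function(class, k, parent, del, span,
                                   abolished_fraction) {
  switch(class,
    R = ,
    r = {
      span <- if (is.na(span)) ifelse(class == "R", 3, 1.5) else span
      lo <- parent / 10^(span / 2)
      hi <- min(parent * 10^(span / 2), del)
      stratified_log_uniform(k, lo, hi)
    },
    T = {
      frac <- if (is.na(abolished_fraction)) 0.5 else abolished_fraction
      n_off <- max(1L, min(k - 1L, round(frac * k)))
      vals <- c(rep(del, n_off),
                parent * 10^stats::runif(k - n_off, -0.1, 0.1))
      sample(vals)
    },
    N = {
      # lognormal within the 2-fold band (truncated at +/- 0.25 log10)
      off <- stats::rnorm(k, 0, 0.08)
      while (any(abs(off) > 0.25)) {
        idx <- abs(off) > 0.25
        off[idx] <- stats::rnorm(sum(idx), 0, 0.08)
      }
      parent * 10^off
    },
    n = {
      # 5-fold band; stratification guarantees excursions beyond 2-fold
      stratified_log_uniform(k, parent / 4.8, parent * 4.8)
    },
    x = rep(del, k),
    three_state = {
      n3 <- max(1L, k %/% 3L)
      vals <- c(rep(parent, k - 2L * n3),
                rep(sqrt(parent * del), n3), rep(del, n3))
      sample(vals)
    },
    abort(sprintf("Unknown class '%s'", class))
  )
}

measure <- function(true, cv, n_reps) {
  if (cv == 0) {
    return(tibble(mean = true, sd = 0,
                  n = as.integer(n_reps)))
  }
  sigma <- sqrt(log(1 + cv^2))
  reps <- matrix(
    true * exp(stats::rnorm(length(true) * n_reps,
                            -sigma^2 / 2, sigma)),
    nrow = length(true)
  )
  tibble(
    mean = rowMeans(reps),
    sd = apply(reps, 1, stats::sd),
    n = as.integer(n_reps)
  )
}

#' Simulate a parallel-mutagenesis variant dataset
#'
#' Generates a variant activity table with known ground truth. True variant
#' activities are drawn per position class (stratified log-uniform over the
#' configured span for rheostats, a parent-level/DEL-level mixture with no
#' intermediates for toggles, a truncated lognormal within the 2-fold band
#' for neutral positions, the DEL floor for dead positions, and
#' parent/geometric-midpoint/DEL levels for three-state positions).
#' Reported means and sds come from `n_replicates` lognormal replicate
#' draws with coefficient of variation `noise_cv`; at `noise_cv = 0`
#' measurements equal the true values exactly. Each homolog's parent and
#' DEL control are measured the same way. In the non-readout effector
#' condition every variant and parent induces to the DEL level, except the
#' `n_allosteric` planted variants, which keep their readout-condition
#' activity (no allosteric response).
#'
#' @param cfg A [sim_config()].
#' @return A list: `measurements` (variant table, both conditions, parent
#'   rows included), `contexts` (measured homolog contexts), `truth`
#'   (`homolog`, `position`, `true_class`), `variant_truth` (per-variant
#'   true activities and planted allosteric flags), `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  withr::with_seed(cfg$seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  k <- cfg$substitutions_per_position
  aa <- amino_acids()
  grid <- tidyr::expand_grid(
    homolog = cfg$homologs$homolog,
    position = cfg$positions$position
  ) %>%
    dplyr::left_join(cfg$positions, by = "position") %>%
    dplyr::left_join(cfg$homologs, by = "homolog")

  variants <- purrr::pmap_dfr(grid, function(...) {
    row <- list(...)
    wt <- sample(aa, 1)
    pool <- setdiff(aa, wt)
    w <- rep(1, length(pool))
    if (cfg$anti_met_bias) w[pool == "M"] <- 0.25
    subs <- sample(pool, k, prob = w)
    true_act <- sample_true_activities(
      row$true_class, k, row$parent_mean, row$del_mean,
      row$span_log10, row$abolished_fraction
    )
    tibble(
      homolog = row$homolog, position = row$position,
      wt_aa = wt, sub_aa = subs, true_active = true_act,
      true_class = row$true_class, del_mean_true = row$del_mean,
      active_condition = row$active_condition
    )
  })

  # plant allosteric changes on variants far enough below DEL that the
  # altered response is detectable by the dual criterion
  eligible <- which(variants$true_active <= variants$del_mean_true / 4 &
                      variants$true_class != "x")
  n_allo <- min(cfg$n_allosteric, length(eligible))
  if (n_allo < cfg$n_allosteric) {
    warn(sprintf("Only %d variants eligible for allosteric planting", n_allo))
  }
  planted <- if (n_allo > 0) sample(eligible, n_allo) else integer(0)
  variants$allosteric <- FALSE
  variants$allosteric[planted] <- TRUE
  variants$true_inactive <- ifelse(variants$allosteric,
                                   variants$true_active,
                                   variants$del_mean_true)

  long <- dplyr::bind_rows(
    variants %>% dplyr::mutate(condition = .data$active_condition,
                               true_value = .data$true_active),
    variants %>% dplyr::mutate(condition = other_condition(.data$active_condition),
                               true_value = .data$true_inactive)
  )
  m <- measure(long$true_value, cfg$noise_cv, cfg$n_replicates)
  measurements <- long %>%
    dplyr::mutate(mean_miller = m$mean, sd_miller = m$sd, n_reps = m$n,
                  excluded = FALSE) %>%
    dplyr::select("homolog", "position", "wt_aa", "sub_aa", "condition",
                  "mean_miller", "sd_miller", "n_reps", "excluded")

  # parent self-substitution rows, one per (homolog, position, condition)
  parent_grid <- variants %>%
    dplyr::distinct(.data$homolog, .data$position, .data$wt_aa,
                    .data$active_condition) %>%
    dplyr::left_join(
      dplyr::select(cfg$homologs, "homolog", "parent_mean", "del_mean"),
      by = "homolog"
    )
  parent_long <- dplyr::bind_rows(
    parent_grid %>% dplyr::mutate(condition = .data$active_condition,
                                  true_value = .data$parent_mean),
    parent_grid %>% dplyr::mutate(condition = other_condition(.data$active_condition),
                                  true_value = .data$del_mean)
  )
  pm <- measure(parent_long$true_value, cfg$noise_cv, cfg$n_replicates)
  parent_rows <- parent_long %>%
    dplyr::mutate(sub_aa = .data$wt_aa, mean_miller = pm$mean,
                  sd_miller = pm$sd, n_reps = pm$n, excluded = FALSE) %>%
    dplyr::select("homolog", "position", "wt_aa", "sub_aa", "condition",
                  "mean_miller", "sd_miller", "n_reps", "excluded")

  # measured homolog contexts
  pmeas <- measure(cfg$homologs$parent_mean, cfg$noise_cv, cfg$n_replicates)
  dmeas <- measure(cfg$homologs$del_mean, cfg$noise_cv, cfg$n_replicates)
  imeas <- measure(cfg$homologs$del_mean, cfg$noise_cv, cfg$n_replicates)
  contexts <- cfg$homologs %>%
    dplyr::mutate(
      parent_mean = pmeas$mean, parent_sd = pmeas$sd,
      del_mean = dmeas$mean, del_sd = dmeas$sd,
      parent_inactive_mean = imeas$mean, parent_inactive_sd = imeas$sd
    )

  list(
    measurements = dplyr::bind_rows(measurements, parent_rows),
    contexts = contexts,
    truth = variants %>%
      dplyr::distinct(.data$homolog, .data$position, .data$true_class),
    variant_truth = variants %>%
      dplyr::select("homolog", "position", "wt_aa", "sub_aa",
                    "true_active", "true_inactive", "allosteric"),
    config = cfg
  )
}

#' MSA simulation configuration
#'
#' @param seed Integer seed.
#' @param n_sequences Number of family sequences (the reference is added on
#'   top).
#' @param motif_fraction Probability that a sequence carries the planted
#'   motif (each sequence draws independently, so the realized count is
#'   binomial).
#' @param concentration Dirichlet concentration of family column
#'   compositions; larger values give flatter columns and higher entropy.
#' @param subfamily_fraction Fraction of sequences assigned to the
#'   low-diversity subfamily (drawn from motif carriers).
#' @param consensus_weight Probability that a subfamily sequence carries
#'   its column consensus letter.
#' @param gap_rate Per-residue gap probability outside motif constraints.
#' @param positions Reference position labels (alignment columns).
#' @param motif Named vector of planted motif constraints (position ->
#'   letter), default [ypal_motif()].
#' @param reference_id Identifier of the ungapped reference sequence.
#' @return A config list of class `sim_msa_config`.
#' @export
sim_msa_config <- function(seed = 1, n_sequences = 300,
                           motif_fraction = 0.6, concentration = 1,
                           subfamily_fraction = 0.15,
                           consensus_weight = 0.9, gap_rate = 0.03,
                           positions = as.character(45:62),
                           motif = ypal_motif(),
                           reference_id = "LacI_ref") {
  if (!all(names(motif) %in% positions)) {
    abort("Motif positions must be among the simulated positions")
  }
  if (motif_fraction < 0 || motif_fraction > 1) {
    abort("motif_fraction must be in [0, 1]")
  }
  structure(
    list(
      seed = as.integer(seed), n_sequences = as.integer(n_sequences),
      motif_fraction = motif_fraction, concentration = concentration,
      subfamily_fraction = subfamily_fraction,
      consensus_weight = consensus_weight, gap_rate = gap_rate,
      positions = as.character(positions), motif = motif,
      reference_id = reference_id
    ),
    class = "sim_msa_config"
  )
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Simulate a family alignment with a planted motif and subfamily
#'
#' Generates an aligned sequence family over the configured positions.
#' Each column of the family draws a categorical composition from a
#' symmetric Dirichlet; a `motif_fraction` of sequences carry the planted
#' motif letters exactly (non-carriers never draw a full motif, so motif
#' membership in the output equals the ground truth); a designated
#' subfamily is generated at low diversity by concentrating each column on
#' its consensus letter. Gaps are introduced at `gap_rate` outside motif
#' constraints. The reference sequence is ungapped and carries the motif.
#'
#' @param cfg A [sim_msa_config()].
#' @return A list: `alignment` (a [ref_alignment()]), `truth` (tibble `id`,
#'   `has_motif`, `in_subfamily`), `config`.
#' @export
simulate_msa <- function(cfg = sim_msa_config()) {
  withr::with_seed(cfg$seed, simulate_msa_impl(cfg))
}

simulate_msa_impl <- function(cfg) {
  aa <- amino_acids()
  npos <- length(cfg$positions)
  n <- cfg$n_sequences
  motif_pos <- names(cfg$motif)

  family_comp <- lapply(seq_len(npos), function(j) {
    rdirichlet1(rep(cfg$concentration, length(aa)))
  })
  consensus <- vapply(family_comp, function(p) aa[which.max(p)],
                      character(1))

  has_motif <- stats::runif(n) < cfg$motif_fraction
  n_sub <- round(cfg$subfamily_fraction * n)
  motif_idx <- which(has_motif)
  in_subfamily <- rep(FALSE, n)
  if (n_sub > 0 && length(motif_idx) > 0) {
    in_subfamily[sample(motif_idx, min(n_sub, length(motif_idx)))] <- TRUE
  }

  seq_matrix <- matrix("", nrow = n, ncol = npos)
  for (j in seq_len(npos)) {
    pos <- cfg$positions[j]
    is_motif_col <- pos %in% motif_pos
    motif_letter <- if (is_motif_col) cfg$motif[[pos]] else NA_character_
    p <- family_comp[[j]]
    pool <- aa
    if (is_motif_col) {
      keep <- pool != motif_letter
      pool <- pool[keep]
      p <- p[keep] / sum(p[keep])
    }
    col <- character(n)
    fam <- !in_subfamily
    col[fam] <- sample(pool, sum(fam), replace = TRUE, prob = p)
    if (any(in_subfamily)) {
      cons <- if (is_motif_col && !is.na(motif_letter) &&
                  consensus[j] == motif_letter) pool[1] else consensus[j]
      use_cons <- stats::runif(sum(in_subfamily)) < cfg$consensus_weight
      sub_col <- ifelse(use_cons, cons,
                        sample(pool, sum(in_subfamily), replace = TRUE,
                               prob = p))
      col[in_subfamily] <- sub_col
    }
    if (is_motif_col) col[has_motif] <- motif_letter
    gap_ok <- if (is_motif_col) !has_motif else rep(TRUE, n)
    gaps <- gap_ok & stats::runif(n) < cfg$gap_rate
    col[gaps] <- "-"
    seq_matrix[, j] <- col
  }

  ref_letters <- vapply(seq_len(npos), function(j) {
    pos <- cfg$positions[j]
    if (pos %in% motif_pos) cfg$motif[[pos]] else consensus[j]
  }, character(1))

  ids <- c(cfg$reference_id, sprintf("seq%04d", seq_len(n)))
  seqs <- c(paste(ref_letters, collapse = ""),
            apply(seq_matrix, 1, paste, collapse = ""))
  aln <- ref_alignment(ids, seqs, cfg$reference_id,
                       reference_offset = as.integer(cfg$positions[1]))
  truth <- tibble(
    id = ids,
    has_motif = c(TRUE, has_motif),
    in_subfamily = c(FALSE, in_subfamily)
  )
  list(alignment = aln, truth = truth, config = cfg)
}

#' Compare behavior calls against simulation ground truth
#'
#' Joins a behavior-call table with a ground-truth class table and reports
#' the confusion matrix, overall accuracy and per-class recall. Keys not
#' present on both sides are an error (listing the orphans), so silent
#' partial comparisons cannot happen.
#'
#' @param calls Output of [classify_behavior()] (needs `homolog`,
#'   `position`, `code`).
#' @param truth Tibble with `homolog`, `position`, `true_class`.
#' @return An object of class `recovery_report`: list with `confusion`
#'   (tibble `true_class`, `code`, `n`), `per_class` (recall per true
#'   class), `accuracy`, `n`.
#' @export
recovery_report <- function(calls, truth) {
  key_calls <- paste(calls$homolog, calls$position)
  key_truth <- paste(truth$homolog, truth$position)
  orphans <- c(setdiff(key_calls, key_truth), setdiff(key_truth, key_calls))
  if (length(orphans) > 0) {
    abort(sprintf("Keys not shared by calls and truth: %s",
                  paste(utils::head(orphans, 5), collapse = "; ")))
  }
  joined <- dplyr::inner_join(
    dplyr::select(calls, "homolog", "position", "code"),
    dplyr::select(truth, "homolog", "position", "true_class"),
    by = c("homolog", "position")
  )
  # a simulated three_state position is called "3" by the classifier
  joined <- joined %>%
    dplyr::mutate(true_code = ifelse(.data$true_class == "three_state",
                                     "3", .data$true_class))
  confusion <- joined %>%
    dplyr::count(.data$true_class, .data$code, name = "n")
  per_class <- joined %>%
    dplyr::group_by(.data$true_class) %>%
    dplyr::summarise(
      n = dplyr::n(),
      recall = mean(.data$code == .data$true_code),
      .groups = "drop"
    )
  structure(
    list(
      confusion = confusion,
      per_class = per_class,
      accuracy = mean(joined$code == joined$true_code),
      n = nrow(joined)
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> accuracy %.3f over %d (homolog, position) cells\n",
              x$accuracy, x$n))
  print(x$per_class)
  invisible(x)
}

#' @rdname recovery_report
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @export
tidy.recovery_report <- function(x, ...) {
  x$confusion
}

#' @rdname recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, n = x$n,
         n_classes = nrow(x$per_class))
}
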