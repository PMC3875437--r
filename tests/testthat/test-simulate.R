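test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_dataset(sim_config(seed = 17))
  b <- simulate_dataset(sim_config(seed = 17))
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$contexts, b$contexts)
  expect_identical(a$variant_truth, b$variant_truth)
  c <- simulate_dataset(sim_config(seed = 18))
  expect_false(identical(a$measurements$mean_miller,
                         c$measurements$mean_miller))
  m1 <- simulate_msa(sim_msa_config(seed = 4))
  m2 <- simulate_msa(sim_msa_config(seed = 4))
  expect_identical(m1$alignment$sequences, m2$alignment$sequences)
})

test_that("zero noise gives exact measurements", {
  sim <- simulate_dataset(sim_config(seed = 3, noise_cv = 0))
  subs <- sim$measurements[sim$measurements$sub_aa !=
                             sim$measurements$wt_aa, ]
  joined <- dplyr::inner_join(
    subs, sim$variant_truth,
    by = c("homolog", "position", "wt_aa", "sub_aa")
  )
  active <- joined$condition == "minus_effector" &
    joined$homolog %in%
      sim$contexts$homolog[sim$contexts$active_condition ==
                             "minus_effector"]
  expect_equal(joined$mean_miller[active], joined$true_active[active])
  expect_true(all(joined$sd_miller == 0))
})

test_that("ground-truth class frequencies match the configuration", {
  cfg <- sim_config(seed = 2)
  sim <- simulate_dataset(cfg)
  per_pos <- dplyr::distinct(sim$truth, position, true_class)
  expect_equal(
    dplyr::arrange(per_pos, position),
    dplyr::arrange(cfg$positions[, c("position", "true_class")], position)
  )
  # every (homolog, position) cell is present
  expect_equal(nrow(sim$truth),
               nrow(cfg$homologs) * nrow(cfg$positions))
})

test_that("rheostat true values realize their configured span", {
  # stratified log-uniform sampling guarantees the realized range of 10
  # draws covers well over 2 orders of a 3-order span
  sim <- simulate_dataset(sim_config(seed = 29, noise_cv = 0))
  r_pos <- sim$config$positions$position[
    sim$config$positions$true_class == "R"]
  spans <- sim$variant_truth |>
    dplyr::filter(position %in% r_pos) |>
    dplyr::group_by(homolog, position) |>
    dplyr::summarise(span = log10(max(true_active) / min(true_active)),
                     .groups = "drop")
  expect_true(all(spans$span > 2))
})

test_that("invalid configurations are rejected before any output", {
  expect_error(sim_config(positions = tibble::tibble(
    position = "46", true_class = "R", span_log10 = 1.5,
    abolished_fraction = NA
  )), "span_log10 > 2")
  expect_error(sim_config(noise_cv = -0.1), "non-negative")
  expect_error(sim_config(positions = tibble::tibble(
    position = "46", true_class = "Z", span_log10 = NA,
    abolished_fraction = NA
  )), "Unknown true_class")
  bad_homologs <- dplyr::mutate(default_homologs(), del_mean = 0.01)
  expect_error(sim_config(homologs = bad_homologs), "del_mean")
})

test_that("simulated alignments plant the motif at the configured rate", {
  cfg <- sim_msa_config(seed = 8, n_sequences = 500, motif_fraction = 0.6)
  sim <- simulate_msa(cfg)
  sub <- subset_by_motif(sim$alignment, ypal_motif())
  # subset membership equals ground truth exactly
  expect_setequal(sub$sequences$id, sim$truth$id[sim$truth$has_motif])
  # realized count is binomial around 300 (within 5 sd of the mean)
  n_carriers <- sum(sim$truth$has_motif) - 1  # reference always carries it
  expect_lt(abs(n_carriers - 300), 5 * sqrt(500 * 0.6 * 0.4))
})

test_that("column entropy rises with the Dirichlet concentration", {
  mean_entropy <- vapply(c(0.05, 0.2, 1, 5, 20), function(conc) {
    sim <- simulate_msa(sim_msa_config(seed = 6, n_sequences = 200,
                                       concentration = conc))
    non_motif <- setdiff(sim$alignment$column_map$position,
                         names(ypal_motif()))
    mean(entropy_table(sim$alignment, non_motif)$entropy)
  }, numeric(1))
  expect_true(all(diff(mean_entropy) > 0))
})

test_that("recovery reports handle the degenerate cases", {
  calls <- tibble::tibble(homolog = "H1", position = c("46", "48"),
                          code = c("R", "N"))
  truth <- tibble::tibble(homolog = "H1", position = c("46", "48"),
                          true_class = c("R", "N"))
  expect_equal(recovery_report(calls, truth)$accuracy, 1)
  all_hash <- dplyr::mutate(calls, code = "#")
  rep0 <- recovery_report(all_hash, truth)
  expect_equal(rep0$accuracy, 0)
  expect_equal(sum(rep0$confusion$n), 2)
  # mismatched keys error with the orphans listed
  expect_error(
    recovery_report(calls, dplyr::mutate(truth, position = c("46", "99"))),
    "99"
  )
  # broom-style accessors
  expect_equal(glance(rep0)$accuracy, 0)
  expect_true(all(c("true_class", "code", "n") %in% names(tidy(rep0))))
})

test_that("end-to-end recovery is perfect at zero noise", {
  sim <- simulate_dataset(sim_config(seed = 41, noise_cv = 0))
  calls <- classify_behavior(sim$measurements, sim$contexts)
  expect_equal(recovery_report(calls, sim$truth)$accuracy, 1)
})

test_that("all simulated classes are recovered at zero noise", {
  pos <- tibble::tibble(
    position = c("46", "48", "50", "51", "52", "54"),
    true_class = c("R", "r", "T", "N", "x", "three_state"),
    span_log10 = c(3, 1.5, NA, NA, NA, NA),
    abolished_fraction = c(NA, NA, 0.5, NA, NA, NA)
  )
  # three-state levels (parent, geometric midpoint, DEL) are separable
  # only when the parent represses far below DEL; use the tight parents
  tight <- dplyr::filter(default_homologs(), parent_mean <= 6)
  sim <- simulate_dataset(sim_config(seed = 19, positions = pos,
                                     homologs = tight, noise_cv = 0))
  calls <- classify_behavior(sim$measurements, sim$contexts)
  rec <- recovery_report(calls, sim$truth)
  per <- rec$per_class
  for (cls in c("R", "T", "N", "x", "three_state")) {
    expect_equal(per$recall[per$true_class == cls], 1,
                 info = paste("class", cls))
  }
})
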