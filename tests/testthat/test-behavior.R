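test_that("the dual change criterion matches its definition", {
  # exactly 2-fold with overlapping sd bands: not a change
  expect_false(is_changed(0.12, 0.06, 0.06, 0.06))
  # 21-fold apart with disjoint bands: a change
  expect_true(is_changed(15, 4, 0.7, 0.2))
  # identical measurements never change
  expect_false(is_changed(3, 0.5, 3, 0.5))
  # >2-fold but overlapping bands: not a change
  expect_false(is_changed(10, 8, 3, 1))
})

test_that("is_changed is symmetric and reflexively false", {
  set.seed(101)
  m1 <- runif(200, 0, 50)
  s1 <- runif(200, 0, 10)
  m2 <- runif(200, 0, 50)
  s2 <- runif(200, 0, 10)
  expect_equal(is_changed(m1, s1, m2, s2), is_changed(m2, s2, m1, s1))
  expect_false(any(is_changed(m1, s1, m1, s1)))
})

test_that("fold-change normalizes against the parent protein", {
  expect_equal(fold_change(0.12, 0.06, 0.12, 0.06)$value, 1)
  expect_equal(fold_change(15, 4, 0.7, 0.2)$value, 15 / 0.7,
               tolerance = 1e-12)
  expect_equal(fold_change(120, 16, 0.5, 0.1)$value, 240)
  # direction: enhanced repression (lower activity) gives value > 1
  expect_gt(fold_change(10, 1, 1, 0.1)$value, 1)
  expect_lt(fold_change(10, 1, 100, 5)$value, 1)
  # zero activity is clamped, not an error
  fc <- fold_change(1, 0.1, c(0, 2), c(0, 0.2), del_mean = 200, del_sd = 5)
  expect_true(all(is.finite(fc$value)))
})

test_that("classification recovers the archetypal rank-order patterns", {
  # all substitutions within 2-fold of parent: neutral
  calls <- classify_position(c(0.6, 0.8, 1.0, 1.1, 1.3, 1.7, 0.9, 1.9),
                             rep(0.05, 8), 1, 0.05, 200, 5)
  expect_equal(calls$code, "N")

  # progressive span over 3 orders of magnitude: full rheostat
  calls <- classify_position(c(0.1, 0.4, 1.5, 6, 25, 120), rep(0, 6),
                             1, 0, 200, 0)
  expect_equal(calls$code, "R")
  expect_equal(calls$span_log10, log10(120 / 0.1), tolerance = 1e-12)

  # two occupied levels (parent-like and MIN), empty between: toggle
  calls <- classify_position(c(0.8, 1.1, 0.9, 1.2, 1.0,
                               195, 205, 200, 190, 210),
                             rep(1, 10), 1, 0.1, 200, 5)
  expect_equal(calls$code, "T")

  # everything at the DEL floor: no measurable repression
  calls <- classify_position(rep(200, 6), rep(8, 6), 1, 0.1, 200, 5)
  expect_equal(calls$code, "x")

  # three well-separated levels: three-state code
  calls <- classify_position(c(1, 1.1, 0.9, 14, 15, 200, 210, 195),
                             rep(0.3, 8), 1, 0.05, 200, 5)
  expect_equal(calls$code, "3")

  # fewer substitutions than the gate: insufficient data, never an error
  calls <- classify_position(c(1, 5, 30), rep(0.2, 3), 1, 0.1, 200, 5)
  expect_equal(calls$code, "#")

  # narrow rheostat character (under two orders of magnitude)
  calls <- classify_position(10^seq(-0.9, 0.9, length.out = 8),
                             rep(0.01, 8), 1, 0.01, 200, 5)
  expect_equal(calls$code, "r")

  # substitutions all inside the 5-fold band but not the 2-fold band
  calls <- classify_position(c(0.25, 0.4, 0.8, 1.2, 2.5, 4),
                             rep(0.01, 6), 1, 0.01, 200, 5)
  expect_equal(calls$code, "n")
})

test_that("hybrid codes fire for mixed rank-order patterns", {
  # a MIN subset plus a wide rheostatic remainder
  act <- c(0.05, 0.4, 3, 30, 90, 200, 210, 195, 205, 190)
  calls <- classify_position(act, act * 0.05, 1, 0.1, 200, 5)
  expect_equal(calls$code, "R+T")
  # a neutral majority plus a changed remainder
  calls <- classify_position(c(0.8, 1.0, 1.2, 0.9, 1.1, 1.05, 8, 20),
                             rep(0.03, 8), 1, 0.03, 200, 5)
  expect_equal(calls$code, "N+r")
})

test_that("classification is invariant to row order and common scaling", {
  act <- c(0.1, 0.5, 2, 9, 40, 120, 1.2, 0.3, 15, 60)
  sds <- act * 0.1
  base <- classify_position(act, sds, 1, 0.1, 400, 20)
  perm <- sample(length(act))
  expect_equal(classify_position(act[perm], sds[perm], 1, 0.1, 400, 20),
               base)
  for (k in c(0.01, 7, 1000)) {
    scaled <- classify_position(act * k, sds * k, 1 * k, 0.1 * k,
                                400 * k, 20 * k)
    expect_equal(scaled$code, base$code)
    expect_equal(scaled$span_log10, base$span_log10, tolerance = 1e-9)
  }
})

test_that("enhancement percentages follow the published formula", {
  expect_equal(enhancement_percent(21, 126, 13), 19L)
  expect_equal(enhancement_percent(0, 96, 14), 0L)
  expect_equal(enhancement_percent(10, 100, 13), 11L)
  # half-up rounding at .5 boundaries
  expect_equal(enhancement_percent(5, 210, 10), 3L)  # 2.5 -> 3
  # degenerate denominator reported as missing
  expect_true(is.na(enhancement_percent(0, 13, 13)))
})

test_that("enhancement_table counts match a brute-force tally", {
  sim <- simulate_dataset(sim_config(seed = 23))
  tab <- enhancement_table(sim$measurements, sim$contexts)
  ctx <- sim$contexts
  for (pos in tab$position) {
    rows <- sim$measurements[
      sim$measurements$position == pos &
        sim$measurements$sub_aa != sim$measurements$wt_aa, ]
    n_enh <- 0L
    n_tot <- 0L
    homs <- character(0)
    for (i in seq_len(nrow(rows))) {
      cx <- ctx[ctx$homolog == rows$homolog[i], ]
      if (rows$condition[i] != cx$active_condition) next
      n_tot <- n_tot + 1L
      homs <- union(homs, rows$homolog[i])
      if (cx$parent_mean / rows$mean_miller[i] > 10) n_enh <- n_enh + 1L
    }
    row <- tab[tab$position == pos, ]
    expect_equal(row$enhanced_gt10, n_enh)
    expect_equal(row$total_variants, n_tot + length(homs))
    expect_equal(row$parents_mutated, length(homs))
    expect_equal(row$pct_enhanced,
                 as.integer(floor(100 * n_enh / n_tot + 0.5)))
  }
})

test_that("allosteric flags follow the parent's effector relationship", {
  ctx <- ctx_row("H1")
  ctx$parent_inactive_mean <- 200  # parent induces fully to DEL
  ctx$parent_inactive_sd <- 5
  m <- dplyr::bind_rows(
    # variant induces to DEL like its parent: no allosteric change
    meas_row("H1", 46, "S", "A", 0.5, 0.05, condition = "minus_effector"),
    meas_row("H1", 46, "S", "A", 205, 6, condition = "plus_effector"),
    # variant stays at its repressing value with effector: flagged
    meas_row("H1", 46, "S", "C", 0.5, 0.05, condition = "minus_effector"),
    meas_row("H1", 46, "S", "C", 0.5, 0.05, condition = "plus_effector"),
    # missing plus-effector measurement: undetermined, not FALSE
    meas_row("H1", 46, "S", "D", 0.5, 0.05, condition = "minus_effector")
  )
  fl <- allosteric_change_flags(m, ctx)
  expect_false(fl$allosteric_change[fl$sub_aa == "A"])
  expect_true(fl$allosteric_change[fl$sub_aa == "C"])
  expect_true(is.na(fl$allosteric_change[fl$sub_aa == "D"]))

  # magnitude-preserving parent: variant scaled by the same factor is FALSE
  ctx2 <- ctx_row("H2")
  ctx2$parent_inactive_mean <- 10  # parent induces 10-fold, not to DEL
  ctx2$parent_inactive_sd <- 1
  m2 <- dplyr::bind_rows(
    meas_row("H2", 46, "S", "A", 3, 0.2, condition = "minus_effector"),
    meas_row("H2", 46, "S", "A", 30, 2, condition = "plus_effector"),
    meas_row("H2", 46, "S", "C", 3, 0.2, condition = "minus_effector"),
    meas_row("H2", 46, "S", "C", 3, 0.2, condition = "plus_effector")
  )
  fl2 <- allosteric_change_flags(m2, ctx2)
  expect_false(fl2$allosteric_change[fl2$sub_aa == "A"])
  expect_true(fl2$allosteric_change[fl2$sub_aa == "C"])
})

test_that("planted allosteric variants are recovered exactly at zero noise", {
  sim <- simulate_dataset(sim_config(seed = 5, noise_cv = 0))
  fl <- allosteric_change_flags(sim$measurements, sim$contexts)
  joined <- dplyr::inner_join(
    fl, sim$variant_truth,
    by = c("homolog", "position", "wt_aa", "sub_aa")
  )
  expect_equal(sum(joined$allosteric), 30)
  expect_equal(joined$allosteric_change, joined$allosteric)
})
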