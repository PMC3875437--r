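# In-code fixtures shared across test files.

# A minimal measurement row builder.
meas_row <- function(homolog, position, wt, sub, mean, sd,
                     condition = "minus_effector", n_reps = 4L,
                     excluded = FALSE) {
  tibble::tibble(
    homolog = homolog, position = as.character(position), wt_aa = wt,
    sub_aa = sub, condition = condition, mean_miller = mean,
    sd_miller = sd, n_reps = n_reps, excluded = excluded
  )
}

# Context builder: tight parents over a 200-Miller DEL control.
ctx_row <- function(homolog, parent_mean = 1, parent_sd = 0.1,
                    del_mean = 200, del_sd = 5,
                    active_condition = "minus_effector",
                    growth_threshold = 13) {
  tibble::tibble(
    homolog = homolog, parent_mean = parent_mean, parent_sd = parent_sd,
    del_mean = del_mean, del_sd = del_sd,
    active_condition = active_condition,
    growth_threshold = growth_threshold
  )
}

# A hand-built three-homolog dataset with planted outcome codes at one
# position (wt Q for all homologs, parents at 1 Miller unit, DEL at 200):
#   C -> A (absent, tolerated in 3), A -> P1+P2+D, S -> P1,
#   W -> L (tolerated only in the reference homolog), K -> insufficient.
planted_crosstab_data <- function() {
  contexts <- ctx_row(c("H1", "H2", "H3"))
  m <- dplyr::bind_rows(
    meas_row("H1", 50, "Q", "C", 0.8, 0.05),
    meas_row("H2", 50, "Q", "C", 1.2, 0.05),
    meas_row("H3", 50, "Q", "C", 0.9, 0.05),
    meas_row("H1", 50, "Q", "A", 40, 2),
    meas_row("H2", 50, "Q", "A", 200, 8),
    meas_row("H3", 50, "Q", "A", 0.02, 0.005),
    meas_row("H1", 50, "Q", "S", 20, 1),
    meas_row("H2", 50, "Q", "S", 30, 2),
    meas_row("H1", 50, "Q", "W", 0.9, 0.05),
    meas_row("H2", 50, "Q", "W", 50, 3),
    meas_row("H3", 50, "Q", "W", 10, 1),
    meas_row("H1", 50, "Q", "K", 5, 0.5)
  )
  freqs <- tibble::tibble(
    position = "50",
    symbol = rheoscan::alignment_alphabet(),
    freq = 0,
    n_sequences = 10L
  )
  freqs$freq[freqs$symbol == "Q"] <- 0.3
  freqs$freq[freqs$symbol == "A"] <- 0.4
  freqs$freq[freqs$symbol == "S"] <- 0.2
  freqs$freq[freqs$symbol == "G"] <- 0.1
  list(measurements = m, contexts = contexts, freqs = freqs)
}

# Independent brute-force re-statement of the dual change criterion,
# deliberately written from the interval/ratio definition rather than the
# package's vectorized form.
brute_force_changed <- function(m1, s1, m2, s2) {
  hi <- max(m1, m2)
  lo <- min(m1, m2)
  if (lo > 0) {
    cond1 <- (hi / lo) > 2
  } else {
    cond1 <- hi > 0
  }
  overlap <- max(m1 - s1, m2 - s2) <= min(m1 + s1, m2 + s2)
  cond1 && !overlap
}
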