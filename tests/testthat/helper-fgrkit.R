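# shared fixture builders

# litter-summary table with no true effects: `n_litters` litters split
# evenly over treatment arms, one genotype, standard-normal litter values
null_summaries <- function(n_litters = 16, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    litter_id = sprintf("L%02d", seq_len(n_litters)),
    treatment = rep(c("water", "SC"), length.out = n_litters),
    genotype = "WT",
    n_pups = 8L,
    value = rnorm(n_litters)
  ))
}

# minimal valid fetus table for clearance / centile tests
tiny_fetuses <- function() {
  tibble::tibble(
    fetus_id = c("f1", "f2"),
    litter_id = c("L1", "L1"),
    treatment = "water",
    genotype = c("WT", "P0"),
    fetal_weight = c(1.2, 0.9),
    placental_weight = c(0.09, 0.06),
    tail_tip_fraction = 0,
    dpm_accumulated = c(100, 80),
    sample_time_x = c(3, 3)
  )
}

# a degenerate-variance calibration: every pup equals its cell mean
zero_sd_calibration <- function() {
  cal <- fgrkit::default_calibration()
  cal[grep("_sd$", names(cal))] <- 0
  cal
}
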