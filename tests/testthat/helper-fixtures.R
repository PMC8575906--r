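# Small in-code fixtures shared across test files.

make_females <- function(n = 3, stage = 6L, prespawning = FALSE) {
  tibble::tibble(
    female_id = sprintf("F%02d", seq_len(n)),
    capture_date = as.Date("2019-05-10") + seq_len(n),
    total_length_cm = seq(30, 40, length.out = n),
    body_weight_g = 0.006 * seq(30, 40, length.out = n)^3.13,
    ovary_weight_g = 0.05 * 0.006 * seq(30, 40, length.out = n)^3.13,
    maturity_stage = as.integer(stage),
    prespawning_flag = prespawning
  )
}

# one-female histology fixture with known fractions and spherical oocytes
make_histology <- function(female_id = "F01", d_um = 200, n_profiles = 3) {
  hits <- tibble::tibble(
    female_id = female_id,
    structure = c("PVO2", "VO1", "OTHERS"),
    hits = c(100L, 150L, 250L),
    total_points = 500L,
    section_area_mm2 = 80
  )
  axes <- tibble::tibble(
    female_id = female_id,
    phase = rep(c("PVO2", "VO1"), each = n_profiles),
    long_axis_um = d_um,
    short_axis_um = d_um
  )
  list(hits = hits, axes = axes)
}

small_sim <- function(n = 40, seed = 7, ...) {
  simulate_dataset(sim_config(n_females = n, seed = seed, ...))
}
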