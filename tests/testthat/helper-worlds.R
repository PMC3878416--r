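# Small synthetic worlds shared across tests. Everything is generated in
# code at test time; sizes are scaled down from the full screen so the
# suite stays fast, with the structure (two phases, two trials, shared
# cultivars, plate plots, duplicates, standards) intact.

# Two-trial world with a configurable cultivar count / block count and a
# reduced random-term set (keeps REML fits cheap in property tests).
light_vc <- function(rho = 0.66, vg = c(8, 5), resid = c(4, 3),
                     trials = c("t1", "t2"),
                     terms = c(F_block = 6, L_platexplot = 10, L_row = 2)) {
  variance_components(
    terms = setNames(list(terms, terms), trials),
    genetic_var = setNames(vg, trials),
    genetic_correlation = rho,
    residual_var = setNames(resid, trials))
}

tiny_world <- function(n_cult = 24, n_blocks = 2, seed = 1, vc = light_vc(),
                       means = c(t1 = 90, t2 = 55), sim_seed = seed + 100,
                       genetic_shift = NULL) {
  trials <- vc$trials
  ids <- sprintf("CV%04d", seq_len(n_cult))
  field <- lapply(setNames(trials, trials), function(tr)
    generate_field_design(ids, n_blocks = n_blocks, n_rows = 8, trial = tr,
                          seed = seed + match(tr, trials)))
  lab <- lapply(setNames(trials, trials), function(tr)
    generate_lab_design(field[[tr]], plates_per_day = 4,
                        pad_to_full_plates = FALSE,
                        seed = seed + 10 + match(tr, trials)))
  pheno <- simulate_met(field, lab, vc, means, seed = sim_seed,
                        genetic_shift = genetic_shift)
  list(field = field, lab = lab, vc = vc, means = means, pheno = pheno)
}

# Hand-built flat phenotype table for matrix-level unit tests: every
# factor column present, one row per well.
flat_table <- function(trial, cultivar, sugar, block = 1, field_row = 1,
                       field_column = 1, day = 1, plate = 1, plate_plot = 1,
                       plate_row = "A", plate_column = 1) {
  data.frame(trial = trial, block = block, field_row = field_row,
             field_column = field_column, day = day, plate = plate,
             plate_plot = plate_plot, plate_row = plate_row,
             plate_column = plate_column, cultivar = cultivar, copy = 1,
             is_standard = FALSE, sugar = sugar, stringsAsFactors = FALSE)
}

# Balanced one-way layout (g groups x r replicates) as a phenotype table.
balanced_oneway_table <- function(g = 25, r = 4, vg = 4, ve = 2, mu = 50,
                                  seed = 1, trial = "t1") {
  with_seed <- metphase:::with_seed
  with_seed(seed, {
    eff <- rnorm(g, 0, sqrt(vg))
    y <- rep(eff, each = r) + rnorm(g * r, 0, sqrt(ve)) + mu
  })
  flat_table(trial = trial, cultivar = rep(sprintf("g%03d", 1:g), each = r),
             sugar = y, block = rep(1:r, g),
             field_column = rep(1:g, each = r))
}
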