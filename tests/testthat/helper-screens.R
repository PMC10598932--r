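# In-code fixtures: tiny well tables and cohorts built deterministically.

# A well table for one PDO x drug triple of levels, with explicit viability
# percentages realized exactly (controls noiseless at `scale` RLU).
wells_for_profile <- function(pdo, drug, viability, plate = "P1",
                              scale = 10000, n_controls = 6) {
  levels <- c("low", "medium", "high")
  cond <- data.frame(
    plate = plate,
    well = center_wells()[seq_len(3 * length(levels))][1:9],
    pdo = pdo, drug = drug,
    level = rep(levels, each = 3),
    signal = as.character(rep(viability, each = 3) / 100 * scale),
    stringsAsFactors = FALSE)
  cond
}

# Control rows for a plate.
control_wells <- function(pdo, plate = "P1", scale = 10000, n = 6,
                          offset = 50) {
  data.frame(
    plate = plate,
    well = center_wells()[offset + seq_len(n)],
    pdo = pdo, drug = "CONTROL", level = "control",
    signal = as.character(rep(scale, n)),
    stringsAsFactors = FALSE)
}

# Noiseless screen: one plate per PDO, viability list is drug -> triple.
toy_screen <- function(profiles_by_pdo, scale = 10000) {
  rows <- list()
  for (pdo in names(profiles_by_pdo)) {
    prof <- profiles_by_pdo[[pdo]]
    pos <- 0
    for (drug in names(prof)) {
      w <- wells_for_profile(pdo, drug, prof[[drug]],
                             plate = paste0(pdo, "_P1"), scale = scale)
      w$well <- center_wells()[pos + 1:9]
      pos <- pos + 9
      rows[[length(rows) + 1]] <- w
    }
    rows[[length(rows) + 1]] <- control_wells(pdo, paste0(pdo, "_P1"),
                                              scale, offset = pos)
  }
  validate_wells(do.call(rbind, rows))
}

# Profile data frame straight from viability triples (bypasses wells).
toy_profiles <- function(triples) {
  # triples: data frame pdo, drug, v1, v2, v3
  data.frame(pdo = triples$pdo, drug = triples$drug,
             v_low = triples$v1, v_medium = triples$v2, v_high = triples$v3,
             available = TRUE, stringsAsFactors = FALSE)
}

# Random cohort of available profiles for property tests.
random_profiles <- function(n_pdos, drugs, seed) {
  set.seed(seed)
  grid <- expand.grid(pdo = sprintf("R%02d", seq_len(n_pdos)), drug = drugs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(grid,
             v_low = stats::runif(nrow(grid), 0, 120),
             v_medium = stats::runif(nrow(grid), 0, 110),
             v_high = stats::runif(nrow(grid), 0, 100),
             available = TRUE, stringsAsFactors = FALSE)
}

# Small panel subset keeping panel invariants.
mini_panel <- function(drugs = c("5FU", "Oxaliplatin", "Gemcitabine")) {
  p <- default_panel()
  as_drug_panel(p[panel_match(p, drugs), ])
}
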