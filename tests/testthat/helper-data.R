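# Shared fixtures, all built in code.

# A minimal hand-constructed vial table (2 treatments x 1 timepoint x 2
# replicates) with round-number activities for arithmetic checks.
tiny_vials <- function() {
  tibble::tibble(
    vial_id = sprintf("T%02d", 1:4),
    treatment = rep(c("control", "EZ"), each = 2),
    timepoint_h = 5,
    dry_mass_g = 0.5,
    act_ca45_skel_kbq = c(2, 2, 0.5, 0.5),
    act_c14_skel_kbq = c(1, 1, 0.4, 0.4),
    act_c14_org_kbq = c(3, 3, 0, 0),
    act_c14_co2_kbq = c(1.5, 1.5, 0.2, 0.2),
    o2_rate_umol_h_g = c(1.2, 1.1, 0.6, 0.7)
  )
}

# Label spec engineered so Con = 1.5 nmol/kBq on both isotopes, making
# incorporation arithmetic checkable by hand.
unit_labels <- function(con_nmol_kbq = 1.5) {
  label_specs(activity_kbq = 1000, vial_volume_l = 1,
              ca_mol_kg = con_nmol_kbq * 1e-9 * 1000,
              dic_mol_kg = con_nmol_kbq * 1e-9 * 1000)
}

# Independent brute-force Kruskal-Wallis: mid-ranks by pairwise counting,
# H from the definition, tie correction applied. Deliberately naive.
kw_brute <- function(values, groups) {
  n <- length(values)
  ranks <- vapply(seq_len(n), function(i) {
    1 + sum(values < values[i]) + 0.5 * sum(values == values[i]) - 0.5
  }, numeric(1))
  gs <- split(ranks, groups)
  h <- 12 / (n * (n + 1)) *
    sum(vapply(gs, function(r) length(r) * (mean(r) - (n + 1) / 2)^2,
               numeric(1)))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

noise_free_config <- function(...) {
  sim_config(dry_mass_cv = 0, individual_cv = 0, noise_cv = 0, ...)
}
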