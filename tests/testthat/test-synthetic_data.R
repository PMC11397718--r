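test_that("identical configs give byte-identical datasets", {
  cfg <- sim_config(n_species = 8, n_cultivars = 10, seed = 99)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  # a different seed must actually change the draws
  c2 <- generate_dataset(sim_config(n_species = 8, n_cultivars = 10,
                                    seed = 100))
  expect_false(identical(a$true_means, c2$true_means))
})

test_that("species means respect configured ranges and section structure", {
  cfg <- sim_config(n_species = 25, n_cultivars = 0,
                    section_size_slope = 0, seed = 5)
  taxa <- generate_taxa(cfg)
  tm <- taxa$true_means
  rng <- cfg$trait_mean_ranges
  for (tr in c("P", "S", "RW", "FW", "PD")) {
    expect_true(all(tm[[tr]] >= rng[[tr]][1] - 1e-9 &
                      tm[[tr]] <= rng[[tr]][2] + 1e-9), label = tr)
  }
  expect_true(all(tm$P / tm$E >= cfg$pe_ratio_range[1] &
                    tm$P / tm$E <= cfg$pe_ratio_range[2]))
  expect_true(all(tm$Eprime / tm$E >= cfg$eprime_ratio_range[1] &
                    tm$Eprime / tm$E <= cfg$eprime_ratio_range[2]))
  expect_true(all(taxa$taxonomy$section_value %in% 1:5))
  expect_equal(sum(tm$PD == 0), round(0.327 * 25))
})

test_that("zero-PD fraction boundaries behave", {
  all_zero <- generate_taxa(sim_config(n_species = 10, frac_zero_pd = 1,
                                       seed = 2))
  expect_true(all(all_zero$true_means$PD == 0))
  none_zero <- generate_taxa(sim_config(n_species = 10, frac_zero_pd = 0,
                                        seed = 2))
  expect_true(all(none_zero$true_means$PD > 0))
})

test_that("negative section-size slope induces a negative size trend", {
  hits <- 0L
  for (i in 1:200) {
    taxa <- generate_taxa(sim_config(n_species = 200,
                                     section_size_slope = -0.8,
                                     seed = 1000 + i))
    r <- cor(taxa$taxonomy$section_value, taxa$true_means$P)
    if (r < 0) hits <- hits + 1L
  }
  expect_gte(hits, 190)  # >= 95% of runs
})

test_that("zero slope leaves sections uncorrelated with size", {
  rs <- vapply(1:200, function(i) {
    taxa <- generate_taxa(sim_config(n_species = 60,
                                     section_size_slope = 0,
                                     seed = 3000 + i))
    cor(taxa$taxonomy$section_value, taxa$true_means$P)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("noise-free unit-drift cultivars sit exactly at the midparent", {
  cfg <- sim_config(n_species = 6, n_cultivars = 12,
                    progeny_noise_sd = 0, pd_drift = 1,
                    midparent_weight = 0.5, frac_unknown_parent = 0,
                    frac_zero_pd = 0, seed = 8)
  taxa <- generate_taxa(cfg)
  cult <- generate_pedigree_and_cultivars(cfg, taxa)
  sp <- taxa$true_means
  for (i in seq_len(nrow(cult$pedigree))) {
    row <- cult$pedigree[i, ]
    mid <- (sp[sp$taxon_id == row$parent1, pollen_traits()] +
              sp[sp$taxon_id == row$parent2, pollen_traits()]) / 2
    got <- cult$true_means[cult$true_means$taxon_id == row$progeny,
                           pollen_traits()]
    expect_equal(unlist(got), unlist(mid), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("PD drift multiplies the midparent perforation density", {
  cfg <- sim_config(n_species = 6, n_cultivars = 10,
                    progeny_noise_sd = 0, pd_drift = 2,
                    frac_unknown_parent = 0, frac_zero_pd = 0, seed = 9)
  taxa <- generate_taxa(cfg)
  cult <- generate_pedigree_and_cultivars(cfg, taxa)
  sp <- taxa$true_means
  for (i in seq_len(nrow(cult$pedigree))) {
    row <- cult$pedigree[i, ]
    mid_pd <- mean(c(sp$PD[sp$taxon_id == row$parent1],
                     sp$PD[sp$taxon_id == row$parent2]))
    got <- cult$true_means$PD[cult$true_means$taxon_id == row$progeny]
    expect_equal(got, 2 * mid_pd, tolerance = 1e-12)
  }
  # doubled PD makes every evaluable progeny progress in both modes
  pd_means <- setNames(c(sp$PD, cult$true_means$PD),
                       c(sp$taxon_id, cult$true_means$taxon_id))
  for (mode in c("exclude_unknown", "assume_lower")) {
    rep_ <- pd_progression(pd_means, cult$pedigree, mode)
    expect_equal(rep_$percentage, 100)
  }
})

test_that("all-unknown second parents give single-parent inheritance", {
  cfg <- sim_config(n_species = 5, n_cultivars = 8,
                    progeny_noise_sd = 0, pd_drift = 1,
                    frac_unknown_parent = 1, frac_zero_pd = 0, seed = 3)
  taxa <- generate_taxa(cfg)
  cult <- generate_pedigree_and_cultivars(cfg, taxa)
  expect_true(all(cult$pedigree$parent2 == "unknown"))
  sp <- taxa$true_means
  for (i in seq_len(nrow(cult$pedigree))) {
    row <- cult$pedigree[i, ]
    expect_equal(
      unlist(cult$true_means[cult$true_means$taxon_id == row$progeny,
                             pollen_traits()]),
      unlist(sp[sp$taxon_id == row$parent1, pollen_traits()]),
      tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("replicate noise honours the target coefficient of variation", {
  cfg0 <- sim_config(n_species = 4, n_cultivars = 0, frac_zero_pd = 0,
                     within_cv = c(P = 0, E = 0, Eprime = 0, S = 0,
                                   RW = 0, FW = 0, PD = 0), seed = 4)
  taxa <- generate_taxa(cfg0)
  tab <- generate_replicates(taxa$true_means, cfg0)
  u <- intraspecific_uniformity(tab, "P")
  expect_equal(u$cvbar, 0)

  # zero-mean taxa yield all-zero replicates
  cfg1 <- sim_config(n_species = 6, n_cultivars = 0, frac_zero_pd = 1,
                     seed = 4)
  taxa1 <- generate_taxa(cfg1)
  tab1 <- generate_replicates(taxa1$true_means, cfg1)
  expect_true(all(tab1$values$value[tab1$values$trait == "PD"] == 0))
})

test_that("generator output passes trait-table validation end to end", {
  ds <- generate_dataset(sim_config(n_species = 10, n_cultivars = 15,
                                    seed = 12))
  # re-validating the long values must succeed without error
  expect_s3_class(trait_table(ds$table$values, ap = ds$table$ap,
                              expected_replicates = 30), "trait_table")
  expect_true(all(ds$table$values$value >= 0))
  expect_s3_class(ds$pedigree, "pedigree")
  expect_setequal(ds$pedigree$progeny,
                  ds$taxonomy$taxon_id[ds$taxonomy$rank == "cultivar"])
})
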