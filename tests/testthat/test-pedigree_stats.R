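routes <- read_family_routes()

test_that("the 28-route fixture reproduces all four headline percentages", {
  expect_equal(round(aggregation_from_routes(routes, "four_group")$percentage,
                     2), 92.86)
  expect_equal(round(aggregation_from_routes(routes, "six_group")$percentage,
                     2), 67.86)
  expect_equal(round(pd_progression_from_routes(routes,
                                                "assume_lower")$percentage,
                     2), 96.43)
  expect_equal(round(pd_progression_from_routes(routes,
                                                "exclude_unknown")$percentage,
                     2), 53.57)
})

test_that("aggregation respects level coarsening and the all-parents rule", {
  four <- aggregation_from_routes(routes, "four_group")
  six <- aggregation_from_routes(routes, "six_group")
  expect_gte(four$percentage, six$percentage)
  # per-route: aggregation at six-group level implies it at four-group level
  expect_true(all(!six$per_progeny | four$per_progeny, na.rm = TRUE))

  all_rule <- aggregation_from_routes(routes, "four_group", rule = "all")
  expect_lte(all_rule$percentage, four$percentage)
})

test_that("progression modes order as construction dictates", {
  lower <- pd_progression_from_routes(routes, "assume_lower")
  excl <- pd_progression_from_routes(routes, "exclude_unknown")
  expect_gte(lower$percentage, excl$percentage)
  expect_true(all(lower$percentage >= 0 & lower$percentage <= 100))

  # property over synthetic pipelines: both invariants hold whatever the draw
  for (seed in c(101, 202, 303)) {
    ds <- generate_dataset(sim_config(n_species = 10, n_cultivars = 20,
                                      seed = seed))
    fm <- build_feature_matrix(ds$table)
    cr <- cut_two_level(hierarchical_cluster(fm), 4, 3)
    f4 <- family_aggregation(cr, ds$pedigree, "four_group")
    f6 <- family_aggregation(cr, ds$pedigree, "six_group")
    expect_gte(f4$percentage, f6$percentage)
    tm <- taxon_means(ds$table)
    pdm <- setNames(tm$PD, tm$taxon_id)
    lo <- pd_progression(pdm, ds$pedigree, "assume_lower", result = cr)
    ex <- pd_progression(pdm, ds$pedigree, "exclude_unknown", result = cr)
    expect_gte(lo$percentage, ex$percentage)
  }
})

test_that("progeny clustered with their only known parent always aggregate", {
  asn <- data.frame(taxon_id = c("p1", "p2", "c1", "c2"),
                    group = c("A", "B", "A", "B"),
                    subgroup = NA_character_,
                    label6 = c("A", "B", "A", "B"))
  cr <- structure(list(assignments = asn), class = "cluster_result")
  ped <- pedigree(data.frame(progeny = c("c1", "c2"),
                             parent1 = c("p1", "p2"),
                             parent2 = "unknown"))
  expect_equal(family_aggregation(cr, ped, "four_group")$percentage, 100)
  # progeny with no clustered parent are not evaluable
  ped2 <- pedigree(data.frame(progeny = c("c1", "c2"),
                              parent1 = c("p1", "ghost"),
                              parent2 = "unknown"))
  rep2 <- family_aggregation(cr, ped2, "four_group")
  expect_equal(rep2$n_evaluable, 1)
  expect_error(
    family_aggregation(cr, pedigree(data.frame(progeny = "c1",
                                               parent1 = "ghost",
                                               parent2 = "unknown"))),
    "no evaluable")
})

test_that("section aggregation recovers the modal-membership shares", {
  sec <- utils::read.csv(system.file("extdata",
                                     "section_assignments_synthetic.csv",
                                     package = "pollenphen"))
  tax <- data.frame(taxon_id = sec$taxon_id, name = sec$name,
                    rank = sec$rank, section = sec$section)
  sa <- section_aggregation(sec[c("taxon_id", "group", "label6")], tax)
  expect_equal(round(sa$group$percentage, 1), 82.6)     # 19 of 23
  expect_equal(round(sa$subgroup$percentage, 1), 52.2)  # 12 of 23
  expect_equal(sa$group$n_matched, 19)
  expect_equal(sa$subgroup$n_matched, 12)

  # one species per section is trivially modal
  tiny <- data.frame(taxon_id = c("s1", "s2"),
                     group = c("A", "D"), label6 = c("A", "D3"))
  tiny_tax <- data.frame(taxon_id = c("s1", "s2"), rank = "species",
                         section = c("I", "II"))
  expect_equal(section_aggregation(tiny, tiny_tax)$group$percentage, 100)
})

test_that("hybridization frequencies count species once per route", {
  ped <- pedigree(data.frame(progeny = c("c1", "c2", "c3"),
                             parent1 = c("A", "A", "B"),
                             parent2 = c("B", "unknown", "C")))
  hf <- hybridization_frequency(ped)
  expect_equal(unname(hf$frequency[c("A", "B", "C")]),
               c(2 / 3, 2 / 3, 1 / 3))
  expect_equal(hf$total_crosses, 3)

  single <- hybridization_frequency(
    pedigree(data.frame(progeny = "c1", parent1 = "A", parent2 = "B")))
  expect_equal(unname(single$frequency), c(1, 1))
  expect_identical(unname(single$classification), c("high", "high"))

  # selfed route counts the species once
  selfed <- hybridization_frequency(
    pedigree(data.frame(progeny = "c1", parent1 = "A", parent2 = "A")))
  expect_equal(unname(selfed$frequency["A"]), 1)

  # classification bands: 5/20 = 0.25 high, 2/20 = 0.10 medium,
  # 1/20 = 0.05 medium (inclusive bound), 12/20 = 0.60 high
  many <- pedigree(data.frame(progeny = sprintf("c%d", 1:20),
                              parent1 = c(rep("A", 2), rep("B", 1),
                                          rep("C", 5), rep("D", 12)),
                              parent2 = "unknown"))
  hf2 <- hybridization_frequency(many)
  expect_identical(unname(hf2$classification[c("D", "C", "A", "B")]),
                   c("high", "high", "medium", "medium"))
})

test_that("frequency concordance matches closed-form expectations", {
  expect_equal(frequency_concordance(c(a = .1, b = .2, c = .3),
                                     c(a = .1, b = .2, c = .3))$pearson_r,
               1, tolerance = 1e-12)
  r <- frequency_concordance(c(a = .1, b = .2, c = .3),
                             c(a = .2, b = .4, c = .6))
  expect_equal(r$pearson_r, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_error(frequency_concordance(c(a = .1, b = .2), c(a = .1, b = .2)),
               "at least 3")
  expect_error(frequency_concordance(c(a = .1, b = .1, c = .1),
                                     c(a = .1, b = .2, c = .3)),
               "zero variance")
})

test_that("null concordance R-squared matches its 1/(n-1) expectation", {
  set.seed(90)
  n <- 12
  r2 <- replicate(1000, {
    a <- setNames(runif(n), letters[1:n])
    b <- setNames(runif(n), letters[1:n])
    frequency_concordance(a, b)$r_squared
  })
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 0.02)
})

test_that("well-separated midparent families aggregate near-perfectly", {
  ok <- 0L
  for (i in 1:100) {
    sim <- simulate_families(seed = 500 + i)
    hc <- hierarchical_cluster(sim$features)
    cr <- cut_two_level(hc, k_top = sim$k, k_sub = 1)
    fa <- family_aggregation(cr, sim$pedigree, "four_group")
    if (fa$percentage >= 92.9) ok <- ok + 1L
  }
  expect_gte(ok, 90)
})
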