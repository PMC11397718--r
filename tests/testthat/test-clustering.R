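test_that("feature matrix is z-scored and tracks exclusions", {
  ds <- generate_dataset(sim_config(n_species = 12, n_cultivars = 8,
                                    seed = 14))
  fm <- build_feature_matrix(ds$table)
  expect_identical(colnames(fm), cluster_features())
  expect_true(all(abs(colMeans(fm)) < 1e-10))
  expect_equal(unname(apply(fm, 2, sd)), rep(1, ncol(fm)))

  # taxa lacking PD are excluded with a message
  v <- ds$table$values
  drop_id <- v$taxon_id[1]
  v <- v[!(v$taxon_id == drop_id & v$trait == "PD"), ]
  tab2 <- suppressWarnings(trait_table(v))
  expect_message(fm2 <- build_feature_matrix(tab2), "incomplete features")
  expect_false(drop_id %in% rownames(fm2))

  # constant feature -> named zero-variance error
  v3 <- ds$table$values
  v3$value[v3$trait == "RW"] <- 0.2
  tab3 <- suppressWarnings(trait_table(v3))
  expect_error(build_feature_matrix(tab3), "RW")
})

test_that("two taxa merge at their pairwise distance", {
  x <- rbind(a = c(0, 0), b = c(3, 4))
  hc <- hierarchical_cluster(x)
  expect_equal(hc$height, 5)
  expect_error(hierarchical_cluster(rbind(c(1, NA), c(0, 0))), "missing")
})

test_that("merge sequences match a brute-force oracle for n <= 8", {
  set.seed(50)
  for (linkage in c("ward", "average", "complete")) {
    for (n in 3:8) {
      for (rep_i in 1:5) {
        x <- matrix(rnorm(n * 3), n, 3)
        rownames(x) <- sprintf("t%d", seq_len(n))
        hc <- hierarchical_cluster(x, linkage = linkage)
        oracle <- oracle_agglomerate(x, linkage)
        expect_equal(hc$height, oracle$heights, tolerance = 1e-8,
                     label = sprintf("%s n=%d heights", linkage, n))
        expect_identical(hclust_comps(hc), oracle$comps,
                         label = sprintf("%s n=%d merges", linkage, n))
      }
    }
  }
})

test_that("the first cut separates two well-separated blobs", {
  set.seed(60)
  for (rep_i in 1:10) {
    x <- rbind(matrix(rnorm(10 * 4, 0, 1), 10, 4),
               matrix(rnorm(10 * 4, 12, 1), 10, 4))
    rownames(x) <- sprintf("t%d", 1:20)
    hc <- hierarchical_cluster(x)
    cut2 <- cutree(hc, 2)
    expect_equal(length(unique(cut2[1:10])), 1)
    expect_equal(length(unique(cut2[11:20])), 1)
  }
})

test_that("two-level cut labels by size and splits the largest group", {
  # four tight clusters with the advertised 7/6/6/88 composition
  set.seed(70)
  sizes <- c(7, 6, 6, 88)
  centers <- rbind(c(0, 0), c(30, 0), c(0, 30), c(30, 30))
  x <- do.call(rbind, lapply(1:4, function(i) {
    sweep(matrix(rnorm(sizes[i] * 2, 0, 0.5), sizes[i], 2), 2,
          centers[i, ], `+`)
  }))
  rownames(x) <- sprintf("t%03d", seq_len(sum(sizes)))
  cr <- cut_two_level(hierarchical_cluster(x), k_top = 4, k_sub = 3)
  tab <- table(cr$assignments$group)
  expect_equal(unname(tab["D"]), 88)
  expect_setequal(unname(tab[c("A", "B", "C")]), c(7, 6, 6))
  sub <- cr$assignments$subgroup
  expect_equal(sum(!is.na(sub)), 88)
  expect_setequal(unique(cr$assignments$subgroup[!is.na(sub)]),
                  c("D1", "D2", "D3"))
  # subgroup sizes ascend with their labels
  st <- table(sub)
  expect_true(st["D1"] <= st["D2"] && st["D2"] <= st["D3"])
  # share arithmetic on the printed-style counts
  expect_equal(round(count_share(unname(tab))[4], 2), 82.24)

  # six-level labels partition all taxa
  expect_false(any(is.na(cr$assignments$label6)))
})

test_that("k_top = n gives singletons and no subdivision", {
  set.seed(71)
  x <- matrix(rnorm(12), 6, 2)
  rownames(x) <- letters[1:6]
  expect_warning(cr <- cut_two_level(hierarchical_cluster(x),
                                     k_top = 6, k_sub = 3),
                 "no subdivision")
  expect_equal(length(unique(cr$assignments$group)), 6)
  expect_true(all(is.na(cr$assignments$subgroup)))
  expect_error(cut_two_level(hierarchical_cluster(x), k_top = 7),
               "exceeds")
})

test_that("the partition is invariant to taxon relabeling", {
  set.seed(72)
  x <- matrix(rnorm(40), 20, 2)
  rownames(x) <- sprintf("t%02d", 1:20)
  cr1 <- cut_two_level(hierarchical_cluster(x), 3, 2)
  y <- x
  rownames(y) <- sprintf("zz%02d", 1:20)
  cr2 <- cut_two_level(hierarchical_cluster(y), 3, 2)
  # same partition structure under renaming
  m1 <- split(cr1$assignments$taxon_id, cr1$assignments$group)
  m2 <- split(cr2$assignments$taxon_id, cr2$assignments$group)
  strip <- function(v) sort(as.integer(sub("^[a-z]+", "", v)))
  expect_identical(lapply(m1, strip), lapply(m2, strip))
})

test_that("dendrograms export as readable Newick", {
  set.seed(73)
  x <- matrix(rnorm(16), 8, 2)
  rownames(x) <- sprintf("t%d", 1:8)
  path <- withr::local_tempfile(fileext = ".nwk")
  export_newick(hierarchical_cluster(x), path)
  tree <- ape::read.tree(path)
  expect_equal(ape::Ntip(tree), 8)
  expect_setequal(tree$tip.label, rownames(x))
})

test_that("group summaries report means, sds and defensible letters", {
  # null case: all groups from one distribution should mostly share letters
  set.seed(80)
  share_all <- 0L
  for (rep_i in 1:20) {
    means <- data.frame(taxon_id = sprintf("t%02d", 1:24),
                        P = rnorm(24, 40, 2))
    tab <- table_from_means(means, replicates = 3, jitter_sd = 0.5)
    groups <- split(means$P, rep(c("A", "B", "C"), each = 8))
    r <- tukey_cld(groups)
    if (length(unique(unname(r$letters))) == 1) share_all <- share_all + 1L
  }
  expect_gte(share_all, 18)  # >= 90% of null runs

  # a +5 sd shift must earn its own letter
  set.seed(81)
  shifted <- list(A = rnorm(10, 40, 1), B = rnorm(10, 40, 1),
                  C = rnorm(10, 45, 1))
  r2 <- tukey_cld(shifted)
  expect_false(grepl(r2$letters["C"], paste0(r2$letters["A"],
                                             r2$letters["B"])))

  # full group_summaries over a synthetic clustering
  ds <- generate_dataset(sim_config(n_species = 15, n_cultivars = 15,
                                    seed = 82))
  fm <- build_feature_matrix(ds$table)
  cr <- cut_two_level(hierarchical_cluster(fm), 4, 3)
  gs <- group_summaries(ds$table, result = cr)
  expect_setequal(unique(gs$level), c("group", "six_group"))
  expect_true(all(c("P", "PD", "Eprime_E") %in% gs$trait))
  singles <- gs[gs$n == 1, ]
  if (nrow(singles) > 0) expect_true(all(is.na(singles$sd)))
  expect_true(all(!is.na(gs$mean)))
})
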