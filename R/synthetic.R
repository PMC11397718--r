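#' Simulation configuration for synthetic pollen datasets
#'
#' Defines a germplasm collection emulating the statistical structure the
#' downstream analyses assume: species with ordinal sections and trait
#' means drawn within realistic ranges, cultivars inheriting midparent
#' trait values from species parents with directional perforation-density
#' drift, and within-taxon replicate noise at controlled coefficients of
#' variation.
#'
#' Default trait-mean ranges reflect a congeneric crabapple collection:
#' P 29.44-52.35 um, E 20.95-29.64 um, S 560.25-1108.89 um^2,
#' RW 0.13-0.25 um, FW 0.04-0.28 um, PD 0-11.18 per um^2. E' is drawn as
#' E times a ratio in `eprime_ratio_range` (default 0.80-0.87). Default
#' within-taxon CVs are 0.10 for the size traits and ridge width and 0.20
#' for furrow width and perforation density, the regimes in which the
#' uniformity verdicts split.
#'
#' @param n_species number of species (default 23).
#' @param n_cultivars number of cultivars (default 84).
#' @param replicates replicates per taxon per trait (default 30).
#' @param trait_mean_ranges named list trait -> c(lo, hi) of species-mean
#'   ranges; partial overrides are merged into the defaults.
#' @param pe_ratio_range range of the P/E shape ratio the species means
#'   must respect (default 1.22-2.21); E is drawn conditionally on P so
#'   that the ratio stays inside it.
#' @param eprime_ratio_range range of the E'/E ratio used to derive E'.
#' @param within_cv named vector trait -> target within-taxon coefficient
#'   of variation; partial overrides merged into defaults.
#' @param midparent_weight weight w of parent 1 in cultivar means
#'   (default 0.5; a single known parent always gets weight 1).
#' @param progeny_noise_sd relative sd of cultivar-mean noise around the
#'   midparent value, as a fraction of that value (default 0.05).
#' @param pd_drift multiplicative perforation-density drift delta >= 0
#'   applied to cultivar PD after midparent averaging (default 1.2;
#'   values > 1 emulate the low-to-high progression expected across
#'   generations).
#' @param section_size_slope additive shift per section ordinal applied
#'   to the size traits P, E and S (default -0.8; negative values emulate
#'   a weak large-to-small trend from ancient to advanced sections).
#' @param frac_zero_pd fraction of species with perforation density
#'   exactly 0, i.e. imperforate exine (default 0.327).
#' @param frac_unknown_parent probability that a cultivar's second parent
#'   slot is unknown (default 0.35).
#' @param ap_range range of per-taxon aberrant pollen rates (default
#'   0-0.956).
#' @param seed integer seed; every stage derives its own sub-stream from
#'   it, so identical configs give byte-identical output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_species = 23L,
                       n_cultivars = 84L,
                       replicates = 30L,
                       trait_mean_ranges = list(),
                       pe_ratio_range = c(1.22, 2.21),
                       eprime_ratio_range = c(0.80, 0.87),
                       within_cv = numeric(0),
                       midparent_weight = 0.5,
                       progeny_noise_sd = 0.05,
                       pd_drift = 1.2,
                       section_size_slope = -0.8,
                       frac_zero_pd = 0.327,
                       frac_unknown_parent = 0.35,
                       ap_range = c(0, 0.956),
                       seed = 1L) {
  default_ranges <- list(P = c(29.44, 52.35), E = c(20.95, 29.64),
                         S = c(560.25, 1108.89), RW = c(0.13, 0.25),
                         FW = c(0.04, 0.28), PD = c(0, 11.18))
  default_cv <- c(P = 0.10, E = 0.10, Eprime = 0.10, S = 0.10,
                  RW = 0.10, FW = 0.20, PD = 0.20)
  ranges <- utils::modifyList(default_ranges, as.list(trait_mean_ranges))
  cv <- default_cv
  cv[names(within_cv)] <- within_cv

  stopifnot(n_species >= 1, n_cultivars >= 0, replicates >= 2,
            midparent_weight >= 0, midparent_weight <= 1,
            progeny_noise_sd >= 0, pd_drift >= 0,
            frac_zero_pd >= 0, frac_zero_pd <= 1,
            frac_unknown_parent >= 0, frac_unknown_parent <= 1,
            length(eprime_ratio_range) == 2,
            eprime_ratio_range[1] <= eprime_ratio_range[2],
            length(pe_ratio_range) == 2, pe_ratio_range[1] > 0,
            pe_ratio_range[1] <= pe_ratio_range[2],
            all(vapply(ranges, function(r) r[1] <= r[2], logical(1))),
            all(cv >= 0))

  structure(list(n_species = as.integer(n_species),
                 n_cultivars = as.integer(n_cultivars),
                 replicates = as.integer(replicates),
                 trait_mean_ranges = ranges,
                 pe_ratio_range = pe_ratio_range,
                 eprime_ratio_range = eprime_ratio_range,
                 within_cv = cv,
                 midparent_weight = midparent_weight,
                 progeny_noise_sd = progeny_noise_sd,
                 pd_drift = pd_drift,
                 section_size_slope = section_size_slope,
                 frac_zero_pd = frac_zero_pd,
                 frac_unknown_parent = frac_unknown_parent,
                 ap_range = ap_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# per-stage sub-seed: adding taxa or stages must not perturb earlier
# draws, so each stage reseeds from a deterministic function of the
# master seed (kept below 2^31)
stage_seed <- function(config, stage) {
  offsets <- c(taxa = 101L, pedigree = 211L, replicates = 307L, ap = 401L)
  (abs(config$seed) %% 1000000L) * 1000L + offsets[[stage]]
}

#' Generate species taxonomy and true trait means
#'
#' Species are assigned sections I-V cyclically; trait means are drawn
#' uniformly within the configured ranges, after which
#' `section_size_slope * section_value` is added to the size traits P, E
#' and S (floored at 0). A `frac_zero_pd` share of species (rounded)
#' receives perforation density exactly 0. E' is E times a uniform draw
#' from `eprime_ratio_range`.
#'
#' @param config a `sim_config`.
#' @return List with `taxonomy` (data.frame `taxon_id`, `name`, `rank`,
#'   `section`, `section_value`) and `true_means` (data.frame of
#'   per-species trait means, one column per trait).
#' @export
generate_taxa <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "taxa"))
  n <- config$n_species
  ids <- sprintf("sp%02d", seq_len(n))
  sec_vals <- rep(1:5, length.out = n)
  taxonomy <- data.frame(
    taxon_id = ids,
    name = sprintf("Species %02d", seq_len(n)),
    rank = "species",
    section = names(section_levels())[sec_vals],
    section_value = sec_vals,
    stringsAsFactors = FALSE
  )

  draw <- function(tr) stats::runif(n, config$trait_mean_ranges[[tr]][1],
                                    config$trait_mean_ranges[[tr]][2])
  means <- data.frame(taxon_id = ids,
                      P = draw("P"), S = draw("S"),
                      RW = draw("RW"), FW = draw("FW"), PD = draw("PD"),
                      stringsAsFactors = FALSE)
  shift <- config$section_size_slope * sec_vals
  means$P <- pmax(0, means$P + shift)
  means$S <- pmax(0, means$S + shift)
  # E is drawn conditionally on the section-adjusted P so that every
  # species lands inside the configured P/E shape range as well as the
  # (equally section-shifted) E mean range; if the two constraints are
  # incompatible the shape range wins
  e_rng <- config$trait_mean_ranges[["E"]]
  pe_rng <- config$pe_ratio_range
  lo <- pmax(e_rng[1] + shift, means$P / pe_rng[2])
  hi <- pmin(e_rng[2] + shift, means$P / pe_rng[1])
  bad <- lo > hi
  lo[bad] <- means$P[bad] / pe_rng[2]
  hi[bad] <- means$P[bad] / pe_rng[1]
  means$E <- stats::runif(n, lo, hi)
  # E' from the realized E so that E'/E stays inside its ratio range
  means$Eprime <- means$E * stats::runif(n, config$eprime_ratio_range[1],
                                         config$eprime_ratio_range[2])
  # imperforate share: deterministic count, random choice within stream
  n_zero <- round(config$frac_zero_pd * n)
  if (n_zero > 0) means$PD[sample.int(n, n_zero)] <- 0
  list(taxonomy = taxonomy, true_means = means)
}

#' Generate cultivars and their breeding routes
#'
#' Each cultivar draws two distinct species parents; with probability
#' `frac_unknown_parent` the second slot is recorded as unknown. Cultivar
#' trait means are `w * parent1 + (1 - w) * parent2` plus relative
#' Gaussian noise (`progeny_noise_sd` as a fraction of the midparent
#' value); with an unknown slot the single known parent contributes with
#' weight 1. Perforation density is additionally multiplied by the drift
#' factor `pd_drift`.
#'
#' @param config a `sim_config`.
#' @param taxa output of [generate_taxa()].
#' @return List with `pedigree` (a [pedigree()]), `taxonomy` (cultivar
#'   rows) and `true_means` (cultivar trait means).
#' @export
generate_pedigree_and_cultivars <- function(config, taxa) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_species < 2) stop("need at least 2 species for crosses")
  set.seed(stage_seed(config, "pedigree"))
  n <- config$n_cultivars
  if (n == 0L) {
    empty_tax <- data.frame(taxon_id = character(0), name = character(0),
                            rank = character(0), section = character(0),
                            section_value = integer(0),
                            stringsAsFactors = FALSE)
    empty_means <- taxa$true_means[0, ]
    return(list(pedigree = pedigree(data.frame(progeny = character(0),
                                               parent1 = character(0),
                                               parent2 = character(0))),
                taxonomy = empty_tax, true_means = empty_means))
  }
  ids <- sprintf("cv%02d", seq_len(n))
  sp <- taxa$true_means
  traits <- pollen_traits()
  w <- config$midparent_weight

  parent1 <- character(n); parent2 <- character(n)
  mean_rows <- vector("list", n)
  for (i in seq_len(n)) {
    pick <- sample.int(nrow(sp), 2L)
    parent1[i] <- sp$taxon_id[pick[1]]
    unknown2 <- stats::runif(1) < config$frac_unknown_parent
    parent2[i] <- if (unknown2) PARENT_UNKNOWN else sp$taxon_id[pick[2]]
    base <- if (unknown2) {
      unlist(sp[pick[1], traits])
    } else {
      w * unlist(sp[pick[1], traits]) + (1 - w) * unlist(sp[pick[2], traits])
    }
    noise <- stats::rnorm(length(traits), 0,
                          config$progeny_noise_sd * abs(base))
    vals <- pmax(base + noise, 0)  # named arg first: pmax keeps its attributes
    vals["PD"] <- vals["PD"] * config$pd_drift
    # E' tracks E geometrically: perturbing the two independently would
    # let the E'/E ratio drift above 1, which no real grain shows; the
    # inherited ratio gets its own (small) noise instead
    ratio <- base[["Eprime"]] / base[["E"]]
    ratio <- ratio * (1 + stats::rnorm(1, 0, config$progeny_noise_sd / 2))
    vals["Eprime"] <- vals[["E"]] * min(max(ratio, 0.05), 0.99)
    mean_rows[[i]] <- vals
  }
  true_means <- cbind(data.frame(taxon_id = ids, stringsAsFactors = FALSE),
                      as.data.frame(do.call(rbind, mean_rows)))
  taxonomy <- data.frame(taxon_id = ids,
                         name = sprintf("Cultivar %02d", seq_len(n)),
                         rank = "cultivar",
                         section = NA_character_,
                         section_value = NA_integer_,
                         stringsAsFactors = FALSE)
  ped <- if (n > 0) {
    pedigree(data.frame(progeny = ids, parent1 = parent1, parent2 = parent2,
                        source = "synthetic", stringsAsFactors = FALSE))
  } else {
    pedigree(data.frame(progeny = character(0), parent1 = character(0),
                        parent2 = character(0)))
  }
  list(pedigree = ped, taxonomy = taxonomy, true_means = true_means)
}

#' Generate replicated measurements around true means
#'
#' Each taxon x trait cell receives `replicates` draws from
#' Normal(mean, cv * mean) truncated at zero; a zero mean yields all-zero
#' replicates. Aberrant pollen rates are drawn uniformly within
#' `ap_range` per taxon.
#'
#' @param true_means data.frame with `taxon_id` and one column per trait.
#' @param config a `sim_config`.
#' @return A validated `trait_table`.
#' @export
generate_replicates <- function(true_means, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "replicates"))
  traits <- intersect(pollen_traits(), names(true_means))
  reps <- config$replicates
  rows <- vector("list", nrow(true_means) * length(traits))
  idx <- 0L
  for (i in seq_len(nrow(true_means))) {
    for (tr in traits) {
      mu <- true_means[[tr]][i]
      vals <- if (mu == 0) {
        rep(0, reps)
      } else {
        pmax(0, stats::rnorm(reps, mu, config$within_cv[[tr]] * mu))
      }
      idx <- idx + 1L
      rows[[idx]] <- data.frame(taxon_id = true_means$taxon_id[i],
                                replicate = seq_len(reps),
                                trait = tr, value = vals,
                                stringsAsFactors = FALSE)
    }
  }
  values <- do.call(rbind, rows)
  set.seed(stage_seed(config, "ap"))
  ap <- stats::setNames(stats::runif(nrow(true_means), config$ap_range[1],
                                     config$ap_range[2]),
                        true_means$taxon_id)
  suppressWarnings(
    trait_table(values, ap = ap, expected_replicates = config$replicates)
  )
}

#' Generate a full synthetic dataset
#'
#' Chains [generate_taxa()], [generate_pedigree_and_cultivars()] and
#' [generate_replicates()] into one deterministic dataset.
#'
#' @param config a `sim_config`.
#' @return List with `taxonomy`, `true_means` (species and cultivars
#'   combined), `pedigree`, `table` (the replicated `trait_table`).
#' @export
generate_dataset <- function(config = sim_config()) {
  taxa <- generate_taxa(config)
  cult <- generate_pedigree_and_cultivars(config, taxa)
  taxonomy <- rbind(taxa$taxonomy, cult$taxonomy)
  common <- intersect(names(taxa$true_means), names(cult$true_means))
  true_means <- rbind(taxa$true_means[common], cult$true_means[common])
  table <- generate_replicates(true_means, config)
  list(taxonomy = taxonomy, true_means = true_means,
       pedigree = cult$pedigree, table = table)
}
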