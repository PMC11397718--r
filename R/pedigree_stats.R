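#' Read a family-routes table
#'
#' A family-routes table carries, per breeding route, everything the
#' aggregation and perforation-density scores need at row level: the
#' progeny's cluster label, each parent's identity, status and label, and
#' perforation densities. Columns: `progeny`, `parent1`, `parent2`,
#' `parent1_status`, `parent2_status` (`measured`, `untested`, `unknown`),
#' `progeny_label6`, `parent1_label6`, `parent2_label6` (six-level labels
#' such as `A` or `D2`; empty when not clustered), `pd_progeny`,
#' `pd_parent1`, `pd_parent2` (empty when not measured) and optionally
#' `reconstructed`.
#'
#' The packaged fixture `family_routes_synthetic.csv` transcribes a
#' published 28-cultivar route table; rows whose routes appear only
#' graphically in the source, and all perforation-density values (raw
#' data not deposited), are synthetic reconstructions consistent with the
#' table's printed per-row indicator columns. See the package vignette.
#'
#' @param path file path; default the packaged fixture.
#' @return data.frame of routes.
#' @export
read_family_routes <- function(path = system.file("extdata",
                                                  "family_routes_synthetic.csv",
                                                  package = "pollenphen")) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("progeny", "parent1", "parent2", "parent1_status",
                "parent2_status", "progeny_label6", "parent1_label6",
                "parent2_label6", "pd_progeny", "pd_parent1", "pd_parent2")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("routes table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- !df$parent1_status %in% c("measured", "untested", "unknown") |
    !df$parent2_status %in% c("measured", "untested", "unknown")
  if (any(bad)) stop("invalid parent status at row(s) ",
                     paste(which(bad), collapse = ", "))
  df
}

label_to_group <- function(label6) {
  out <- sub("[0-9]+$", "", label6)
  out[is.na(label6) | label6 == ""] <- NA_character_
  out
}

new_aggregation_report <- function(per_progeny, level, rule) {
  evaluable <- !is.na(per_progeny)
  if (!any(evaluable)) {
    stop("no evaluable progeny: aggregation percentage undefined")
  }
  structure(list(per_progeny = per_progeny,
                 level = level,
                 rule = rule,
                 n_evaluable = sum(evaluable),
                 n_aggregated = sum(per_progeny[evaluable]),
                 percentage = 100 * mean(per_progeny[evaluable])),
            class = "aggregation_report")
}

#' @export
print.aggregation_report <- function(x, ...) {
  cat(sprintf("Family aggregation (%s, rule = %s): %.2f%% (%d/%d evaluable)\n",
              x$level, x$rule, x$percentage, x$n_aggregated, x$n_evaluable))
  invisible(x)
}

#' Family aggregation from a routes table
#'
#' A progeny aggregates if its cluster label equals the label of at least
#' one labelled parent (`rule = "any"`, the default) or of every labelled
#' parent (`rule = "all"`). At `four_group` level labels are compared
#' after collapsing subgroups to their top-level group; at `six_group`
#' level the six-level labels are compared directly. Progeny with no
#' labelled parent are not evaluable and are excluded from the
#' denominator.
#'
#' @param routes data.frame as from [read_family_routes()].
#' @param level `"four_group"` or `"six_group"`.
#' @param rule `"any"` (default) or `"all"`.
#' @return An `aggregation_report`.
#' @export
aggregation_from_routes <- function(routes,
                                    level = c("four_group", "six_group"),
                                    rule = c("any", "all")) {
  level <- match.arg(level)
  rule <- match.arg(rule)
  collapse <- if (level == "four_group") label_to_group else identity
  per <- stats::setNames(rep(NA, nrow(routes)), routes$progeny)
  for (i in seq_len(nrow(routes))) {
    child <- collapse(routes$progeny_label6[i])
    plabs <- c(routes$parent1_label6[i], routes$parent2_label6[i])
    plabs <- collapse(plabs[!is.na(plabs) & plabs != ""])
    if (length(plabs) == 0 || is.na(child)) next
    per[i] <- if (rule == "any") any(plabs == child) else all(plabs == child)
  }
  new_aggregation_report(per, level, rule)
}

# build a routes table from a cluster partition plus a pedigree; named
# parents absent from the partition are downgraded to `untested`
routes_from_cluster <- function(result, ped, pd_means = NULL) {
  stopifnot(inherits(result, "cluster_result"), inherits(ped, "pedigree"))
  lab <- stats::setNames(result$assignments$label6,
                         result$assignments$taxon_id)
  pd_of <- function(id) {
    if (is.null(pd_means)) return(NA_real_)
    if (id %in% names(pd_means)) unname(pd_means[[id]]) else NA_real_
  }
  slot <- function(p) {
    if (p == PARENT_UNKNOWN) {
      list(status = "unknown", label = "", pd = NA_real_)
    } else if (p == PARENT_UNTESTED) {
      list(status = "untested", label = "", pd = NA_real_)
    } else {
      measured <- p %in% names(lab) ||
        (!is.null(pd_means) && p %in% names(pd_means))
      list(status = if (measured) "measured" else "untested",
           label = if (p %in% names(lab)) unname(lab[[p]]) else "",
           pd = pd_of(p))
    }
  }
  rows <- lapply(seq_len(nrow(ped)), function(i) {
    s1 <- slot(ped$parent1[i]); s2 <- slot(ped$parent2[i])
    child <- ped$progeny[i]
    data.frame(progeny = child,
               parent1 = ped$parent1[i], parent2 = ped$parent2[i],
               parent1_status = s1$status, parent2_status = s2$status,
               progeny_label6 = if (child %in% names(lab))
                 unname(lab[[child]]) else "",
               parent1_label6 = s1$label, parent2_label6 = s2$label,
               pd_progeny = pd_of(child),
               pd_parent1 = s1$pd, pd_parent2 = s2$pd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Family aggregation of progeny with their parents
#'
#' Scores, for every breeding route, whether the progeny falls in the
#' same cluster group as at least one of its clustered parents -- the
#' family-aggregation statistic used to judge whether a phenotype-based
#' clustering recovers pedigree structure.
#'
#' @param result a `cluster_result`.
#' @param ped a `pedigree`.
#' @param level `"four_group"` (top-level groups) or `"six_group"`
#'   (subgroups where present).
#' @param rule `"any"` (default: one matching parent suffices) or
#'   `"all"`.
#' @return An `aggregation_report`.
#' @export
family_aggregation <- function(result, ped,
                               level = c("four_group", "six_group"),
                               rule = c("any", "all")) {
  aggregation_from_routes(routes_from_cluster(result, ped),
                          level = match.arg(level), rule = match.arg(rule))
}

new_pd_report <- function(per_progeny, mode) {
  evaluable <- !is.na(per_progeny)
  if (!any(evaluable)) {
    stop("no evaluable progeny: progression percentage undefined")
  }
  structure(list(per_progeny = per_progeny,
                 mode = mode,
                 n_evaluable = sum(evaluable),
                 n_progressing = sum(per_progeny[evaluable]),
                 percentage = 100 * mean(per_progeny[evaluable])),
            class = "pd_progression_report")
}

#' @export
print.pd_progression_report <- function(x, ...) {
  cat(sprintf("PD progression (%s): %.2f%% (%d/%d evaluable)\n",
              x$mode, x$percentage, x$n_progressing, x$n_evaluable))
  invisible(x)
}

#' Perforation-density progression from a routes table
#'
#' A progeny progresses if its perforation density exceeds that of at
#' least one comparator parent. In `exclude_unknown` mode only measured
#' parents are comparators; progeny with no measured parent are not
#' evaluable. In `assume_lower` mode an unknown or untested parent is
#' assumed to have lower perforation density than the progeny, so it
#' auto-succeeds as a comparator. By construction the `assume_lower`
#' percentage can never fall below the `exclude_unknown` one.
#'
#' @param routes data.frame as from [read_family_routes()].
#' @param mode `"exclude_unknown"` or `"assume_lower"`.
#' @return A `pd_progression_report`.
#' @export
pd_progression_from_routes <- function(routes,
                                       mode = c("exclude_unknown",
                                                "assume_lower")) {
  mode <- match.arg(mode)
  per <- stats::setNames(rep(NA, nrow(routes)), routes$progeny)
  for (i in seq_len(nrow(routes))) {
    child_pd <- routes$pd_progeny[i]
    if (is.na(child_pd)) next
    status <- c(routes$parent1_status[i], routes$parent2_status[i])
    ppd <- c(routes$pd_parent1[i], routes$pd_parent2[i])
    measured <- status == "measured" & !is.na(ppd)
    beats_measured <- any(child_pd > ppd[measured])
    if (mode == "exclude_unknown") {
      if (!any(measured)) next
      per[i] <- beats_measured
    } else {
      per[i] <- any(!measured) || beats_measured
    }
  }
  new_pd_report(per, mode)
}

#' Perforation-density progression of progeny over parents
#'
#' @param pd_means named numeric vector taxon -> mean perforation
#'   density; every evaluable progeny must be present.
#' @param ped a `pedigree`.
#' @param mode `"exclude_unknown"` or `"assume_lower"`; see
#'   [pd_progression_from_routes()].
#' @param result optional `cluster_result` (labels are carried through
#'   but not needed for this score).
#' @return A `pd_progression_report`.
#' @export
pd_progression <- function(pd_means, ped,
                           mode = c("exclude_unknown", "assume_lower"),
                           result = NULL) {
  if (is.null(result)) {
    # a label-free shell: only statuses and PD values matter here
    assignments <- data.frame(taxon_id = character(0),
                              label6 = character(0),
                              stringsAsFactors = FALSE)
    result <- structure(list(assignments = assignments),
                        class = "cluster_result")
  }
  routes <- routes_from_cluster(result, ped, pd_means = pd_means)
  pd_progression_from_routes(routes, mode = match.arg(mode))
}

#' Section aggregation of species in cluster groups
#'
#' For each taxonomic section, finds the modal cluster label among its
#' species; a species aggregates if its label equals its section's modal
#' label. Ties for the mode are resolved permissively (a species matching
#' any tied modal label counts) and reported. Percentages are computed
#' separately at group level and at six-level (subgroup) resolution.
#'
#' @param result a `cluster_result` (or a data.frame with `taxon_id`,
#'   `group`, `label6`).
#' @param taxonomy data.frame with `taxon_id`, `rank`, `section`.
#' @return List of class `section_aggregation`: per-level percentage,
#'   matched/total counts, modal labels per section, and tie flags.
#' @export
section_aggregation <- function(result, taxonomy) {
  assignments <- if (inherits(result, "cluster_result")) {
    result$assignments
  } else {
    as.data.frame(result)
  }
  sp <- taxonomy[taxonomy$rank == "species" & !is.na(taxonomy$section) &
                   taxonomy$section != "", c("taxon_id", "section")]
  if (nrow(sp) == 0) stop("no species with section labels")
  a <- merge(sp, assignments, by = "taxon_id")
  if (nrow(a) == 0) stop("no sectioned species present in the partition")

  score_level <- function(labels) {
    ok <- !is.na(labels) & labels != ""
    labs <- labels[ok]
    secs <- a$section[ok]
    modal <- lapply(split(labs, secs), function(x) {
      tab <- table(x)
      names(tab)[tab == max(tab)]
    })
    ties <- names(modal)[lengths(modal) > 1]
    matched <- mapply(function(lab, sec) lab %in% modal[[sec]], labs, secs)
    list(percentage = 100 * mean(matched),
         n_matched = sum(matched), n_total = length(matched),
         modal = modal, ties = ties)
  }

  out <- list(group = score_level(label_to_group(a$label6)),
              subgroup = score_level(a$label6))
  for (lv in names(out)) {
    if (length(out[[lv]]$ties) > 0) {
      message("modal-label tie(s) at ", lv, " level in section(s): ",
              paste(out[[lv]]$ties, collapse = ", "))
    }
  }
  structure(out, class = "section_aggregation")
}

#' @export
print.section_aggregation <- function(x, ...) {
  cat(sprintf("Section aggregation: %.1f%% same group (%d/%d), %.1f%% same subgroup (%d/%d)\n",
              x$group$percentage, x$group$n_matched, x$group$n_total,
              x$subgroup$percentage, x$subgroup$n_matched,
              x$subgroup$n_total))
  invisible(x)
}

#' Hybridization frequency of parent species
#'
#' The frequency of a species is the fraction of breeding routes in which
#' it appears as a parent; a species crossed with itself in one route is
#' counted once for that route. Frequencies are classified into high,
#' medium and low bands.
#'
#' @param ped a `pedigree` (one row per route).
#' @param thresholds named vector with `high` and `medium` lower bounds
#'   on the frequency scale (defaults 0.20 and 0.05).
#' @return List of class `hybridization_frequency`: `frequency` (named,
#'   sorted decreasing), `classification`, `counts`, `total_crosses`.
#' @export
hybridization_frequency <- function(ped,
                                    thresholds = c(high = 0.20,
                                                   medium = 0.05)) {
  stopifnot(inherits(ped, "pedigree"))
  if (nrow(ped) == 0) stop("empty pedigree: frequencies undefined")
  per_route <- lapply(seq_len(nrow(ped)),
                      function(i) known_parents(ped[i, ]))
  counts <- table(unlist(per_route))
  freq <- sort(as.numeric(counts) / nrow(ped), decreasing = TRUE)
  names(freq) <- names(counts)[order(-as.numeric(counts),
                                     names(counts))]
  freq <- stats::setNames(as.numeric(counts[names(freq)]) / nrow(ped),
                          names(freq))
  cls <- ifelse(freq >= thresholds[["high"]], "high",
                ifelse(freq >= thresholds[["medium"]], "medium", "low"))
  structure(list(frequency = freq,
                 classification = stats::setNames(cls, names(freq)),
                 counts = stats::setNames(as.integer(counts[names(freq)]),
                                          names(freq)),
                 total_crosses = nrow(ped)),
            class = "hybridization_frequency")
}

#' @export
print.hybridization_frequency <- function(x, ...) {
  cat("Hybridization frequency over", x$total_crosses, "crosses\n")
  df <- data.frame(species = names(x$frequency),
                   frequency = round(x$frequency, 3),
                   class = x$classification, row.names = NULL)
  print(utils::head(df, 10))
  if (nrow(df) > 10) cat("  ...", nrow(df) - 10, "more\n")
  invisible(x)
}

#' Concordance of two hybridization-frequency estimates
#'
#' Pearson correlation between two frequency vectors over their shared
#' species, e.g. a study-derived estimate against literature records.
#'
#' @param study,literature `hybridization_frequency` objects or named
#'   numeric vectors.
#' @param min_shared minimum number of shared species (default 3).
#' @return List with `pearson_r`, `r_squared`, `p`, `n_shared`, `species`.
#' @export
frequency_concordance <- function(study, literature, min_shared = 3L) {
  fv <- function(x) if (inherits(x, "hybridization_frequency"))
    x$frequency else unlist(x)
  a <- fv(study); b <- fv(literature)
  shared <- intersect(names(a), names(b))
  if (length(shared) < min_shared) {
    stop("need at least ", min_shared, " shared species; got ",
         length(shared))
  }
  if (stats::sd(a[shared]) == 0 || stats::sd(b[shared]) == 0) {
    stop("zero variance in a frequency vector; correlation undefined")
  }
  ct <- stats::cor.test(a[shared], b[shared], method = "pearson")
  list(pearson_r = unname(ct$estimate),
       r_squared = unname(ct$estimate)^2,
       p = ct$p.value,
       n_shared = length(shared),
       species = shared)
}
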