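#' Trait codes usable in uniformity/distinctness statistics
#'
#' The seven measured traits plus the three replicate-level shape ratios
#' (`P_E`, `P_Eprime`, `Eprime_E`, formed by pairing replicates by index).
#'
#' @return Character vector of codes accepted by
#'   [intraspecific_uniformity()] and [interspecific_distinctness()].
#' @export
stat_traits <- function() {
  c(pollen_traits(), "P_E", "P_Eprime", "Eprime_E")
}

# long data.frame (taxon_id, replicate, value) for a measured trait or a
# replicate-level ratio trait
long_values <- function(table, trait) {
  stopifnot(inherits(table, "trait_table"))
  v <- table$values
  if (trait %in% pollen_traits()) {
    out <- v[v$trait == trait, c("taxon_id", "replicate", "value")]
    rownames(out) <- NULL
    return(out)
  }
  parts <- switch(trait,
    P_E = c("P", "E"),
    P_Eprime = c("P", "Eprime"),
    Eprime_E = c("Eprime", "E"),
    stop("unknown trait code: ", trait)
  )
  num <- v[v$trait == parts[1], c("taxon_id", "replicate", "value")]
  den <- v[v$trait == parts[2], c("taxon_id", "replicate", "value")]
  m <- merge(num, den, by = c("taxon_id", "replicate"),
             suffixes = c("_num", "_den"))
  if (any(m$value_den == 0)) stop("zero denominator replicate for ", trait)
  data.frame(taxon_id = m$taxon_id, replicate = m$replicate,
             value = m$value_num / m$value_den, stringsAsFactors = FALSE)
}

#' Intraspecific uniformity: mean within-taxon coefficient of variation
#'
#' For each taxon i with replicated values of the trait, the within-taxon
#' coefficient of variation is S_i / X-bar_i, with S_i the sample (n-1)
#' standard deviation of the replicates and X-bar_i their mean. The
#' uniformity statistic cvbar is the unweighted mean of these over taxa.
#' A trait with cvbar at or below the threshold (default 15%) is
#' considered uniform within taxa. Taxa whose mean is zero for the trait
#' (e.g. perforation density of imperforate taxa) have an undefined CV;
#' they are excluded from the average and counted.
#'
#' @param table a `trait_table`.
#' @param trait one of [stat_traits()].
#' @param threshold uniformity threshold on the CV scale (default 0.15).
#' @return List of class `uniformity_result`: `trait`, `cvbar`,
#'   `n_taxa_used`, `n_excluded_zero_mean`, `uniform`, `threshold`.
#' @export
intraspecific_uniformity <- function(table, trait, threshold = 0.15) {
  lv <- long_values(table, trait)
  if (nrow(lv) == 0) stop("no data for trait ", trait)
  means <- tapply(lv$value, lv$taxon_id, mean)
  sds <- tapply(lv$value, lv$taxon_id, stats::sd)
  zero <- means == 0
  if (all(zero)) stop("no taxon with non-zero mean for trait ", trait)
  cvs <- sds[!zero] / means[!zero]
  cvbar <- mean(cvs)
  structure(list(trait = trait,
                 cvbar = unname(cvbar),
                 per_taxon_cv = cvs,
                 n_taxa_used = sum(!zero),
                 n_excluded_zero_mean = sum(zero),
                 uniform = unname(cvbar <= threshold + 1e-12),
                 threshold = threshold),
            class = "uniformity_result")
}

#' Interspecific distinctness: coefficient of variation of taxon means
#'
#' The distinctness statistic is cv = S' / X-bar', where S' and X-bar'
#' are the sample standard deviation and mean of the per-taxon trait
#' means. A trait with cv at or above the threshold (default 15%)
#' discriminates well among taxa. A one-way ANOVA of replicate values
#' across taxa accompanies the statistic.
#'
#' @param table a `trait_table`.
#' @param trait one of [stat_traits()].
#' @param threshold distinctness threshold on the CV scale (default 0.15).
#' @return List of class `distinctness_result`: `trait`, `cv`, `distinct`,
#'   `anova_F`, `anova_p`, `n_taxa`, `threshold`.
#' @export
interspecific_distinctness <- function(table, trait, threshold = 0.15) {
  lv <- long_values(table, trait)
  taxa <- unique(lv$taxon_id)
  if (length(taxa) < 2) stop("need at least 2 taxa for distinctness")
  means <- tapply(lv$value, lv$taxon_id, mean)
  grand <- mean(means)
  if (grand == 0) stop("mean of taxon means is zero for trait ", trait,
                       "; cv undefined")
  cv <- stats::sd(means) / grand
  fit <- stats::aov(value ~ factor(taxon_id), data = lv)
  an <- summary(fit)[[1]]
  structure(list(trait = trait,
                 cv = unname(cv),
                 distinct = unname(cv >= threshold - 1e-12),
                 anova_F = an[["F value"]][1],
                 anova_p = an[["Pr(>F)"]][1],
                 n_taxa = length(taxa),
                 threshold = threshold),
            class = "distinctness_result")
}

#' Uniformity and distinctness across traits, tidy
#'
#' @param table a `trait_table`.
#' @param traits trait codes (default: every code in [stat_traits()] with
#'   data present).
#' @param threshold CV threshold applied to both statistics.
#' @return data.frame with columns `trait`, `statistic` (`cvbar`/`cv`),
#'   `value`, `threshold`, `verdict` (`uniform`/`non_uniform` or
#'   `distinct`/`not_distinct`), `n_taxa`, `n_excluded`.
#' @export
uniformity_distinctness_summary <- function(table, traits = NULL,
                                            threshold = 0.15) {
  if (is.null(traits)) {
    present <- unique(table$values$trait)
    ratio_ok <- all(c("P", "E", "Eprime") %in% present)
    traits <- c(intersect(pollen_traits(), present),
                if (ratio_ok) c("P_E", "P_Eprime", "Eprime_E"))
  }
  rows <- lapply(traits, function(tr) {
    u <- intraspecific_uniformity(table, tr, threshold)
    d <- interspecific_distinctness(table, tr, threshold)
    rbind(
      data.frame(trait = tr, statistic = "cvbar", value = u$cvbar,
                 threshold = threshold,
                 verdict = if (u$uniform) "uniform" else "non_uniform",
                 n_taxa = u$n_taxa_used, n_excluded = u$n_excluded_zero_mean,
                 stringsAsFactors = FALSE),
      data.frame(trait = tr, statistic = "cv", value = d$cv,
                 threshold = threshold,
                 verdict = if (d$distinct) "distinct" else "not_distinct",
                 n_taxa = d$n_taxa, n_excluded = 0L,
                 stringsAsFactors = FALSE)
    )
  })
  do.call(rbind, rows)
}

#' Tukey HSD with a compact letter display
#'
#' Runs a one-way ANOVA followed by Tukey's honest significant difference
#' over all group pairs, then summarizes the pairwise pattern as a compact
#' letter display (CLD): two groups share no letter exactly when their
#' Tukey p-value is below `alpha`. Letters are assigned with the
#' insert-and-absorb algorithm, processing groups in order of descending
#' mean (ties broken lexicographically by group label), so "a" attaches to
#' the largest mean.
#'
#' If every value in every group is identical the comparison is degenerate
#' and all groups share the single letter "a".
#'
#' @param groups named list of numeric vectors (group label -> values),
#'   at least 2 groups with at least 2 values each (groups of size 1 are
#'   tolerated but contribute no within-group variance).
#' @param alpha significance level (default 0.05).
#' @return List of class `cld_result`: `letters` (named character),
#'   `p_values` (symmetric matrix), `means`, `alpha`.
#' @export
tukey_cld <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("`groups` must be a named list")
  }
  labs <- names(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labs, lengths(groups)), levels = labs)
  means <- vapply(groups, mean, numeric(1))

  k <- length(labs)
  pmat <- matrix(1, k, k, dimnames = list(labs, labs))
  if (stats::var(values) > 0) {
    fit <- stats::aov(values ~ g)
    resid_ms <- sum(stats::resid(fit)^2)
    if (resid_ms > 1e-12 * stats::var(values) * length(values)) {
      tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
      pairs <- rownames(tk)
      for (idx in seq_along(pairs)) {
        ab <- strsplit(pairs[idx], "-", fixed = TRUE)[[1]]
        # group labels may themselves contain "-": split at every
        # position and keep the one matching two known labels
        if (length(ab) != 2 || !all(ab %in% labs)) {
          hit <- NULL
          for (pos in gregexpr("-", pairs[idx], fixed = TRUE)[[1]]) {
            a <- substr(pairs[idx], 1, pos - 1)
            b <- substr(pairs[idx], pos + 1, nchar(pairs[idx]))
            if (a %in% labs && b %in% labs) { hit <- c(a, b); break }
          }
          if (is.null(hit)) stop("cannot parse Tukey pair label: ", pairs[idx])
          ab <- hit
        }
        pmat[ab[1], ab[2]] <- pmat[ab[2], ab[1]] <- tk[idx, "p adj"]
      }
    } else {
      # zero residual variance but distinct means: exact separation
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        if (means[i] != means[j]) pmat[i, j] <- pmat[j, i] <- 0
      }
    }
  }

  letters_out <- cld_letters(pmat, alpha = alpha, means = means)
  structure(list(letters = letters_out, p_values = pmat, means = means,
                 alpha = alpha),
            class = "cld_result")
}

#' Compact letters from a pairwise p-value matrix
#'
#' Insert-and-absorb letter assignment: start from one letter shared by
#' all groups; for each significant pair sharing a letter, split that
#' letter column in two, dropping one member from each copy; absorb any
#' column whose membership is a subset of another's. The resulting
#' display satisfies, for every pair, shared-letter iff not significant.
#'
#' @param pmat symmetric matrix of pairwise p-values with group dimnames.
#' @param alpha significance level.
#' @param means optional named means used to order groups (descending)
#'   before letters are assigned; default alphabetical order.
#' @return Named character vector of letter strings.
#' @export
cld_letters <- function(pmat, alpha = 0.05, means = NULL) {
  labs <- rownames(pmat)
  k <- length(labs)
  if (is.null(means)) means <- stats::setNames(rep(0, k), labs)
  ord <- order(-means[labs], labs)
  labs <- labs[ord]

  # columns: logical membership vectors over ordered labels
  cols <- list(rep(TRUE, k))
  sig <- function(a, b) pmat[labs[a], labs[b]] < alpha

  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      if (!sig(a, b)) next
      new_cols <- list()
      for (col in cols) {
        if (col[a] && col[b]) {
          c1 <- col; c1[b] <- FALSE
          c2 <- col; c2[a] <- FALSE
          new_cols <- c(new_cols, list(c1, c2))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop any column whose members are a subset of another's
      # (maximal columns are never dropped, so subset chains resolve)
      keep <- rep(TRUE, length(new_cols))
      for (i in seq_along(new_cols)) {
        for (j in seq_along(new_cols)) {
          if (i == j) next
          is_subset <- all(!new_cols[[i]] | new_cols[[j]])
          is_equal <- identical(new_cols[[i]], new_cols[[j]])
          if (is_subset && (!is_equal || j < i)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }

  # order letters by first member, then assign a, b, c, ...
  first_member <- vapply(cols, function(col) which(col)[1], integer(1))
  cols <- cols[order(first_member)]
  letter_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- stats::setNames(rep("", k), labs)
  for (i in seq_along(cols)) {
    out[cols[[i]]] <- paste0(out[cols[[i]]], letter_pool[i])
  }
  out[rownames(pmat)]
}

#' Erdtman pollen size class from mean polar-axis length
#'
#' Medium-sized pollen spans 25.1-50 micrometres (both ends inclusive);
#' shorter grains are small, longer ones large.
#'
#' @param mean_P mean polar-axis length in micrometres (> 0); vectorized.
#' @return Character vector in `{"small", "medium", "large"}`.
#' @export
classify_size <- function(mean_P) {
  if (any(!is.finite(mean_P) | mean_P <= 0)) {
    stop("mean polar-axis length must be positive and finite")
  }
  ifelse(mean_P > 50, "large", ifelse(mean_P >= 25.1, "medium", "small"))
}

#' Erdtman pollen shape class from the P/E ratio
#'
#' Subprolate: P/E in \[1.14, 1.33); prolate: \[1.33, 2.00\] (both ends
#' inclusive); perprolate: > 2.00. Ratios below 1.14 fall outside the
#' prolate catalogue and are flagged `"out_of_range"` rather than raising
#' an error.
#'
#' @param P_over_E P/E ratio (> 0); vectorized.
#' @return Character vector in `{"subprolate", "prolate", "perprolate",
#'   "out_of_range"}`.
#' @export
classify_shape <- function(P_over_E) {
  if (any(!is.finite(P_over_E) | P_over_E <= 0)) {
    stop("P/E must be positive and finite")
  }
  ifelse(P_over_E > 2, "perprolate",
         ifelse(P_over_E >= 1.33, "prolate",
                ifelse(P_over_E >= 1.14, "subprolate", "out_of_range")))
}
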