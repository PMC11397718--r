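#' Ordinal trend of a trait across taxonomic sections
#'
#' Pearson correlation between the ordinal section value (1 = most
#' ancient to 5 = most advanced) and per-species trait means, with a
#' two-sided test on n - 2 degrees of freedom. Only species carry
#' sections; cultivars are ignored.
#'
#' @param means data.frame with `taxon_id` and a column named `trait`
#'   ([taxon_means()] output, optionally merged with derived ratios).
#' @param taxonomy data.frame with `taxon_id`, `rank`, `section_value`.
#' @param trait column of `means` to correlate.
#' @param alpha significance level for the `significant` flag.
#' @return List of class `trend_result`: `trait`, `coding`, `r`, `p`,
#'   `n`, `significant`.
#' @export
section_trend <- function(means, taxonomy, trait, alpha = 0.05) {
  sp <- taxonomy[taxonomy$rank == "species" & !is.na(taxonomy$section_value),
                 c("taxon_id", "section_value")]
  m <- merge(sp, means[c("taxon_id", trait)], by = "taxon_id")
  m <- m[!is.na(m[[trait]]), ]
  if (nrow(m) < 3) stop("need at least 3 sectioned species with the trait")
  trend_cor(m$section_value, m[[trait]], trait, "section_order", alpha)
}

#' Ordinal trend of a trait from species to cultivars
#'
#' Pearson correlation between rank coding (species = 1, cultivar = 2)
#' and per-taxon trait means. With binary coding this is the
#' point-biserial correlation, and its p-value equals that of a
#' pooled-variance two-sample t-test between the two rank populations.
#'
#' @inheritParams section_trend
#' @return A `trend_result` with `coding = "rank_order"`.
#' @export
rank_trend <- function(means, taxonomy, trait, alpha = 0.05) {
  tx <- taxonomy[c("taxon_id", "rank")]
  m <- merge(tx, means[c("taxon_id", trait)], by = "taxon_id")
  m <- m[!is.na(m[[trait]]), ]
  if (!all(c("species", "cultivar") %in% m$rank)) {
    stop("both ranks must be present with trait data")
  }
  coding <- ifelse(m$rank == "species", 1, 2)
  trend_cor(coding, m[[trait]], trait, "rank_order", alpha)
}

trend_cor <- function(x, y, trait, coding, alpha) {
  if (stats::sd(y) == 0) stop("trait '", trait, "' is constant; correlation undefined")
  if (stats::sd(x) == 0) stop("ordinal coding is constant; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  structure(list(trait = trait, coding = coding,
                 r = unname(ct$estimate), p = ct$p.value,
                 n = length(x), significant = ct$p.value < alpha),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Trend (%s) for %s: r = %.3f, p = %.4g, n = %d%s\n",
              x$coding, x$trait, x$r, x$p, x$n,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Trend correlations across traits, tidy
#'
#' @param means per-taxon means (with derived ratio columns if wanted).
#' @param taxonomy taxonomy data.frame.
#' @param traits columns of `means` to test; default every trait column
#'   present.
#' @param codings subset of `c("section_order", "rank_order")`.
#' @param alpha significance level.
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#'   applied within each coding (default `"none"`; raw p-values are
#'   conventional here, Holm available for the cautious).
#' @return data.frame: `trait`, `coding`, `r`, `p`, `n`, `significant`.
#' @export
trend_summary <- function(means, taxonomy, traits = NULL,
                          codings = c("section_order", "rank_order"),
                          alpha = 0.05, adjust = "none") {
  if (is.null(traits)) {
    traits <- intersect(c(pollen_traits(), "P_E", "P_Eprime", "Eprime_E"),
                        names(means))
  }
  rows <- list()
  for (coding in codings) {
    fn <- if (coding == "section_order") section_trend else rank_trend
    res <- lapply(traits, function(tr) {
      tryCatch(fn(means, taxonomy, tr, alpha), error = function(e) NULL)
    })
    res <- Filter(Negate(is.null), res)
    if (length(res) == 0) next
    p_adj <- stats::p.adjust(vapply(res, `[[`, numeric(1), "p"),
                             method = adjust)
    for (i in seq_along(res)) {
      rows[[length(rows) + 1L]] <- data.frame(
        trait = res[[i]]$trait, coding = coding,
        r = res[[i]]$r, p = p_adj[i], n = res[[i]]$n,
        significant = p_adj[i] < alpha, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
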