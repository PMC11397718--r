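#' Measured pollen traits
#'
#' Trait codes used throughout the package: polar-axis length `P`,
#' equatorial diameter `E`, half-polar diameter `Eprime` (written E' in the
#' palynological literature), equatorial-view area `S`, ridge width `RW`,
#' furrow width `FW` (all linear traits in micrometres, `S` in square
#' micrometres), and perforation density `PD` (perforations per square
#' micrometre of exine).
#'
#' @return Character vector of the seven trait codes.
#' @export
pollen_traits <- function() {
  c("P", "E", "Eprime", "S", "RW", "FW", "PD")
}

#' Taxonomic sections in evolutionary order
#'
#' Sections are coded by Roman numerals I-V, from the most ancient (I) to
#' the most advanced (V). Only species carry a section; cultivars do not.
#'
#' @return Named integer vector mapping Roman numeral to ordinal value.
#' @export
section_levels <- function() {
  stats::setNames(1:5, c("I", "II", "III", "IV", "V"))
}

#' Build a validated replicated trait table
#'
#' A trait table holds replicated measurements in long format (one row per
#' taxon x replicate x trait) together with an optional per-taxon aberrant
#' pollen rate `ap` (the fraction of grains deviating from the taxon's
#' typical morphology; a population fraction, so it is stored once per
#' taxon, not per replicate).
#'
#' @param values data.frame with columns `taxon_id`, `replicate`, `trait`,
#'   `value`. `trait` must be one of [pollen_traits()]; values must be
#'   finite and non-negative.
#' @param ap optional named numeric vector (names = taxon ids) of aberrant
#'   pollen rates in \[0, 1\].
#' @param expected_replicates replicate count the study design calls for
#'   (default 30). Taxa with fewer replicates than this trigger a warning;
#'   fewer than 2 replicates for a present trait is an error.
#'
#' @return An object of class `trait_table`: a list with elements `values`
#'   (the long data.frame) and `ap`.
#' @export
trait_table <- function(values, ap = NULL, expected_replicates = 30L) {
  required <- c("taxon_id", "replicate", "trait", "value")
  missing_cols <- setdiff(required, names(values))
  if (length(missing_cols) > 0) {
    stop("trait table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  values <- as.data.frame(values)[required]
  values$taxon_id <- as.character(values$taxon_id)
  values$trait <- as.character(values$trait)
  values$replicate <- as.integer(values$replicate)
  values$value <- as.numeric(values$value)

  bad_trait <- !values$trait %in% pollen_traits()
  if (any(bad_trait)) {
    stop("unknown trait code(s): ",
         paste(unique(values$trait[bad_trait]), collapse = ", "))
  }
  bad <- which(!is.finite(values$value) | values$value < 0)
  if (length(bad) > 0) {
    stop("non-finite or negative trait value at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  }
  if (any(values$replicate < 1L)) stop("replicate indices must be positive")

  n_rep <- stats::aggregate(replicate ~ taxon_id + trait, data = values,
                            FUN = function(x) length(unique(x)))
  if (any(n_rep$replicate < 2L)) {
    few <- n_rep[n_rep$replicate < 2L, ]
    stop("taxon/trait with fewer than 2 replicates: ",
         paste(paste0(few$taxon_id, "/", few$trait), collapse = ", "))
  }
  if (any(n_rep$replicate < expected_replicates)) {
    warning(sum(n_rep$replicate < expected_replicates),
            " taxon/trait combination(s) have fewer than ",
            expected_replicates, " replicates")
  }

  if (!is.null(ap)) {
    ap <- unlist(ap)
    if (is.null(names(ap)) || any(!nzchar(names(ap)))) {
      stop("`ap` must be a named vector of per-taxon aberrant rates")
    }
    if (any(!is.finite(ap) | ap < 0 | ap > 1)) {
      stop("aberrant pollen rates must lie in [0, 1]")
    }
  }

  structure(list(values = values, ap = ap), class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  n_taxa <- length(unique(x$values$taxon_id))
  cat("Replicated pollen trait table\n")
  cat("  taxa:  ", n_taxa, "\n", sep = "")
  cat("  traits:", paste(sort(unique(x$values$trait)), collapse = ", "), "\n")
  cat("  rows:  ", nrow(x$values), "\n", sep = "")
  if (!is.null(x$ap)) cat("  aberrant rates for", length(x$ap), "taxa\n")
  invisible(x)
}

#' Read a trait table from CSV/TSV
#'
#' Expects long format with columns `taxon_id`, `replicate`, `trait`,
#' `value` and optionally `ap` (repeated within taxon; the first value per
#' taxon is used).
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param expected_replicates passed to [trait_table()].
#' @return A `trait_table`.
#' @export
read_trait_table <- function(path, dialect = c("csv", "tsv"),
                             expected_replicates = 30L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  ap <- NULL
  if ("ap" %in% names(df)) {
    first <- !duplicated(df$taxon_id)
    ok <- first & !is.na(df$ap)
    if (any(ok)) ap <- stats::setNames(as.numeric(df$ap[ok]),
                                       as.character(df$taxon_id[ok]))
    df$ap <- NULL
  }
  trait_table(df, ap = ap, expected_replicates = expected_replicates)
}

#' Write a trait table to CSV/TSV
#'
#' Inverse of [read_trait_table()]; the round trip is lossless for values,
#' taxon ids, and aberrant rates.
#'
#' @param table a `trait_table`.
#' @param path destination file.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path, dialect = c("csv", "tsv")) {
  stopifnot(inherits(table, "trait_table"))
  dialect <- match.arg(dialect)
  df <- table$values
  if (!is.null(table$ap)) df$ap <- unname(table$ap[df$taxon_id])
  utils::write.table(df, path, sep = if (dialect == "csv") "," else "\t",
                     row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Per-taxon trait means in wide format
#'
#' @param table a `trait_table`.
#' @return data.frame with one row per taxon and one column per trait
#'   present; absent taxon/trait cells are `NA`.
#' @export
taxon_means <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  v <- table$values
  m <- tapply(v$value, list(v$taxon_id, v$trait), mean)
  out <- data.frame(taxon_id = rownames(m), stringsAsFactors = FALSE)
  for (tr in intersect(pollen_traits(), colnames(m))) out[[tr]] <- unname(m[, tr])
  rownames(out) <- NULL
  out
}

#' Derived shape ratios per taxon
#'
#' Computes the three dimensionless shape ratios P/E, P/E' and E'/E per
#' taxon. Under `ratio_of_means` each ratio is formed from the taxon's
#' trait means; under `mean_of_ratios` ratios are formed per replicate
#' (replicates paired by index) and then averaged. With constant
#' replicates the two conventions coincide. E'/E below 1 is expected for
#' valid grains (E' is an interior diameter); values >= 1 are retained but
#' flagged with a warning.
#'
#' @param table a `trait_table` with P, E and Eprime present for each taxon
#'   to be included; taxa lacking any of the three are skipped and listed
#'   in the `excluded` attribute.
#' @param convention `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return data.frame with columns `taxon_id`, `P_E`, `P_Eprime`,
#'   `Eprime_E`; attributes `convention` and `excluded`.
#' @export
compute_derived_ratios <- function(table,
                                   convention = c("ratio_of_means",
                                                  "mean_of_ratios")) {
  stopifnot(inherits(table, "trait_table"))
  convention <- match.arg(convention)
  v <- table$values
  need <- c("P", "E", "Eprime")
  have <- tapply(v$trait, v$taxon_id, function(tr) all(need %in% tr))
  taxa <- names(have)[have]
  excluded <- names(have)[!have]

  one_taxon <- function(id) {
    sub <- v[v$taxon_id == id & v$trait %in% need, ]
    if (convention == "ratio_of_means") {
      m <- tapply(sub$value, sub$trait, mean)
      if (m["E"] == 0 || m["Eprime"] == 0) {
        stop("zero mean E or Eprime for taxon ", id, "; ratios undefined")
      }
      c(P_E = unname(m["P"] / m["E"]),
        P_Eprime = unname(m["P"] / m["Eprime"]),
        Eprime_E = unname(m["Eprime"] / m["E"]))
    } else {
      w <- tapply(sub$value, list(sub$replicate, sub$trait), mean)
      if (any(w[, "E"] == 0) || any(w[, "Eprime"] == 0)) {
        stop("zero replicate E or Eprime for taxon ", id, "; ratios undefined")
      }
      c(P_E = mean(w[, "P"] / w[, "E"]),
        P_Eprime = mean(w[, "P"] / w[, "Eprime"]),
        Eprime_E = mean(w[, "Eprime"] / w[, "E"]))
    }
  }

  mat <- t(vapply(taxa, one_taxon, numeric(3)))
  out <- data.frame(taxon_id = taxa, mat, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (any(out$Eprime_E >= 1)) {
    warning("E'/E >= 1 for taxa: ",
            paste(out$taxon_id[out$Eprime_E >= 1], collapse = ", "))
  }
  attr(out, "convention") <- convention
  attr(out, "excluded") <- excluded
  out
}

#' Read taxonomy metadata
#'
#' CSV with columns `taxon_id`, `name`, `rank` (species/cultivar) and
#' `section` (Roman numeral I-V, empty for cultivars and unplaced species).
#' A non-empty section on a cultivar is an error: sections are an
#' infrageneric rank of species.
#'
#' @param path file path.
#' @return data.frame with `section_value` (1-5 ordinal) added.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("taxon_id", "name", "rank", "section")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("taxonomy is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  validate_taxonomy(df)
}

#' Validate a taxonomy data.frame
#'
#' @param df data.frame with `taxon_id`, `name`, `rank`, `section`.
#' @return The validated data.frame with a `section_value` column.
#' @export
validate_taxonomy <- function(df) {
  df <- as.data.frame(df)
  df$taxon_id <- as.character(df$taxon_id)
  if (anyDuplicated(df$taxon_id)) {
    stop("duplicate taxon_id in taxonomy: ",
         paste(unique(df$taxon_id[duplicated(df$taxon_id)]), collapse = ", "))
  }
  if (!all(df$rank %in% c("species", "cultivar"))) {
    stop("rank must be 'species' or 'cultivar'")
  }
  sec <- as.character(df$section)
  sec[is.na(sec) | sec == ""] <- NA_character_
  bad <- !is.na(sec) & !sec %in% names(section_levels())
  if (any(bad)) stop("unknown section code(s): ", paste(unique(sec[bad]), collapse = ", "))
  if (any(!is.na(sec) & df$rank == "cultivar")) {
    stop("cultivars cannot carry a section label")
  }
  df$section <- sec
  df$section_value <- unname(section_levels()[sec])
  df
}

#' Write taxonomy metadata
#' @param taxonomy data.frame as returned by [read_taxonomy()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  out <- taxonomy[c("taxon_id", "name", "rank", "section")]
  out$section[is.na(out$section)] <- ""
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
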