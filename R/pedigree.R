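#' Parent-slot marker tokens
#'
#' Breeding-route records distinguish two kinds of missing parent:
#' `"unknown"` (the parent was never named, e.g. open pollination) and
#' `"untested"` (the parent is named in the literature but was not
#' measured in the study). The two states behave differently in
#' perforation-density progression scoring, so they are kept distinct.
#'
#' @name parent_markers
NULL

PARENT_UNKNOWN <- "unknown"
PARENT_UNTESTED <- "untested"

is_parent_marker <- function(x) {
  tolower(x) %in% c(PARENT_UNKNOWN, PARENT_UNTESTED)
}

normalize_parent <- function(x) {
  x <- as.character(x)
  low <- tolower(trimws(x))
  x[low == PARENT_UNKNOWN] <- PARENT_UNKNOWN
  # tolerate the truncated token used in printed route tables
  x[low %in% c(PARENT_UNTESTED, "untest")] <- PARENT_UNTESTED
  x[is.na(x) | trimws(x) == ""] <- PARENT_UNKNOWN
  x
}

#' Build a validated pedigree
#'
#' A pedigree is a set of breeding routes: `progeny` with up to two
#' parents, each of which may be a taxon id, `"unknown"`, or
#' `"untested"` (case-insensitive on input). Duplicate progeny rows and
#' ancestry cycles are rejected. An entry is evaluable downstream only if
#' at least one parent slot is not `"unknown"`.
#'
#' @param df data.frame with columns `progeny`, `parent1`, `parent2` and
#'   optionally `source`.
#' @return data.frame of class `pedigree` with normalized marker tokens.
#' @export
pedigree <- function(df) {
  required <- c("progeny", "parent1", "parent2")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("pedigree is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)
  df$progeny <- as.character(df$progeny)
  df$parent1 <- normalize_parent(df$parent1)
  df$parent2 <- normalize_parent(df$parent2)
  if (!"source" %in% names(df)) df$source <- character(nrow(df))
  if (anyDuplicated(df$progeny)) {
    stop("duplicate progeny row(s): ",
         paste(unique(df$progeny[duplicated(df$progeny)]), collapse = ", "))
  }
  check_pedigree_cycles(df)
  class(df) <- c("pedigree", "data.frame")
  df
}

# depth-first search over progeny -> parent edges; a progeny reachable
# from itself means the routes are not a valid ancestry
check_pedigree_cycles <- function(df) {
  parents_of <- function(id) {
    row <- df[df$progeny == id, , drop = FALSE]
    if (nrow(row) == 0) return(character(0))
    p <- c(row$parent1[1], row$parent2[1])
    p[!is_parent_marker(p)]
  }
  for (start in df$progeny) {
    stack <- parents_of(start)
    seen <- character(0)
    while (length(stack) > 0) {
      node <- stack[[1]]
      stack <- stack[-1]
      if (node == start) stop("pedigree cycle involving '", start, "'")
      if (node %in% seen) next
      seen <- c(seen, node)
      stack <- c(stack, parents_of(node))
    }
  }
  invisible(df)
}

#' Read breeding routes from CSV
#'
#' Columns `progeny`, `parent1`, `parent2`, optional `source`. The tokens
#' `unknown` and `untested` (any case; `untest` also accepted) mark
#' missing-parent slots and are preserved as distinct states.
#'
#' @param path file path.
#' @return A `pedigree`.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty pedigree: downstream percentages will be undefined")
  }
  pedigree(df)
}

#' Write breeding routes to CSV
#' @param ped a `pedigree`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  utils::write.csv(as.data.frame(ped)[c("progeny", "parent1", "parent2",
                                        "source")],
                   path, row.names = FALSE)
  invisible(path)
}

# parents of one route row, with markers dropped
known_parents <- function(row) {
  p <- c(row$parent1, row$parent2)
  unique(p[!is_parent_marker(p)])
}
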