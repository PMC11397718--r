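#' Default clustering feature set
#'
#' The six variables used for taxon clustering: polar axis P, equatorial
#' diameter E, shape ratio E'/E, ridge width RW, furrow width FW and
#' perforation density PD. P/E and P/E' are omitted as near-functions of
#' P, E and E'/E; S is omitted as a near-function of P and E.
#'
#' @return Character vector of feature names.
#' @export
cluster_features <- function() {
  c("P", "E", "Eprime_E", "RW", "FW", "PD")
}

#' Standardized per-taxon feature matrix
#'
#' Assembles per-taxon trait means and derived shape ratios into a matrix
#' and z-scores each feature (mean 0, sd 1 across taxa). Taxa lacking any
#' requested feature are dropped and listed in the `excluded` attribute.
#' Mixed measurement units make unstandardized Euclidean distances
#' meaningless, hence standardization is not optional.
#'
#' @param table a `trait_table`.
#' @param derived output of [compute_derived_ratios()]; computed from
#'   `table` when `NULL` and ratio features are requested.
#' @param features feature names among [pollen_traits()] and the derived
#'   ratios `P_E`, `P_Eprime`, `Eprime_E`; default [cluster_features()].
#' @return Numeric matrix (taxa x features, z-scored) with attributes
#'   `center`, `scale` (standardization parameters) and `excluded`.
#' @export
build_feature_matrix <- function(table, derived = NULL,
                                 features = cluster_features()) {
  tm <- taxon_means(table)
  ratio_feats <- intersect(features, c("P_E", "P_Eprime", "Eprime_E"))
  if (length(ratio_feats) > 0 && is.null(derived)) {
    derived <- compute_derived_ratios(table)
  }
  wide <- tm
  if (!is.null(derived)) {
    wide <- merge(tm, derived, by = "taxon_id", all.x = TRUE)
  }
  missing_feats <- setdiff(features, names(wide))
  if (length(missing_feats) > 0) {
    stop("feature(s) unavailable: ", paste(missing_feats, collapse = ", "))
  }
  m <- as.matrix(wide[features])
  rownames(m) <- wide$taxon_id
  complete <- stats::complete.cases(m)
  excluded <- rownames(m)[!complete]
  if (length(excluded) > 0) {
    message("excluding ", length(excluded),
            " taxa with incomplete features: ",
            paste(utils::head(excluded, 5L), collapse = ", "),
            if (length(excluded) > 5L) " ..." else "")
  }
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 taxa with complete features")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance feature(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  z <- scale(m)
  out <- z[, , drop = FALSE]
  attr(out, "center") <- attr(z, "scaled:center")
  attr(out, "scale") <- attr(z, "scaled:scale")
  attr(out, "excluded") <- excluded
  out
}

# map user-facing linkage names onto stats::hclust methods
linkage_method <- function(linkage) {
  switch(linkage,
         ward = "ward.D2",
         upgma = "average",
         average = "average",
         complete = "complete",
         stop("unsupported linkage: ", linkage))
}

#' Agglomerative clustering of taxa
#'
#' Hierarchical agglomeration on Euclidean distances between standardized
#' feature vectors. Default linkage is Ward's minimum-variance criterion
#' (on the distance scale, i.e. merge heights are Euclidean-compatible);
#' UPGMA and complete linkage are also available.
#'
#' @param features matrix from [build_feature_matrix()] (rows = taxa).
#' @param linkage `"ward"` (default), `"upgma"`/`"average"` or
#'   `"complete"`.
#' @param distance currently only `"euclidean"`.
#' @return An [stats::hclust] tree with taxon ids as labels.
#' @export
hierarchical_cluster <- function(features, linkage = "ward",
                                 distance = "euclidean") {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (anyNA(features) || any(!is.finite(features))) {
    stop("features contain missing or non-finite values")
  }
  if (nrow(features) < 2) stop("need at least 2 taxa to cluster")
  distance <- match.arg(distance, "euclidean")
  stats::hclust(stats::dist(features, method = distance),
                method = linkage_method(linkage))
}

# label clusters by ascending size so the largest cluster gets the last
# label; ties broken by order of first appearance among the dendrogram
# leaves (labels are presentation only -- the partition is the contract)
label_by_size <- function(membership, leaf_rank, pool) {
  ids <- sort(unique(membership))
  size <- vapply(ids, function(i) sum(membership == i), integer(1))
  first <- vapply(ids, function(i) min(leaf_rank[membership == i]),
                  numeric(1))
  ord <- order(size, first)
  stats::setNames(pool[seq_along(ids)][order(ord)], ids)
}

#' Two-level group/subgroup cut of a dendrogram
#'
#' Cuts the tree into `k_top` groups, labelled by ascending size (A, B,
#' C, ... with the largest group receiving the final label), then re-cuts
#' the largest group's own subtree into `k_sub` subgroups labelled
#' `<G>1..<G>k_sub`, again by ascending size. Subgroups partition exactly
#' the largest group; other taxa carry `NA` subgroups. If the largest
#' group has fewer than `k_sub` members no subdivision is performed.
#'
#' @param hc an [stats::hclust] tree with taxon labels.
#' @param k_top number of top-level groups (default 4).
#' @param k_sub number of subgroups within the largest group (default 3).
#' @return List of class `cluster_result`: `tree` (the hclust),
#'   `assignments` (data.frame `taxon_id`, `group`, `subgroup`,
#'   `label6` = subgroup where present else group), `k_top`, `k_sub`.
#' @export
cut_two_level <- function(hc, k_top = 4L, k_sub = 3L) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$labels)
  if (k_top > n) stop("k_top exceeds number of taxa")
  membership <- stats::cutree(hc, k = k_top)
  leaf_rank <- stats::setNames(match(seq_len(n), hc$order), hc$labels)

  pool <- LETTERS
  lab_map <- label_by_size(membership, leaf_rank[names(membership)], pool)
  group <- unname(lab_map[as.character(membership)])
  names(group) <- names(membership)

  big_label <- pool[length(unique(membership))]
  big_members <- names(group)[group == big_label]
  subgroup <- stats::setNames(rep(NA_character_, n), names(group))

  if (length(big_members) >= k_sub && k_sub > 1L) {
    sub_membership <- cut_subtree(hc, big_members, k_sub)
    sub_map <- label_by_size(sub_membership,
                             leaf_rank[names(sub_membership)],
                             paste0(big_label, seq_len(k_sub)))
    subgroup[names(sub_membership)] <-
      unname(sub_map[as.character(sub_membership)])
  } else if (k_sub > 1L) {
    warning("largest group has fewer than k_sub members; no subdivision")
  }

  assignments <- data.frame(
    taxon_id = hc$labels,
    group = unname(group[hc$labels]),
    subgroup = unname(subgroup[hc$labels]),
    stringsAsFactors = FALSE
  )
  assignments$label6 <- ifelse(is.na(assignments$subgroup),
                               assignments$group, assignments$subgroup)
  structure(list(tree = hc, assignments = assignments,
                 k_top = k_top, k_sub = k_sub),
            class = "cluster_result")
}

# cut the subtree spanned by `members` into k clusters by dropping its
# k-1 highest merges (hclust merge rows are height-ordered), then taking
# connected components of the remaining merges
cut_subtree <- function(hc, members, k) {
  n <- length(hc$labels)
  leaf_idx <- match(members, hc$labels)
  in_sub_leaf <- seq_len(n) %in% leaf_idx

  n_merge <- nrow(hc$merge)
  node_leaves <- vector("list", n_merge)
  in_sub_node <- logical(n_merge)
  for (i in seq_len(n_merge)) {
    kids <- hc$merge[i, ]
    lv <- unlist(lapply(kids, function(kid) {
      if (kid < 0) -kid else node_leaves[[kid]]
    }))
    node_leaves[[i]] <- lv
    in_sub_node[i] <- all(lv %in% leaf_idx)
  }
  sub_merges <- which(in_sub_node)
  stopifnot(length(sub_merges) == length(members) - 1)
  keep <- utils::head(sub_merges[order(hc$height[sub_merges])],
                      length(sub_merges) - (k - 1))

  # union-find over kept merges
  parent <- stats::setNames(seq_along(leaf_idx), leaf_idx)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in keep) {
    lv <- node_leaves[[i]]
    kids <- hc$merge[i, ]
    sides <- lapply(kids, function(kid) {
      if (kid < 0) -kid else node_leaves[[kid]]
    })
    ra <- find(match(sides[[1]][1], leaf_idx))
    rb <- find(match(sides[[2]][1], leaf_idx))
    parent[[rb]] <- ra
  }
  roots <- vapply(seq_along(leaf_idx), find, numeric(1))
  comp <- as.integer(factor(roots))
  stats::setNames(comp, members)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Two-level cluster partition\n")
  cat("  taxa:", nrow(x$assignments), "\n")
  tab <- table(x$assignments$group)
  cat("  groups:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  sub <- x$assignments$subgroup[!is.na(x$assignments$subgroup)]
  if (length(sub) > 0) {
    st <- table(sub)
    cat("  subgroups:",
        paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' @param x a `cluster_result` or [stats::hclust] tree.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
export_newick <- function(x, path) {
  hc <- if (inherits(x, "cluster_result")) x$tree else x
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Per-group trait summaries with letters
#'
#' For each trait, per-group (and, where present, per-subgroup) means and
#' standard deviations over per-taxon means, with compact letters from
#' Tukey HSD at `alpha` comparing groups on per-taxon values. Letters are
#' computed separately within the top-level grouping and within the
#' six-level grouping (subgroups replacing the subdivided group). Groups
#' of size 1 report a missing sd.
#'
#' @param table a `trait_table`.
#' @param derived output of [compute_derived_ratios()] (computed when
#'   `NULL`).
#' @param result a `cluster_result`.
#' @param traits trait columns to summarize; defaults to the measured
#'   traits plus the three shape ratios.
#' @param alpha significance level for the letter display.
#' @return Tidy data.frame: `level`, `group`, `trait`, `n`, `mean`, `sd`,
#'   `letter`.
#' @export
group_summaries <- function(table, derived = NULL, result,
                            traits = NULL, alpha = 0.05) {
  stopifnot(inherits(result, "cluster_result"))
  if (is.null(derived)) derived <- compute_derived_ratios(table)
  wide <- merge(taxon_means(table), derived, by = "taxon_id", all = TRUE)
  if (is.null(traits)) {
    traits <- intersect(c("P", "E", "Eprime", "S", "P_E", "P_Eprime",
                          "Eprime_E", "RW", "FW", "PD"), names(wide))
  }
  a <- merge(result$assignments, wide, by = "taxon_id")

  summarize_level <- function(labels, level_name) {
    rows <- list()
    for (tr in traits) {
      ok <- !is.na(labels) & !is.na(a[[tr]])
      split_vals <- split(a[[tr]][ok], labels[ok])
      split_vals <- split_vals[lengths(split_vals) > 0]
      lets <- if (length(split_vals) >= 2 && sum(lengths(split_vals)) >
                  length(split_vals)) {
        tukey_cld(split_vals, alpha = alpha)$letters
      } else {
        stats::setNames(rep(NA_character_, length(split_vals)),
                        names(split_vals))
      }
      for (gl in names(split_vals)) {
        v <- split_vals[[gl]]
        rows[[length(rows) + 1L]] <- data.frame(
          level = level_name, group = gl, trait = tr,
          n = length(v), mean = mean(v),
          sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
          letter = unname(lets[gl]), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }

  out <- rbind(summarize_level(a$group, "group"),
               summarize_level(a$label6, "six_group"))
  rownames(out) <- NULL
  out
}
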