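# Small fixture builders and independent brute-force oracles used across
# the suite. Oracles are deliberately naive re-derivations, not calls into
# the package code paths they check.

# long trait table from a replicate matrix (taxa x replicates) for one trait
table_from_matrix <- function(m, trait = "P", taxa = NULL) {
  if (is.null(taxa)) taxa <- sprintf("t%02d", seq_len(nrow(m)))
  values <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    data.frame(taxon_id = taxa[i], replicate = seq_len(ncol(m)),
               trait = trait, value = m[i, ], stringsAsFactors = FALSE)
  }))
  suppressWarnings(trait_table(values))
}

# trait table with constant replicates at given per-taxon means for
# several traits; means: data.frame taxon_id + trait columns
table_from_means <- function(means, replicates = 3L, jitter_sd = 0) {
  traits <- setdiff(names(means), "taxon_id")
  rows <- list()
  for (i in seq_len(nrow(means))) {
    for (tr in traits) {
      v <- rep(means[[tr]][i], replicates)
      if (jitter_sd > 0) v <- pmax(v + rnorm(replicates, 0, jitter_sd), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_id = means$taxon_id[i], replicate = seq_len(replicates),
        trait = tr, value = v, stringsAsFactors = FALSE)
    }
  }
  suppressWarnings(trait_table(do.call(rbind, rows)))
}

# two-pass brute-force uniformity statistic (sample sd / mean, averaged
# over taxa with non-zero mean)
oracle_cvbar <- function(m) {
  cvs <- c()
  for (i in seq_len(nrow(m))) {
    mu <- sum(m[i, ]) / ncol(m)
    if (mu == 0) next
    ss <- sum((m[i, ] - mu)^2) / (ncol(m) - 1)
    cvs <- c(cvs, sqrt(ss) / mu)
  }
  sum(cvs) / length(cvs)
}

# brute-force distinctness statistic over per-taxon means
oracle_cv <- function(m) {
  mus <- apply(m, 1, function(r) sum(r) / length(r))
  grand <- sum(mus) / length(mus)
  s <- sqrt(sum((mus - grand)^2) / (length(mus) - 1))
  s / grand
}

# naive agglomeration: recompute the linkage criterion from raw points at
# every step; returns per-step merged member sets and heights
oracle_agglomerate <- function(x, linkage) {
  cl <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  comps <- list()
  pair_d <- function(A, B) {
    dm <- as.matrix(dist(x))
    if (linkage == "complete") return(max(dm[A, B]))
    if (linkage %in% c("average", "upgma")) return(mean(dm[A, B]))
    if (linkage == "ward") {
      muA <- colMeans(x[A, , drop = FALSE])
      muB <- colMeans(x[B, , drop = FALSE])
      return(sqrt(2 * length(A) * length(B) / (length(A) + length(B))) *
               sqrt(sum((muA - muB)^2)))
    }
    stop("linkage?")
  }
  while (length(cl) > 1) {
    best <- NULL; bd <- Inf
    for (i in 1:(length(cl) - 1)) {
      for (j in (i + 1):length(cl)) {
        d <- pair_d(cl[[i]], cl[[j]])
        if (d < bd) { bd <- d; best <- c(i, j) }
      }
    }
    merged <- sort(c(cl[[best[1]]], cl[[best[2]]]))
    comps <- c(comps, list(merged))
    heights <- c(heights, bd)
    cl <- c(cl[-best], list(merged))
  }
  list(comps = comps, heights = heights)
}

# member sets created at each hclust merge step
hclust_comps <- function(hc) {
  comps <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    comps[[i]] <- sort(unlist(lapply(kids, function(k) {
      if (k < 0) -k else comps[[k]]
    })))
  }
  comps
}

# does a compact letter display agree with a significance pattern?
# shared letter <=> pair NOT significant
cld_consistent <- function(letters_vec, pmat, alpha) {
  labs <- names(letters_vec)
  for (i in seq_along(labs)[-length(labs)]) {
    for (j in (i + 1):length(labs)) {
      shared <- length(intersect(strsplit(letters_vec[i], "")[[1]],
                                 strsplit(letters_vec[j], "")[[1]])) > 0
      sig <- pmat[labs[i], labs[j]] < alpha
      if (shared == sig) return(FALSE)
    }
  }
  all(nchar(letters_vec) >= 1)
}

# symmetric pseudo p-value matrix from a significance bit pattern
pmat_from_bits <- function(k, bits) {
  pm <- matrix(1, k, k, dimnames = list(LETTERS[1:k], LETTERS[1:k]))
  idx <- 1L
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      if (bits[idx]) pm[i, j] <- pm[j, i] <- 0.001
      idx <- idx + 1L
    }
  }
  pm
}

# midparent family simulation: k families of 2 parent species + n_prog
# cultivars whose feature vectors are midparents plus small noise;
# between-family centers are separated well beyond the within-family sd
simulate_families <- function(seed, k = 4, n_prog = 5, sep = 5,
                              within_sd = 1) {
  set.seed(seed)
  p <- 6
  centers <- matrix(0, k, p)
  for (f in seq_len(k)) centers[f, ((f - 1) %% p) + 1] <- sep * f
  feats <- list(); ids <- character(0)
  ped_rows <- list()
  for (f in seq_len(k)) {
    par_ids <- sprintf("f%d_sp%d", f, 1:2)
    par_feats <- sweep(matrix(rnorm(2 * p, 0, within_sd), 2, p), 2,
                       centers[f, ], `+`)
    prog_ids <- sprintf("f%d_cv%d", f, seq_len(n_prog))
    mid <- colMeans(par_feats)
    prog_feats <- sweep(matrix(rnorm(n_prog * p, 0, within_sd / 3),
                               n_prog, p), 2, mid, `+`)
    feats[[f]] <- rbind(par_feats, prog_feats)
    ids <- c(ids, par_ids, prog_ids)
    for (pr in prog_ids) {
      ped_rows[[length(ped_rows) + 1L]] <- data.frame(
        progeny = pr, parent1 = par_ids[1], parent2 = par_ids[2],
        stringsAsFactors = FALSE)
    }
  }
  x <- do.call(rbind, feats)
  rownames(x) <- ids
  list(features = x, pedigree = pedigree(do.call(rbind, ped_rows)),
       k = k)
}
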