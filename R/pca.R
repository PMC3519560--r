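#' Normalize condition means for the organ effect
#'
#' Removes the organ main effect gene by gene on the log2 scale: shoot
#' condition means are offset by the difference of the organ averages,
#' `norm(shoot, c) = raw(shoot, c) + mean_c raw(root, c) - mean_c raw(shoot, c)`,
#' while root values are left untouched,
#' `norm(root, c) = raw(root, c)`. After normalization the per-gene average
#' over conditions is identical in the two organs, so the organ main effect
#' is exactly zero; within-organ condition profiles are preserved.
#'
#' Genes with any of the 10 cell means missing are dropped (a message reports
#' how many).
#'
#' @param means a `ck_means` from [condition_means()].
#' @return a `ck_means` of the complete genes with shoot columns normalized.
#' @export
organ_normalize <- function(means) {
  stopifnot(inherits(means, "ck_means"))
  root_cols <- paste0("root_", CK_CONDITIONS)
  shoot_cols <- paste0("shoot_", CK_CONDITIONS)
  complete <- stats::complete.cases(means[, c(root_cols, shoot_cols)])
  if (any(!complete))
    message(sum(!complete), " gene(s) dropped from normalization ",
            "(missing condition means)")
  out <- means[complete, , drop = FALSE]
  root_avg <- rowMeans(out[, root_cols])
  shoot_avg <- rowMeans(out[, shoot_cols])
  for (col in shoot_cols) out[[col]] <- out[[col]] + root_avg - shoot_avg
  rownames(out) <- NULL
  class(out) <- c("ck_means", "data.frame")
  out
}

#' Select genes for ordination
#'
#' The restricted gene set used for PCA and support-tree clustering: genes
#' with at least `abb_model_min` (default 10) spots above background in total
#' and a minimum FDR-adjusted p-value over the organ, cytokinin and
#' interaction effects of the full model of at most `pca_q` (default 1e-4).
#'
#' @param detection a `ck_detection`.
#' @param stats_full full-model `ck_stats`.
#' @param th a `ck_thresholds`.
#' @return character vector of selected gene ids.
#' @export
select_pca_genes <- function(detection, stats_full, th = thresholds()) {
  stopifnot(inherits(th, "ck_thresholds"))
  i <- match(detection$gene, stats_full$gene)
  qmin <- pmin(ifelse(is.na(stats_full$q_organ[i]), 1, stats_full$q_organ[i]),
               ifelse(is.na(stats_full$q_cytokinin[i]), 1,
                      stats_full$q_cytokinin[i]),
               ifelse(is.na(stats_full$q_interaction[i]), 1,
                      stats_full$q_interaction[i]))
  sel <- detection$gene[detection$abb_total >= th$abb_model_min &
                        qmin <= th$pca_q]
  if (length(sel) == 0)
    stop("no gene passes the PCA selection; consider raising pca_q")
  sel
}

#' Condition-mean profiles for ordination
#'
#' Builds the samples x genes matrix whose 10 rows are the (organ, condition)
#' mean profiles (each averaging the biological and technical replicates of
#' one experimental condition).
#'
#' @param means a `ck_means`.
#' @param genes genes to keep (default all complete genes).
#' @return numeric matrix, rows named `<organ>_<condition>`.
#' @export
condition_profiles <- function(means, genes = NULL) {
  stopifnot(inherits(means, "ck_means"))
  if (!is.null(genes)) means <- means[means$gene %in% genes, , drop = FALSE]
  cols <- as.vector(outer(CK_ORGANS, CK_CONDITIONS, paste, sep = "_"))
  m <- as.matrix(means[, cols, drop = FALSE])
  keep <- !apply(is.na(m), 1, any)
  m <- m[keep, , drop = FALSE]
  profiles <- t(m)
  colnames(profiles) <- means$gene[keep]
  profiles
}

#' Principal component analysis of condition profiles
#'
#' Covariance PCA of the samples: genes (columns) are mean-centered, no
#' scaling; the decomposition is the eigenanalysis of the sample covariance.
#' Component signs are fixed by forcing the largest-magnitude gene loading of
#' each component to be positive, so results are reproducible across
#' platforms.
#'
#' @param profiles samples x genes matrix, e.g. [condition_profiles()].
#' @return a `ck_pca` list: `scores` (samples x components), `loadings`,
#'   `eig_fractions` (eigenvalue fractions over all components, summing to
#'   1), `eigenvalues`, `genes`.
#' @export
run_pca <- function(profiles) {
  stopifnot(is.matrix(profiles))
  if (nrow(profiles) < 2 || ncol(profiles) < 2)
    stop("PCA needs at least 2 samples and 2 genes")
  centered <- scale(profiles, center = TRUE, scale = FALSE)
  if (max(abs(centered)) < 1e-12) stop("rank-0 matrix: no variation to analyze")
  pr <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(pr$rotation))) {
    j <- which.max(abs(pr$rotation[, k]))
    if (pr$rotation[j, k] < 0) {
      pr$rotation[, k] <- -pr$rotation[, k]
      pr$x[, k] <- -pr$x[, k]
    }
  }
  ev <- pr$sdev^2
  structure(list(scores = pr$x, loadings = pr$rotation,
                 eig_fractions = ev / sum(ev), eigenvalues = ev,
                 genes = colnames(profiles)),
            class = "ck_pca")
}

#' @export
print.ck_pca <- function(x, ...) {
  cat(sprintf("ck_pca: %d samples, %d genes; eigenvalue fractions: %s\n",
              nrow(x$scores), length(x$genes),
              paste(sprintf("%.3f", utils::head(x$eig_fractions, 3)),
                    collapse = ", ")))
  invisible(x)
}

# Clades (as sorted tip-label sets) of an hclust tree.
.hclust_clades <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) hc$labels[-j] else members[[j]]
    members[[i]] <- sort(c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2])))
  }
  members
}

#' Support-tree clustering of condition profiles
#'
#' Average-linkage hierarchical clustering of the samples under the
#' Pearson-correlation distance `1 - cor`, with branch support estimated by
#' resampling genes with replacement: the support of an internal branch is
#' the fraction of bootstrap trees containing the same sample clade. With 10
#' condition profiles the resampling unit has to be the gene.
#'
#' @param profiles samples x genes matrix.
#' @param n_boot number of bootstrap resamples (0 = tree without supports).
#' @param seed optional integer seed for the resampling.
#' @return a `ck_support_tree` list: `hclust` (the tree), `phylo` (an
#'   [ape::as.phylo()] conversion with supports as node labels), `clades`
#'   (list of tip-label sets), `support` (numeric per clade, `NA` when
#'   `n_boot = 0`), `n_boot`.
#' @export
support_tree <- function(profiles, n_boot = 100, seed = NULL) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 3, n_boot >= 0)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("S", seq_len(nrow(profiles)))
  sds <- apply(profiles, 1, stats::sd)
  if (any(sds < 1e-12))
    stop("constant profile(s): correlation distance undefined for ",
         paste(rownames(profiles)[sds < 1e-12], collapse = ", "))
  cor_dist <- function(m) stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(cor_dist(profiles), method = "average")
  clades <- .hclust_clades(hc)
  support <- rep(NA_real_, length(clades))
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- numeric(length(clades))
    keys <- vapply(clades, paste, character(1), collapse = "\r")
    for (b in seq_len(n_boot)) {
      idx <- sample.int(ncol(profiles), replace = TRUE)
      bm <- profiles[, idx, drop = FALSE]
      bsd <- apply(bm, 1, stats::sd)
      if (any(bsd < 1e-12)) next  # degenerate resample: contributes no hit
      bhc <- stats::hclust(cor_dist(bm), method = "average")
      bkeys <- vapply(.hclust_clades(bhc), paste, character(1),
                      collapse = "\r")
      hits <- hits + as.numeric(keys %in% bkeys)
    }
    support <- hits / n_boot
  }
  phylo <- ape::as.phylo(hc)
  # ape orders internal nodes so that node i + Ntip corresponds to a clade;
  # map supports through tip-set identity to be safe
  ph_clades <- lapply(seq_len(phylo$Nnode) + length(phylo$tip.label),
                      function(nd) sort(ape::extract.clade(phylo, nd)$tip.label))
  ph_keys <- vapply(ph_clades, paste, character(1), collapse = "\r")
  keys <- vapply(clades, paste, character(1), collapse = "\r")
  node_support <- support[match(ph_keys, keys)]
  phylo$node.label <- ifelse(is.na(node_support), "",
                             format(node_support, trim = TRUE))
  structure(list(hclust = hc, phylo = phylo, clades = clades,
                 support = support, n_boot = n_boot),
            class = "ck_support_tree")
}

#' Write a support tree in Newick format
#'
#' Internal node labels carry the bootstrap support fractions.
#'
#' @param tree a `ck_support_tree`.
#' @param path output file.
#' @export
write_support_tree <- function(tree, path) {
  stopifnot(inherits(tree, "ck_support_tree"))
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}
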