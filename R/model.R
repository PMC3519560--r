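#' Fit the two-factor model for one gene
#'
#' Fits the fixed-effects cell-means model `value ~ organ * condition` by
#' ordinary least squares on the non-missing (above-background) observations
#' and returns type-II sum-of-squares F-tests for the organ main effect, the
#' cytokinin (condition) main effect, and their interaction. Type-II tests
#' keep main effects order-independent when missingness unbalances the
#' design. Technical replicates are treated as independent observations.
#'
#' Degenerate fits are handled explicitly: if after dropping missing values
#' an (organ, condition) cell is empty, or a factor collapses to one level,
#' the gene is skipped (`reason` set, statistics `NA`). A saturated fit (zero
#' residual degrees of freedom) returns F = 0, p = 1 when the cell means are
#' all equal and F = Inf, p = 0 (reason `"saturated"`) otherwise. Effects
#' with zero sum of squares under zero residual variance return F = 0, p = 1.
#'
#' @param y numeric vector of per-array log2 values (`NA` = below background).
#' @param organ factor/character of organ labels, parallel to `y`.
#' @param condition factor/character of condition labels, parallel to `y`.
#' @return a one-row data frame: `F_organ`, `p_organ`, `F_cytokinin`,
#'   `p_cytokinin`, `F_interaction`, `p_interaction`, `residual_df`, `n_obs`,
#'   `reason` (`NA` when the fit is regular).
#' @export
fit_gene_model <- function(y, organ, condition) {
  out <- data.frame(F_organ = NA_real_, p_organ = NA_real_,
                    F_cytokinin = NA_real_, p_cytokinin = NA_real_,
                    F_interaction = NA_real_, p_interaction = NA_real_,
                    residual_df = NA_integer_, n_obs = 0L,
                    reason = NA_character_, stringsAsFactors = FALSE)
  ok <- is.finite(y)
  if (!any(ok)) { out$reason <- "no observations"; return(out) }
  y <- y[ok]
  organ <- droplevels(factor(organ[ok], levels = CK_ORGANS))
  condition <- droplevels(factor(condition[ok], levels = CK_CONDITIONS))
  out$n_obs <- length(y)
  if (nlevels(organ) < 2 || nlevels(condition) < 2) {
    out$reason <- "factor collapsed to one level"
    return(out)
  }
  if (any(table(organ, condition) == 0)) {
    out$reason <- "empty design cell"
    return(out)
  }
  n_cells <- nlevels(organ) * nlevels(condition)
  rdf <- length(y) - n_cells
  out$residual_df <- as.integer(rdf)
  if (rdf < 1) {
    # saturated: one observation per cell, no residual to test against
    cell_means <- tapply(y, list(organ, condition), mean)
    if (max(cell_means) - min(cell_means) < 1e-12) {
      out[c("F_organ", "F_cytokinin", "F_interaction")] <- 0
      out[c("p_organ", "p_cytokinin", "p_interaction")] <- 1
    } else {
      out[c("F_organ", "F_cytokinin", "F_interaction")] <- Inf
      out[c("p_organ", "p_cytokinin", "p_interaction")] <- 0
      out$reason <- "saturated"
    }
    return(out)
  }
  fit <- stats::lm(y ~ organ * condition)
  tot <- sum((y - mean(y))^2)
  rss_full <- sum(fit$residuals^2)
  if (rss_full <= 1e-10 * max(tot, 1e-12)) {
    # zero residual variance (e.g. noise-free data): an effect is either
    # absent (its type-II sum of squares is zero too) or infinitely strong
    rss_of <- function(f) sum(stats::lm(f)$residuals^2)
    rss_add <- rss_of(y ~ organ + condition)
    ss <- c(organ = rss_of(y ~ condition) - rss_add,
            cytokinin = rss_of(y ~ organ) - rss_add,
            interaction = rss_add - rss_full)
    tol <- 1e-8 * max(tot, 1e-12)
    for (k in names(ss)) {
      out[[paste0("F_", k)]] <- if (ss[[k]] > tol) Inf else 0
      out[[paste0("p_", k)]] <- if (ss[[k]] > tol) 0 else 1
    }
    return(out)
  }
  aov2 <- car::Anova(fit, type = 2, singular.ok = TRUE)
  eff <- c(organ = "organ", cytokinin = "condition",
           interaction = "organ:condition")
  ss <- aov2[["Sum Sq"]]
  rss <- ss[rownames(aov2) == "Residuals"]
  for (k in names(eff)) {
    i <- match(eff[[k]], rownames(aov2))
    f <- aov2[["F value"]][i]
    p <- aov2[["Pr(>F)"]][i]
    if (!is.finite(f)) {
      # zero residual variance: effect either absent (F = 0) or infinitely
      # strong relative to it
      if (rss < 1e-24 || ss[i] / max(rss, 1e-300) > 1e12) {
        if (ss[i] < 1e-12) { f <- 0; p <- 1 } else { f <- Inf; p <- 0 }
      }
    }
    out[[paste0("F_", k)]] <- f
    out[[paste0("p_", k)]] <- p
  }
  out
}

#' Fit per-gene models over an analysis subset
#'
#' Runs [fit_gene_model()] for every eligible gene on the arrays of one
#' analysis subset and appends Benjamini-Hochberg q-values per effect
#' (computed over the genes that were actually tested). For the deficiency
#' subset the condition factor has the two levels BA0/CKX1, so the
#' "cytokinin" effect is the genotype effect of that analysis.
#'
#' @param expr a `ck_expr`.
#' @param subset `"induction"`, `"deficiency"`, or `"full"`.
#' @param detection optional `ck_detection`; when given, only genes whose
#'   subset eligibility flag (`induction_eligible`, `deficiency_eligible`, or
#'   `model_eligible` for the full model) is set are fitted, the rest get `NA`
#'   rows with reason `"not eligible"`.
#' @return a `ck_stats` data frame: `gene`, F/p/q for the three effects,
#'   `residual_df`, `n_obs`, `reason`; `attr(, "subset")` records the subset.
#' @export
fit_models <- function(expr, subset = c("induction", "deficiency", "full"),
                       detection = NULL) {
  stopifnot(inherits(expr, "ck_expr"))
  subset <- match.arg(subset)
  arrays <- subset_arrays(expr$design, subset)
  idx <- match(arrays, expr$design$array_id)
  organ <- expr$design$organ[idx]
  condition <- expr$design$condition[idx]
  genes <- rownames(expr$values)
  eligible <- rep(TRUE, length(genes))
  if (!is.null(detection)) {
    flag <- switch(subset, induction = "induction_eligible",
                   deficiency = "deficiency_eligible",
                   full = "model_eligible")
    eligible <- detection[[flag]][match(genes, detection$gene)] &
      !detection$not_expressed[match(genes, detection$gene)]
    eligible[is.na(eligible)] <- FALSE
  }
  vals <- expr$values[, arrays, drop = FALSE]
  rows <- vector("list", length(genes))
  blank <- fit_gene_model(NA_real_, CK_ORGANS[1], CK_CONDITIONS[1])
  blank$reason <- "not eligible"
  for (g in seq_along(genes)) {
    rows[[g]] <- if (eligible[g]) fit_gene_model(vals[g, ], organ, condition)
                 else blank
  }
  stats <- do.call(rbind, rows)
  stats <- cbind(gene = genes, stats, stringsAsFactors = FALSE)
  for (k in c("organ", "cytokinin", "interaction")) {
    p <- stats[[paste0("p_", k)]]
    q <- rep(NA_real_, length(p))
    tested <- !is.na(p)
    q[tested] <- fdr_adjust(p[tested])
    stats[[paste0("q_", k)]] <- q
  }
  stats <- stats[, c("gene", "F_organ", "p_organ", "q_organ",
                     "F_cytokinin", "p_cytokinin", "q_cytokinin",
                     "F_interaction", "p_interaction", "q_interaction",
                     "residual_df", "n_obs", "reason")]
  rownames(stats) <- NULL
  attr(stats, "subset") <- subset
  class(stats) <- c("ck_stats", "data.frame")
  stats
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR-adjusted p-values ("q-values"):
#' `q_(i) = min over j >= i of m * p_(j) / j`, clipped at 1, returned in the
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must be in [0, 1] and non-missing")
  stats::p.adjust(p, method = "BH")
}

#' @rdname fit_models
#' @param stats a `ck_stats`.
#' @param path output TSV path.
#' @export
write_stats_table <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
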