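CK_CATEGORIES <- c("root_specific", "shoot_specific", "differential",
                   "similar", "uncategorized", "not_regulated",
                   "not_expressed")

#' Per-(organ, condition) mean log2 expression
#'
#' Arithmetic mean of the above-background log2 values in each of the 10
#' (organ, condition) cells. A cell with no above-background value yields
#' `NA`, which propagates to the ratios built on it.
#'
#' @param expr a `ck_expr`.
#' @return a `ck_means` data frame: `gene` plus columns `<organ>_<condition>`
#'   (e.g. `root_BA0`, ..., `shoot_CKX1`).
#' @export
condition_means <- function(expr) {
  stopifnot(inherits(expr, "ck_expr"))
  cells <- expand.grid(organ = CK_ORGANS, condition = CK_CONDITIONS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(gene = rownames(expr$values), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    arrays <- expr$design$array_id[
      expr$design$organ == cells$organ[i] &
      expr$design$condition == cells$condition[i]]
    col <- paste0(cells$organ[i], "_", cells$condition[i])
    if (length(arrays) == 0) { out[[col]] <- NA_real_; next }
    m <- rowMeans(expr$values[, arrays, drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    out[[col]] <- m
  }
  rownames(out) <- NULL
  class(out) <- c("ck_means", "data.frame")
  out
}

#' Linear-scale fold-change ratios versus the control
#'
#' For each organ and treated condition t in {BA15, BA120, BA1080, CKX1}:
#' `r(organ, t) = 2^(mean(organ, t) - mean(organ, BA0))`, plus the organ
#' baseline ratio `r_base = 2^(mean(root, BA0) - mean(shoot, BA0))`. Ratios
#' are linear-scale to match how fold changes are conventionally reported;
#' a missing cell mean yields a missing ratio.
#'
#' @param means a `ck_means` from [condition_means()].
#' @return a `ck_ratios` data frame: `gene`, `r_root_BA15` ... `r_shoot_CKX1`,
#'   `r_base`.
#' @export
fold_change_ratios <- function(means) {
  stopifnot(inherits(means, "ck_means"))
  out <- data.frame(gene = means$gene, stringsAsFactors = FALSE)
  for (org in CK_ORGANS) {
    base <- means[[paste0(org, "_BA0")]]
    for (cond in setdiff(CK_CONDITIONS, "BA0")) {
      out[[paste0("r_", org, "_", cond)]] <-
        2^(means[[paste0(org, "_", cond)]] - base)
    }
  }
  out$r_base <- 2^(means$root_BA0 - means$shoot_BA0)
  rownames(out) <- NULL
  class(out) <- c("ck_ratios", "data.frame")
  out
}

# Decision core shared by the induction and deficiency categorizations.
# r_root / r_shoot: matrices genes x timepoints of linear ratios (NA allowed).
# sig: logical significance gate per gene. Returns category + evidence.
.classify_core <- function(genes, r_root, r_shoot, sig, th) {
  T <- th$fold_change
  G <- th$gray_zone
  n <- length(genes)
  category <- character(n)
  evidence <- character(n)
  tps <- colnames(r_root)
  for (i in seq_len(n)) {
    rr <- r_root[i, ]
    rs <- r_shoot[i, ]
    up_r <- !is.na(rr) & rr >= T
    dn_r <- !is.na(rr) & rr <= 1 / T
    up_s <- !is.na(rs) & rs >= T
    dn_s <- !is.na(rs) & rs <= 1 / T
    reg_r <- any(up_r | dn_r)
    reg_s <- any(up_s | dn_s)
    ev <- function(up, dn) {
      if (!any(up | dn)) return("-")
      paste0(c(if (any(up)) paste0("up@", paste(tps[up], collapse = "+")),
               if (any(dn)) paste0("down@", paste(tps[dn], collapse = "+"))),
             collapse = ";")
    }
    evidence[i] <- paste0("root:", ev(up_r, dn_r), "|shoot:", ev(up_s, dn_s),
                          "|sig:", sig[i],
                          if (all(is.na(rr))) "|root_ratios_missing" else "",
                          if (all(is.na(rs))) "|shoot_ratios_missing" else "")
    if (!isTRUE(sig[i]) || (!reg_r && !reg_s)) {
      category[i] <- "not_regulated"
      next
    }
    if (xor(reg_r, reg_s)) {
      quiet <- if (reg_r) rs else rr
      in_gray <- is.null(G) ||
        all(is.na(quiet) | (quiet >= 1 / G & quiet <= G))
      category[i] <- if (!in_gray) "uncategorized"
                     else if (reg_r) "root_specific" else "shoot_specific"
      next
    }
    dir_of <- function(up, dn) {
      if (any(up) && any(dn)) "mixed" else if (any(up)) "up" else "down"
    }
    d_r <- dir_of(up_r, dn_r)
    d_s <- dir_of(up_s, dn_s)
    category[i] <- if (d_r == "mixed" || d_s == "mixed") "uncategorized"
                   else if (d_r == d_s) "similar" else "differential"
  }
  list(category = category, evidence = evidence)
}

#' Organ-specificity categorization, cytokinin-induction analysis
#'
#' Assigns each gene one of the categories `root_specific`, `shoot_specific`,
#' `differential`, `similar`, `uncategorized`, `not_regulated` (or
#' `not_expressed` for genes failing the induction detection filter),
#' evaluated over the treated time points BA15/BA120/BA1080:
#' \enumerate{
#'   \item significance gate: cytokinin-effect q or interaction q of the
#'     induction-subset model `<= alpha_q` (missing q counts as 1);
#'   \item per organ, a time point counts as responding when its ratio is
#'     `>= T` (up) or `<= 1/T` (down), `T = fold_change`; missing ratios are
#'     ignored, an organ with all ratios missing counts as unresponsive (and
#'     is flagged in the evidence);
#'   \item not significant, or neither organ responding: `not_regulated`;
#'   \item exactly one organ responding: that organ's specific category
#'     (unless the optional gray-zone rule demotes it to `uncategorized`);
#'   \item both responding: mixed direction in either organ gives
#'     `uncategorized`, equal directions `similar`, opposite `differential`.
#' }
#'
#' @param ratios a `ck_ratios`.
#' @param stats induction-subset `ck_stats` (or any data frame with `gene`,
#'   `q_cytokinin`, `q_interaction`).
#' @param detection a `ck_detection`; genes without `induction_eligible` are
#'   called `not_expressed`.
#' @param th a `ck_thresholds`.
#' @return a `ck_calls` data frame: `gene`, `analysis`, `category`,
#'   `evidence`.
#' @export
classify_induction <- function(ratios, stats, detection, th = thresholds()) {
  .classify_analysis(ratios, stats, detection, th,
                     analysis = "induction",
                     tps = c("BA15", "BA120", "BA1080"),
                     elig_flag = "induction_eligible")
}

#' Organ-specificity categorization, cytokinin-deficiency analysis
#'
#' Same decision list as [classify_induction()] with the single contrast
#' CKX1 vs BA0 per organ; the significance gate uses the genotype-effect q
#' (the `q_cytokinin` column of the deficiency-subset fit) and, when
#' available, the interaction q. With one contrast per organ a mixed
#' direction cannot occur.
#'
#' @inheritParams classify_induction
#' @export
classify_deficiency <- function(ratios, stats, detection, th = thresholds()) {
  .classify_analysis(ratios, stats, detection, th,
                     analysis = "deficiency",
                     tps = "CKX1",
                     elig_flag = "deficiency_eligible")
}

.classify_analysis <- function(ratios, stats, detection, th,
                               analysis, tps, elig_flag) {
  stopifnot(inherits(th, "ck_thresholds"))
  genes <- ratios$gene
  get_q <- function(col) {
    if (is.null(stats[[col]])) return(rep(1, length(genes)))
    q <- stats[[col]][match(genes, stats$gene)]
    ifelse(is.na(q), 1, q)
  }
  sig <- get_q("q_cytokinin") <= th$alpha_q |
         get_q("q_interaction") <= th$alpha_q
  r_root <- as.matrix(ratios[, paste0("r_root_", tps), drop = FALSE])
  r_shoot <- as.matrix(ratios[, paste0("r_shoot_", tps), drop = FALSE])
  colnames(r_root) <- colnames(r_shoot) <- tps
  res <- .classify_core(genes, r_root, r_shoot, sig, th)
  eligible <- detection[[elig_flag]][match(genes, detection$gene)] &
    !detection$not_expressed[match(genes, detection$gene)]
  eligible[is.na(eligible)] <- FALSE
  res$category[!eligible] <- "not_expressed"
  res$evidence[!eligible] <- "below detection threshold"
  calls <- data.frame(gene = genes, analysis = analysis,
                      category = res$category, evidence = res$evidence,
                      stringsAsFactors = FALSE)
  class(calls) <- c("ck_calls", "data.frame")
  calls
}
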