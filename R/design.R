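#' @keywords internal
CK_ORGANS <- c("root", "shoot")

#' @keywords internal
CK_CONDITIONS <- c("BA0", "BA15", "BA120", "BA1080", "CKX1")

#' @keywords internal
CK_INDUCTION_CONDITIONS <- c("BA0", "BA15", "BA120", "BA1080")

#' @keywords internal
CK_DEFICIENCY_CONDITIONS <- c("BA0", "CKX1")

#' Build the factorial array design of the study
#'
#' Generates the per-array design table of the organ-resolved cytokinin
#' experiment: 2 organs (root, shoot) x 5 conditions (mock control `BA0`,
#' benzyladenine treatments `BA15`/`BA120`/`BA1080`, and the cytokinin-deficient
#' `CKX1` genotype) x `n_bio` biological x `n_tech` technical replicates.
#' With the defaults this yields 40 arrays, four per (organ, condition) cell.
#'
#' @param n_bio number of biological replicates per (organ, condition) cell.
#' @param n_tech number of technical (hybridization) replicates per biological
#'   sample.
#' @return A `ck_design` data frame with columns `array_id`, `organ`,
#'   `condition`, `biological_replicate`, `technical_replicate`.
#' @examples
#' d <- generate_design()
#' nrow(d)                       # 40 arrays
#' length(induction_arrays(d))   # 32
#' length(deficiency_arrays(d))  # 16
#' @export
generate_design <- function(n_bio = 2, n_tech = 2) {
  stopifnot(n_bio >= 1, n_tech >= 1)
  d <- expand.grid(
    technical_replicate = seq_len(n_tech),
    biological_replicate = seq_len(n_bio),
    condition = CK_CONDITIONS,
    organ = CK_ORGANS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  d <- d[, c("organ", "condition", "biological_replicate", "technical_replicate")]
  d$array_id <- sprintf("%s_%s_b%d_t%d", d$organ, d$condition,
                        d$biological_replicate, d$technical_replicate)
  d <- d[, c("array_id", "organ", "condition",
             "biological_replicate", "technical_replicate")]
  validate_design(d)
}

#' Validate a study design table
#'
#' Checks the structural invariants required by the downstream analysis:
#' unique array identifiers and known organ and condition labels. A design
#' with single-array (organ, condition) cells is accepted with a warning:
#' per-gene models on such cells are saturated (no residual degrees of
#' freedom) and are flagged by the model layer.
#'
#' @param design a data frame with columns `array_id`, `organ`, `condition`,
#'   `biological_replicate`, `technical_replicate`.
#' @return the design, classed `ck_design`, with `organ` and `condition` as
#'   factors with the canonical level order.
#' @export
validate_design <- function(design) {
  req <- c("array_id", "organ", "condition",
           "biological_replicate", "technical_replicate")
  miss <- setdiff(req, names(design))
  if (length(miss) > 0)
    stop("design is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$array_id))
    stop("duplicate array_id in design: ",
         design$array_id[duplicated(design$array_id)][1])
  if (!all(design$organ %in% CK_ORGANS))
    stop("unknown organ label(s): ",
         paste(unique(setdiff(design$organ, CK_ORGANS)), collapse = ", "))
  if (!all(design$condition %in% CK_CONDITIONS))
    stop("unknown condition label(s): ",
         paste(unique(setdiff(design$condition, CK_CONDITIONS)), collapse = ", "))
  design$organ <- factor(as.character(design$organ), levels = CK_ORGANS)
  design$condition <- factor(as.character(design$condition), levels = CK_CONDITIONS)
  cell_n <- table(design$organ, design$condition)
  if (any(cell_n == 1))
    warning("some (organ, condition) cells have a single array; ",
            "per-gene models on them are saturated (no residual df)")
  rownames(design) <- NULL
  class(design) <- c("ck_design", "data.frame")
  design
}

#' Array subsets of the two analyses
#'
#' The cytokinin-induction analysis uses the wild-type time-course arrays
#' (conditions `BA0`, `BA15`, `BA120`, `BA1080`); the cytokinin-deficiency
#' analysis contrasts the `CKX1` genotype against the control (`BA0`, `CKX1`).
#' The two subsets share only the `BA0` arrays.
#'
#' @param design a `ck_design` data frame.
#' @return character vector of `array_id`s in the subset.
#' @export
induction_arrays <- function(design) {
  design$array_id[design$condition %in% CK_INDUCTION_CONDITIONS]
}

#' @rdname induction_arrays
#' @export
deficiency_arrays <- function(design) {
  design$array_id[design$condition %in% CK_DEFICIENCY_CONDITIONS]
}

#' @rdname induction_arrays
#' @param subset one of `"induction"`, `"deficiency"`, `"full"`.
#' @export
subset_arrays <- function(design, subset = c("induction", "deficiency", "full")) {
  subset <- match.arg(subset)
  switch(subset,
    induction = induction_arrays(design),
    deficiency = deficiency_arrays(design),
    full = design$array_id
  )
}

#' Analysis thresholds
#'
#' Bundles the tunable cutoffs of the pipeline. Defaults follow the original
#' study: a 2.5-fold change threshold, an FDR (q-value) gate of 0.03, a PCA
#' gene-selection q cutoff of 1e-4, "not expressed" below 4 spots above
#' background in total, model eligibility at >= 10 spots above background,
#' and per-subset detection on at least 25% of the subset's arrays.
#'
#' @param fold_change linear-scale fold-change threshold T (> 1).
#' @param alpha_q FDR-adjusted p-value (q-value) significance gate, in `[0, 1]`.
#' @param pca_q q-value cutoff for PCA gene selection.
#' @param abb_not_expressed genes detected on fewer than this many arrays in
#'   total are called "not expressed".
#' @param abb_model_min minimum total spots above background for model fitting.
#' @param abb_subset_fraction fraction of a subset's arrays on which a gene
#'   must be detected to enter that subset's analysis (ceiling is applied).
#' @param gray_zone optional "quiet organ" gray-zone ratio G with
#'   `1 < G <= fold_change`; when set, a gene regulated in exactly one organ is
#'   demoted to `uncategorized` if the other organ has any ratio outside
#'   `[1/G, G]`. `NULL` (the default) disables the rule.
#' @return a `ck_thresholds` list.
#' @export
thresholds <- function(fold_change = 2.5, alpha_q = 0.03, pca_q = 1e-4,
                       abb_not_expressed = 4L, abb_model_min = 10L,
                       abb_subset_fraction = 0.25, gray_zone = NULL) {
  stopifnot(is.numeric(fold_change), length(fold_change) == 1, fold_change > 1)
  stopifnot(is.numeric(alpha_q), length(alpha_q) == 1,
            alpha_q >= 0, alpha_q <= 1)
  stopifnot(is.numeric(pca_q), pca_q >= 0, pca_q <= 1)
  stopifnot(abb_not_expressed >= 0, abb_model_min >= 0,
            abb_subset_fraction > 0, abb_subset_fraction <= 1)
  if (!is.null(gray_zone))
    stopifnot(is.numeric(gray_zone), gray_zone > 1, gray_zone <= fold_change)
  structure(list(
    fold_change = fold_change, alpha_q = alpha_q, pca_q = pca_q,
    abb_not_expressed = as.integer(abb_not_expressed),
    abb_model_min = as.integer(abb_model_min),
    abb_subset_fraction = abb_subset_fraction,
    gray_zone = gray_zone
  ), class = "ck_thresholds")
}
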