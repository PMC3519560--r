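#' Build the input table of the developmental-shift filter
#'
#' Collects, per gene, the three quantities the shift filter tests: the
#' root-vs-shoot baseline ratio at BA0 (`r_base`), the 18 h cytokinin response
#' in roots (`r_root_BA1080`), the deficiency response in shoots
#' (`r_shoot_CKX1`), and the three q-values of the full 2 organ x 5 condition
#' model (organ, cytokinin, interaction).
#'
#' @param ratios a `ck_ratios`.
#' @param stats_full full-model `ck_stats`.
#' @return a data frame with columns `gene`, `r_base`, `r_root_BA1080`,
#'   `r_shoot_CKX1`, `q_organ`, `q_cytokinin`, `q_interaction`.
#' @export
shift_input_table <- function(ratios, stats_full) {
  i <- match(ratios$gene, stats_full$gene)
  data.frame(gene = ratios$gene,
             r_base = ratios$r_base,
             r_root_BA1080 = ratios$r_root_BA1080,
             r_shoot_CKX1 = ratios$r_shoot_CKX1,
             q_organ = stats_full$q_organ[i],
             q_cytokinin = stats_full$q_cytokinin[i],
             q_interaction = stats_full$q_interaction[i],
             stringsAsFactors = FALSE)
}

#' Find genes shifting toward the other organ's expression level
#'
#' A gene is a "developmental shift" gene when all three criteria hold:
#' \enumerate{
#'   \item baseline differential: root and shoot differ >= T-fold in the
#'     untreated control, i.e. `r_base >= T` (root-higher) or `r_base <= 1/T`
#'     (shoot-higher);
#'   \item the treatment moves the gene >= T-fold toward the other organ's
#'     level: mode `root_under_BA1080` requires `r_root_BA1080 >= T` for
#'     shoot-higher genes (root rises toward the shoot level) or `<= 1/T` for
#'     root-higher genes; mode `shoot_under_CKX1` requires `r_shoot_CKX1 >= T`
#'     for root-higher genes or `<= 1/T` for shoot-higher genes;
#'   \item at least one of the organ, cytokinin and interaction q-values of
#'     the full model is `<= alpha_q` ("and/or").
#' }
#' With `toward_other_organ = FALSE` criterion 2 drops the direction
#' requirement and accepts any >= T-fold change of the tested contrast
#' (sensitivity-analysis variant).
#'
#' @param tab a shift input table ([shift_input_table()] or an equivalent
#'   data frame, e.g. the bundled [shift_example()]).
#' @param th a `ck_thresholds`.
#' @param mode `"root_under_BA1080"` (roots after 18 h cytokinin) or
#'   `"shoot_under_CKX1"` (shoots under chronic cytokinin deficiency).
#' @param toward_other_organ require the change to be direction-consistent
#'   (default `TRUE`).
#' @return a `ck_shift_set` data frame of the member genes: `gene`,
#'   `baseline_side` (`root_higher`/`shoot_higher`), `direction` (`up`/`down`
#'   of the tested contrast; movement is toward the other organ's baseline),
#'   the tested ratio, and the three q-values. Genes with a missing required
#'   ratio are excluded; their ids are in `attr(, "excluded")`.
#' @export
find_shift_genes <- function(tab, th = thresholds(),
                             mode = c("root_under_BA1080", "shoot_under_CKX1"),
                             toward_other_organ = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(th, "ck_thresholds"))
  T <- th$fold_change
  contrast_col <- if (mode == "root_under_BA1080") "r_root_BA1080"
                  else "r_shoot_CKX1"
  need <- c("gene", "r_base", contrast_col,
            "q_organ", "q_cytokinin", "q_interaction")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("shift input table is missing columns: ", paste(miss, collapse = ", "))

  usable <- !is.na(tab$r_base) & !is.na(tab[[contrast_col]])
  excluded <- tab$gene[!usable]
  d <- tab[usable, , drop = FALSE]

  root_higher <- d$r_base >= T
  shoot_higher <- d$r_base <= 1 / T
  baseline_diff <- root_higher | shoot_higher

  r <- d[[contrast_col]]
  up <- r >= T
  down <- r <= 1 / T
  toward <- if (!toward_other_organ) (up | down)
  else if (mode == "root_under_BA1080") {
    # root moves toward the shoot level
    (shoot_higher & up) | (root_higher & down)
  } else {
    # shoot moves toward the root level
    (root_higher & up) | (shoot_higher & down)
  }

  qmin <- pmin(ifelse(is.na(d$q_organ), 1, d$q_organ),
               ifelse(is.na(d$q_cytokinin), 1, d$q_cytokinin),
               ifelse(is.na(d$q_interaction), 1, d$q_interaction))
  member <- baseline_diff & toward & qmin <= th$alpha_q

  set <- data.frame(
    gene = d$gene[member],
    baseline_side = ifelse(root_higher[member], "root_higher", "shoot_higher"),
    direction = ifelse(up[member], "up", "down"),
    ratio = r[member],
    q_organ = d$q_organ[member],
    q_cytokinin = d$q_cytokinin[member],
    q_interaction = d$q_interaction[member],
    stringsAsFactors = FALSE)
  attr(set, "mode") <- mode
  attr(set, "excluded") <- excluded
  class(set) <- c("ck_shift_set", "data.frame")
  set
}

#' Overlap partition of the two shift gene sets
#'
#' Intersects the root-under-treatment and shoot-under-deficiency shift sets
#' and splits the common genes by direction pair: genes with an enhanced
#' transcript level in cytokinin-treated roots and a repressed level in
#' cytokinin-deficient shoots (`root_up_shoot_down`), and the converse
#' (`root_down_shoot_up`).
#'
#' @param set_root a `ck_shift_set` with mode `root_under_BA1080`.
#' @param set_shoot a `ck_shift_set` with mode `shoot_under_CKX1`.
#' @return list with character vectors `root_up_shoot_down`,
#'   `root_down_shoot_up`, and integer `total`.
#' @export
shift_overlap <- function(set_root, set_shoot) {
  common <- intersect(set_root$gene, set_shoot$gene)
  dir_root <- set_root$direction[match(common, set_root$gene)]
  dir_shoot <- set_shoot$direction[match(common, set_shoot$gene)]
  g1 <- common[dir_root == "up" & dir_shoot == "down"]
  g2 <- common[dir_root == "down" & dir_shoot == "up"]
  list(root_up_shoot_down = g1, root_down_shoot_up = g2,
       total = length(g1) + length(g2))
}

#' Fraction of a gene set carrying a subcellular localization code
#'
#' Counts the members whose comma-separated localization code set contains
#' the given single-character code. The match is case-sensitive: uppercase
#' `P` (plastid) is distinct from lowercase `p`.
#'
#' @param genes character vector of probe ids.
#' @param annotation a `ck_annotation` (or data frame with `probe_id` and
#'   `localization`).
#' @param code single character, default `"P"`.
#' @return list with `count` and `fraction` (`NA` for an empty gene set).
#' @export
localization_fraction <- function(genes, annotation, code = "P") {
  stopifnot(is.character(code), nchar(code) == 1)
  if (length(genes) == 0) return(list(count = 0L, fraction = NA_real_))
  loc <- annotation$localization[match(genes, annotation$probe_id)]
  loc[is.na(loc)] <- ""
  has <- vapply(strsplit(loc, ","), function(codes) code %in% codes, logical(1))
  list(count = as.integer(sum(has)), fraction = sum(has) / length(genes))
}

#' Bundled 63-gene developmental-shift example table
#'
#' A curated table of 63 genes flagged as developmental-shift candidates in
#' an organ-resolved cytokinin transcriptome experiment on the CATMA v2.3
#' platform: per gene the total AbB count, the BA1080-vs-BA0 root ratio, the
#' CKX1-vs-BA0 shoot ratio, the root-vs-shoot baseline ratio at BA0, the
#' three FDR-adjusted p-values of the full organ x cytokinin model, the AGI
#' locus, subcellular localization codes and a description. Ratios and
#' q-values are stored at the table's printed precision. Ready to use as
#' input to [find_shift_genes()] (it already carries the required column
#' names) and [localization_fraction()].
#'
#' @return a data frame of 63 rows.
#' @examples
#' tab <- shift_example()
#' sr <- find_shift_genes(tab, mode = "root_under_BA1080")
#' ss <- find_shift_genes(tab, mode = "shoot_under_CKX1")
#' shift_overlap(sr, ss)$total  # 63
#' @export
shift_example <- function() {
  path <- system.file("extdata", "shift_table_63genes.tsv",
                      package = "ckorgan", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab)[names(tab) == "ratio_root_ba1080"] <- "r_root_BA1080"
  names(tab)[names(tab) == "ratio_shoot_ckx1"] <- "r_shoot_CKX1"
  names(tab)[names(tab) == "ratio_root_vs_shoot_ba0"] <- "r_base"
  tab$gene <- tab$probe_id
  tab
}
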