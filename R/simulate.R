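CK_SIM_CLASSES <- c("root_specific", "shoot_specific", "similar",
                    "differential", "shift_up_root", "shift_down_root",
                    "shift_root_like_shoot", "not_regulated", "not_expressed")

#' Simulation configuration
#'
#' Parameters of the synthetic CATMA-like data generator. The generator plants
#' per-gene ground-truth classes and reproduces the study design: log2
#' expression is a per-gene baseline plus planted (organ, condition) offsets,
#' a biological-replicate effect shared by the technical replicates of one
#' sample, and independent technical noise; above-background detection is
#' Bernoulli per cell.
#'
#' Classes: `root_specific` / `shoot_specific` / `similar` / `differential`
#' plant a cytokinin response of `effect_log2` (random per-gene sign) at the
#' BA120, BA1080 and CKX1 conditions in the corresponding organ(s)
#' (`differential` with opposite signs in the two organs). The three shift
#' classes additionally carry an organ-baseline offset of
#' `baseline_organ_log2`: `shift_up_root` genes are shoot-higher and rise in
#' roots under 18 h cytokinin (BA1080) while falling in cytokinin-deficient
#' shoots (CKX1); `shift_down_root` is the mirror image; `shift_root_like_shoot`
#' genes are shoot-higher and fall toward the root level only in CKX1 shoots.
#' `not_regulated` genes have no planted offsets; `not_expressed` genes use the
#' low detection probability everywhere.
#'
#' @param n_genes number of genes.
#' @param class_proportions named numeric vector over the classes above,
#'   summing to 1.
#' @param effect_log2 planted cytokinin-response magnitude, log2 units.
#' @param baseline_organ_log2 organ-baseline offset of shift genes, log2 units.
#' @param sigma_tech technical (per-array) noise sd, log2 units.
#' @param sigma_bio biological-replicate effect sd, log2 units.
#' @param detect_prob_expressed per-cell detection probability for expressed
#'   genes.
#' @param detect_prob_unexpressed per-cell detection probability for
#'   `not_expressed` genes.
#' @param detect_couple_strength optional coupling of detection to expression:
#'   detection probability becomes
#'   `plogis(qlogis(p) + strength * (value - mean baseline))`. 0 (default)
#'   keeps detection independent of level.
#' @param mixed_direction when `TRUE`, `differential` genes flip the sign of
#'   their BA1080 offset in the root, producing mixed-direction
#'   (uncategorized-style) response patterns.
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return a `ck_sim_config` list.
#' @export
simulation_config <- function(n_genes = 1000,
                              class_proportions = c(
                                root_specific = 0.05, shoot_specific = 0.05,
                                similar = 0.05, differential = 0.05,
                                shift_up_root = 0.03, shift_down_root = 0.03,
                                shift_root_like_shoot = 0.02,
                                not_regulated = 0.62, not_expressed = 0.10),
                              effect_log2 = 2.0, baseline_organ_log2 = 3.0,
                              sigma_tech = 0.25, sigma_bio = 0.25,
                              detect_prob_expressed = 0.95,
                              detect_prob_unexpressed = 0.05,
                              detect_couple_strength = 0,
                              mixed_direction = FALSE,
                              seed = 1L) {
  stopifnot(n_genes >= 1, effect_log2 > 0, baseline_organ_log2 > 0,
            sigma_tech >= 0, sigma_bio >= 0,
            detect_prob_expressed > 0, detect_prob_expressed <= 1,
            detect_prob_unexpressed >= 0, detect_prob_unexpressed <= 1)
  if (!all(names(class_proportions) %in% CK_SIM_CLASSES))
    stop("unknown class name(s): ",
         paste(setdiff(names(class_proportions), CK_SIM_CLASSES), collapse = ", "))
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1 (got ", sum(class_proportions), ")")
  full <- stats::setNames(numeric(length(CK_SIM_CLASSES)), CK_SIM_CLASSES)
  full[names(class_proportions)] <- class_proportions
  structure(list(
    n_genes = as.integer(n_genes), class_proportions = full,
    effect_log2 = effect_log2, baseline_organ_log2 = baseline_organ_log2,
    sigma_tech = sigma_tech, sigma_bio = sigma_bio,
    detect_prob_expressed = detect_prob_expressed,
    detect_prob_unexpressed = detect_prob_unexpressed,
    detect_couple_strength = detect_couple_strength,
    mixed_direction = isTRUE(mixed_direction),
    seed = as.integer(seed)
  ), class = "ck_sim_config")
}

# Deterministic class assignment: largest-remainder apportionment of
# n_genes over the configured proportions, genes assigned in block order.
.sim_classes <- function(cfg) {
  p <- cfg$class_proportions
  n <- cfg$n_genes
  base <- floor(p * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- p * n - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(p), times = base)
}

#' Planted (organ, condition) mean offsets for one gene class
#' @keywords internal
.planted_offsets <- function(class, sign, effect, baseline, mixed = FALSE) {
  off <- matrix(0, 2, 5, dimnames = list(CK_ORGANS, CK_CONDITIONS))
  treated <- c("BA120", "BA1080", "CKX1")
  switch(class,
    root_specific = { off["root", treated] <- sign * effect },
    shoot_specific = { off["shoot", treated] <- sign * effect },
    similar = {
      off["root", treated] <- sign * effect
      off["shoot", treated] <- sign * effect
    },
    differential = {
      off["root", treated] <- sign * effect
      off["shoot", treated] <- -sign * effect
      if (mixed) off["root", "BA1080"] <- -sign * effect
    },
    shift_up_root = {
      off["shoot", ] <- baseline
      off["root", "BA1080"] <- effect
      off["shoot", "CKX1"] <- off["shoot", "CKX1"] - effect
    },
    shift_down_root = {
      off["root", ] <- baseline
      off["root", "BA1080"] <- off["root", "BA1080"] - effect
      off["shoot", "CKX1"] <- effect
    },
    shift_root_like_shoot = {
      off["shoot", ] <- baseline
      off["shoot", "CKX1"] <- off["shoot", "CKX1"] - effect
    },
    not_regulated = , not_expressed = NULL
  )
  off
}

#' Simulate a CATMA-like dataset with planted ground truth
#'
#' Draws a log2 expression matrix and detection mask under the configured
#' design and gene classes. The value of gene g on array a is
#' `mu_g + offset(organ_a, condition_a) + b(g, sample_a) + e(g, a)` with
#' `b ~ N(0, sigma_bio^2)` shared by the technical replicates of one
#' biological sample and `e ~ N(0, sigma_tech^2)` independent. The biological
#' replicate effect is deliberately absent from the fitted two-factor model
#' downstream; it is a realism stressor.
#'
#' @param cfg a `ck_sim_config`.
#' @param design a `ck_design`, e.g. [generate_design()].
#' @return list with elements `expr` (a `ck_expr`), `truth` (data frame:
#'   `gene`, `class`, `sign`; planted offsets in `attr(truth, "offsets")`, a
#'   genes x organ x condition array), and `annotation` (a `ck_annotation`
#'   where shoot-baseline shift genes are enriched for the plastid code `P`).
#' @export
simulate_dataset <- function(cfg, design = generate_design()) {
  stopifnot(inherits(cfg, "ck_sim_config"))
  design <- validate_design(design)
  set.seed(cfg$seed)
  n <- cfg$n_genes
  genes <- sprintf("GENE%05d", seq_len(n))
  classes <- .sim_classes(cfg)
  signs <- sample(c(-1, 1), n, replace = TRUE)
  mu <- stats::rnorm(n, mean = 8, sd = 1)

  offsets <- array(0, dim = c(n, 2, 5),
                   dimnames = list(genes, CK_ORGANS, CK_CONDITIONS))
  for (g in seq_len(n)) {
    off <- .planted_offsets(classes[g], signs[g], cfg$effect_log2,
                            cfg$baseline_organ_log2, cfg$mixed_direction)
    if (!is.null(off)) offsets[g, , ] <- off
  }

  n_arr <- nrow(design)
  oi <- as.integer(design$organ)
  ci <- as.integer(design$condition)
  # biological sample index: one b-effect per (organ, condition, bio rep)
  samp <- interaction(design$organ, design$condition,
                      design$biological_replicate, drop = TRUE)
  si <- as.integer(samp)
  n_samp <- nlevels(samp)

  bio <- matrix(stats::rnorm(n * n_samp, 0, cfg$sigma_bio), n, n_samp)
  tech <- matrix(stats::rnorm(n * n_arr, 0, cfg$sigma_tech), n, n_arr)
  planted <- matrix(offsets[cbind(rep(seq_len(n), n_arr),
                                  rep(oi, each = n), rep(ci, each = n))],
                    n, n_arr)
  values <- mu + planted + bio[, si] + tech
  dimnames(values) <- list(genes, design$array_id)

  p_det <- matrix(ifelse(classes == "not_expressed",
                         cfg$detect_prob_unexpressed,
                         cfg$detect_prob_expressed), n, n_arr)
  if (cfg$detect_couple_strength != 0) {
    p_det <- stats::plogis(stats::qlogis(pmin(pmax(p_det, 1e-12), 1 - 1e-12)) +
                           cfg$detect_couple_strength * (values - mu))
  }
  mask <- matrix(stats::runif(n * n_arr) < p_det, n, n_arr,
                 dimnames = dimnames(values))

  truth <- data.frame(gene = genes, class = classes, sign = signs,
                      stringsAsFactors = FALSE)
  attr(truth, "offsets") <- offsets

  shoot_base <- classes %in% c("shift_up_root", "shift_root_like_shoot")
  p_plastid <- ifelse(shoot_base, 0.75, 0.10)
  other_codes <- c("c", "e", "m", "n", "v", "w", "-")
  loc <- ifelse(stats::runif(n) < p_plastid, "P",
                sample(other_codes, n, replace = TRUE))
  annotation <- data.frame(
    probe_id = genes,
    agi = sprintf("AT%dG%05d", sample(1:5, n, replace = TRUE),
                  sample(10000:79999, n, replace = TRUE)),
    description = paste("synthetic", classes, "gene"),
    localization = loc, stringsAsFactors = FALSE)
  class(annotation) <- c("ck_annotation", "data.frame")

  list(expr = expression_matrix(values, mask, design),
       truth = truth, annotation = annotation)
}
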