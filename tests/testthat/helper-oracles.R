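# Independent oracles and small fixtures used across the suite.
# Each oracle is a deliberately naive re-derivation, kept separate from the
# package code paths it checks.

# Classical balanced two-way ANOVA by explicit sums of squares.
# y: response; A, B: factors; assumes a complete balanced layout.
oracle_anova2 <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  a <- nlevels(A); b <- nlevels(B)
  r <- length(y) / (a * b)
  stopifnot(r == round(r), all(table(A, B) == r))
  grand <- mean(y)
  mA <- tapply(y, A, mean)
  mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  ss_A <- r * b * sum((mA - grand)^2)
  ss_B <- r * a * sum((mB - grand)^2)
  ss_AB <- r * sum((sweep(sweep(mAB, 1, mA), 2, mB) + grand)^2)
  ss_E <- sum((y - mAB[cbind(A, B)])^2)
  df <- c(A = a - 1, B = b - 1, AB = (a - 1) * (b - 1), E = a * b * (r - 1))
  mse <- ss_E / df[["E"]]
  Fs <- c(A = ss_A / df[["A"]], B = ss_B / df[["B"]],
          AB = ss_AB / df[["AB"]]) / mse
  ps <- stats::pf(Fs, df[c("A", "B", "AB")], df[["E"]], lower.tail = FALSE)
  list(F_A = Fs[["A"]], p_A = ps[["A"]], F_B = Fs[["B"]], p_B = ps[["B"]],
       F_AB = Fs[["AB"]], p_AB = ps[["AB"]])
}

# Straight-line re-implementation of the organ-specificity decision list for
# one gene. rr, rs: ratio vectors (NA allowed); sig: significance gate.
oracle_classify <- function(rr, rs, sig, T = 2.5, G = NULL) {
  up_r <- which(rr >= T); dn_r <- which(rr <= 1 / T)
  up_s <- which(rs >= T); dn_s <- which(rs <= 1 / T)
  reg_r <- length(up_r) + length(dn_r) > 0
  reg_s <- length(up_s) + length(dn_s) > 0
  if (!sig || (!reg_r && !reg_s)) return("not_regulated")
  if (reg_r && !reg_s) {
    if (!is.null(G) && any(rs > G | rs < 1 / G, na.rm = TRUE))
      return("uncategorized")
    return("root_specific")
  }
  if (reg_s && !reg_r) {
    if (!is.null(G) && any(rr > G | rr < 1 / G, na.rm = TRUE))
      return("uncategorized")
    return("shoot_specific")
  }
  mixed_r <- length(up_r) > 0 && length(dn_r) > 0
  mixed_s <- length(up_s) > 0 && length(dn_s) > 0
  if (mixed_r || mixed_s) return("uncategorized")
  dir_r <- if (length(up_r) > 0) "up" else "down"
  dir_s <- if (length(up_s) > 0) "up" else "down"
  if (dir_r == dir_s) "similar" else "differential"
}

# Three-predicate shift filter for one gene.
oracle_shift_member <- function(r_base, r, q_organ, q_ck, q_int,
                                mode, T = 2.5, alpha = 0.03) {
  if (is.na(r_base) || is.na(r)) return(FALSE)
  root_higher <- r_base >= T
  shoot_higher <- r_base <= 1 / T
  crit1 <- root_higher || shoot_higher
  crit2 <- if (mode == "root_under_BA1080")
    (shoot_higher && r >= T) || (root_higher && r <= 1 / T)
  else
    (root_higher && r >= T) || (shoot_higher && r <= 1 / T)
  qs <- c(q_organ, q_ck, q_int)
  qs[is.na(qs)] <- 1
  crit1 && crit2 && min(qs) <= alpha
}

# Minimal detection frame making every gene eligible (or not).
fake_detection <- function(genes, eligible = TRUE, abb_total = 40L) {
  data.frame(gene = genes, abb_total = abb_total,
             abb_induction = 32L, abb_deficiency = 16L,
             not_expressed = FALSE,
             model_eligible = TRUE,
             induction_eligible = eligible,
             deficiency_eligible = eligible,
             stringsAsFactors = FALSE)
}

# Published-style example rows of the cytokinin-induction analysis:
# per-timepoint linear ratios (BA15, BA120, BA1080) per organ, the
# cytokinin-effect q, and the expected category. The printed 0.00 ratio of
# the major-intrinsic-protein row is stored as a small positive value.
t1_example_rows <- function() {
  rows <- list(
    list("CATMA1a44090", c(5.71, 75.18, 156.88), c(0.74, 0.47, 0.52),
         1.81e-2, "root_specific"),
    list("CATMA1a56420", c(4.19, 60.47, 29.56), c(0.90, 0.62, 1.50),
         4.72e-3, "root_specific"),
    list("CATMA5a49210", c(2.28, 1.71, 0.79), c(5.42, 7.91, 6.22),
         2.53e-5, "shoot_specific"),
    list("CATMA5a07985", c(2.96, 2.22, 1.85), c(14.50, 30.04, 4.43),
         2.03e-2, "similar"),
    list("CATMA4a13955", c(1.87, 1.07, 0.22), c(10.41, 4.16, 2.68),
         2.25e-4, "differential"),
    list("CATMA5a43410", c(0.48, 0.18, 0.004), c(3.30, 0.70, 0.10),
         1.31e-6, "uncategorized"),
    list("NULLGENE", c(1, 1, 1), c(1, 1, 1), 1, "not_regulated")
  )
  ratios <- data.frame(
    gene = vapply(rows, `[[`, character(1), 1),
    t(vapply(rows, function(r) c(r[[2]], r[[3]]), numeric(6))),
    stringsAsFactors = FALSE)
  names(ratios)[2:7] <- c(paste0("r_root_", c("BA15", "BA120", "BA1080")),
                          paste0("r_shoot_", c("BA15", "BA120", "BA1080")))
  stats <- data.frame(gene = ratios$gene,
                      q_cytokinin = vapply(rows, `[[`, numeric(1), 4),
                      stringsAsFactors = FALSE)
  list(ratios = ratios, stats = stats,
       expected = vapply(rows, `[[`, character(1), 5))
}

# Deficiency-analysis example rows: single CKX1-vs-control contrast per organ.
t2_example_rows <- function() {
  rows <- list(
    list("CATMA5a61330", 18.32, 1.26, 7.99e-4, "root_specific"),
    list("CATMA4a00090", 1.00, 76.53, 1.19e-3, "shoot_specific"),
    list("CATMA5a07985", 16.98, 57.30, 3.42e-3, "similar")
  )
  ratios <- data.frame(
    gene = vapply(rows, `[[`, character(1), 1),
    r_root_CKX1 = vapply(rows, `[[`, numeric(1), 2),
    r_shoot_CKX1 = vapply(rows, `[[`, numeric(1), 3),
    stringsAsFactors = FALSE)
  stats <- data.frame(gene = ratios$gene,
                      q_cytokinin = vapply(rows, `[[`, numeric(1), 4),
                      stringsAsFactors = FALSE)
  list(ratios = ratios, stats = stats,
       expected = vapply(rows, `[[`, character(1), 5))
}

# Random ratio tuple generator for property tests: mixes quiet, strong and
# near-threshold ratios and occasional missing values.
random_ratio_vec <- function(n, na_prob = 0.1) {
  r <- exp(stats::rnorm(n, 0, 1.2))
  r[stats::runif(n) < na_prob] <- NA
  r
}
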