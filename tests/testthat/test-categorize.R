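test_that("condition means are missing-aware cell averages", {
  design <- generate_design()
  v <- matrix(NA_real_, 2, 40, dimnames = list(c("G1", "G2"),
                                               design$array_id))
  root_ba0 <- design$array_id[design$organ == "root" &
                              design$condition == "BA0"]
  v["G1", root_ba0] <- 2
  v["G2", root_ba0] <- c(1, 3, NA, NA)
  m <- !is.na(v)
  expr <- expression_matrix(v, m, design)
  means <- condition_means(expr)
  expect_equal(means$root_BA0, c(2, 2))
  expect_true(all(is.na(means$shoot_BA0)))   # empty cells propagate NA
})

test_that("ratios are 2^(log2 difference) with the control as baseline", {
  design <- generate_design()
  v <- matrix(5, 1, 40, dimnames = list("G1", design$array_id))
  pick <- function(org, cond) design$array_id[design$organ == org &
                                              design$condition == cond]
  v[1, pick("root", "BA120")] <- 7   # +2 log2 -> ratio 4
  v[1, pick("shoot", "BA15")] <- 5   # unchanged -> ratio 1
  expr <- expression_matrix(v, !is.na(v), design)
  r <- fold_change_ratios(condition_means(expr))
  expect_equal(r$r_root_BA120, 4)
  expect_equal(r$r_shoot_BA15, 1)
  expect_equal(r$r_base, 1)
})

test_that("published-style induction rows classify into their categories", {
  t1 <- t1_example_rows()
  calls <- classify_induction(t1$ratios, t1$stats,
                              fake_detection(t1$ratios$gene))
  expect_equal(calls$category, t1$expected)
  # supporting evidence names the crossing time points
  ev <- calls$evidence[calls$gene == "CATMA1a56420"]
  expect_match(ev, "root:up@BA15\\+BA120\\+BA1080")
  expect_match(ev, "shoot:-")
})

test_that("published-style deficiency rows classify into their categories", {
  t2 <- t2_example_rows()
  calls <- classify_deficiency(t2$ratios, t2$stats,
                               fake_detection(t2$ratios$gene))
  expect_equal(calls$category, t2$expected)
})

test_that("ineligible genes are reported as not expressed", {
  t1 <- t1_example_rows()
  det <- fake_detection(t1$ratios$gene, eligible = FALSE)
  calls <- classify_induction(t1$ratios, t1$stats, det)
  expect_true(all(calls$category == "not_expressed"))
})

test_that("classification matches a brute-force decision list on random tuples", {
  set.seed(17)
  n <- 1000
  genes <- sprintf("R%04d", seq_len(n))
  ratios <- data.frame(gene = genes)
  for (tp in c("BA15", "BA120", "BA1080")) {
    ratios[[paste0("r_root_", tp)]] <- random_ratio_vec(n)
    ratios[[paste0("r_shoot_", tp)]] <- random_ratio_vec(n)
  }
  q <- ifelse(runif(n) < 0.6, runif(n, 0, 0.03), runif(n, 0.03, 1))
  stats <- data.frame(gene = genes, q_cytokinin = q,
                      q_interaction = runif(n))
  for (G in list(NULL, 2)) {
    th <- thresholds(gray_zone = G)
    calls <- classify_induction(ratios, stats, fake_detection(genes), th)
    sig <- stats$q_cytokinin <= 0.03 | stats$q_interaction <= 0.03
    expected <- vapply(seq_len(n), function(i) {
      oracle_classify(
        unlist(ratios[i, paste0("r_root_", c("BA15", "BA120", "BA1080"))]),
        unlist(ratios[i, paste0("r_shoot_", c("BA15", "BA120", "BA1080"))]),
        sig[i], T = 2.5, G = G)
    }, character(1))
    expect_equal(calls$category, expected)
  }
})

test_that("tightening thresholds never promotes a gene into a regulated category", {
  set.seed(23)
  n <- 400
  genes <- sprintf("R%04d", seq_len(n))
  ratios <- data.frame(gene = genes)
  for (tp in c("BA15", "BA120", "BA1080")) {
    ratios[[paste0("r_root_", tp)]] <- random_ratio_vec(n, na_prob = 0)
    ratios[[paste0("r_shoot_", tp)]] <- random_ratio_vec(n, na_prob = 0)
  }
  stats <- data.frame(gene = genes, q_cytokinin = runif(n),
                      q_interaction = runif(n))
  det <- fake_detection(genes)
  loose <- classify_induction(ratios, stats, det, thresholds())
  for (th in list(thresholds(fold_change = 4),
                  thresholds(alpha_q = 0.005),
                  thresholds(fold_change = 4, alpha_q = 0.005))) {
    tight <- classify_induction(ratios, stats, det, th)
    moved <- loose$category == "not_regulated" &
             tight$category != "not_regulated"
    expect_false(any(moved))
  }
})

test_that("zero-noise simulated data classify exactly as planted", {
  cfg <- simulation_config(
    n_genes = 120, sigma_tech = 0, sigma_bio = 0,
    detect_prob_expressed = 1, seed = 41,
    class_proportions = c(root_specific = 0.25, shoot_specific = 0.25,
                          similar = 0.2, differential = 0.2,
                          not_regulated = 0.1))
  ds <- simulate_dataset(cfg)
  det <- detection_report(ds$expr)
  st <- fit_models(ds$expr, "induction", det)
  calls <- classify_induction(fold_change_ratios(condition_means(ds$expr)),
                              st, det)
  expect_equal(calls$category[match(ds$truth$gene, calls$gene)],
               ds$truth$class)
})

test_that("mixed-direction responses are uncategorized", {
  genes <- "GMIX"
  ratios <- data.frame(gene = genes,
                       r_root_BA15 = 4, r_root_BA120 = 0.2, r_root_BA1080 = 1,
                       r_shoot_BA15 = 4, r_shoot_BA120 = 4, r_shoot_BA1080 = 4)
  stats <- data.frame(gene = genes, q_cytokinin = 1e-5)
  calls <- classify_induction(ratios, stats, fake_detection(genes))
  expect_equal(calls$category, "uncategorized")
})
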