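test_that("single-gene membership follows the three criteria", {
  # shoot-higher gene rising in treated roots (plastid ribosomal protein row)
  tab <- data.frame(gene = "CATMA5a16150", r_base = 0.03,
                    r_root_BA1080 = 2.80, r_shoot_CKX1 = 0.09,
                    q_organ = 5.98e-18, q_cytokinin = 1.83e-6,
                    q_interaction = 2.95e-5)
  set <- find_shift_genes(tab, mode = "root_under_BA1080")
  expect_equal(set$gene, "CATMA5a16150")
  expect_equal(set$baseline_side, "shoot_higher")
  expect_equal(set$direction, "up")
  # no baseline organ differential -> never a member
  tab$r_base <- 1.0
  expect_equal(nrow(find_shift_genes(tab, mode = "root_under_BA1080")), 0)
  # direction matters: a shoot-higher gene falling further is not a shift
  tab2 <- data.frame(gene = "g", r_base = 0.03, r_root_BA1080 = 0.2,
                     r_shoot_CKX1 = NA, q_organ = 1e-9, q_cytokinin = 1e-9,
                     q_interaction = 1e-9)
  expect_equal(nrow(find_shift_genes(tab2, mode = "root_under_BA1080")), 0)
  expect_equal(nrow(find_shift_genes(tab2, mode = "root_under_BA1080",
                                     toward_other_organ = FALSE)), 1)
})

test_that("membership equals an independent three-predicate filter", {
  set.seed(53)
  n <- 500
  tab <- data.frame(
    gene = sprintf("S%04d", seq_len(n)),
    r_base = random_ratio_vec(n, na_prob = 0.05) *
      sample(c(0.05, 1, 20), n, replace = TRUE),
    r_root_BA1080 = random_ratio_vec(n, na_prob = 0.05),
    r_shoot_CKX1 = random_ratio_vec(n, na_prob = 0.05),
    q_organ = runif(n), q_cytokinin = runif(n, 0, 0.1),
    q_interaction = runif(n))
  for (mode in c("root_under_BA1080", "shoot_under_CKX1")) {
    got <- find_shift_genes(tab, mode = mode)
    col <- if (mode == "root_under_BA1080") "r_root_BA1080" else "r_shoot_CKX1"
    expected <- tab$gene[vapply(seq_len(n), function(i)
      oracle_shift_member(tab$r_base[i], tab[[col]][i], tab$q_organ[i],
                          tab$q_cytokinin[i], tab$q_interaction[i], mode),
      logical(1))]
    expect_setequal(got$gene, expected)
    # excluded genes are exactly those with a missing required ratio
    expect_setequal(attr(got, "excluded"),
                    tab$gene[is.na(tab$r_base) | is.na(tab[[col]])])
  }
  # membership does not depend on row order
  perm <- sample(n)
  expect_setequal(find_shift_genes(tab[perm, ], mode = "root_under_BA1080")$gene,
                  find_shift_genes(tab, mode = "root_under_BA1080")$gene)
})

test_that("overlap partition is disjoint, contained, and direction-split", {
  tab <- shift_example()
  sr <- find_shift_genes(tab, mode = "root_under_BA1080")
  ss <- find_shift_genes(tab, mode = "shoot_under_CKX1")
  ov <- shift_overlap(sr, ss)
  expect_length(intersect(ov$root_up_shoot_down, ov$root_down_shoot_up), 0)
  both <- c(ov$root_up_shoot_down, ov$root_down_shoot_up)
  expect_true(all(both %in% sr$gene) && all(both %in% ss$gene))
  expect_equal(ov$total, length(both))
  # degenerate overlaps
  empty <- sr[0, ]
  expect_equal(shift_overlap(sr, empty)$total, 0)
  same <- sr; same$direction <- "up"
  same2 <- sr; same2$direction <- "down"
  expect_equal(shift_overlap(same, same2)$root_up_shoot_down, same$gene)
})

test_that("localization fractions are case-sensitive set lookups", {
  ann <- data.frame(probe_id = c("g1", "g2", "g3"),
                    agi = NA, description = NA,
                    localization = c("w,p", "a,P", "-"))
  expect_equal(localization_fraction(c("g1", "g2", "g3"), ann, "P")$count, 1L)
  expect_equal(localization_fraction(c("g1", "g2", "g3"), ann, "p")$count, 1L)
  lf <- localization_fraction(character(0), ann, "P")
  expect_equal(lf$count, 0L)
  expect_true(is.na(lf$fraction))
  lf3 <- localization_fraction("g3", ann, "P")
  expect_equal(lf3$fraction, 0)
})

test_that("planted shift genes are recovered and nulls stay out", {
  cfg <- simulation_config(
    n_genes = 300, seed = 61, effect_log2 = 2.5,
    class_proportions = c(shift_up_root = 0.15, shift_down_root = 0.15,
                          not_regulated = 0.7))
  ds <- simulate_dataset(cfg)
  det <- detection_report(ds$expr)
  st <- fit_models(ds$expr, "full", det)
  tab <- shift_input_table(fold_change_ratios(condition_means(ds$expr)), st)
  sr <- find_shift_genes(tab, mode = "root_under_BA1080")
  ss <- find_shift_genes(tab, mode = "shoot_under_CKX1")
  ov <- shift_overlap(sr, ss)
  up <- ds$truth$gene[ds$truth$class == "shift_up_root"]
  dn <- ds$truth$gene[ds$truth$class == "shift_down_root"]
  nulls <- ds$truth$gene[ds$truth$class == "not_regulated"]
  expect_gte(mean(up %in% ov$root_up_shoot_down), 0.9)
  expect_gte(mean(dn %in% ov$root_down_shoot_up), 0.9)
  expect_lte(mean(nulls %in% c(sr$gene, ss$gene)), 0.05)
})
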