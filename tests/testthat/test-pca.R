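make_means <- function(df) {
  class(df) <- c("ck_means", "data.frame")
  df
}

full_means <- function(gene, root, shoot) {
  df <- data.frame(gene = gene)
  for (i in seq_along(ckorgan:::CK_CONDITIONS)) {
    df[[paste0("root_", ckorgan:::CK_CONDITIONS[i])]] <- root[, i]
    df[[paste0("shoot_", ckorgan:::CK_CONDITIONS[i])]] <- shoot[, i]
  }
  make_means(df)
}

test_that("organ normalization applies the mean-offset formula exactly", {
  m <- full_means("g1", root = matrix(5, 1, 5),
                  shoot = matrix(c(1, 2, 3, 4, 5), 1))
  norm <- organ_normalize(m)
  # shoot mean 3, root mean 5 -> +2 shift
  expect_equal(unlist(norm[1, paste0("shoot_", ckorgan:::CK_CONDITIONS)],
                      use.names = FALSE), c(3, 4, 5, 6, 7))
  expect_equal(unlist(norm[1, paste0("root_", ckorgan:::CK_CONDITIONS)],
                      use.names = FALSE), rep(5, 5))
  # equal organ averages leave the shoot untouched
  m2 <- full_means("g2", root = matrix(c(1, 2, 3, 4, 5), 1),
                   shoot = matrix(c(5, 4, 3, 2, 1), 1))
  norm2 <- organ_normalize(m2)
  expect_equal(unlist(norm2[1, paste0("shoot_", ckorgan:::CK_CONDITIONS)],
                      use.names = FALSE), c(5, 4, 3, 2, 1))
})

test_that("normalization leaves a per-gene organ main effect of exactly zero", {
  set.seed(71)
  n <- 50
  root <- matrix(rnorm(n * 5, 8), n)
  shoot <- matrix(rnorm(n * 5, 11), n)
  m <- full_means(sprintf("g%02d", 1:n), root, shoot)
  norm <- organ_normalize(m)
  ra <- rowMeans(norm[, paste0("root_", ckorgan:::CK_CONDITIONS)])
  sa <- rowMeans(norm[, paste0("shoot_", ckorgan:::CK_CONDITIONS)])
  expect_lt(max(abs(ra - sa)), 1e-12)
  # genes with missing cells are dropped with a message
  m$root_BA0[3] <- NA
  expect_message(norm2 <- organ_normalize(m), "dropped")
  expect_equal(nrow(norm2), n - 1)
})

test_that("PCA gene selection gates on AbB and the minimum q", {
  det <- fake_detection(c("g1", "g2", "g3"), abb_total = c(9L, 40L, 40L))
  stats <- data.frame(gene = c("g1", "g2", "g3"),
                      q_organ = c(1e-9, 1, 1),
                      q_cytokinin = c(1e-9, 1, 1e-6),
                      q_interaction = c(1e-9, 1, 1))
  expect_equal(select_pca_genes(det, stats), "g3")   # g1 fails AbB, g2 fails q
  stats$q_cytokinin <- 1; stats$q_organ <- 1; stats$q_interaction <- 1
  expect_error(select_pca_genes(det, stats), "raising pca_q")
})

test_that("PCA conserves variance and handles degenerate shapes", {
  set.seed(73)
  # one informative gene -> rank one, first fraction 1
  prof <- cbind(g1 = c(1, 2, 3, 4), g2 = rep(5, 4))
  rownames(prof) <- paste0("s", 1:4)
  p <- run_pca(prof)
  expect_equal(p$eig_fractions[1], 1)
  # duplicate samples get identical scores
  prof2 <- matrix(rnorm(40), 4, 10,
                  dimnames = list(paste0("s", 1:4), paste0("g", 1:10)))
  prof2[2, ] <- prof2[1, ]
  p2 <- run_pca(prof2)
  expect_equal(p2$scores[1, ], p2$scores[2, ])
  # eigenvalues sum to the total centered variance
  centered <- scale(prof2, center = TRUE, scale = FALSE)
  expect_equal(sum(p2$eigenvalues), sum(centered^2) / (nrow(prof2) - 1),
               tolerance = 1e-9)
  expect_equal(sum(p2$eig_fractions), 1, tolerance = 1e-9)
  expect_error(run_pca(matrix(3, 4, 4)), "rank-0")
})

test_that("a realized covariance of [[2,1],[1,2]] yields fractions 3/4 and 1/4", {
  set.seed(79)
  n <- 40
  x <- matrix(rnorm(n * 2), n, 2)
  x <- scale(x, center = TRUE, scale = FALSE)
  # rotate to exact sample covariance [[2,1],[1,2]]
  x <- x %*% solve(chol(cov(x))) %*% chol(matrix(c(2, 1, 1, 2), 2))
  colnames(x) <- c("g1", "g2"); rownames(x) <- paste0("s", 1:n)
  p <- run_pca(x)
  expect_equal(p$eig_fractions, c(0.75, 0.25), tolerance = 1e-9)
})

test_that("support tree recovers a planted bipartition with full support", {
  set.seed(83)
  n_genes <- 200
  organ_off <- rnorm(n_genes, 0, 3)
  base <- rnorm(n_genes, 8, 1)
  prof <- t(vapply(1:10, function(s) {
    base + (if (s > 5) organ_off else 0) + rnorm(n_genes, 0, 0.2)
  }, numeric(n_genes)))
  rownames(prof) <- c(paste0("root_", 1:5), paste0("shoot_", 1:5))
  tree <- support_tree(prof, n_boot = 50, seed = 7)
  key <- vapply(tree$clades, paste, character(1), collapse = "+")
  i <- match(paste(sort(paste0("shoot_", 1:5)), collapse = "+"), key)
  j <- match(paste(sort(paste0("root_", 1:5)), collapse = "+"), key)
  expect_true(!is.na(i) || !is.na(j))
  expect_true(any(tree$support[c(i, j)] == 1, na.rm = TRUE))
  # n_boot = 0 gives a tree without supports
  t0 <- support_tree(prof, n_boot = 0)
  expect_true(all(is.na(t0$support)))
  # sample order does not change topology or supports
  perm <- sample(10)
  tree_p <- support_tree(prof[perm, ], n_boot = 50, seed = 7)
  key_p <- vapply(tree_p$clades, paste, character(1), collapse = "+")
  expect_setequal(key, key_p)
  expect_equal(tree$support[order(key)], tree_p$support[order(key_p)])
  # constant profiles are rejected
  prof[1, ] <- 4
  expect_error(support_tree(prof), "constant profile")
})

test_that("newick export carries support labels", {
  set.seed(89)
  prof <- matrix(rnorm(5 * 50), 5, 50,
                 dimnames = list(paste0("s", 1:5), NULL))
  tree <- support_tree(prof, n_boot = 20, seed = 3)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_support_tree(tree, path)
  txt <- readLines(path)
  expect_match(txt, "^\\(")
  reread <- ape::read.tree(path)
  expect_setequal(reread$tip.label, rownames(prof))
})
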