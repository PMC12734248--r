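toy_gt <- function() {
  # 10 individuals x 5 sites; one site violates each filter, two are clean
  n <- 10
  geno <- cbind(
    c(rep(0L, 5), rep(2L, 5)), # clean
    c(rep(0L, 5), rep(2L, 5)), # will get bad depth
    c(rep(0L, 9), 1L), # MAF 0.05 (not > 0.05)
    c(NA, rep(0L, 4), rep(2L, 5)), # 10% missing
    c(rep(1L, 5), rep(0L, 4), 2L) # clean
  )
  depth <- matrix(10L, n, 5)
  depth[, 2] <- 30L # mean depth outside [8, 12]
  depth[1, 4] <- 0L
  genotype_table(
    sprintf("i%02d", 1:n), sprintf("chr1:%d", 1:5), geno, depth,
    class_label = rep(c("Africa", "Asia"), each = 5)
  )
}

test_that("site filtering removes exactly the violating sites and is idempotent", {
  gt <- toy_gt()
  out <- suppressMessages(
    filter_sites(gt, max_missing = 0.01, min_maf = 0.05,
      depth_range = c(8, 12))
  )
  expect_equal(out$sites, c("chr1:1", "chr1:5"))
  again <- suppressMessages(
    filter_sites(out, max_missing = 0.01, min_maf = 0.05,
      depth_range = c(8, 12))
  )
  expect_identical(again$geno, out$geno)

  # vacuous thresholds: identity
  all_kept <- suppressMessages(
    filter_sites(gt, max_missing = 1, min_maf = 0, depth_range = c(0, Inf))
  )
  expect_identical(all_kept$sites, gt$sites)
  expect_error(
    suppressMessages(filter_sites(gt, max_missing = -1)),
    "all sites removed"
  )
})

test_that("class-conditional mode imputation follows the stated tie-breaks", {
  geno <- cbind(
    c(0L, 0L, 0L, NA, 2L, 2L, 2L, 2L), # class A mode 0
    c(0L, 0L, 2L, NA, 1L, 1L, 1L, 1L), # class A tie 0/2 -> 0 (x2 with NA)
    c(1L, 1L, 1L, 1L, NA, NA, NA, NA) # class B all missing -> global mode
  )
  depth <- matrix(10L, 8, 3)
  depth[is.na(geno)] <- 1L # keep depth positive so only geno NA drives it
  gt <- genotype_table(
    paste0("i", 1:8), paste0("chr1:", 1:3),
    geno, depth,
    class_label = rep(c("A", "B"), each = 4)
  )
  out <- impute_genotypes(gt)
  expect_false(anyNA(out$geno))
  expect_equal(unname(out$geno[4, 1]), 0)
  expect_equal(unname(out$geno[4, 2]), 0) # tie broken toward lower dosage
  expect_equal(unname(out$geno[5, 3]), 1) # global mode
  # no missing data: identity
  expect_identical(impute_genotypes(out)$geno, out$geno)
})

test_that("recursive feature elimination recovers planted diagnostic sites", {
  sim <- simulate_genotypes(sim_config(
    n_pop_a = 100, n_pop_b = 100, n_sites = 200,
    planted_sites = 2, planted_freqs = c(0, 1),
    divergence = 0.05, missing_rate = 0.005, seed = 11
  ))
  gti <- impute_genotypes(sim$gt)
  panel <- rfe_select(gti, grid = c(1, 2, 5, 10), folds = 5, repeats = 2,
    ntree = 100, seed = 3)
  planted <- sim$site_info$site[sim$site_info$planted]
  expect_setequal(head(panel$selected_sites, 2), planted)
  expect_equal(
    panel$cv_accuracy$mean_accuracy[panel$cv_accuracy$size == 2], 1.0
  )
  # determinism
  panel2 <- rfe_select(gti, grid = c(1, 2, 5, 10), folds = 5, repeats = 2,
    ntree = 100, seed = 3)
  expect_identical(panel$selected_sites, panel2$selected_sites)
  expect_identical(panel$cv_accuracy, panel2$cv_accuracy)
})

test_that("panel validation reaches accuracy 1 on a diagnostic site and chance under a null", {
  sim <- simulate_genotypes(sim_config(
    n_pop_a = 40, n_pop_b = 40, n_sites = 3,
    planted_sites = 1, planted_freqs = c(0, 1),
    divergence = 0, missing_rate = 0, seed = 19
  ))
  gti <- impute_genotypes(sim$gt)
  diag_site <- sim$site_info$site[sim$site_info$planted]
  val <- validate_panel(gti, diag_site, repeats = 20, ntree = 100, seed = 5)
  expect_equal(val$mean_accuracy[val$class == "overall"], 1.0)
  expect_equal(val$sd_accuracy[val$class == "overall"], 0.0)

  # one non-informative site: accuracy near the majority-class prevalence
  sim0 <- simulate_genotypes(sim_config(
    n_pop_a = 60, n_pop_b = 40, n_sites = 3, divergence = 0,
    missing_rate = 0, seed = 23
  ))
  gt0 <- impute_genotypes(sim0$gt)
  val0 <- validate_panel(gt0, gt0$sites[1], repeats = 20, ntree = 100,
    seed = 5)
  prevalence <- 0.6
  expect_lt(
    abs(val0$mean_accuracy[val0$class == "overall"] - prevalence), 0.15
  )
  # reproducible summaries
  val0b <- validate_panel(gt0, gt0$sites[1], repeats = 20, ntree = 100,
    seed = 5)
  expect_identical(val0, val0b)
})

test_that("decision trees split fixed differences once and use both planted sites when needed", {
  # single fixed-difference SNP: one split, two pure leaves
  geno <- cbind(c(rep(0L, 6), rep(2L, 6)), rep(1L, 12))
  gt <- genotype_table(
    paste0("i", 1:12), c("chr1:1", "chr1:2"),
    geno, matrix(10L, 12, 2),
    class_label = rep(c("Africa", "Asia"), each = 6)
  )
  tree <- build_decision_tree(gt, gt$sites, min_leaf = 2)
  expect_equal(sum(!tree$nodes$is_leaf), 1)
  expect_equal(tree$sites_used, "chr1:1")
  leaves <- tree$counts[tree$nodes$is_leaf, ]
  expect_true(all(apply(leaves, 1, function(r) sum(r > 0) == 1)))

  # identical rows with mixed labels collapse to a single majority leaf
  geno_m <- matrix(1L, 6, 1)
  gt_m <- genotype_table(
    paste0("j", 1:6), "chr1:9", geno_m, matrix(10L, 6, 1),
    class_label = c(rep("Africa", 4), rep("Asia", 2))
  )
  tree_m <- build_decision_tree(gt_m, "chr1:9")
  expect_equal(nrow(tree_m$nodes), 1)
  expect_equal(tree_m$nodes$class, "Africa")

  # two near-fixed planted SNPs: tree uses both, training accuracy >= 0.95
  sim <- simulate_genotypes(sim_config(
    n_pop_a = 200, n_pop_b = 200, n_sites = 1,
    planted_sites = 2, planted_freqs = c(0.05, 0.95),
    divergence = 0, missing_rate = 0, seed = 29
  ))
  gti <- impute_genotypes(sim$gt)
  planted <- sim$site_info$site[sim$site_info$planted]
  tree2 <- build_decision_tree(gti, planted, min_leaf = 5)
  expect_setequal(tree2$sites_used, planted)
  calls <- classify_genotype_table(tree2, gti, min_depth = 0)
  expect_gte(mean(calls$origin == gti$class_label), 0.95)

  # cross-check the single-split tree against the reference CART routine
  rp <- rpart::rpart(
    factor(cl) ~ ., data = data.frame(cl = gt$class_label, s1 = geno[, 1]),
    method = "class", minsplit = 2, minbucket = 2, cp = 0
  )
  expect_equal(
    as.character(predict(rp, type = "class")),
    classify_genotype_table(tree, gt, min_depth = 0)$origin
  )
})

test_that("depth masking is exhaustive: any covered site below threshold voids the call", {
  geno <- cbind(c(rep(0L, 4), rep(2L, 4)), c(rep(0L, 4), rep(2L, 4)))
  gt <- genotype_table(
    paste0("i", 1:8), c("chr1:1", "chr1:2"),
    geno, matrix(10L, 8, 2),
    class_label = rep(c("Africa", "Asia"), each = 4)
  )
  # force a 2-site tree by making each site imperfect on one individual
  gt$geno[1, 1] <- 2L
  gt$geno[8, 2] <- 0L
  tree <- build_decision_tree(gt, gt$sites, min_leaf = 1)
  expect_setequal(tree$sites_used, gt$sites)

  masks <- expand.grid(m1 = c(FALSE, TRUE), m2 = c(FALSE, TRUE))
  genos <- expand.grid(g1 = 0:2, g2 = 0:2)
  for (gi in seq_len(nrow(genos))) {
    for (mi in seq_len(nrow(masks))) {
      g <- c("chr1:1" = genos$g1[gi], "chr1:2" = genos$g2[gi])
      d <- c("chr1:1" = ifelse(masks$m1[mi], 5, 10),
             "chr1:2" = ifelse(masks$m2[mi], 5, 10))
      call <- classify_specimen(tree, g, d, min_depth = 6)
      if (any(unlist(masks[mi, ]))) {
        expect_true(is.na(call$origin))
        expect_equal(call$reason, "incomplete_panel")
      } else {
        expect_false(is.na(call$origin))
      }
    }
  }

  # boundary: depth exactly 6 is accepted
  ok <- classify_specimen(tree,
    c("chr1:1" = 0, "chr1:2" = 0), c("chr1:1" = 6, "chr1:2" = 6),
    min_depth = 6
  )
  expect_false(is.na(ok$origin))
  # a missing site voids the call with its own reason
  absent <- classify_specimen(tree, c("chr1:1" = 0), c("chr1:1" = 10))
  expect_equal(absent$reason, "site_absent")
})

test_that("the nuclear panel pipeline reaches 95% holdout accuracy with planted sites", {
  sim <- simulate_genotypes(sim_config(
    n_pop_a = 80, n_pop_b = 80, n_sites = 500,
    planted_sites = 2, planted_freqs = c(0.03, 0.97),
    divergence = 0.05, missing_rate = 0.005, seed = 37
  ))
  gtf <- suppressMessages(
    filter_sites(sim$gt, max_missing = 0.05, min_maf = 0.02,
      depth_range = c(0, Inf))
  )
  gti <- impute_genotypes(gtf)
  set.seed(41)
  hold <- stats::aggregate(seq_along(gti$individuals),
    by = list(gti$class_label), FUN = function(ix) sample(ix, 20))
  hold <- sort(unlist(hold$x))
  train <- setdiff(seq_along(gti$individuals), hold)
  gt_train <- genotype_table(
    gti$individuals[train], gti$sites,
    gti$geno[train, ],
    matrix(10L, length(train), length(gti$sites)),
    class_label = gti$class_label[train]
  )
  panel <- rfe_select(gt_train, grid = c(1, 2, 5), folds = 5, repeats = 1,
    ntree = 100, seed = 3)
  tree <- build_decision_tree(gt_train, head(panel$selected_sites, 2))
  planted <- sim$site_info$site[sim$site_info$planted]
  fst_rank <- order(-abs(
    colMeans(gti$geno[gti$class_label == "Africa", ]) -
      colMeans(gti$geno[gti$class_label == "Asia", ])
  ))
  allowed <- union(planted, gti$sites[head(fst_rank, 10)])
  expect_true(all(tree$sites_used %in% allowed))
  gt_hold <- genotype_table(
    gti$individuals[hold], gti$sites,
    gti$geno[hold, ], matrix(10L, length(hold), length(gti$sites)),
    class_label = gti$class_label[hold]
  )
  calls <- classify_genotype_table(tree, gt_hold, min_depth = 6)
  expect_gte(mean(calls$origin == gt_hold$class_label), 0.95)
})
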