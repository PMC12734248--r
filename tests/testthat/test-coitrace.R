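# shared three-region fixture: two private haplotypes per region plus light
# terminal mutation noise; DAPC-level tests use the true haplotype labels
coi_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_barcodes(haplotype_sim_config(
        regions = c("Africa" = 40, "East Asia" = 40, "South Asia" = 40),
        mutation_rate = 0.003, barcode_length = 400, seed = 3
      ))
      cache <<- list(
        sim = sim,
        am = encode_alignment(sim$aln),
        labels = as.character(sim$truth$haplotype)
      )
    }
    cache
  }
})

test_that("curation rejects stop codons, ambiguity overloads and private gaps", {
  # 12-column frame-1 sequences; TAA at codon 2 is an internal stop
  clean <- "ATGGCAGCTACT"
  ids <- c(sprintf("ok%02d", 1:20), "stopper", "enns", "gapper")
  seqs <- c(
    rep(clean, 20),
    "ATGTAAGCTACT", # internal TAA
    "ATGNNNNNTACT", # 5 ambiguous
    "ATGGCAGC-ACT" # private gap among otherwise gapless
  )
  aln <- barcode_alignment(ids, seqs)
  cur <- curate_alignment(aln, max_ambiguous = 3, gap_consistency = 0.1,
    frame = 1)
  expect_equal(sort(cur$rejected$id), c("enns", "gapper", "stopper"))
  expect_equal(
    cur$rejected$reason[cur$rejected$id == "stopper"], "stop_codon"
  )
  expect_equal(
    cur$rejected$reason[cur$rejected$id == "enns"], "too_many_ambiguities"
  )
  expect_equal(
    cur$rejected$reason[cur$rejected$id == "gapper"], "inconsistent_gap"
  )
  expect_equal(length(cur$alignment$ids), 20)

  # clean alignment: identity, no rejections
  aln2 <- barcode_alignment(ids[1:20], seqs[1:20])
  cur2 <- curate_alignment(aln2, frame = 1)
  expect_equal(nrow(cur2$rejected), 0)
  expect_identical(cur2$alignment$seqs, aln2$seqs)

  # frame inference from a reference row; no frame and no reference errors
  expect_error(curate_alignment(aln), "frame")
  cur3 <- curate_alignment(aln, ref_id = "ok01", max_ambiguous = 3,
    gap_consistency = 0.1)
  expect_equal(cur3$frame, 1L)
})

test_that("region excision counts non-gap reference positions and keeps in-window gaps", {
  ids <- c("ref", "q1")
  seqs <- c(
    "AC-GTAC--GTACGT",
    "ACTGTACGTGTACGT"
  )
  aln <- barcode_alignment(ids, seqs)
  # gapless window: ref positions 1..2 -> columns 1..2
  out <- excise_region(aln, "ref", ref_start = 1, ref_len = 2)
  expect_equal(out$columns, 2)
  # window covering ref positions 1..10 spans 3 reference gap columns
  out2 <- excise_region(aln, "ref", ref_start = 1, ref_len = 10)
  expect_equal(out2$columns, 13)
  expect_error(excise_region(aln, "ref", ref_start = 1, ref_len = 13), "exceeds")
  expect_error(excise_region(aln, "nope", 1, 2), "not found")
})

test_that("one-hot encoding matches the hand-worked example and flags missing", {
  aln <- barcode_alignment(c("s1", "s2", "s3"), c("ACG", "AAG", "ACG"))
  am <- encode_alignment(aln)
  expect_equal(am$columns, c("2.C", "2.A")) # major allele first
  expect_equal(unname(am$x), matrix(c(1, 0, 1, 0, 1, 0), nrow = 3))

  alnN <- barcode_alignment(c("s1", "s2", "s3"), c("ACG", "AAG", "ANG"))
  amN <- encode_alignment(alnN)
  expect_true(all(is.na(amN$x["s3", ])))

  expect_error(
    encode_alignment(barcode_alignment(c("a", "b"), c("ACG", "ACG"))),
    "polymorphic"
  )
})

test_that("cluster number selection recovers planted structure and is seed-stable", {
  # six well-separated pools (no terminal mutation): exact recovery
  sim <- simulate_barcodes(haplotype_sim_config(
    regions = c("Africa" = 40, "East Asia" = 40, "South Asia" = 40),
    mutation_rate = 0, barcode_length = 400, seed = 3
  ))
  am <- encode_alignment(sim$aln)
  cl <- find_clusters(am, k_max = 15, seed = 1)
  expect_equal(cl$chosen_k, 6) # two planted haplotypes per region
  expect_equal(adjusted_rand_index(cl$labels, sim$truth$haplotype), 1)
  cl2 <- find_clusters(am, k_max = 15, seed = 1)
  expect_identical(cl$labels, cl2$labels)

  # single homogeneous cloud
  sim1 <- simulate_barcodes(haplotype_sim_config(
    regions = c("Africa" = 40), haplotype_pools = list("Africa" = 1),
    mutation_rate = 0.01, barcode_length = 300, seed = 6
  ))
  cl1 <- find_clusters(encode_alignment(sim1$aln), k_max = 10, seed = 1)
  expect_equal(cl1$chosen_k, 1)
  expect_error(find_clusters(am, k_max = 1000), "k_max")
})

test_that("cross-validated PC selection is exact on separable clusters and reproducible", {
  # perfectly separable pools: accuracy 1 everywhere, fewest PCs win
  sim <- simulate_barcodes(haplotype_sim_config(
    regions = c("Africa" = 30, "East Asia" = 30),
    haplotype_pools = list("Africa" = c(1, 0), "East Asia" = c(0, 1)),
    mutation_rate = 0, barcode_length = 300, seed = 15
  ))
  am <- encode_alignment(sim$aln)
  lab <- sim$truth$haplotype
  xv <- suppressWarnings(
    xval_pc_selection(am, lab, pc_grid = c(1, 2, 5), reps = 5, seed = 2)
  )
  expect_true(all(xv$xval_table$mean_accuracy == 1))
  expect_equal(xv$best_n_pcs, 1) # ties break toward fewer PCs

  fx <- coi_fixture()
  xv1 <- xval_pc_selection(fx$am, fx$labels, pc_grid = c(5, 10, 20),
    reps = 5, seed = 2)
  xv2 <- xval_pc_selection(fx$am, fx$labels, pc_grid = c(5, 10, 20),
    reps = 5, seed = 2)
  expect_identical(xv1$xval_table, xv2$xval_table)
  expect_gte(max(xv1$xval_table$mean_accuracy), 0.95)
})

test_that("permuted labels drive cross-validated accuracy to the prevalence floor", {
  fx <- coi_fixture()
  set.seed(99)
  perm <- sample(fx$labels)
  xvp <- xval_pc_selection(fx$am, perm, pc_grid = c(5, 10), reps = 8, seed = 3)
  prevalence <- max(table(perm)) / length(perm)
  expect_lt(abs(mean(xvp$xval_table$mean_accuracy) - prevalence), 0.15)
})

test_that("DAPC respects the k-1 axis contract and matches an LDA-on-PCs oracle", {
  fx <- coi_fixture()
  # two clusters -> exactly one axis
  two <- as.integer(fx$labels %in% c("1", "2", "3"))
  fit2 <- fit_dapc(fx$am, two, n_pcs = 10)
  expect_equal(fit2$n_da, 1L)
  expect_equal(ncol(fit2$da_axes), 1)

  # 60 x 30 instance: assignments equal classical LDA on the PC scores
  rows <- 1:60
  am60 <- subset_allele_matrix(fx$am, rows)
  lab60 <- fx$labels[rows]
  fit <- fit_dapc(am60, lab60, n_pcs = 30)
  pred <- assign_barcode(fit, am60)
  imp <- am60$x
  for (j in seq_len(ncol(imp))) {
    imp[is.na(imp[, j]), j] <- mean(imp[, j], na.rm = TRUE)
  }
  sc <- prcomp(scale(imp, center = TRUE, scale = FALSE),
    center = FALSE)$x[, seq_len(fit$n_pcs)]
  oracle <- MASS::lda(sc, grouping = factor(lab60))
  expect_equal(
    pred$cluster,
    as.character(predict(oracle, sc)$class)
  )
  expect_equal(fit$self_assignment, 1.0)

  # training points duplicated at their centroids self-assign perfectly
  dup <- barcode_alignment(
    paste0("d", 1:12),
    rep(c("AAAA", "TTTT", "AATT"), each = 4)
  )
  am_dup <- encode_alignment(dup)
  fit_dup <- suppressWarnings(
    fit_dapc(am_dup, rep(c("x", "y", "z"), each = 4), n_pcs = 2)
  )
  expect_equal(fit_dup$self_assignment, 1.0)
})

test_that("assignment posteriors normalize, symmetrize and honour the overlap floor", {
  fx <- coi_fixture()
  fit <- fit_dapc(fx$am, fx$labels, n_pcs = 10)
  pred <- assign_barcode(fit, fx$am)
  post <- attr(pred, "posteriors")
  expect_lt(max(abs(rowSums(post) - 1)), 1e-9)

  # column permutation of the query leaves the argmax unchanged
  perm <- sample(seq_along(fx$am$columns))
  qperm <- fx$am
  qperm$x <- fx$am$x[, perm]
  qperm$columns <- fx$am$columns[perm]
  qperm$column_means <- fx$am$column_means[perm]
  pred_p <- assign_barcode(fit, qperm)
  expect_identical(pred$cluster, pred_p$cluster)

  # symmetric two-cluster geometry: equidistant query gets (0.5, 0.5)
  aln <- barcode_alignment(
    c(sprintf("a%d", 1:4), sprintf("b%d", 1:4), "mid"),
    c(rep("AAAA", 4), rep("TTTT", 4), "AATT")
  )
  am <- encode_alignment(aln)
  fit_s <- suppressWarnings(
    fit_dapc(subset_allele_matrix(am, 1:8), rep(1:2, each = 4), n_pcs = 2)
  )
  pm <- attr(assign_barcode(fit_s, subset_allele_matrix(am, 9)), "posteriors")
  expect_equal(unname(pm[1, ]), c(0.5, 0.5), tolerance = 1e-6)

  # a query with almost no shared observed columns is declined
  sparse <- subset_allele_matrix(fx$am, 1)
  sparse$x[1, ] <- NA
  sparse$x[1, 1] <- fx$am$x[1, 1]
  dec <- assign_barcode(fit, sparse)
  expect_true(is.na(dec$cluster))
  expect_equal(dec$reason, "insufficient_overlap")
})

test_that("regional profiles normalize sampling effort as in the 0.9/0.01 worked example", {
  # cluster X holds 9/10 of region A's samples and 1/100 of region B's
  labels <- c(rep("X", 9), "Y", rep("X", 1), rep("Y", 99))
  regions <- c(rep("Africa", 10), rep("East Asia", 100))
  prof <- region_profile(labels, regions)
  expect_equal(
    unname(prof$normalized["X", ]),
    c(0.9 / 0.91, 0.01 / 0.91),
    tolerance = 1e-9
  )
  expect_lt(max(abs(rowSums(prof$normalized) - 1)), 1e-9)
  expect_equal(unname(prof$n_known["X"]), 10)

  # Unknown regions are excluded from the totals
  prof2 <- region_profile(
    c(labels, "X"), c(regions, "Unknown")
  )
  expect_equal(prof2$region_totals, prof$region_totals)
})

test_that("cluster origins honour dominance, ambiguity ordering and the Mascarene mapping", {
  prof <- region_profile(
    labels = c(rep("1", 19), "2"),
    regions = c(rep("Africa", 19), "Mascarenes")
  )
  # cluster dominated by Africa
  expect_equal(cluster_origin(prof, "1"), "Africa")
  # pure Mascarene cluster maps to Asia
  expect_equal(cluster_origin(prof, "2"), "Asia")

  # mixed profile below the dominance threshold -> ordered ambiguity,
  # shares under the minor floor omitted
  mixed <- prof
  mixed$normalized <- matrix(
    c(0.26, 0.70, 0.04), nrow = 1,
    dimnames = list("m", c("Africa", "South Asia", "Pacific"))
  )
  mixed$origin_map <- DEFAULT_ORIGIN_MAP
  expect_equal(cluster_origin(mixed, "m"), "ambiguous:Asia,Africa")
})

test_that("the full barcode pipeline assigns held-out queries to their true origin", {
  sim <- simulate_barcodes(haplotype_sim_config(
    regions = c("Africa" = 45, "East Asia" = 45, "South Asia" = 45),
    mutation_rate = 0.003, barcode_length = 400, seed = 31
  ))
  am <- encode_alignment(sim$aln)
  set.seed(7)
  hold <- unlist(lapply(split(seq_along(am$ids), sim$truth$mito_region),
    sample, size = 5))
  train <- setdiff(seq_along(am$ids), hold)
  am_tr <- subset_allele_matrix(am, train)
  cl <- find_clusters(am_tr, k_max = 12, seed = 1)
  xv <- suppressWarnings(
    xval_pc_selection(am_tr, cl$labels, pc_grid = c(5, 10, 20),
      reps = 5, seed = 2)
  )
  fit <- suppressWarnings(fit_dapc(am_tr, cl$labels, n_pcs = xv$best_n_pcs))
  prof <- region_profile(cl$labels, am_tr$region)
  calls <- coi_origin_calls(fit, subset_allele_matrix(am, hold), prof)
  truth <- DEFAULT_ORIGIN_MAP[sim$truth$mito_region[hold]]
  expect_gte(mean(calls$origin == truth), 0.95)
})

test_that("planted mitonuclear discordance surfaces as conflicting origin calls", {
  rate <- 0.12
  sim <- simulate_barcodes(haplotype_sim_config(
    regions = c("Africa" = 100, "East Asia" = 100),
    mutation_rate = 0.003, barcode_length = 300,
    discordance_rate = rate, seed = 41
  ))
  am <- encode_alignment(sim$aln)
  cl <- find_clusters(am, k_max = 10, seed = 1)
  fit <- suppressWarnings(fit_dapc(am, cl$labels, n_pcs = 5))
  prof <- region_profile(cl$labels, am$region)
  calls <- coi_origin_calls(fit, am, prof)
  nuclear_origin <- DEFAULT_ORIGIN_MAP[sim$truth$nuclear_region]
  conflict <- mean(calls$origin != nuclear_origin)
  planted <- mean(sim$truth$discordant)
  expect_lt(abs(conflict - planted), 0.05)
  expect_gt(conflict, 0.02)
})
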