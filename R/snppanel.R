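## Diagnostic nuclear-SNP panel discovery: site filtering, deterministic
## imputation, recursive feature elimination with a random-forest learner,
## repeated holdout validation, decision-tree distillation, and
## depth-masked classification of query specimens.

#' Filter genotype-table sites on missingness, MAF and mean depth
#'
#' Keeps sites with a missing fraction at most `max_missing`, a minor
#' allele frequency strictly above `min_maf` (computed from non-missing
#' genotypes), and a mean depth inside the closed interval `depth_range`.
#' Site order is preserved; the counts removed per criterion are logged.
#'
#' @param gt A [genotype_table()].
#' @param max_missing Maximum tolerated missing fraction per site.
#' @param min_maf Minor-allele-frequency threshold (exclusive).
#' @param depth_range Closed interval for the per-site mean depth.
#' @return The filtered [genotype_table()].
#' @export
filter_sites <- function(gt, max_missing = 0.01, min_maf = 0.05,
                         depth_range = c(8, 12)) {
  stopifnot(inherits(gt, "genotype_table"))
  stopifnot(length(depth_range) == 2, depth_range[1] <= depth_range[2])
  miss <- colMeans(is.na(gt$geno))
  af <- colMeans(gt$geno, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0 # all-missing site: fails MAF too
  mean_depth <- colMeans(gt$depth)
  ok_miss <- miss <= max_missing
  ok_maf <- maf > min_maf
  ok_depth <- mean_depth >= depth_range[1] & mean_depth <= depth_range[2]
  keep <- ok_miss & ok_maf & ok_depth
  message(sprintf(
    "filter_sites: removed %d (missingness), %d (MAF), %d (depth); %d of %d kept",
    sum(!ok_miss), sum(!ok_maf), sum(!ok_depth), sum(keep), length(keep)
  ))
  if (!any(keep)) stop("all sites removed by filtering")
  genotype_table(
    individuals = gt$individuals,
    sites = gt$sites[keep],
    geno = gt$geno[, keep, drop = FALSE],
    depth = gt$depth[, keep, drop = FALSE],
    class_label = gt$class_label,
    ref = gt$ref[gt$sites[keep]],
    alt = gt$alt[gt$sites[keep]]
  )
}

# modal genotype with ties broken toward the lower dosage
modal_genotype <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    return(NA_integer_)
  }
  tab <- table(factor(v, levels = 0:2))
  as.integer(names(tab)[which.max(tab)]) # which.max: first max => lower dosage
}

#' Impute missing genotypes by the within-class modal genotype
#'
#' Deterministic class-conditional mode imputation: each missing genotype
#' is replaced by the modal genotype of its individual's class at that
#' site, with ties broken toward the lower dosage. Sites at which a class
#' is entirely missing fall back to the global mode; individuals without a
#' class label are imputed from the global mode with a warning.
#'
#' @param gt A [genotype_table()] with `class_label`.
#' @return A [genotype_table()] without missing genotypes (depths
#'   unchanged).
#' @export
impute_genotypes <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  geno <- gt$geno
  if (!anyNA(geno)) {
    return(gt)
  }
  labels <- gt$class_label
  if (is.null(labels)) labels <- rep(NA_character_, length(gt$individuals))
  if (any(is.na(labels)) && anyNA(geno[is.na(labels), , drop = FALSE])) {
    warning("individual(s) without class label imputed from the global mode")
  }
  global_mode <- apply(geno, 2, modal_genotype)
  for (g in unique(labels[!is.na(labels)])) {
    rows <- which(labels == g)
    sub <- geno[rows, , drop = FALSE]
    if (!anyNA(sub)) next
    mode_g <- apply(sub, 2, modal_genotype)
    mode_g[is.na(mode_g)] <- global_mode[is.na(mode_g)]
    for (j in which(colSums(is.na(sub)) > 0)) {
      sub[is.na(sub[, j]), j] <- mode_g[j]
    }
    geno[rows, ] <- sub
  }
  rows <- which(is.na(labels))
  if (length(rows) > 0) {
    sub <- geno[rows, , drop = FALSE]
    for (j in which(colSums(is.na(sub)) > 0)) {
      sub[is.na(sub[, j]), j] <- global_mode[j]
    }
    geno[rows, ] <- sub
  }
  out <- gt
  out$geno <- geno
  out
}

# stratified index sample: frac of each class (at least 1, at least 1 left)
stratified_holdout <- function(labels, frac) {
  idx <- integer(0)
  for (g in unique(labels)) {
    rows <- which(labels == g)
    n_h <- max(1, round(frac * length(rows)))
    n_h <- min(n_h, length(rows) - 1)
    idx <- c(idx, sample(rows, n_h))
  }
  sort(idx)
}

rf_fit <- function(x, y, ntree) {
  randomForest::randomForest(
    x = as.data.frame(x), y = factor(y),
    ntree = ntree, importance = FALSE
  )
}

rf_importance_order <- function(fit) {
  imp <- fit$importance[, "MeanDecreaseGini"]
  names(sort(imp, decreasing = TRUE))
}

#' Select a diagnostic SNP panel by recursive feature elimination
#'
#' A stratified 30% holdout is set aside for internal validation; on the
#' remaining training data, repeated stratified k-fold cross-validation
#' evaluates candidate panel sizes: within each resample a random forest is
#' fitted on all sites, sites are ranked by mean decrease in Gini impurity,
#' and a forest refitted on the top-`s` sites is scored on the held-out
#' fold for each panel size `s` in `grid`. The final site ranking comes
#' from a forest on the full training set. The best panel size maximizes
#' mean cross-validated accuracy (ties toward the smaller panel) and its
#' holdout accuracy is reported.
#'
#' @param gt A complete (no missing genotypes) [genotype_table()] with
#'   `class_label`.
#' @param grid Candidate panel sizes (the classic grid up to 200 sites by
#'   default); values exceeding the available site count are skipped with
#'   a warning.
#' @param folds Number of cross-validation folds.
#' @param repeats Number of cross-validation repeats.
#' @param holdout Fraction held out for internal validation.
#' @param ntree Trees per random forest.
#' @param seed Integer seed; fixed seeds give identical rankings.
#' @return An object of class `snp_panel` with `selected_sites` (ordered by
#'   importance), `panel_size_grid`, `cv_accuracy` (data.frame: size, mean,
#'   sd), `best_size`, `holdout_accuracy`, `ref`/`alt` polarity of the
#'   selected sites and `min_depth` (default 6; used at classification).
#' @export
rfe_select <- function(gt, grid = c(1, 2, 5, 10, 15, 20, 50, 80, 100, 150, 200),
                       folds = 10, repeats = 10, holdout = 0.30,
                       ntree = 500, seed = 1L) {
  stopifnot(inherits(gt, "genotype_table"))
  if (is.null(gt$class_label)) stop("class labels are required")
  if (anyNA(gt$geno)) stop("genotype table must be complete; run impute_genotypes()")
  labels <- gt$class_label
  classes <- unique(labels)
  if (length(classes) < 2) stop("need at least 2 classes")
  if (any(table(labels) < folds)) {
    stop("every class needs at least `folds` members")
  }
  m <- length(gt$sites)
  grid <- sort(unique(as.integer(grid)))
  usable <- grid[grid <= m]
  if (length(usable) < length(grid)) {
    warning("panel size(s) larger than the available ", m, " sites skipped")
  }
  grid <- usable
  if (length(grid) == 0) stop("no usable panel sizes in grid")

  set.seed(seed)
  hold_idx <- stratified_holdout(labels, holdout)
  train_idx <- setdiff(seq_along(labels), hold_idx)
  xtr <- gt$geno[train_idx, , drop = FALSE]
  ytr <- labels[train_idx]

  acc <- array(NA_real_, dim = c(repeats, folds, length(grid)))
  for (r in seq_len(repeats)) {
    # stratified fold assignment
    fold_of <- integer(length(ytr))
    for (g in classes) {
      rows <- which(ytr == g)
      fold_of[rows] <- sample(rep(seq_len(folds), length.out = length(rows)))
    }
    for (f in seq_len(folds)) {
      in_fold <- fold_of == f
      fit_all <- rf_fit(xtr[!in_fold, , drop = FALSE], ytr[!in_fold], ntree)
      ranking <- rf_importance_order(fit_all)
      for (s in seq_along(grid)) {
        top <- ranking[seq_len(grid[s])]
        fit_s <- rf_fit(xtr[!in_fold, top, drop = FALSE], ytr[!in_fold], ntree)
        pred <- predict(fit_s, as.data.frame(xtr[in_fold, top, drop = FALSE]))
        acc[r, f, s] <- mean(pred == ytr[in_fold])
      }
    }
  }
  cv <- data.frame(
    size = grid,
    mean_accuracy = apply(acc, 3, mean),
    sd_accuracy = apply(acc, 3, sd)
  )
  best_size <- grid[which.max(cv$mean_accuracy)]

  fit_final <- rf_fit(xtr, ytr, ntree)
  ranking <- rf_importance_order(fit_final)
  selected <- ranking[seq_len(min(max(grid), m))]

  top_best <- ranking[seq_len(best_size)]
  fit_best <- rf_fit(xtr[, top_best, drop = FALSE], ytr, ntree)
  pred_hold <- predict(
    fit_best,
    as.data.frame(gt$geno[hold_idx, top_best, drop = FALSE])
  )
  holdout_acc <- mean(pred_hold == labels[hold_idx])

  structure(
    list(
      selected_sites = selected,
      panel_size_grid = grid,
      cv_accuracy = cv,
      best_size = best_size,
      holdout_accuracy = holdout_acc,
      ref = gt$ref[selected],
      alt = gt$alt[selected],
      tree = NULL,
      validation = NULL,
      min_depth = 6L
    ),
    class = "snp_panel"
  )
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf(
    "snp_panel: %d ranked sites, best size %d (cv accuracy %.4f)\n",
    length(x$selected_sites), x$best_size,
    x$cv_accuracy$mean_accuracy[x$cv_accuracy$size == x$best_size]
  ))
  if (!is.null(x$tree)) {
    cat(sprintf("decision tree over %d site(s)\n", length(x$tree$sites_used)))
  }
  invisible(x)
}

#' Repeated-holdout validation of a SNP panel
#'
#' For each repeat a stratified split withholds `holdout` of the data, a
#' random forest is retrained on the panel sites only, and per-class plus
#' overall holdout accuracy is recorded; means and SDs over repeats are
#' returned.
#'
#' @param gt A complete labelled [genotype_table()].
#' @param sites Panel site ids.
#' @param repeats Number of random validation subsets.
#' @param holdout Withheld fraction per repeat.
#' @param ntree Trees per forest.
#' @param seed Integer seed.
#' @return A data.frame with one row per class plus `"overall"`, columns
#'   `class`, `mean_accuracy`, `sd_accuracy`.
#' @export
validate_panel <- function(gt, sites, repeats = 100, holdout = 0.25,
                           ntree = 500, seed = 1L) {
  stopifnot(inherits(gt, "genotype_table"))
  if (is.null(gt$class_label)) stop("class labels are required")
  missing_sites <- setdiff(sites, gt$sites)
  if (length(missing_sites) > 0) {
    stop("site(s) absent from table: ", paste(missing_sites, collapse = ", "))
  }
  labels <- gt$class_label
  classes <- sort(unique(labels))
  x <- gt$geno[, sites, drop = FALSE]
  set.seed(seed)
  acc <- matrix(NA_real_, nrow = repeats, ncol = length(classes) + 1,
    dimnames = list(NULL, c(classes, "overall"))
  )
  for (r in seq_len(repeats)) {
    hold <- stratified_holdout(labels, holdout)
    train <- setdiff(seq_along(labels), hold)
    fit <- rf_fit(x[train, , drop = FALSE], labels[train], ntree)
    pred <- predict(fit, as.data.frame(x[hold, , drop = FALSE]))
    truth <- labels[hold]
    for (g in classes) {
      acc[r, g] <- mean(pred[truth == g] == g)
    }
    acc[r, "overall"] <- mean(pred == truth)
  }
  data.frame(
    class = colnames(acc),
    mean_accuracy = colMeans(acc),
    sd_accuracy = apply(acc, 2, sd),
    row.names = NULL
  )
}

## ---------------------------------------------------------------------------
## CART decision tree over allele dosages
## ---------------------------------------------------------------------------

gini_impurity <- function(labels) {
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

#' Distill a SNP panel into a CART decision tree
#'
#' Classification tree with Gini impurity over alternate-allele counts.
#' Because dosages are integers in {0, 1, 2}, candidate splits are
#' restricted to `dosage < 0.5` and `dosage < 1.5` (any other threshold is
#' equivalent to one of these). Nodes are split until pure or smaller than
#' `min_leaf`; leaves store the majority class and the full class counts.
#'
#' @param gt A complete labelled [genotype_table()].
#' @param sites Candidate split sites (the selected panel).
#' @param min_leaf Minimum node size still considered for splitting.
#' @return An object of class `snp_tree`: `nodes` (data.frame with `id`,
#'   `site`, `threshold`, `left`, `right`, `is_leaf`, `class`, `n`),
#'   `counts` (node x class matrix), `classes` and `sites_used` (split
#'   sites actually appearing in the tree).
#' @export
build_decision_tree <- function(gt, sites, min_leaf = 5) {
  stopifnot(inherits(gt, "genotype_table"))
  if (is.null(gt$class_label)) stop("class labels are required")
  missing_sites <- setdiff(sites, gt$sites)
  if (length(missing_sites) > 0) {
    stop("site(s) absent from table: ", paste(missing_sites, collapse = ", "))
  }
  x <- gt$geno[, sites, drop = FALSE]
  if (anyNA(x)) stop("genotypes must be complete; run impute_genotypes()")
  y <- gt$class_label
  classes <- sort(unique(y))

  nodes <- list()
  counts <- list()
  new_node <- function(rows) {
    id <- length(nodes) + 1L
    cnt <- table(factor(y[rows], levels = classes))
    cls <- names(cnt)[which.max(cnt)]
    nodes[[id]] <<- list(
      id = id, site = NA_character_, threshold = NA_real_,
      left = NA_integer_, right = NA_integer_, is_leaf = TRUE,
      class = cls, n = length(rows)
    )
    counts[[id]] <<- as.integer(cnt)
    id
  }
  grow <- function(rows, id) {
    labs <- y[rows]
    if (length(unique(labs)) == 1 || length(rows) < min_leaf) {
      return(invisible(NULL))
    }
    parent_gini <- gini_impurity(labs)
    best <- NULL
    for (s in sites) {
      for (t in c(0.5, 1.5)) {
        left <- rows[x[rows, s] < t]
        right <- rows[x[rows, s] >= t]
        if (length(left) == 0 || length(right) == 0) next
        g <- (length(left) * gini_impurity(y[left]) +
          length(right) * gini_impurity(y[right])) / length(rows)
        gain <- parent_gini - g
        if (gain > 1e-12 && (is.null(best) || gain > best$gain + 1e-12)) {
          best <- list(site = s, threshold = t, gain = gain,
                       left = left, right = right)
        }
      }
    }
    if (is.null(best)) {
      return(invisible(NULL))
    }
    lid <- new_node(best$left)
    rid <- new_node(best$right)
    nodes[[id]]$site <<- best$site
    nodes[[id]]$threshold <<- best$threshold
    nodes[[id]]$left <<- lid
    nodes[[id]]$right <<- rid
    nodes[[id]]$is_leaf <<- FALSE
    grow(best$left, lid)
    grow(best$right, rid)
  }
  root <- new_node(seq_along(y))
  grow(seq_along(y), root)

  nd <- do.call(rbind, lapply(nodes, function(n) {
    data.frame(
      id = n$id, site = n$site, threshold = n$threshold,
      left = n$left, right = n$right, is_leaf = n$is_leaf,
      class = n$class, n = n$n, stringsAsFactors = FALSE
    )
  }))
  cm <- do.call(rbind, counts)
  colnames(cm) <- classes
  structure(
    list(
      nodes = nd, counts = cm, classes = classes,
      sites_used = unique(nd$site[!nd$is_leaf])
    ),
    class = "snp_tree"
  )
}

#' @export
print.snp_tree <- function(x, ...) {
  cat(sprintf(
    "snp_tree: %d nodes, split sites: %s\n",
    nrow(x$nodes), paste(x$sites_used, collapse = ", ")
  ))
  invisible(x)
}

#' Classify a specimen with a SNP decision tree under a depth mask
#'
#' Conservative classification: if any site used by the tree is absent
#' from the query the call is `NA` with reason `"site_absent"`; if any
#' tree-used site has read depth below `min_depth` (exclusive; depth equal
#' to `min_depth` is accepted) or a missing genotype, the call is `NA`
#' with reason `"incomplete_panel"`. Otherwise the tree is traversed and
#' the leaf's majority class returned, with the leaf class fraction as the
#' probability.
#'
#' @param tree An `snp_tree`.
#' @param geno Named dosage vector (alternate-allele counts) for the query.
#' @param depth Named read-depth vector for the query.
#' @param min_depth Minimum accepted depth at every tree site (default 6).
#' @param id Specimen identifier for the returned record.
#' @return A one-row data.frame: `id`, `method` (`"SNPs"`), `origin`,
#'   `posterior` (leaf class fraction), `reason`.
#' @export
classify_specimen <- function(tree, geno, depth, min_depth = 6,
                              id = "query") {
  stopifnot(inherits(tree, "snp_tree"))
  used <- tree$sites_used
  na_call <- function(reason) {
    data.frame(
      id = id, method = "SNPs", origin = NA_character_,
      posterior = NA_real_, reason = reason, stringsAsFactors = FALSE
    )
  }
  if (length(used) > 0) {
    if (!all(used %in% names(geno)) || !all(used %in% names(depth))) {
      return(na_call("site_absent"))
    }
    if (any(depth[used] < min_depth) || anyNA(geno[used])) {
      return(na_call("incomplete_panel"))
    }
  }
  node <- 1L
  while (!tree$nodes$is_leaf[node]) {
    s <- tree$nodes$site[node]
    node <- if (geno[[s]] < tree$nodes$threshold[node]) {
      tree$nodes$left[node]
    } else {
      tree$nodes$right[node]
    }
  }
  cnt <- tree$counts[node, ]
  data.frame(
    id = id, method = "SNPs", origin = tree$nodes$class[node],
    posterior = unname(cnt[tree$nodes$class[node]] / sum(cnt)),
    reason = NA_character_, stringsAsFactors = FALSE
  )
}

#' Classify every individual of a genotype table with a SNP tree
#'
#' @param tree An `snp_tree`.
#' @param gt A [genotype_table()] carrying the query genotypes and depths.
#' @param min_depth Minimum accepted depth at every tree site.
#' @return A data.frame with one [classify_specimen()] record per
#'   individual.
#' @export
classify_genotype_table <- function(tree, gt, min_depth = 6) {
  stopifnot(inherits(gt, "genotype_table"))
  do.call(rbind, lapply(seq_along(gt$individuals), function(i) {
    classify_specimen(
      tree,
      setNames(gt$geno[i, ], gt$sites),
      setNames(gt$depth[i, ], gt$sites),
      min_depth = min_depth,
      id = gt$individuals[i]
    )
  }))
}

## ---------------------------------------------------------------------------
## Panel JSON serialization
## ---------------------------------------------------------------------------

#' Save a SNP panel (ranking, tree, validation) as JSON
#'
#' @param panel An `snp_panel`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_snp_panel <- function(panel, path) {
  stopifnot(inherits(panel, "snp_panel"))
  payload <- list(
    version = FLYTRACE_MODEL_VERSION,
    kind = "snp_panel",
    panel = unclass(panel)
  )
  if (!is.null(panel$tree)) {
    payload$panel$tree <- unclass(panel$tree)
  }
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' Load a SNP panel saved with [save_snp_panel()]
#'
#' @param path Path to the panel JSON.
#' @return An `snp_panel` (with its `snp_tree`, when present).
#' @export
read_snp_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$version, FLYTRACE_MODEL_VERSION)) {
    stop("unsupported panel version: ", payload$version)
  }
  p <- payload$panel
  p$ref <- setNames(unlist(p$ref), p$selected_sites)
  p$alt <- setNames(unlist(p$alt), p$selected_sites)
  if (!is.null(p$tree)) {
    tr <- p$tree
    tr$counts <- matrix(as.matrix(tr$counts),
      ncol = length(tr$classes),
      dimnames = list(NULL, tr$classes)
    )
    class(tr) <- "snp_tree"
    p$tree <- tr
  }
  class(p) <- "snp_panel"
  p
}
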