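## COI-barcode origin tracing: curation, one-hot encoding, unsupervised
## haplotype clustering (PCA + k-means + BIC), cross-validated DAPC,
## posterior assignment, and normalized regional profiles per cluster.

# Stop codons of the invertebrate mitochondrial genetic code. TGA encodes
# tryptophan and AGA/AGG encode serine in this code, so only TAA/TAG stop.
INVERT_MITO_STOPS <- c("TAA", "TAG")

count_internal_stops <- function(seq_nogap, frame) {
  s <- substring(seq_nogap, frame)
  n_codon <- nchar(s) %/% 3
  if (n_codon < 2) {
    return(0L)
  }
  starts <- seq(1, by = 3, length.out = n_codon - 1) # exclude final codon
  codons <- substring(s, starts, starts + 2)
  sum(codons %in% INVERT_MITO_STOPS)
}

#' Curate a barcode alignment
#'
#' Automated proxies for manual alignment curation: sequences are rejected
#' when they (a) contain an internal stop codon under the invertebrate
#' mitochondrial code in the stated reading frame, (b) carry more than
#' `max_ambiguous` ambiguity characters (`N` or any IUPAC ambiguity code),
#' or (c) possess a gap at an alignment column where fewer than
#' `gap_consistency` of all sequences are gapped (a "private",
#' inconsistent gap).
#'
#' @param aln A [barcode_alignment()] with at least 3 columns.
#' @param max_ambiguous Maximum tolerated ambiguity characters per
#'   sequence.
#' @param gap_consistency Minimum fraction of gapped sequences for a gap
#'   column to be considered consistent.
#' @param frame Reading frame (1, 2 or 3) of the first alignment column;
#'   when `NULL` it is inferred from `ref_id` as the frame minimizing
#'   internal stops in that reference sequence.
#' @param ref_id Reference row used for frame inference.
#' @return A list with `alignment` (the curated [barcode_alignment()]),
#'   `rejected` (data.frame of id and reason) and `frame` (the frame used).
#' @export
curate_alignment <- function(aln, max_ambiguous = 10, gap_consistency = 0.05,
                             frame = NULL, ref_id = NULL) {
  stopifnot(inherits(aln, "barcode_alignment"))
  if (aln$columns < 3) stop("alignment must have at least 3 columns")
  if (is.null(frame)) {
    if (is.null(ref_id)) {
      stop("either a reading frame or a reference row (ref_id) is required")
    }
    ri <- match(ref_id, aln$ids)
    if (is.na(ri)) stop("reference id not found: ", ref_id)
    ref_nogap <- gsub("-", "", aln$seqs[ri], fixed = TRUE)
    stops <- vapply(1:3, function(f) count_internal_stops(ref_nogap, f), integer(1))
    frame <- which.min(stops)
  }
  stopifnot(frame %in% 1:3)

  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  gap_frac <- colMeans(mat == "-")
  inconsistent_col <- gap_frac > 0 & gap_frac < gap_consistency

  reasons <- rep(NA_character_, length(aln$ids))
  for (i in seq_along(aln$ids)) {
    nogap <- gsub("-", "", aln$seqs[i], fixed = TRUE)
    if (count_internal_stops(nogap, frame) > 0) {
      reasons[i] <- "stop_codon"
      next
    }
    n_amb <- sum(!strsplit(aln$seqs[i], "")[[1]] %in% c("A", "C", "G", "T", "-"))
    if (n_amb > max_ambiguous) {
      reasons[i] <- "too_many_ambiguities"
      next
    }
    if (any(mat[i, ] == "-" & inconsistent_col)) {
      reasons[i] <- "inconsistent_gap"
    }
  }
  keep <- is.na(reasons)
  list(
    alignment = barcode_alignment(
      aln$ids[keep], aln$seqs[keep], aln$region[keep]
    ),
    rejected = data.frame(
      id = aln$ids[!keep], reason = reasons[!keep],
      stringsAsFactors = FALSE
    ),
    frame = as.integer(frame)
  )
}

#' Excise the barcode region spanned by a reference row
#'
#' Keeps the alignment columns spanned by positions
#' `[ref_start, ref_start + ref_len - 1]` of the reference sequence,
#' counting its non-gap characters. Gap columns of the reference inside the
#' window are retained, so the output width can exceed `ref_len`.
#'
#' @param aln A [barcode_alignment()].
#' @param ref_id Identifier of the reference row.
#' @param ref_start 1-based start position on the ungapped reference.
#' @param ref_len Window length on the ungapped reference (default 658, the
#'   classic barcode fragment length).
#' @return The excised [barcode_alignment()].
#' @export
excise_region <- function(aln, ref_id, ref_start = 1, ref_len = 658) {
  stopifnot(inherits(aln, "barcode_alignment"))
  ri <- match(ref_id, aln$ids)
  if (is.na(ri)) stop("reference id not found: ", ref_id)
  chars <- strsplit(aln$seqs[ri], "")[[1]]
  nongap <- chars != "-"
  pos <- cumsum(nongap)
  pos[!nongap] <- NA
  last_needed <- ref_start + ref_len - 1
  if (sum(nongap) < last_needed) {
    stop(sprintf(
      "window [%d, %d] exceeds reference length %d",
      ref_start, last_needed, sum(nongap)
    ))
  }
  cols <- which(!is.na(pos) & pos >= ref_start & pos <= last_needed)
  keep <- seq(min(cols), max(cols))
  barcode_alignment(
    aln$ids,
    substring(aln$seqs, min(keep), max(keep)),
    aln$region
  )
}

#' One-hot encode a barcode alignment
#'
#' Converts the alignment into a haploid presence/absence genotype matrix.
#' Only alignment columns at which at least two different unambiguous bases
#' (A/C/G/T) are observed contribute; each observed base becomes an
#' indicator column labelled `"<column>.<base>"` (within a column,
#' indicators are ordered by descending allele count, ties alphabetical).
#' Gaps, `N` and IUPAC ambiguity codes are treated as missing: every
#' indicator of that column is `NA` for that individual. Indicator columns
#' whose allele count falls below `min_mac` are dropped.
#'
#' @param aln A [barcode_alignment()].
#' @param min_mac Minimum allele count for an indicator column to be kept.
#' @return An object of class `allele_matrix` with fields `ids`, `columns`
#'   (indicator labels), `x` (matrix with entries 0/1/NA), `column_means`
#'   (observed means, used for imputation) and `region` (carried through).
#' @export
encode_alignment <- function(aln, min_mac = 1) {
  stopifnot(inherits(aln, "barcode_alignment"))
  if (length(aln$ids) == 0) stop("empty alignment: nothing to encode")
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  n <- nrow(mat)
  blocks <- list()
  labels <- character(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    observed <- col %in% c("A", "C", "G", "T")
    bases <- table(col[observed])
    bases <- bases[bases > 0]
    if (length(bases) < 2) next # monomorphic or fully missing column
    ord <- order(-as.integer(bases), names(bases))
    bases <- bases[ord]
    for (b in names(bases)) {
      if (bases[[b]] < min_mac) next
      v <- rep(NA_real_, n)
      v[observed] <- as.numeric(col[observed] == b)
      blocks[[length(blocks) + 1]] <- v
      labels <- c(labels, sprintf("%d.%s", j, b))
    }
  }
  if (length(blocks) == 0) {
    stop("no polymorphic columns: nothing to encode")
  }
  x <- do.call(cbind, blocks)
  dimnames(x) <- list(aln$ids, labels)
  structure(
    list(
      ids = aln$ids, columns = labels, x = x,
      column_means = colMeans(x, na.rm = TRUE),
      region = aln$region
    ),
    class = "allele_matrix"
  )
}

#' @export
print.allele_matrix <- function(x, ...) {
  cat(sprintf(
    "allele_matrix: %d individuals x %d indicator columns\n",
    nrow(x$x), ncol(x$x)
  ))
  invisible(x)
}

# mean-impute missing indicators, optionally with supplied training means
impute_allele_matrix <- function(x, means = NULL) {
  m <- x$x
  if (is.null(means)) means <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) m[miss, j] <- means[j]
  }
  list(x = m, means = means)
}

# retained-PC count: fewest PCs reaching a variance fraction, or fixed count
n_pcs_to_keep <- function(sdev, pca_keep, cap) {
  if (pca_keep < 1) {
    v <- cumsum(sdev^2) / sum(sdev^2)
    k <- which(v >= pca_keep)[1]
  } else {
    k <- as.integer(pca_keep)
  }
  max(1L, min(k, cap))
}

#' Infer haplotype clusters by successive k-means on principal components
#'
#' Missing indicators are mean-imputed, the matrix centered, and PCA
#' applied; the fewest PCs reaching the requested variance fraction (or a
#' fixed count) are retained. k-means (with seeded restarts) is run for
#' `k = 1..k_max` and each solution is scored with
#' `BIC(k) = n * ln(WSS_k / n) + k * ln(n)`. The number of clusters is
#' chosen with the diffNgroup rule: successive decreases
#' `delta_k = BIC(k) - BIC(k+1)` are split into two groups by 1-D Ward
#' clustering, and `chosen_k` is one more than the largest `k` whose
#' decrease falls in the high-decrease group. When the BIC curve never
#' decreases, the `k` minimizing BIC (i.e. 1) is returned.
#'
#' @param x An `allele_matrix` from [encode_alignment()].
#' @param k_max Largest number of clusters explored (default 40).
#' @param pca_keep Either a variance fraction in (0, 1) (default 0.9) or a
#'   fixed integer count of PCs; capped at `n_ind - 1`.
#' @param n_start k-means restarts per k (best within-cluster sum of
#'   squares kept).
#' @param seed Integer seed making the labels reproducible.
#' @return An object of class `coi_clusters`: `labels` (integer cluster per
#'   individual for `chosen_k`), `chosen_k`, `bic_curve` (data.frame of k,
#'   WSS and BIC), `n_pcs_used` and `scores`.
#' @export
find_clusters <- function(x, k_max = 40, pca_keep = 0.9, n_start = 10,
                          seed = 1L) {
  stopifnot(inherits(x, "allele_matrix"))
  n <- nrow(x$x)
  if (k_max >= n) stop("k_max must be smaller than the number of individuals")
  imp <- impute_allele_matrix(x)
  pca <- prcomp(imp$x, center = TRUE, scale. = FALSE)
  n_pc <- n_pcs_to_keep(pca$sdev, pca_keep, cap = n - 1L)
  scores <- pca$x[, seq_len(n_pc), drop = FALSE]

  n_distinct <- nrow(unique(scores))
  ks <- seq_len(min(k_max, n_distinct))
  set.seed(seed)
  wss <- numeric(length(ks))
  labs <- vector("list", length(ks))
  total_center <- colMeans(scores)
  for (k in ks) {
    if (k == 1) {
      wss[1] <- sum(sweep(scores, 2, total_center)^2)
      labs[[1]] <- rep(1L, n)
    } else {
      km <- suppressWarnings(
        kmeans(scores, centers = k, nstart = n_start, iter.max = 50)
      )
      wss[k] <- km$tot.withinss
      labs[[k]] <- km$cluster
    }
  }
  # guard zero WSS (perfectly collapsed clusters) in the log
  bic <- n * log(pmax(wss, .Machine$double.eps) / n) + ks * log(n)
  chosen_k <- 1L
  if (length(ks) > 1) {
    delta <- bic[-length(bic)] - bic[-1]
    if (all(delta <= 0)) {
      chosen_k <- ks[which.min(bic)]
    } else if (length(delta) == 1) {
      chosen_k <- if (delta > 0) 2L else 1L
    } else {
      hc <- hclust(dist(delta), method = "ward.D2")
      grp <- cutree(hc, k = 2)
      high <- which.max(tapply(delta, grp, mean))
      chosen_k <- 1L + max(which(grp == high))
    }
  }
  structure(
    list(
      labels = setNames(labs[[chosen_k]], x$ids),
      chosen_k = as.integer(chosen_k),
      bic_curve = data.frame(k = ks, wss = wss, bic = bic),
      n_pcs_used = n_pc,
      scores = scores
    ),
    class = "coi_clusters"
  )
}

#' @export
print.coi_clusters <- function(x, ...) {
  cat(sprintf(
    "coi_clusters: %d clusters over %d individuals (%d PCs)\n",
    x$chosen_k, length(x$labels), x$n_pcs_used
  ))
  invisible(x)
}

#' Fit a DAPC model
#'
#' Discriminant analysis of principal components: the (mean-imputed,
#' centered) indicator matrix is reduced to `n_pcs` principal components,
#' on which Fisher linear discriminant axes are computed from the cluster
#' labels (`k - 1` axes for `k` clusters). Axes are scaled to unit pooled
#' within-class variance, so Euclidean distance in discriminant space is
#' the Mahalanobis distance of classical LDA. Cluster centroids in
#' discriminant space are stored for posterior assignment.
#'
#' @param x An `allele_matrix`.
#' @param labels Cluster labels, one per individual.
#' @param n_pcs Number of retained principal components
#'   (`<= n_ind - 1`).
#' @param ridge Ridge added to a singular within-class scatter (with a
#'   warning).
#' @return An object of class `dapc_model`.
#' @export
fit_dapc <- function(x, labels, n_pcs, ridge = 1e-8) {
  stopifnot(inherits(x, "allele_matrix"))
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x$x))
  lev <- sort(unique(labels))
  k <- length(lev)
  if (k < 2) stop("need at least 2 clusters")
  n <- nrow(x$x)
  if (n_pcs > n - 1) stop("n_pcs must be at most n_ind - 1")
  n_pcs <- min(n_pcs, ncol(x$x))

  imp <- impute_allele_matrix(x)
  center <- colMeans(imp$x)
  xc <- sweep(imp$x, 2, center)
  pca <- prcomp(xc, center = FALSE, scale. = FALSE)
  n_pcs <- min(n_pcs, sum(pca$sdev > 1e-12))
  load <- pca$rotation[, seq_len(n_pcs), drop = FALSE]
  scores <- xc %*% load

  # Fisher discriminant axes: eigenvectors of W^{-1} B
  grand <- colMeans(scores)
  W <- matrix(0, n_pcs, n_pcs)
  B <- matrix(0, n_pcs, n_pcs)
  for (g in lev) {
    rows <- scores[labels == g, , drop = FALSE]
    mu <- colMeans(rows)
    if (nrow(rows) > 1) {
      W <- W + crossprod(sweep(rows, 2, mu))
    }
    B <- B + nrow(rows) * tcrossprod(mu - grand)
  }
  W <- W / max(n - k, 1)
  Winv <- tryCatch(solve(W), error = function(e) NULL)
  if (is.null(Winv)) {
    warning("singular within-class scatter; adding ridge")
    W <- W + diag(ridge * max(mean(diag(W)), 1), n_pcs)
    Winv <- solve(W)
  }
  ed <- eigen(Winv %*% B)
  n_da <- k - 1L
  axes <- Re(ed$vectors[, seq_len(min(n_da, n_pcs)), drop = FALSE])
  if (ncol(axes) < n_da) {
    # pad (degenerate case n_pcs < k-1); keeps the k-1 axis contract
    axes <- cbind(axes, matrix(0, n_pcs, n_da - ncol(axes)))
  }
  # scale each axis to unit pooled within-class variance
  for (a in seq_len(ncol(axes))) {
    s <- sqrt(drop(t(axes[, a]) %*% W %*% axes[, a]))
    if (s > 1e-12) axes[, a] <- axes[, a] / s
  }
  z <- scores %*% axes
  centroids <- do.call(rbind, lapply(lev, function(g) {
    colMeans(z[labels == g, , drop = FALSE])
  }))
  rownames(centroids) <- lev

  model <- structure(
    list(
      columns = colnames(x$x),
      center = center,
      column_means = imp$means,
      pc_loadings = load,
      n_pcs = as.integer(n_pcs),
      da_axes = axes,
      k = as.integer(k),
      n_da = as.integer(n_da),
      cluster_levels = lev,
      centroids = centroids,
      training_labels = labels
    ),
    class = "dapc_model"
  )
  pred <- assign_barcode(model, x)
  model$self_assignment <- mean(pred$cluster == labels)
  model
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf(
    "dapc_model: %d clusters, %d PCs, %d discriminant axes\n",
    x$k, x$n_pcs, x$n_da
  ))
  if (!is.null(x$self_assignment)) {
    cat(sprintf("training self-assignment accuracy: %.3f\n", x$self_assignment))
  }
  invisible(x)
}

#' Cross-validated selection of the number of retained PCs
#'
#' Repeated stratified splits into training and test sets (default 90/10,
#' 30 repeats); for each candidate PC count a DAPC is fitted on the
#' training rows and the test rows assigned, recording the fraction
#' assigned to their own cluster. The best PC count maximizes mean
#' accuracy, ties broken toward fewer PCs. Clusters with fewer than 2
#' members are excluded from splitting (kept in training) with a warning.
#'
#' @param x An `allele_matrix`.
#' @param labels Cluster labels.
#' @param pc_grid Candidate PC counts (values exceeding what the training
#'   split supports are skipped with a warning).
#' @param reps Number of random splits.
#' @param test_frac Fraction of each cluster held out per split.
#' @param seed Integer seed.
#' @return A list with `xval_table` (data.frame: n_pcs, mean_accuracy,
#'   sd_accuracy) and `best_n_pcs`.
#' @export
xval_pc_selection <- function(x, labels, pc_grid = c(1, 2, 5, 10, 15, 20, 25),
                              reps = 30, test_frac = 0.10, seed = 1L) {
  stopifnot(inherits(x, "allele_matrix"))
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x$x))
  n <- nrow(x$x)
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning(
      "cluster(s) with <2 members excluded from splitting: ",
      paste(small, collapse = ", ")
    )
  }
  splittable <- !(labels %in% small)
  max_train <- n - sum(pmax(1, round(test_frac * sizes[!(names(sizes) %in% small)])))
  pc_grid <- sort(unique(as.integer(pc_grid)))
  usable <- pc_grid[pc_grid <= min(max_train - 1, ncol(x$x))]
  if (length(usable) < length(pc_grid)) {
    warning("PC count(s) beyond what the training split supports skipped")
  }
  if (length(usable) == 0) stop("no usable PC counts in pc_grid")

  set.seed(seed)
  acc <- matrix(NA_real_, nrow = reps, ncol = length(usable))
  for (r in seq_len(reps)) {
    test_idx <- integer(0)
    for (g in setdiff(names(sizes), small)) {
      rows <- which(labels == g)
      n_test <- max(1, round(test_frac * length(rows)))
      n_test <- min(n_test, length(rows) - 1) # keep >=1 in training
      test_idx <- c(test_idx, sample(rows, n_test))
    }
    train_idx <- setdiff(seq_len(n), test_idx)
    xtr <- subset_allele_matrix(x, train_idx)
    xte <- subset_allele_matrix(x, test_idx)
    for (p in seq_along(usable)) {
      fit <- suppressWarnings(fit_dapc(xtr, labels[train_idx], usable[p]))
      pred <- suppressWarnings(assign_barcode(fit, xte))
      acc[r, p] <- mean(pred$cluster == labels[test_idx])
    }
  }
  tab <- data.frame(
    n_pcs = usable,
    mean_accuracy = colMeans(acc),
    sd_accuracy = apply(acc, 2, sd)
  )
  best <- usable[which.max(tab$mean_accuracy)] # which.max takes first => fewest
  list(xval_table = tab, best_n_pcs = best)
}

#' Row subset of an allele matrix
#'
#' Keeps the column bookkeeping (labels, recomputed observed means) so the
#' subset can serve as a training set or as queries for [assign_barcode()].
#'
#' @param x An `allele_matrix`.
#' @param rows Row indices (or logical mask) to keep.
#' @return An `allele_matrix` over the selected individuals.
#' @export
subset_allele_matrix <- function(x, rows) {
  structure(
    list(
      ids = x$ids[rows],
      columns = x$columns,
      x = x$x[rows, , drop = FALSE],
      column_means = colMeans(x$x[rows, , drop = FALSE], na.rm = TRUE),
      region = x$region[rows]
    ),
    class = "allele_matrix"
  )
}

#' Assign query barcodes to DAPC clusters
#'
#' Queries are reconciled to the model's indicator columns: model columns
#' absent from the query (or missing for an individual) are imputed with
#' the training column means; query columns unknown to the model are
#' ignored with a warning. Each query is projected through
#' centering, the PC loadings and the discriminant axes, and cluster
#' membership posteriors are computed as a distance softmax
#' `P(g) ~ exp(-0.5 * ||z - centroid_g||^2)` under equal priors. A query
#' sharing fewer than half of the model's columns is returned as `NA` with
#' reason `"insufficient_overlap"`.
#'
#' @param model A `dapc_model`.
#' @param query An `allele_matrix` (columns matched to the model by name).
#' @return A data.frame with columns `id`, `method`, `cluster`, `posterior`
#'   (rounded to 4 decimals), `origin` (`NA`; see [coi_origin_calls()]) and
#'   `reason`.
#' @export
assign_barcode <- function(model, query) {
  stopifnot(inherits(model, "dapc_model"))
  stopifnot(inherits(query, "allele_matrix"))
  novel <- setdiff(query$columns, model$columns)
  if (length(novel) > 0) {
    warning(length(novel), " query column(s) unknown to the model ignored")
  }
  n <- nrow(query$x)
  m <- length(model$columns)
  xq <- matrix(NA_real_, nrow = n, ncol = m,
    dimnames = list(query$ids, model$columns)
  )
  shared <- intersect(model$columns, query$columns)
  xq[, shared] <- query$x[, shared, drop = FALSE]
  overlap <- rowMeans(!is.na(xq))
  # impute missing model columns with stored training means
  for (j in seq_len(m)) {
    miss <- is.na(xq[, j])
    if (any(miss)) xq[miss, j] <- model$column_means[j]
  }
  z <- sweep(xq, 2, model$center) %*% model$pc_loadings %*% model$da_axes
  d2 <- outer(rowSums(z^2), rowSums(model$centroids^2), "+") -
    2 * z %*% t(model$centroids)
  # softmax of -d2/2, numerically stabilized
  lw <- -d2 / 2
  lw <- lw - apply(lw, 1, max)
  post <- exp(lw) / rowSums(exp(lw))
  colnames(post) <- model$cluster_levels
  best <- max.col(post, ties.method = "first")
  out <- data.frame(
    id = query$ids,
    method = "COI-DAPC",
    cluster = model$cluster_levels[best],
    posterior = round(post[cbind(seq_len(n), best)], 4),
    origin = NA_character_,
    reason = NA_character_,
    stringsAsFactors = FALSE
  )
  low <- overlap < 0.5
  out$cluster[low] <- NA_character_
  out$posterior[low] <- NA_real_
  out$reason[low] <- "insufficient_overlap"
  attr(out, "posteriors") <- post
  out
}

#' Normalized regional profile of each haplotype cluster
#'
#' For cluster `c` and region `r`, the raw proportion is
#' `p_cr = count_cr / region_total_r` (the fraction of region `r`'s
#' reference samples falling in cluster `c`), and the normalized proportion
#' rescales `p_cr` to sum to one across regions within the cluster. The
#' normalization accounts for unequal sampling effort across regions.
#' Individuals with region `"Unknown"` or in `exclusions` are dropped;
#' regions with zero total after exclusion are dropped from the
#' normalization with a warning.
#'
#' @param labels Cluster labels, one per individual.
#' @param regions Region labels (from [REGION_VOCABULARY]), one per
#'   individual.
#' @param exclusions Regions to exclude (e.g. insufficiently documented
#'   areas).
#' @param origin_map Named region -> origin map (default
#'   [DEFAULT_ORIGIN_MAP]).
#' @param dominance_threshold Minimum summed origin share for an
#'   unambiguous origin call (in (0.5, 1]).
#' @param minor_floor Minimum share for an origin to be listed in an
#'   ambiguous call.
#' @return An object of class `cluster_region_profile` with fields
#'   `counts`, `normalized` (clusters x regions), `n_known` (per-cluster
#'   members with known origin), `region_totals`, `origin_map`,
#'   `dominance_threshold`, `minor_floor`.
#' @export
region_profile <- function(labels, regions, exclusions = character(),
                           origin_map = DEFAULT_ORIGIN_MAP,
                           dominance_threshold = 0.90, minor_floor = 0.05) {
  labels <- as.character(labels)
  regions <- as.character(regions)
  stopifnot(length(labels) == length(regions))
  stopifnot(dominance_threshold > 0.5, dominance_threshold <= 1)
  keep <- !(regions %in% c("Unknown", exclusions)) & !is.na(regions)
  labels <- labels[keep]
  regions <- regions[keep]
  if (length(labels) == 0) stop("no individuals with known region remain")
  region_levels <- intersect(REGION_VOCABULARY, unique(regions))
  totals <- table(factor(regions, levels = region_levels))
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0) {
    warning("region(s) with zero total dropped: ", paste(zero, collapse = ", "))
    region_levels <- setdiff(region_levels, zero)
    totals <- totals[region_levels]
  }
  clus_levels <- sort(unique(labels))
  counts <- table(
    factor(labels, levels = clus_levels),
    factor(regions, levels = region_levels)
  )
  counts <- matrix(as.integer(counts),
    nrow = length(clus_levels),
    dimnames = list(clus_levels, region_levels)
  )
  p <- sweep(counts, 2, as.numeric(totals), "/")
  normalized <- p / rowSums(p)
  structure(
    list(
      counts = counts,
      normalized = normalized,
      n_known = rowSums(counts),
      region_totals = setNames(as.numeric(totals), region_levels),
      origin_map = origin_map,
      dominance_threshold = dominance_threshold,
      minor_floor = minor_floor
    ),
    class = "cluster_region_profile"
  )
}

#' @export
print.cluster_region_profile <- function(x, ...) {
  cat("cluster_region_profile (normalized proportions):\n")
  print(round(x$normalized, 3))
  cat(
    "region totals:",
    paste(names(x$region_totals), x$region_totals, sep = "=", collapse = ", "),
    "\n"
  )
  invisible(x)
}

#' Map a haplotype cluster to a geographic origin
#'
#' Each region's normalized proportion is mapped through the profile's
#' region -> origin map and summed per origin. If the top origin reaches
#' the dominance threshold it is returned; otherwise an ambiguous call
#' listing every origin at or above the minor floor (descending share) is
#' returned as `"ambiguous:<o1>,<o2>,..."`.
#'
#' @param profile A `cluster_region_profile`.
#' @param cluster Cluster identifier (row of the profile).
#' @return Character origin label.
#' @export
cluster_origin <- function(profile, cluster) {
  stopifnot(inherits(profile, "cluster_region_profile"))
  cluster <- as.character(cluster)
  if (!cluster %in% rownames(profile$normalized)) {
    stop("unknown cluster: ", cluster)
  }
  props <- profile$normalized[cluster, ]
  origins <- profile$origin_map[names(props)]
  shares <- tapply(props, origins, sum)
  shares <- sort(shares, decreasing = TRUE)
  if (shares[1] >= profile$dominance_threshold) {
    return(names(shares)[1])
  }
  cand <- names(shares)[shares >= profile$minor_floor]
  paste0("ambiguous:", paste(cand, collapse = ","))
}

#' Assign query barcodes and map clusters to origins
#'
#' Convenience wrapper: [assign_barcode()] followed by [cluster_origin()]
#' per assigned cluster.
#'
#' @param model A `dapc_model`.
#' @param query An `allele_matrix` of query barcodes.
#' @param profile A `cluster_region_profile` for the model's clusters.
#' @return The [assign_barcode()] data.frame with its `origin` column
#'   filled in.
#' @export
coi_origin_calls <- function(model, query, profile) {
  calls <- assign_barcode(model, query)
  known <- !is.na(calls$cluster) &
    calls$cluster %in% rownames(profile$normalized)
  calls$origin[known] <- vapply(
    calls$cluster[known],
    function(cl) cluster_origin(profile, cl), character(1)
  )
  calls
}
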