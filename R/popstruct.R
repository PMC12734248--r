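## Structure inference from genotype likelihoods: iterative
## individual-allele-frequency covariance (low-depth-aware PCA) and a
## neighbour-joining tree built from the same matrix.

#' Estimate the sample covariance matrix from genotype likelihoods
#'
#' Iterative individual-allele-frequency estimator for low-depth data.
#' Starting from per-site frequencies computed from likelihood-weighted
#' expected dosages, the algorithm alternates between (a) computing
#' posterior expected dosages under a Hardy-Weinberg prior at each
#' individual's current allele frequency, (b) forming the standardized
#' residual matrix `R[i,j] = (E[g_ij] - 2 f_j) / sqrt(2 f_j (1 - f_j))` and
#' the covariance `R %*% t(R) / n_sites`, and (c) updating the individual
#' allele frequencies from a rank-`n_components` SVD of `R` mapped back to
#' the frequency scale and truncated to `[eps, 1 - eps]`. Iteration stops
#' when the covariance changes by less than `tol` (max absolute entry) or
#' after `max_iter` sweeps. Uninformative likelihood triples (missing data)
#' contribute their posterior expectation rather than an imputed hard call,
#' which is what makes the formulation usable for low-depth samples.
#'
#' @param gl A [genotype_likelihoods()] with at least 2 individuals and 2
#'   polymorphic sites.
#' @param n_components Rank of the structure model used for the individual
#'   allele-frequency update, and number of principal components returned.
#' @param max_iter Maximum number of sweeps.
#' @param tol Convergence tolerance on the covariance matrix.
#' @param eps Truncation bound for individual allele frequencies.
#' @return An object of class `covariance_result` with fields `cov`
#'   (symmetric `n x n`), `pcs` (scores `n x n_components`), `explained`
#'   (per-component fraction of total variance), `site_freq`,
#'   `iterations_run` and `converged`.
#' @export
gl_covariance <- function(gl, n_components = 2, max_iter = 100,
                          tol = 1e-5, eps = 1e-4) {
  stopifnot(inherits(gl, "genotype_likelihoods"))
  n <- length(gl$individuals)
  m <- length(gl$sites)
  if (n < 2) stop("need at least 2 individuals")
  G <- gl$gl
  # expected dosage under the raw (normalized) likelihood triple
  e_raw <- G[, , 2] + 2 * G[, , 3]
  if (m < 2) stop("need at least 2 sites")
  f <- colMeans(e_raw) / 2
  poly <- f > 0 & f < 1
  if (sum(poly) < 2) {
    stop("monomorphic-only input: need at least 2 polymorphic sites")
  }
  if (any(!poly)) {
    G <- G[, poly, , drop = FALSE]
    m <- sum(poly)
    f <- f[poly]
  }
  sites_kept <- gl$sites[poly]
  denom <- sqrt(2 * f * (1 - f))

  pi_mat <- matrix(f, nrow = n, ncol = m, byrow = TRUE)
  cov_prev <- NULL
  converged <- FALSE
  iterations <- 0L
  R <- NULL
  for (it in seq_len(max_iter)) {
    iterations <- it
    # posterior expected dosage under HW prior at individual frequencies
    p0 <- (1 - pi_mat)^2
    p1 <- 2 * pi_mat * (1 - pi_mat)
    p2 <- pi_mat^2
    w0 <- G[, , 1] * p0
    w1 <- G[, , 2] * p1
    w2 <- G[, , 3] * p2
    tot <- w0 + w1 + w2
    eg <- (w1 + 2 * w2) / tot
    R <- sweep(sweep(eg, 2, 2 * f, "-"), 2, denom, "/")
    cov_mat <- tcrossprod(R) / m
    if (!is.null(cov_prev) && max(abs(cov_mat - cov_prev)) < tol) {
      converged <- TRUE
      cov_prev <- cov_mat
      break
    }
    cov_prev <- cov_mat
    # rank-k reconstruction of R -> updated individual allele frequencies
    k <- min(n_components, n - 1, m - 1)
    sv <- svd(R, nu = k, nv = k)
    Rk <- sv$u %*% (diag(sv$d[seq_len(k)], k, k)) %*% t(sv$v)
    pi_mat <- sweep(sweep(Rk, 2, denom, "*"), 2, 2 * f, "+") / 2
    pi_mat <- pmin(pmax(pi_mat, eps), 1 - eps)
  }
  if (!converged) {
    warning("gl_covariance did not converge in ", max_iter, " iterations")
  }
  cov_mat <- (cov_prev + t(cov_prev)) / 2
  dimnames(cov_mat) <- list(gl$individuals, gl$individuals)
  ev <- eigen(cov_mat, symmetric = TRUE)
  k_out <- min(n_components, n)
  pcs <- ev$vectors[, seq_len(k_out), drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[seq_len(k_out)], 0)), k_out, k_out)
  rownames(pcs) <- gl$individuals
  colnames(pcs) <- paste0("PC", seq_len(k_out))
  lam <- pmax(ev$values, 0)
  explained <- if (sum(lam) > 0) lam[seq_len(k_out)] / sum(lam) else rep(0, k_out)
  structure(
    list(
      cov = cov_mat, pcs = pcs, explained = explained,
      site_freq = setNames(f, sites_kept),
      iterations_run = iterations, converged = converged
    ),
    class = "covariance_result"
  )
}

#' @export
print.covariance_result <- function(x, ...) {
  cat(sprintf(
    "covariance_result: %d individuals, %d sites, %d iterations (%s)\n",
    nrow(x$cov), length(x$site_freq), x$iterations_run,
    if (x$converged) "converged" else "NOT converged"
  ))
  cat(sprintf(
    "PC1 explains %.2f%% of all variation\n", 100 * x$explained[1]
  ))
  invisible(x)
}

#' Euclidean distances from a covariance matrix
#'
#' `d_ij = sqrt(c_ii + c_jj - 2 c_ij)`, the Euclidean distance between
#' samples in the latent space implied by the covariance. Zero diagonal,
#' symmetric.
#'
#' @param cov A `covariance_result` or a symmetric covariance matrix.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
cov_to_distance <- function(cov) {
  if (inherits(cov, "covariance_result")) cov <- cov$cov
  cov <- as.matrix(cov)
  d2 <- outer(diag(cov), diag(cov), "+") - 2 * cov
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  diag(d) <- 0
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion is joined and branch lengths follow the standard formulas.
#' Negative branch lengths are clamped to zero with the deficit shifted to
#' the sister edge, so all edge lengths are non-negative while pairwise
#' path lengths between the joined pair are preserved. On additive
#' distances the generating tree is recovered exactly.
#'
#' @param dist Symmetric, non-negative matrix with zero diagonal.
#' @param names Optional leaf labels (defaults to the matrix dimnames or
#'   `t1..tn`).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dist, names = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 taxa")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  if (is.null(names)) {
    names <- if (!is.null(rownames(d))) rownames(d) else paste0("t", seq_len(n))
  }
  if (anyDuplicated(names)) stop("duplicate leaf names")
  if (n == 2) {
    txt <- sprintf("(%s:%g,%s:%g);", names[1], d[1, 2] / 2, names[2], d[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }

  # node bookkeeping in ape's numbering: tips 1..n, internals n+1..
  active <- seq_len(n) # rows of d -> node ids
  node_ids <- seq_len(n)
  next_internal <- 2L * n - 2L # fills downward; root assigned last
  edges <- matrix(0L, nrow = 0, ncol = 2)
  lengths <- numeric(0)
  # we collect edges child<-parent as (parent, child)
  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    lengths <<- c(lengths, max(len, 0))
  }

  internal_counter <- 0L
  internal_map <- integer(0) # temp id -> final id later
  tmp_edges <- list()

  repeat {
    r <- nrow(d)
    if (r == 2) break
    rs <- rowSums(d)
    q <- (r - 2) * d - outer(rs, rs, "+")
    diag(q) <- Inf
    ij <- which(q == min(q), arr.ind = TRUE)[1, ]
    i <- min(ij)
    j <- max(ij)
    dij <- d[i, j]
    li <- dij / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- dij - li
    # clamp negatives, shifting the deficit to the sister edge
    if (li < 0) {
      lj <- lj + li
      li <- 0
    }
    if (lj < 0) {
      li <- li + lj
      lj <- 0
    }
    li <- max(li, 0)
    lj <- max(lj, 0)
    internal_counter <- internal_counter + 1L
    new_tmp <- -internal_counter # negative => internal temp id
    tmp_edges[[length(tmp_edges) + 1]] <- c(new_tmp, node_ids[i], li)
    tmp_edges[[length(tmp_edges) + 1]] <- c(new_tmp, node_ids[j], lj)
    dnew <- (d[i, ] + d[j, ] - dij) / 2
    dnew <- dnew[-c(i, j)]
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, dnew), c(dnew, 0))
    node_ids <- c(node_ids[-c(i, j)], new_tmp)
  }
  # join the last two nodes with a single edge
  internal_counter <- internal_counter + 1L
  root_tmp <- -internal_counter
  l1 <- d[1, 2] / 2
  tmp_edges[[length(tmp_edges) + 1]] <- c(root_tmp, node_ids[1], l1)
  tmp_edges[[length(tmp_edges) + 1]] <- c(root_tmp, node_ids[2], d[1, 2] - l1)

  # map temp internal ids (-1..-K, root last) to ape ids (n+1 = root)
  K <- internal_counter
  map_internal <- function(tmp) {
    # root_tmp -> n+1; earlier internals keep creation order after the root
    if (tmp == root_tmp) n + 1L else n + 1L + (K - (-tmp))
  }
  em <- matrix(0L, nrow = length(tmp_edges), ncol = 2)
  el <- numeric(length(tmp_edges))
  for (k in seq_along(tmp_edges)) {
    e <- tmp_edges[[k]]
    p <- if (e[1] < 0) map_internal(e[1]) else e[1]
    c_ <- if (e[2] < 0) map_internal(e[2]) else e[2]
    em[k, ] <- c(p, c_)
    el[k] <- e[3]
  }
  tree <- list(
    edge = em, edge.length = el, tip.label = names, Nnode = as.integer(K)
  )
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

#' Nearest-centroid origin call from principal components
#'
#' The structure analysis leaves cluster membership to inspection; this
#' helper automates the simplest defensible rule: reference individuals of
#' known origin define per-origin centroids on the first two PCs, and each
#' query is assigned the origin of its nearest centroid.
#'
#' @param covres A `covariance_result` from [gl_covariance()].
#' @param ref_origins Named character vector (individual id -> origin) for
#'   the reference individuals; ids absent from it are treated as queries.
#' @return A data.frame with columns `id`, `method` (`"PCA/NJT"`) and
#'   `origin` for every individual (references get their own label back).
#' @export
pca_origin_call <- function(covres, ref_origins) {
  stopifnot(inherits(covres, "covariance_result"))
  pcs <- covres$pcs[, seq_len(min(2, ncol(covres$pcs))), drop = FALSE]
  ids <- rownames(pcs)
  is_ref <- ids %in% names(ref_origins)
  if (!any(is_ref)) stop("no reference individuals found in the covariance")
  origins <- ref_origins[ids[is_ref]]
  cents <- do.call(rbind, lapply(unique(origins), function(o) {
    colMeans(pcs[is_ref, , drop = FALSE][origins == o, , drop = FALSE])
  }))
  rownames(cents) <- unique(origins)
  d2 <- outer(rowSums(pcs^2), rowSums(cents^2), "+") - 2 * pcs %*% t(cents)
  call <- rownames(cents)[max.col(-d2, ties.method = "first")]
  data.frame(
    id = ids, method = "PCA/NJT", origin = call,
    stringsAsFactors = FALSE
  )
}
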