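#' First-level voxelwise GLM of BOLD on an autonomic regressor
#'
#' Ordinary least squares of every in-mask voxel time series on
#' `[intercept, linear drift, regressor]` (plus optional confound
#' columns), returning the regressor's effect, its variance and a
#' Gaussianized Z statistic per voxel, for both signed contrasts.
#' Volumes with a missing regressor value are dropped listwise.
#'
#' @param bold A [synth_bold()] dataset, or any list with `data`
#'   (volumes x voxels matrix over in-mask voxels), `dims`, `mask`.
#' @param reg A convolved [regressor_series()] whose length matches the
#'   number of volumes.
#' @param confounds Optional numeric matrix of additional nuisance
#'   columns (one row per volume).
#' @param drift Include a linear drift column (default `TRUE`).
#' @return An object of class `level_result`: list with `beta`, `var`,
#'   `z` (vectors over in-mask voxels, positive contrast; the negative
#'   contrast is the negation), `dof`, `dims`, `mask`, `level = 1`.
#' @export
first_level <- function(bold, reg, confounds = NULL, drift = TRUE) {
  stopifnot(inherits(reg, "regressor_series"))
  Y <- bold$data
  if (nrow(Y) != reg$n_vols)
    stop("BOLD volume count does not match the regressor", call. = FALSE)
  if (sum(bold$mask) != ncol(Y))
    stop("mask size does not match the data matrix", call. = FALSE)
  n <- reg$n_vols
  X <- cbind(intercept = 1,
             if (drift) cbind(drift = seq_len(n) / n),
             confounds,
             regressor = reg$values)
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cf <- qr.coef(qrX, Y)
  res <- Y - X %*% cf
  dof <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dof
  XtXinv <- chol2inv(qr.R(qrX))
  j <- ncol(X)                         # regressor of interest is last
  beta <- cf[j, ]
  var_b <- sigma2 * XtXinv[j, j]
  tstat <- beta / sqrt(var_b)
  z <- t_to_z(tstat, dof)
  structure(list(beta = beta, var = var_b, z = z, dof = dof,
                 dims = bold$dims, mask = bold$mask, level = 1L),
            class = "level_result")
}

# Gaussianize a t statistic (two-tail-symmetric, stable in the tails)
t_to_z <- function(tstat, dof) {
  z <- sign(tstat) * stats::qnorm(stats::pt(abs(tstat), dof,
                                            lower.tail = FALSE,
                                            log.p = TRUE),
                                  lower.tail = FALSE, log.p = TRUE)
  z[!is.finite(z)] <- sign(tstat[!is.finite(z)]) * 40
  z
}

#' @export
print.level_result <- function(x, ...) {
  cat(sprintf("Level-%d GLM result: %d voxels, dof %.1f\n", x$level,
              length(x$z), x$dof))
  cat(sprintf("  Z range [%.2f, %.2f]\n", min(x$z), max(x$z)))
  invisible(x)
}

#' Within-subject fixed-effects combination of two runs
#'
#' Inverse-variance-weighted fixed-effects combination of the run-level
#' effects; the combined variance is \eqn{(\sum_i 1/v_i)^{-1}}.
#'
#' @param run_a,run_b `level_result`s on the same grid and mask.
#' @return A `level_result` with `level = 2`.
#' @export
second_level_fixed <- function(run_a, run_b) {
  if (!identical(run_a$dims, run_b$dims) ||
      !identical(which(run_a$mask), which(run_b$mask)))
    stop("runs are not on the same grid/mask", call. = FALSE)
  w_a <- 1 / run_a$var
  w_b <- 1 / run_b$var
  v <- 1 / (w_a + w_b)
  beta <- (w_a * run_a$beta + w_b * run_b$beta) * v
  structure(list(beta = beta, var = v, z = beta / sqrt(v),
                 dof = run_a$dof + run_b$dof, dims = run_a$dims,
                 mask = run_a$mask, level = 2L),
            class = "level_result")
}

# DerSimonian-Laird one-sample combination, vectorized over voxels.
# B, V: subjects x voxels matrices of effects and within-subject variances.
# `pre` (from dl_precompute) caches the flip-invariant pieces so that
# sign-flip permutations only recompute the weighted means.
dl_precompute <- function(B, V) {
  Wm <- 1 / V
  WmB <- Wm * B
  sw <- colSums(Wm)
  list(B = B, V = V, Wm = Wm, WmB = WmB, sw = sw,
       wb2 = colSums(Wm * B^2),
       cc = sw - colSums(Wm^2) / sw, S = nrow(B))
}

dl_combine <- function(B, V, signs = NULL, pre = NULL) {
  if (is.null(pre)) pre <- dl_precompute(B, V)
  S <- pre$S
  Bs <- if (is.null(signs)) pre$B else pre$B * signs
  swb <- if (is.null(signs)) colSums(pre$WmB)
         else drop(crossprod(signs, pre$WmB))
  bw <- swb / pre$sw
  Q <- pre$wb2 - bw^2 * pre$sw       # sum w (b - bw)^2, flip-invariant w
  tau2 <- pmax(0, (Q - (S - 1)) / pre$cc)
  Ws <- 1 / (pre$V + rep(tau2, each = S))
  vs <- 1 / colSums(Ws)
  beta <- colSums(Ws * Bs) * vs
  list(beta = beta, var = vs, z = beta / sqrt(vs), tau2 = tau2)
}

#' Group-level one-sample mixed-effects analysis
#'
#' Simplified FLAME-style combination: a between-subject variance
#' component is estimated per voxel by a restricted method of moments
#' (DerSimonian-Laird, floored at zero), added to the within-subject
#' variances, and the subjects combined by inverse total variance.  The
#' subject-level effects are retained in the result so that
#' [cluster_correct()] can build its sign-flip permutation null.
#'
#' @param subjects List (length >= 3) of `level_result`s on a common
#'   grid.
#' @return A `level_result` with `level = 3` and components
#'   `subject_beta` / `subject_var` (subjects x voxels matrices) and
#'   `tau2`.
#' @export
group_mixed_effects <- function(subjects) {
  if (length(subjects) < 3L)
    stop("need at least 3 subjects for a group analysis", call. = FALSE)
  dims <- subjects[[1L]]$dims
  maskv <- which(subjects[[1L]]$mask)
  for (s in subjects[-1L]) {
    if (!identical(s$dims, dims) || !identical(which(s$mask), maskv))
      stop("subjects are not on the same grid/mask", call. = FALSE)
  }
  B <- do.call(rbind, lapply(subjects, `[[`, "beta"))
  V <- do.call(rbind, lapply(subjects, `[[`, "var"))
  g <- dl_combine(B, V)
  structure(list(beta = g$beta, var = g$var, z = g$z, tau2 = g$tau2,
                 dof = length(subjects) - 1L, dims = dims,
                 mask = subjects[[1L]]$mask, level = 3L,
                 subject_beta = B, subject_var = V),
            class = "level_result")
}

# 26-connected components among supra-threshold in-mask voxels.
# vox: linear indices into the 3D grid.  Returns a membership vector.
connected_components_26 <- function(vox, dims) {
  n <- length(vox)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  coords <- arrayInd(vox, dims)
  key <- vox
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  edges <- list()
  for (r in seq_len(nrow(off))) {
    nb <- sweep(coords, 2, off[r, ], `+`)
    inside <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb_lin <- rep(NA_integer_, n)
    nb_lin[inside] <- (nb[inside, 3] - 1L) * dims[1] * dims[2] +
      (nb[inside, 2] - 1L) * dims[1] + nb[inside, 1]
    hit <- match(nb_lin, key)
    ok <- which(!is.na(hit))
    if (length(ok)) edges[[length(edges) + 1L]] <- cbind(ok, hit[ok])
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(integer(0), 0, 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

# max cluster size above threshold for a z vector over in-mask voxels
max_cluster_size <- function(z, maskv, dims, threshold) {
  sup <- maskv[z > threshold]
  if (length(sup) == 0L) return(0L)
  memb <- connected_components_26(sup, dims)
  max(tabulate(memb))
}

#' Cluster-based correction by sign-flip permutation
#'
#' Thresholds the group Z map (signed; run once per contrast), forms
#' 26-connected supra-threshold clusters, and compares each observed
#' cluster extent with the permutation null distribution of the maximal
#' cluster extent obtained by randomly sign-flipping the subject-level
#' effects and recombining (exact under a symmetric null; no smoothness
#' estimation required).  Corrected p is the rank of the observed extent
#' in the null.
#'
#' @param group A `level_result` from [group_mixed_effects()].
#' @param threshold Z cut; default 2.3.
#' @param alpha Significance level; default 0.05.
#' @param n_perm Number of sign-flip permutations, >= 100; default 1000.
#' @param seed RNG seed for the flips.
#' @param negative If `TRUE`, test the negative contrast (thresholds
#'   `-z`).
#' @return An object of class `cluster_table`: data frame with columns
#'   `id`, `size`, `peak_z`, `p_corrected`, `significant`, plus
#'   attributes `voxels` (list of linear indices per cluster),
#'   `threshold`, `alpha`, `null_max_size`.
#' @export
cluster_correct <- function(group, threshold = 2.3, alpha = 0.05,
                            n_perm = 1000, seed = 1, negative = FALSE) {
  stopifnot(inherits(group, "level_result"))
  if (is.null(group$subject_beta))
    stop("`group` must carry subject-level effects (see group_mixed_effects)",
         call. = FALSE)
  if (n_perm < 100) stop("`n_perm` must be at least 100", call. = FALSE)
  z <- if (negative) -group$z else group$z
  dims <- group$dims
  maskv <- which(group$mask)
  sup <- maskv[z > threshold]
  empty <- data.frame(id = integer(0), size = integer(0),
                      peak_z = numeric(0), p_corrected = numeric(0),
                      significant = logical(0))
  if (length(sup) == 0L) {
    return(structure(empty, voxels = list(), threshold = threshold,
                     alpha = alpha, null_max_size = NULL,
                     class = c("cluster_table", "data.frame")))
  }
  memb <- connected_components_26(sup, dims)
  sizes <- tabulate(memb)
  S <- nrow(group$subject_beta)
  set.seed(seed)
  null_max <- integer(n_perm)
  sgn <- if (negative) -1 else 1
  pre <- dl_precompute(group$subject_beta, group$subject_var)
  for (p in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), S, replace = TRUE)
    gp <- dl_combine(signs = flips, pre = pre)
    null_max[p] <- max_cluster_size(sgn * gp$z, maskv, dims, threshold)
  }
  p_corr <- vapply(sizes, function(s)
    (1 + sum(null_max >= s)) / (n_perm + 1), numeric(1))
  ord <- order(sizes, decreasing = TRUE)
  tab <- data.frame(id = seq_along(ord), size = sizes[ord],
                    peak_z = vapply(ord, function(cl)
                      max(z[match(sup[memb == cl], maskv)]), numeric(1)),
                    p_corrected = p_corr[ord],
                    significant = p_corr[ord] <= alpha)
  structure(tab,
            voxels = lapply(ord, function(cl) sup[memb == cl]),
            threshold = threshold, alpha = alpha, null_max_size = null_max,
            class = c("cluster_table", "data.frame"))
}

#' Overlap of significant clusters with a labelled volume
#'
#' Generic region attribution: for every cluster, the fraction of its
#' voxels falling in each named integer label, sorted descending.
#'
#' @param ct A [cluster_correct()] table.
#' @param labels Integer array on the same grid (0 = unlabelled).
#' @param names Optional character vector naming label values
#'   (`names[i]` names label `i`).
#' @param significant_only Restrict to significant clusters (default
#'   `TRUE`).
#' @return Data frame with columns `cluster`, `label`, `name`,
#'   `fraction`.
#' @export
label_clusters <- function(ct, labels, names = NULL,
                           significant_only = TRUE) {
  stopifnot(inherits(ct, "cluster_table"))
  voxels <- attr(ct, "voxels")
  rows <- if (significant_only) which(ct$significant) else seq_len(nrow(ct))
  out <- list()
  for (r in rows) {
    lv <- labels[voxels[[r]]]
    tb <- sort(table(lv), decreasing = TRUE)
    lab <- as.integer(base::names(tb))
    nm <- as.character(lab)
    if (!is.null(names)) {
      known <- lab >= 1L & lab <= length(names)
      nm[known] <- names[lab[known]]
    }
    out[[length(out) + 1L]] <- data.frame(
      cluster = ct$id[r], label = lab, name = nm,
      fraction = as.numeric(tb) / length(lv))
  }
  if (length(out) == 0L)
    return(data.frame(cluster = integer(0), label = integer(0),
                      name = character(0), fraction = numeric(0)))
  do.call(rbind, out)
}

#' Dice overlap between a cluster and a reference voxel set
#'
#' @param cluster_voxels Linear voxel indices of a cluster.
#' @param truth_voxels Linear voxel indices of the reference (e.g. a
#'   planted active mask).
#' @return Dice coefficient in [0, 1].
#' @export
dice_overlap <- function(cluster_voxels, truth_voxels) {
  2 * length(intersect(cluster_voxels, truth_voxels)) /
    (length(cluster_voxels) + length(truth_voxels))
}
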