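#' Voxelwise one-sample t map
#'
#' One-sample t statistic against zero at every voxel across subjects.
#' Zero-variance voxels give `NaN`.
#'
#' @param subject_maps list of aligned 3-D arrays (one per subject).
#' @return 3-D t array with attributes `df` and `n`.
#' @export
one_sample_t_map <- function(subject_maps) {
  stopifnot(length(subject_maps) >= 2)
  dims <- dim(subject_maps[[1]])
  stopifnot(all(vapply(subject_maps, function(m)
    identical(dim(m), dims), logical(1))))
  X <- vapply(subject_maps, as.vector, numeric(prod(dims)))
  n <- ncol(X)
  m <- rowMeans(X)
  v <- (rowSums(X^2) - n * m^2) / (n - 1)
  t <- m / sqrt(v / n)
  t[v <= 0] <- NaN
  out <- array(t, dims)
  attr(out, "df") <- n - 1
  attr(out, "n") <- n
  out
}

# Connected components of a set of suprathreshold voxels under 6- or
# 26-connectivity.  Vectorized edge construction (half-neighborhood, so
# each edge is built once) followed by union-find.  Returns an integer
# label per supra voxel.
label_clusters <- function(supra_idx, dims, connectivity = 26) {
  k <- length(supra_idx)
  if (!k) return(integer(0))
  neigh <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  if (connectivity == 6) {
    neigh <- neigh[rowSums(abs(neigh)) == 1, , drop = FALSE]
  } else if (connectivity == 26) {
    neigh <- neigh[rowSums(abs(neigh)) > 0, , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
  # half neighborhood: lexicographically positive offsets only
  half <- neigh[neigh[, 3] > 0 |
                  (neigh[, 3] == 0 & neigh[, 2] > 0) |
                  (neigh[, 3] == 0 & neigh[, 2] == 0 & neigh[, 1] > 0), ,
                drop = FALSE]
  pos <- integer(prod(dims))          # map linear index -> position in set
  pos[supra_idx] <- seq_len(k)
  cc <- arrayInd(supra_idx, dims)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (o in seq_len(nrow(half))) {
    nx <- cc[, 1] + half[o, 1]
    ny <- cc[, 2] + half[o, 2]
    nz <- cc[, 3] + half[o, 3]
    ok <- nx >= 1 & nx <= dims[1] & ny >= 1 & ny <= dims[2] &
      nz >= 1 & nz <= dims[3]
    if (!any(ok)) next
    lin <- nx[ok] + (ny[ok] - 1) * dims[1] + (nz[ok] - 1) * dims[1] * dims[2]
    j <- pos[lin]
    from <- which(ok)[j > 0L]
    to <- j[j > 0L]
    for (e in seq_along(from)) {
      ra <- find(from[e]); rb <- find(to[e])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  match(roots, unique(roots))
}

#' Sign-flip cluster permutation test
#'
#' Group-level nonparametric inference on subject maps: the observed
#' one-sample t map is thresholded at the (positive, one-sided)
#' cluster-forming threshold and clustered under the chosen connectivity;
#' the null distribution of the maximum cluster size is built by randomly
#' negating each subject's map (`n_perm` sign-flip draws).  Clusters whose
#' family-wise p-value `(1 + #{null max >= size}) / (n_perm + 1)` is below
#' `alpha` are retained in the corrected mask.
#'
#' @param subject_maps list of aligned 3-D arrays.
#' @param n_perm number of sign-flip permutations (the emulated analysis
#'   uses 5000).
#' @param cluster_forming_p one-sided p-value defining the cluster-forming
#'   t threshold (the emulated analysis uses 1e-4).
#' @param alpha family-wise error level.
#' @param connectivity 6 or 26 (default) neighborhood.
#' @param seed integer seed.
#' @return An object of class `ca_signflip`: observed `t` array, `clusters`
#'   table (`id`, `size`, `p`, `peak_t`), corrected logical `mask`,
#'   `null_max` sizes and the forming `threshold`.
#' @export
sign_flip_permutation <- function(subject_maps, n_perm = 5000,
                                  cluster_forming_p = 1e-4, alpha = 0.05,
                                  connectivity = 26, seed = 1) {
  stopifnot(length(subject_maps) >= 2, n_perm >= 100)
  dims <- dim(subject_maps[[1]])
  X <- vapply(subject_maps, as.vector, numeric(prod(dims)))
  n <- ncol(X)
  df <- n - 1
  tcrit <- stats::qt(1 - cluster_forming_p, df)
  ss <- rowSums(X^2)  # invariant under sign flips

  t_from_mean <- function(m) {
    v <- (ss - n * m^2) / df
    tv <- m / sqrt(v / n)
    tv[!is.finite(tv)] <- 0
    tv
  }
  cluster_sizes <- function(tv) {
    supra <- which(tv > tcrit)
    if (!length(supra)) return(list(idx = supra, labels = integer(0)))
    list(idx = supra, labels = label_clusters(supra, dims, connectivity))
  }

  t_obs <- t_from_mean(rowMeans(X))
  obs <- cluster_sizes(t_obs)
  null_max <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    means <- (X %*% signs) / n
    vapply(seq_len(n_perm), function(j) {
      cs <- cluster_sizes(t_from_mean(means[, j]))
      if (!length(cs$labels)) 0L else max(tabulate(cs$labels))
    }, integer(1))
  })
  if (length(obs$labels)) {
    sizes <- tabulate(obs$labels)
    clusters <- data.frame(
      id = seq_along(sizes), size = sizes,
      p = vapply(sizes, function(s)
        (1 + sum(null_max >= s)) / (n_perm + 1), numeric(1)),
      peak_t = vapply(seq_along(sizes), function(k)
        max(t_obs[obs$idx[obs$labels == k]]), numeric(1)))
  } else {
    clusters <- data.frame(id = integer(0), size = integer(0),
                           p = numeric(0), peak_t = numeric(0))
  }
  mask <- array(FALSE, dims)
  keep <- clusters$id[clusters$p < alpha]
  if (length(keep))
    mask[obs$idx[obs$labels %in% keep]] <- TRUE
  structure(list(t = array(t_obs, dims), clusters = clusters, mask = mask,
                 null_max = null_max, threshold = tcrit, n_perm = n_perm,
                 alpha = alpha),
            class = "ca_signflip")
}

#' @export
print.ca_signflip <- function(x, ...) {
  cat(sprintf(
    "<ca_signflip> %d permutations, forming t > %.2f; %d cluster(s), %d significant\n",
    x$n_perm, x$threshold, nrow(x$clusters), sum(x$clusters$p < x$alpha)))
  invisible(x)
}

#' Conjunction mask and spherical ROI extraction
#'
#' `conjunction_mask()` intersects two aligned binary masks (voxels
#' surviving correction in both analyses).  `roi_extract()` returns the
#' voxels within `radius_mm` of a peak that also lie inside the surviving
#' mask and the grid.
#'
#' @param mask_a,mask_b aligned 3-D logical/0-1 arrays.
#' @return `conjunction_mask()`: logical array; warns when empty.
#' @export
conjunction_mask <- function(mask_a, mask_b) {
  stopifnot(identical(dim(mask_a), dim(mask_b)))
  out <- (mask_a != 0) & (mask_b != 0)
  if (!any(out)) warning("empty conjunction mask")
  out
}

#' @rdname conjunction_mask
#' @param stat_map 3-D statistic array (defines the grid).
#' @param peak integer voxel coordinates (x, y, z) of the sphere center.
#' @param radius_mm sphere radius in mm.
#' @param voxel_size_mm voxel edge length in mm.
#' @param surviving_mask optional 3-D mask restricting the ROI.
#' @return `roi_extract()`: list with voxel `coords` (matrix), linear
#'   `indices`, and the extracted `values`; warns when empty.
#' @export
roi_extract <- function(stat_map, peak, radius_mm, voxel_size_mm = 2,
                        surviving_mask = NULL) {
  dims <- dim(stat_map)
  stopifnot(length(dims) == 3, length(peak) == 3)
  nb <- sweep(sphere_offsets(radius_mm, voxel_size_mm), 2, peak, "+")
  ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
  nb <- nb[ok, , drop = FALSE]
  lin <- nb[, 1] + (nb[, 2] - 1) * dims[1] + (nb[, 3] - 1) * dims[1] * dims[2]
  if (!is.null(surviving_mask)) {
    keep <- surviving_mask[lin] != 0
    nb <- nb[keep, , drop = FALSE]
    lin <- lin[keep]
  }
  if (!length(lin)) warning("empty ROI")
  list(coords = nb, indices = lin, values = stat_map[lin])
}

#' Brain-behavior regression
#'
#' OLS of per-participant ROI effect sizes (e.g. identity-RSA betas) on
#' credit-assignment estimates, optionally controlling for the learning
#' rate as an additive covariate; a pooled-ROI variant stacks ROIs with an
#' ROI indicator.
#'
#' @param roi_betas numeric vector of per-participant (or stacked
#'   participant x ROI) effect sizes.
#' @param ca aligned credit-assignment estimates.
#' @param lr optional aligned learning-rate covariate.
#' @param roi optional ROI labels for the pooled variant.
#' @return data.frame of coefficients (`term`, `estimate`, `se`, `t`, `p`)
#'   with the fitted `lm` in `attr(, "model")`.
#' @export
brain_behavior_regression <- function(roi_betas, ca, lr = NULL, roi = NULL) {
  stopifnot(length(roi_betas) == length(ca))
  if (length(roi_betas) < 4) stop("need at least 4 observations")
  d <- data.frame(beta = roi_betas, ca = ca)
  f <- "beta ~ ca"
  if (!is.null(lr)) { d$lr <- lr; f <- paste(f, "+ lr") }
  if (!is.null(roi)) { d$roi <- factor(roi); f <- paste(f, "+ roi") }
  fit <- stats::lm(stats::as.formula(f), d)
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    t = sm[, 3], p = sm[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "model") <- fit
  out
}
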