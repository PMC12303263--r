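#' Construct a volume set
#'
#' Container for per-speaker 3D contrast volumes sharing one grid, mask
#' and geometry. Voxel indices are 0-based internally; all reported
#' coordinates are in mm: `mm = origin + index * voxel_size_mm`.
#'
#' @param data 4D array (x, y, z, speaker) or list of identically shaped
#'   3D arrays.
#' @param voxel_size_mm isotropic voxel edge in mm.
#' @param origin mm coordinate of voxel (0,0,0); length-3 numeric.
#' @param mask 3D logical analysis mask; default all-TRUE.
#' @param speaker_ids ids, one per volume.
#' @return A `vm_volume_set`.
#' @export
volume_set <- function(data, voxel_size_mm = 2, origin = NULL, mask = NULL,
                       speaker_ids = NULL) {
  if (is.list(data)) {
    dims <- dim(data[[1]])
    data <- array(unlist(data), dim = c(dims, length(data)))
  }
  if (length(dim(data)) != 4) {
    vm_stop("data must be a 4D array or list of 3D arrays",
            class = "voicemod_validation_error")
  }
  shape <- dim(data)[1:3]
  if (any(shape <= 0)) {
    vm_stop("non-positive grid dimensions", class = "voicemod_validation_error")
  }
  if (is.null(mask)) mask <- array(TRUE, shape)
  if (!identical(dim(mask), as.integer(shape)) || !any(mask)) {
    vm_stop("mask must match the grid and be non-empty",
            class = "voicemod_validation_error")
  }
  if (is.null(origin)) origin <- -(shape - 1) / 2 * voxel_size_mm
  n <- dim(data)[4]
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 origin = as.numeric(origin), mask = mask,
                 speaker_ids = speaker_ids %||% paste0("s", seq_len(n))),
            class = "vm_volume_set")
}

#' Voxelwise covariate regression
#'
#' Random-effects group-level model: at each masked voxel, OLS of the
#' per-speaker contrast values on an intercept, the covariate of interest,
#' and covariates of no interest (age, sex). Returns the t-map for the
#' covariate term and its p-preserving z-map (two-sided p preserved, sign
#' retained); df = n - number of regressors.
#'
#' Voxels with zero variance across speakers get NA in both maps; their
#' count is recorded in `n_degenerate`.
#'
#' @param volumes a [volume_set()].
#' @param covariate numeric vector, one value per speaker (e.g. ED).
#' @param nuisance data.frame of covariates of no interest (e.g. columns
#'   `age`, `sex`), or NULL.
#' @return A `vm_stat_map` list: `t_map`, `z_map` (3D arrays), `df`,
#'   `n_degenerate`, plus geometry copied from the input.
#' @export
voxelwise_regression <- function(volumes, covariate, nuisance = NULL) {
  stopifnot(inherits(volumes, "vm_volume_set"))
  n <- dim(volumes$data)[4]
  if (length(covariate) != n) {
    vm_stop("covariate length %d != %d volumes", length(covariate), n,
            class = "voicemod_validation_error")
  }
  X <- cbind(`(Intercept)` = 1, covariate = covariate)
  if (!is.null(nuisance) && NCOL(nuisance) > 0) {
    zm <- as.data.frame(nuisance)
    if ("sex" %in% names(zm) && !is.numeric(zm$sex)) {
      zm$sex <- as.numeric(vm_normalize_label(zm$sex, c("female", "male")) == "male")
    }
    X <- cbind(X, as.matrix(zm))
  }
  p <- ncol(X)
  if (n <= p) vm_stop("n = %d speakers <= %d regressors", n, p,
                      class = "voicemod_validation_error")
  if (qr(X)$rank < p) vm_stop("rank-deficient voxelwise design",
                              class = "voicemod_rank_error")
  shape <- dim(volumes$data)[1:3]
  vox <- which(volumes$mask)
  Y <- matrix(volumes$data, nrow = prod(shape), ncol = n)[vox, , drop = FALSE]
  Y <- t(Y)                                   # n x V
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)             # p x V
  res <- Y - X %*% B
  df <- n - p
  s2 <- colSums(res^2) / df
  c_cov <- XtXinv[2, 2]
  tvals <- B[2, ] / sqrt(s2 * c_cov)
  # a voxel constant across speakers (zero between-speaker variance up to
  # floating-point noise) carries no information and is excluded
  mu <- colMeans(Y)
  tss_v <- colSums((Y - rep(mu, each = n))^2)
  degenerate <- tss_v <= (n - 1) * (1e-10 * (1 + abs(mu)))^2 |
    !is.finite(tvals)
  tvals[degenerate] <- NA_real_
  t_map <- array(NA_real_, shape); t_map[vox] <- tvals
  z_map <- array(NA_real_, shape); z_map[vox] <- vm_t_to_z(tvals, df)
  structure(list(t_map = t_map, z_map = z_map, df = df,
                 n_degenerate = sum(degenerate),
                 mask = volumes$mask, voxel_size_mm = volumes$voxel_size_mm,
                 origin = volumes$origin),
            class = "vm_stat_map")
}

# sign-retaining p-preserving t -> z transform, numerically stable in the
# tails via log-scale quantiles
vm_t_to_z <- function(t, df) {
  z <- rep(NA_real_, length(t))
  ok <- is.finite(t)
  lp <- stats::pt(abs(t[ok]), df, lower.tail = FALSE, log.p = TRUE)
  z[ok] <- sign(t[ok]) * stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  z
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Kernel sd per axis is `fwhm_mm / voxel_size_mm / (2*sqrt(2*log(2)))`
#' voxels; the kernel is truncated at 4 sd and renormalized (zero-padded
#' boundaries). `fwhm_mm = 0` returns the input unchanged.
#'
#' @param x 3D numeric array.
#' @param fwhm_mm smoothing kernel full width at half maximum, mm.
#' @param voxel_size_mm voxel edge, mm.
#' @return Smoothed array of the same shape.
#' @export
smooth_gaussian <- function(x, fwhm_mm, voxel_size_mm = 2) {
  if (fwhm_mm < 0) vm_stop("fwhm must be >= 0", class = "voicemod_validation_error")
  if (fwhm_mm == 0) return(x)
  sigma <- fwhm_mm / voxel_size_mm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  shape <- dim(x)
  conv_axis <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(a, perm), nrow = d[axis])   # axis-first
    nz <- nrow(m)
    padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    out <- matrix(0, nz, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * padded[i:(i + nz - 1), , drop = FALSE]
    aperm(array(out, dim = d[perm]), order(perm))
  }
  for (ax in 1:3) x <- conv_axis(x, ax)
  x
}

# connectivity offsets: 6 = faces, 18 = faces+edges, 26 = full neighborhood
vm_conn_offsets <- function(connectivity = c(18, 6, 26)) {
  connectivity <- match.arg(as.character(connectivity), c("18", "6", "26"))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(connectivity,
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  g[keep, , drop = FALSE]
}

#' Label connected components of a 3D binary array
#'
#' Breadth-first labeling under 6-, 18- (default) or 26-connectivity.
#'
#' @param binary 3D logical array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of the same shape; 0 outside components,
#'   components numbered from 1 in decreasing size order.
#' @export
label_clusters <- function(binary, connectivity = 18) {
  shape <- dim(binary)
  stopifnot(length(shape) == 3)
  off <- vm_conn_offsets(connectivity)
  labels <- array(0L, shape)
  idx <- which(binary)
  if (length(idx) == 0) return(labels)
  coords <- arrayInd(idx, shape)
  in_set <- array(FALSE, shape); in_set[idx] <- TRUE
  lab <- 0L
  sizes <- integer(0)
  for (start in idx) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    count <- 0L
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer(0)
      count <- count + length(cur)
      cc <- arrayInd(cur, shape)
      for (o in seq_len(nrow(off))) {
        nb <- cc + matrix(off[o, ], nrow(cc), 3, byrow = TRUE)
        ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
              nb[, 2] >= 1 & nb[, 2] <= shape[2] &
              nb[, 3] >= 1 & nb[, 3] <= shape[3]
        if (!any(ok)) next
        nbi <- (nb[ok, 3] - 1L) * (shape[1] * shape[2]) +
               (nb[ok, 2] - 1L) * shape[1] + nb[ok, 1]
        new <- nbi[in_set[nbi] & labels[nbi] == 0L]
        if (length(new) > 0) {
          new <- unique(new)
          labels[new] <- lab
          queue <- c(queue, new)
        }
      }
    }
    sizes <- c(sizes, count)
  }
  # renumber by decreasing size (stable for ties)
  ord <- order(sizes, decreasing = TRUE)
  remap <- integer(lab); remap[ord] <- seq_len(lab)
  pos <- labels != 0L
  labels[pos] <- remap[labels[pos]]
  labels
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates `n_iter` white standard-normal noise volumes, smooths each to
#' the stated FWHM, re-standardizes to unit variance inside the mask,
#' thresholds at the one-tailed `voxel_p` normal quantile, and records the
#' largest cluster per iteration. The returned `k_min` is the smallest
#' cluster size k such that the empirical probability of observing a
#' maximum cluster of at least k voxels is `<= alpha`.
#'
#' The simulation uses the nominal FWHM (no smoothness estimation from
#' residuals) and the supplied mask geometry.
#'
#' @param grid_shape length-3 integer grid dimensions.
#' @param mask 3D logical mask (default full grid).
#' @param fwhm_mm,voxel_size_mm smoothing parameters.
#' @param voxel_p cluster-forming voxel threshold (one-tailed), in (0,1).
#' @param n_iter number of iterations (>= 100).
#' @param alpha cluster-level family-wise error rate.
#' @param seed integer RNG seed (local to this call).
#' @param connectivity cluster connectivity (6/18/26).
#' @return Integer `k_min`, with the simulated per-iteration maxima in
#'   attribute `"max_sizes"`.
#' @export
mc_cluster_threshold <- function(grid_shape, mask = NULL, fwhm_mm = 8,
                                 voxel_size_mm = 2, voxel_p = 0.001,
                                 n_iter = 1000, alpha = 0.05, seed = 1,
                                 connectivity = 18) {
  if (!(voxel_p > 0 && voxel_p < 1)) {
    vm_stop("voxel_p must lie in (0,1)", class = "voicemod_validation_error")
  }
  if (n_iter < 100) vm_stop("n_iter must be >= 100", class = "voicemod_validation_error")
  if (fwhm_mm < 0) vm_stop("fwhm must be >= 0", class = "voicemod_validation_error")
  if (any(grid_shape <= 0)) {
    vm_stop("non-positive grid dimensions", class = "voicemod_validation_error")
  }
  if (is.null(mask)) mask <- array(TRUE, grid_shape)
  if (!any(mask)) vm_stop("degenerate (empty) mask", class = "voicemod_validation_error")
  zc <- stats::qnorm(voxel_p, lower.tail = FALSE)
  max_sizes <- vm_with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      noise <- array(stats::rnorm(prod(grid_shape)), grid_shape)
      sm <- smooth_gaussian(noise, fwhm_mm, voxel_size_mm)
      v <- sm[mask]
      sm_std <- array(0, grid_shape)
      sm_std[mask] <- (v - mean(v)) / stats::sd(v)
      supra <- sm_std > zc & mask
      if (!any(supra)) return(0L)
      labs <- label_clusters(supra, connectivity)
      max(tabulate(labs[labs > 0L]))
    }, integer(1))
  })
  k <- 1L
  while (mean(max_sizes >= k) > alpha) k <- k + 1L
  structure(k, max_sizes = max_sizes)
}

#' Extract suprathreshold clusters and peaks from a statistic map
#'
#' Thresholds the direction-signed t-map at the one-tailed `voxel_p`
#' critical value of t(df), labels connected components, discards those
#' smaller than `k_min`, and reports for each surviving cluster up to
#' `max_peaks` local maxima separated by at least `peak_sep_mm`, with
#' coordinates in mm.
#'
#' @param stat_map a `vm_stat_map` from [voxelwise_regression()].
#' @param voxel_p cluster-forming threshold.
#' @param k_min minimum cluster extent (voxels), e.g. from
#'   [mc_cluster_threshold()].
#' @param direction `"negative"` or `"positive"` covariate effects.
#' @param connectivity 6/18/26.
#' @param peak_sep_mm minimum peak separation, mm.
#' @param max_peaks maximum reported peaks per cluster.
#' @return data.frame with one row per peak: `cluster`, `k`, `region`
#'   (blank; no atlas), `hemisphere` (blank), `x`, `y`, `z`, `T`, `Z`.
#'   Zero rows when nothing survives.
#' @export
extract_clusters <- function(stat_map, voxel_p = 0.001, k_min = 1,
                             direction = c("negative", "positive"),
                             connectivity = 18, peak_sep_mm = 8,
                             max_peaks = 3) {
  direction <- match.arg(direction)
  stopifnot(inherits(stat_map, "vm_stat_map"))
  tmap <- stat_map$t_map
  signed <- if (direction == "negative") -tmap else tmap
  tc <- stats::qt(voxel_p, df = stat_map$df, lower.tail = FALSE)
  supra <- !is.na(signed) & signed > tc & stat_map$mask
  empty <- data.frame(cluster = integer(0), k = integer(0),
                      region = character(0), hemisphere = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      T = numeric(0), Z = numeric(0))
  if (!any(supra)) return(empty)
  labs <- label_clusters(supra, connectivity)
  sizes <- tabulate(labs[labs > 0L])
  keep <- which(sizes >= k_min)
  if (length(keep) == 0) return(empty)
  shape <- dim(tmap)
  rows <- lapply(seq_along(keep), function(ci) {
    lab <- keep[ci]
    vox <- which(labs == lab)
    coords <- arrayInd(vox, shape)                  # 1-based
    vals <- signed[vox]
    ord <- order(vals, decreasing = TRUE)
    mm <- sweep((coords - 1) * stat_map$voxel_size_mm, 2, stat_map$origin, `+`)
    sel <- integer(0)
    for (i in ord) {
      if (length(sel) >= max_peaks) break
      if (length(sel) == 0 ||
          all(sqrt(rowSums((mm[sel, , drop = FALSE] -
                            matrix(mm[i, ], length(sel), 3, byrow = TRUE))^2))
              >= peak_sep_mm)) {
        sel <- c(sel, i)
      }
    }
    data.frame(cluster = ci, k = length(vox), region = "", hemisphere = "",
               x = mm[sel, 1], y = mm[sel, 2], z = mm[sel, 3],
               T = tmap[vox][sel], Z = stat_map$z_map[vox][sel],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # clusters ordered by decreasing size (labels already are)
  out[order(out$cluster, -abs(out$T)), , drop = FALSE]
}
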