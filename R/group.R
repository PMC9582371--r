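#' Voxelwise group t tests
#'
#' One-sample t of the subject maps against zero, or a pooled-variance
#' two-sample t between groups A and B (df = nA + nB - 2, the convention
#' matching t(78)-style reports for 15 vs 65 subjects). Voxels with zero
#' variance get `NA` statistics and are listed in `degenerate`.
#'
#' @param maps_a subjects-by-voxel matrix (or list of equal-length
#'   vectors / `vol_map`s) for group A.
#' @param maps_b optional matrix for group B (two-sample test).
#' @param mask,affine optional geometry to also return `vol_map`s.
#' @return list with `t`, `p` (two-sided), `df`, `n`, `mean_diff`,
#'   `degenerate` (voxel indices), and optional `t_map`, `p_map`.
#' @export
group_ttest <- function(maps_a, maps_b = NULL, mask = NULL, affine = NULL) {
  as_mat <- function(m) {
    if (is.matrix(m)) return(m)
    do.call(rbind, lapply(m, function(x)
      if (inherits(x, "vol_map")) x$values[x$mask] else as.numeric(x)))
  }
  A <- as_mat(maps_a)
  if (nrow(A) < 2) stop("need at least 2 maps per group")
  if (is.null(maps_b)) {
    n <- nrow(A)
    m <- colMeans(A)
    s <- sqrt(colSums(sweep(A, 2, m)^2) / (n - 1))
    se <- s / sqrt(n)
    tval <- m / se
    df <- n - 1
    eff <- m
    nn <- n
  } else {
    B <- as_mat(maps_b)
    if (nrow(B) < 2) stop("need at least 2 maps per group")
    if (ncol(B) != ncol(A)) stop("group maps have mismatched voxel counts")
    na <- nrow(A); nb <- nrow(B)
    ma <- colMeans(A); mb <- colMeans(B)
    va <- colSums(sweep(A, 2, ma)^2); vb <- colSums(sweep(B, 2, mb)^2)
    sp2 <- (va + vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    tval <- (ma - mb) / se
    df <- na + nb - 2
    eff <- ma - mb
    nn <- c(na, nb)
  }
  degenerate <- which(!is.finite(tval))
  tval[degenerate] <- NA_real_
  p <- 2 * pt(-abs(tval), df)
  out <- list(t = tval, p = p, df = df, n = nn, mean_diff = eff,
              degenerate = degenerate)
  if (!is.null(mask)) {
    out$t_map <- vol_map(tval, mask, affine, "t")
    out$p_map <- vol_map(p, mask, affine, "p")
  }
  out
}

# connectivity offsets for 6/18/26 neighbourhoods
conn_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

# label connected components among `idx` (linear indices) on `grid_shape`
connected_components <- function(idx, grid_shape, connectivity = 18) {
  if (length(idx) == 0) return(integer(0))
  off <- conn_offsets(connectivity)
  in_set <- integer(prod(grid_shape))
  in_set[idx] <- seq_along(idx)
  comp <- integer(length(idx))
  cur <- 0L
  for (i in seq_along(idx)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      ijk <- index_to_ijk(idx[v], grid_shape)
      nb <- sweep(off, 2, as.numeric(ijk), `+`)
      ok <- nb[, 1] >= 0 & nb[, 1] < grid_shape[1] &
        nb[, 2] >= 0 & nb[, 2] < grid_shape[2] &
        nb[, 3] >= 0 & nb[, 3] < grid_shape[3]
      nb_idx <- ijk_to_index(nb[ok, , drop = FALSE], grid_shape)
      hits <- in_set[nb_idx]
      hits <- hits[hits > 0]
      hits <- hits[comp[hits] == 0L]
      comp[hits] <- cur
      queue <- c(queue, hits)
    }
  }
  comp
}

#' Threshold a p map and extract clusters
#'
#' Uncorrected thresholds at p < .001 or p < .005, or Benjamini-Hochberg
#' FDR at q = .05 over in-mask voxels. Surviving voxels are grouped into
#' connected components (default 18-connectivity) and summarized with peak
#' world coordinate (mm, from the affine), peak statistic and extent.
#'
#' @param p_map [vol_map()] of p values (or list with `p` vector plus
#'   `mask`).
#' @param method `"unc_001"`, `"unc_005"` or `"fdr_05"`.
#' @param stat_map optional [vol_map()] of the statistic used for peaks
#'   (defaults to -log10 p).
#' @param connectivity 6, 18 or 26.
#' @return list with `binary` (logical 3D array), `clusters` (data.frame:
#'   label, peak_x/y/z mm, peak_stat, k, p_peak) and `n_voxels`.
#' @export
threshold_map <- function(p_map, method = c("unc_001", "unc_005", "fdr_05"),
                          stat_map = NULL, connectivity = 18) {
  method <- match.arg(method)
  stopifnot(inherits(p_map, "vol_map"))
  mask <- p_map$mask
  if (sum(mask) == 0) stop("empty analysis mask")
  pv <- p_map$values[mask]
  if (any(is.finite(pv) & (pv < 0 | pv > 1)))
    stop("p values must lie in [0, 1]")
  sig <- switch(method,
                unc_001 = pv < 0.001,
                unc_005 = pv < 0.005,
                fdr_05 = p.adjust(pv, "BH") < 0.05)
  sig[is.na(sig)] <- FALSE
  bin <- array(FALSE, dim(mask))
  bin[mask][sig] <- TRUE
  idx <- which(bin)
  stat <- if (!is.null(stat_map)) stat_map$values else -log10(p_map$values)
  clusters <- data.frame(label = integer(0), peak_x = numeric(0),
                         peak_y = numeric(0), peak_z = numeric(0),
                         peak_stat = numeric(0), k = integer(0),
                         p_peak = numeric(0))
  if (length(idx) > 0) {
    comp <- connected_components(idx, dim(mask), connectivity)
    clusters <- do.call(rbind, lapply(sort(unique(comp)), function(cc) {
      vox <- idx[comp == cc]
      sv <- stat[vox]
      pk <- vox[which.max(replace(sv, is.na(sv), -Inf))]
      mm <- voxel_to_world(index_to_ijk(pk, dim(mask)), p_map$affine)
      data.frame(label = cc, peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
                 peak_stat = stat[pk], k = length(vox),
                 p_peak = p_map$values[pk])
    }))
    clusters <- clusters[order(-clusters$k), , drop = FALSE]
    clusters$label <- seq_len(nrow(clusters))
    rownames(clusters) <- NULL
  }
  list(binary = bin, clusters = clusters, n_voxels = length(idx),
       method = method)
}
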