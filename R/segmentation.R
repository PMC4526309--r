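# Disc structuring element offsets for radius r (Euclidean).
disc_offsets <- function(r) {
  r <- as.integer(floor(r))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

shift_mask <- function(mask, dr, dc, fill = FALSE) {
  d <- dim(mask)
  out <- matrix(fill, d[1], d[2])
  src_r <- max(1, 1 - dr):min(d[1], d[1] - dr)
  src_c <- max(1, 1 - dc):min(d[2], d[2] - dc)
  out[src_r + dr, src_c + dc] <- mask[src_r, src_c]
  out
}

#' Binary erosion, dilation and opening with a disc
#'
#' Morphological operators on logical matrices with a Euclidean disc
#' structuring element of the given radius (pixels outside the image
#' count as background). `binary_opening()` is erosion followed by
#' dilation — it removes isolated pixel groups smaller than the disc.
#' Radius 0 is the identity.
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels.
#' @return A logical matrix of the same shape.
#' @export
binary_opening <- function(mask, radius = 1) {
  binary_dilate(binary_erode(mask, radius), radius)
}

#' @rdname binary_opening
#' @export
binary_erode <- function(mask, radius = 1) {
  assert_mask(mask)
  if (radius <= 0) return(mask)
  off <- disc_offsets(radius)
  out <- mask
  for (k in seq_len(nrow(off)))
    out <- out & shift_mask(mask, off$dr[k], off$dc[k], fill = FALSE)
  out
}

#' @rdname binary_opening
#' @export
binary_dilate <- function(mask, radius = 1) {
  assert_mask(mask)
  if (radius <= 0) return(mask)
  off <- disc_offsets(radius)
  out <- mask
  for (k in seq_len(nrow(off)))
    out <- out | shift_mask(mask, off$dr[k], off$dc[k], fill = FALSE)
  out
}

#' Connected components of a binary mask
#'
#' Labels connected foreground regions (4- or 8-connectivity) and
#' extracts the largest one.
#'
#' @param mask logical matrix.
#' @param connectivity 4 (edge-sharing neighbours, the default) or 8.
#' @return `label_components()`: an integer matrix of component labels
#'   (0 = background). `largest_component()`: a logical matrix keeping
#'   only the largest component (ties resolve to the smallest label, i.e.
#'   the first component encountered in column-major scan order).
#' @export
label_components <- function(mask, connectivity = 4) {
  assert_mask(mask)
  if (!connectivity %in% c(4, 8)) stop("`connectivity` must be 4 or 8")
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  nb <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  }
  cur <- 0L
  idx_all <- which(mask)
  stack <- integer(length(idx_all))
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    top <- 1L; stack[1L] <- start; lab[start] <- cur
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      pr <- (p - 1L) %% d[1] + 1L
      pc <- (p - 1L) %/% d[1] + 1L
      for (k in seq_len(nrow(nb))) {
        r <- pr + nb[k, 1]; c <- pc + nb[k, 2]
        if (r >= 1L && r <= d[1] && c >= 1L && c <= d[2]) {
          q <- (c - 1L) * d[1] + r
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            top <- top + 1L; stack[top] <- q
          }
        }
      }
    }
  }
  lab
}

#' @rdname label_components
#' @export
largest_component <- function(mask, connectivity = 4) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Segmentation parameters
#'
#' @param opening_radius disc radius (pixels) of the morphological
#'   opening applied after clustering; default 1.
#' @param n_replicates number of k-means restarts (best by within-cluster
#'   inertia); default 10.
#' @param connectivity pixel connectivity (4 or 8) used for the final
#'   largest-component extraction.
#' @param seed integer seed making the clustering deterministic.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(opening_radius = 1, n_replicates = 10,
                                connectivity = 4, seed = NULL) {
  if (opening_radius < 0) stop("`opening_radius` must be >= 0")
  if (n_replicates < 1) stop("`n_replicates` must be >= 1")
  structure(list(n_clusters = 2L, opening_radius = opening_radius,
                 n_replicates = as.integer(n_replicates),
                 connectivity = connectivity, seed = seed),
            class = "segmentation_params")
}

#' Automated lesion segmentation from kinetic maps
#'
#' Segments the lesion inside a rectangular search region: per-pixel
#' (amplitude, wash-in) maps are computed, z-scored within the region
#' (the two features carry different units), and partitioned into 2
#' clusters by k-means; the cluster with the higher mean amplitude is
#' taken as lesion, a morphological opening removes isolated pixel
#' groups, and the largest connected component of enhancing pixels is
#' returned.
#'
#' @param series a [dynamic_series()].
#' @param rect logical matrix marking the search region (`NULL` = whole
#'   frame).
#' @param params a [segmentation_params()].
#' @return A [roi_mask()] of kind `"auto_lesion"`.
#' @export
segment_lesion <- function(series, rect = NULL, params = segmentation_params()) {
  assert_series(series)
  d <- frame_dim(series)
  if (is.null(rect)) rect <- matrix(TRUE, d[1], d[2])
  assert_mask(rect, series)
  if (!any(rect)) stop("empty search region")
  maps <- kinetic_maps(series, rect)
  idx <- which(rect)
  feat <- cbind(amplitude = maps$amplitude[idx], wash_in = maps$wash_in[idx])
  sds <- apply(feat, 2, sd)
  if (any(sds == 0))
    stop("degenerate clustering input: constant ",
         paste(colnames(feat)[sds == 0], collapse = " and "),
         " over the search region (no enhancing pixels to separate)")
  z <- scale(feat)
  km <- with_seed(params$seed,
                  kmeans(z, centers = 2L, nstart = params$n_replicates,
                         iter.max = 100L))
  if (any(km$size == 0L)) stop("degenerate clustering: an empty cluster")
  lesion_cluster <- which.max(tapply(feat[, "amplitude"], km$cluster, mean))
  mask <- matrix(FALSE, d[1], d[2])
  mask[idx[km$cluster == as.integer(lesion_cluster)]] <- TRUE
  mask <- binary_opening(mask, params$opening_radius)
  mask <- largest_component(mask, params$connectivity)
  if (!any(mask))
    stop("segmentation produced an empty mask (opening removed all pixels)")
  roi_mask(mask, "auto_lesion")
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two binary masks of the same
#' shape; defined as 1 when both masks are empty.
#'
#' @param a,b logical matrices.
#' @return A proportion in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}
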