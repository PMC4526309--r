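#' Names of the texture features
#'
#' Nine features derived from the grey-level co-occurrence matrix and
#' eleven from the run-length matrix, in canonical order.
#'
#' @return Character vector of the 20 feature names.
#' @export
texture_feature_names <- function() {
  c("energy", "entropy", "contrast", "homogeneity", "correlation",
    "inv_diff_moment", "sum_average", "sum_variance", "difference_variance",
    "sre", "lre", "gln", "rln", "rp", "lgre", "hgre", "srlge", "srhge",
    "lrlge", "lrhge")
}

#' Grey-level quantization
#'
#' Linear min-max binning of the in-mask intensities into `2^bits` grey
#' levels (default 5 bits = 32 levels); the in-mask maximum maps to the
#' top level. Because the binning is min-max within the analysed region,
#' the result — and hence every texture feature — is invariant under
#' positive affine rescaling of the intensities. A constant region maps
#' entirely to level 0.
#'
#' @param image a [subtract_image()] result or a numeric matrix.
#' @param mask logical matrix selecting the analysed pixels; `NULL` =
#'   whole image.
#' @param bits grey-level depth; levels run 0 .. `2^bits - 1`.
#' @return A list of class `quantized_image`: `levels` (integer matrix,
#'   `NA` outside the mask), `g` (number of levels) and `mask`.
#' @export
quantize <- function(image, mask = NULL, bits = 5) {
  px <- if (inherits(image, "subtracted_image")) image$pixels else image
  if (!is.matrix(px)) stop("`image` must be a matrix or subtracted_image")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(px), ncol(px))
  assert_mask(mask)
  if (!identical(dim(mask), dim(px))) stop("mask shape does not match image")
  if (!any(mask)) stop("empty mask")
  g <- as.integer(2^bits)
  v <- px[mask]
  if (any(!is.finite(v))) stop("non-finite intensities inside the mask")
  rng <- range(v)
  lev <- matrix(NA_integer_, nrow(px), ncol(px))
  if (rng[2] == rng[1]) {
    lev[mask] <- 0L
  } else {
    q <- floor((v - rng[1]) / (rng[2] - rng[1]) * g)
    q[q >= g] <- g - 1L
    lev[mask] <- as.integer(q)
  }
  structure(list(levels = lev, g = g, mask = mask), class = "quantized_image")
}

# The four principal directions as (dr, dc) row/column offsets:
# 0 deg (horizontal), 45 deg, 90 deg (vertical), 135 deg.
texture_directions <- function(directions = c("0", "45", "90", "135")) {
  all <- list("0" = c(0L, 1L), "45" = c(-1L, 1L),
              "90" = c(-1L, 0L), "135" = c(-1L, -1L))
  unknown <- setdiff(directions, names(all))
  if (length(unknown)) stop("unknown direction(s): ", paste(unknown, collapse = ", "))
  all[directions]
}

#' Grey-level co-occurrence matrix
#'
#' Counts ordered pairs of in-mask pixels at distance one in each of the
#' four principal directions (0, 45, 90, 135 degrees), symmetrizes each
#' directional matrix by adding its transpose, pools the directions and
#' normalizes to total 1. After normalization, pooling the four
#' directions and averaging them coincide, so this is the "average over
#' the four main angular relationships". Only pairs whose both pixels
#' lie inside the mask are counted, which makes irregular ROIs exact.
#'
#' @param q a [quantize()]d image.
#' @param directions subset of `c("0", "45", "90", "135")`.
#' @return A list of class `cooc_matrix`: `p` (G x G joint probability
#'   matrix, symmetric, sums to 1), `g`, `n_pairs` (symmetrized count
#'   total).
#' @export
glcm <- function(q, directions = c("0", "45", "90", "135")) {
  if (!inherits(q, "quantized_image")) stop("expected a `quantized_image`")
  dirs <- texture_directions(directions)
  g <- q$g
  lev <- q$levels
  d <- dim(lev)
  counts <- matrix(0, g, g)
  for (off in dirs) {
    dr <- off[1]; dc <- off[2]
    rs <- max(1, 1 - dr):min(d[1], d[1] - dr)
    cs <- max(1, 1 - dc):min(d[2], d[2] - dc)
    a <- lev[rs, cs, drop = FALSE]
    b <- lev[rs + dr, cs + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    dir_counts <- matrix(tabulate(a[ok] * g + b[ok] + 1L, nbins = g * g), g, g,
                         byrow = TRUE)
    counts <- counts + dir_counts + t(dir_counts)
  }
  tot <- sum(counts)
  if (tot == 0) stop("no valid pixel pair in any requested direction")
  structure(list(p = counts / tot, g = g, n_pairs = tot), class = "cooc_matrix")
}

#' Co-occurrence texture features
#'
#' The nine features computed from a normalized co-occurrence matrix,
#' with grey levels indexed 1..G (the classical convention, under which
#' the sum margin runs over k = 2..2G):
#' energy (sum of squared probabilities), entropy (base-2, with
#' 0 log 0 = 0), contrast, homogeneity, correlation, inverse difference
#' moment, sum average, sum variance (centred on the sum average) and
#' difference variance (variance of the |i-j| margin). For a constant
#' region the matrix is a single cell; correlation is then reported as 0
#' with a `degenerate` flag instead of propagating NaN.
#'
#' @param m a [glcm()] result.
#' @return Named numeric vector of the nine features, with attribute
#'   `degenerate` when the grey-level variance is zero.
#' @export
glcm_features <- function(m) {
  if (!inherits(m, "cooc_matrix")) stop("expected a `cooc_matrix`")
  p <- m$p; g <- m$g
  i <- matrix(seq_len(g), g, g)              # row level, 1-based
  j <- t(i)                                  # column level
  energy <- sum(p^2)
  nz <- p > 0
  entropy <- -sum(p[nz] * log2(p[nz]))
  contrast <- sum((i - j)^2 * p)
  homogeneity <- sum(p / (1 + abs(i - j)))
  inv_diff_moment <- sum(p / (1 + (i - j)^2))
  mu_x <- sum(i * p); mu_y <- sum(j * p)
  sig_x <- sqrt(sum((i - mu_x)^2 * p)); sig_y <- sqrt(sum((j - mu_y)^2 * p))
  degenerate <- sig_x * sig_y == 0
  correlation <- if (degenerate) 0 else
    sum((i - mu_x) * (j - mu_y) * p) / (sig_x * sig_y)
  # sum margin p_{x+y}(k), k = 2..2G
  psum <- vapply(2:(2 * g), function(k) sum(p[i + j == k]), numeric(1))
  ks <- 2:(2 * g)
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  # difference margin p_{x-y}(k), k = 0..G-1
  pdiff <- vapply(0:(g - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  kd <- 0:(g - 1)
  difference_variance <- sum(kd^2 * pdiff) - sum(kd * pdiff)^2
  out <- c(energy = energy, entropy = entropy, contrast = contrast,
           homogeneity = homogeneity, correlation = correlation,
           inv_diff_moment = inv_diff_moment, sum_average = sum_average,
           sum_variance = sum_variance,
           difference_variance = difference_variance)
  attr(out, "degenerate") <- degenerate
  out
}

# Decompose one line of levels (NA = outside mask) into maximal runs of
# equal level; returns a list(level, length) per run.
line_runs <- function(v) {
  if (!length(v)) return(NULL)
  seg_id <- cumsum(is.na(v))
  runs_lev <- integer(0); runs_len <- integer(0)
  for (seg in split(v, seg_id)) {
    seg <- seg[!is.na(seg)]
    if (!length(seg)) next
    r <- rle(seg)
    runs_lev <- c(runs_lev, r$values)
    runs_len <- c(runs_len, r$lengths)
  }
  list(level = runs_lev, length = runs_len)
}

# All maximal lines of the lattice along one direction, as vectors of
# levels in traversal order.
direction_lines <- function(lev, dir) {
  d <- dim(lev)
  r <- matrix(seq_len(d[1]), d[1], d[2])
  c <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  key <- if (all(dir == c(0L, 1L))) r            # rows
  else if (all(dir == c(-1L, 0L))) c             # columns
  else if (all(dir == c(1L, 1L)) || all(dir == c(-1L, -1L))) c - r  # diagonals
  else r + c                                      # anti-diagonals
  # column-major order within each key follows the traversal order of
  # the line (increasing column; for anti-diagonals, decreasing row)
  split(as.vector(lev), as.vector(key))
}

#' Grey-level run-length matrix
#'
#' Counts maximal runs of equal grey level along each of the four
#' principal directions, pooled into one G x Lmax matrix `r` where
#' `r[i, j]` is the number of runs of level `i` (grey levels re-indexed
#' 1..G) and length `j`. Runs break at mask boundaries, so only in-mask
#' pixels are counted and the run lengths of an irregular ROI are exact.
#' Each in-mask pixel belongs to exactly one run per direction, hence
#' `sum(j * r[i, j])` equals the number of in-mask pixels times the
#' number of directions.
#'
#' @param q a [quantize()]d image.
#' @param directions subset of `c("0", "45", "90", "135")`.
#' @return A list of class `run_length_matrix`: `r` (count matrix),
#'   `g`, `n_runs`, and `pixel_basis` (total run-length mass, the
#'   denominator of run percentage).
#' @export
rlm <- function(q, directions = c("0", "45", "90", "135")) {
  if (!inherits(q, "quantized_image")) stop("expected a `quantized_image`")
  if (!any(q$mask)) stop("empty mask")
  dirs <- texture_directions(directions)
  g <- q$g
  lmax <- max(dim(q$levels))
  r <- matrix(0, g, lmax)
  for (off in dirs) {
    for (line in direction_lines(q$levels, off)) {
      runs <- line_runs(line)
      if (is.null(runs) || !length(runs$level)) next
      for (k in seq_along(runs$level))
        r[runs$level[k] + 1L, runs$length[k]] <- r[runs$level[k] + 1L, runs$length[k]] + 1
    }
  }
  n_runs <- sum(r)
  if (n_runs == 0) stop("no runs found (empty mask?)")
  structure(list(r = r, g = g, n_runs = n_runs,
                 pixel_basis = sum(r %*% seq_len(lmax))),
            class = "run_length_matrix")
}

#' Run-length texture features
#'
#' The eleven classical run-length statistics, with grey levels indexed
#' i = 1..G (so the low/high grey-level weights 1/i^2 and i^2 are well
#' defined) and run lengths j = 1..Lmax: short/long run emphasis (SRE,
#' LRE), grey-level and run-length non-uniformity (GLN, RLN), run
#' percentage (RP = number of runs over the total run-length mass),
#' low/high grey-level run emphasis (LGRE, HGRE) and the four joint
#' emphases (SRLGE, SRHGE, LRLGE, LRHGE).
#'
#' @param x a [rlm()] result.
#' @return Named numeric vector of the eleven features.
#' @export
rlm_features <- function(x) {
  if (!inherits(x, "run_length_matrix")) stop("expected a `run_length_matrix`")
  r <- x$r
  if (x$n_runs == 0) stop("no runs")
  g <- nrow(r); lmax <- ncol(r)
  i <- matrix(seq_len(g), g, lmax)
  j <- matrix(seq_len(lmax), g, lmax, byrow = TRUE)
  N <- x$n_runs
  c(sre = sum(r / j^2) / N,
    lre = sum(r * j^2) / N,
    gln = sum(rowSums(r)^2) / N,
    rln = sum(colSums(r)^2) / N,
    rp = N / x$pixel_basis,
    lgre = sum(r / i^2) / N,
    hgre = sum(r * i^2) / N,
    srlge = sum(r / (i^2 * j^2)) / N,
    srhge = sum(r * i^2 / j^2) / N,
    lrlge = sum(r * j^2 / i^2) / N,
    lrhge = sum(r * i^2 * j^2) / N)
}

#' All 20 texture features of a masked image
#'
#' Convenience wrapper: quantizes the image within the mask and returns
#' the nine co-occurrence and eleven run-length features as one named
#' vector.
#'
#' @inheritParams quantize
#' @param directions subset of `c("0", "45", "90", "135")`.
#' @return Named numeric vector of length 20 (see
#'   [texture_feature_names()]).
#' @export
texture_features <- function(image, mask = NULL, bits = 5,
                             directions = c("0", "45", "90", "135")) {
  q <- quantize(image, mask, bits)
  out <- c(glcm_features(glcm(q, directions)),
           rlm_features(rlm(q, directions)))
  out[texture_feature_names()]
}

#' Sliding-window texture feature map
#'
#' Computes one co-occurrence feature on the `window x window`
#' neighbourhood around every pixel (quantized within each window), then
#' min-max scales the map to the 0-255 display range. Border pixels
#' whose neighbourhood does not fit are `NA`. A flat map (all values
#' equal) scales to all zeros and carries a `flat = TRUE` attribute.
#'
#' @param image numeric matrix or [subtract_image()] result.
#' @param feature one of the nine co-occurrence feature names.
#' @param window odd neighbourhood size, default 3.
#' @param bits grey-level depth inside each window.
#' @return Numeric matrix scaled to 0-255, attribute `flat`.
#' @export
texture_map <- function(image, feature = "homogeneity", window = 3, bits = 5) {
  px <- if (inherits(image, "subtracted_image")) image$pixels else image
  if (!is.matrix(px)) stop("`image` must be a matrix")
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("`window` must be odd")
  if (window > min(dim(px))) stop("`window` larger than the image")
  glcm_names <- texture_feature_names()[1:9]
  if (!feature %in% glcm_names)
    stop("`feature` must be one of: ", paste(glcm_names, collapse = ", "))
  h <- nrow(px); w <- ncol(px); half <- window %/% 2L
  raw <- matrix(NA_real_, h, w)
  for (r in (1 + half):(h - half)) {
    for (c in (1 + half):(w - half)) {
      crop <- px[(r - half):(r + half), (c - half):(c + half)]
      f <- glcm_features(glcm(quantize(crop, bits = bits)))
      raw[r, c] <- f[[feature]]
    }
  }
  rng <- range(raw, na.rm = TRUE)
  flat <- rng[1] == rng[2]
  out <- if (flat) ifelse(is.na(raw), NA_real_, 0)
  else (raw - rng[1]) / (rng[2] - rng[1]) * 255
  attr(out, "flat") <- flat
  out
}
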