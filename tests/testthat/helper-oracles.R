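# Independent brute-force oracles for the texture matrices and their
# features. Deliberately naive (explicit loops, literal formulas) and
# structurally unrelated to the package implementation.

# GLCM by scanning every pixel and every directional offset, counting
# the ordered pair in both orders (symmetrization), then normalizing.
oracle_glcm <- function(lev, g) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  counts <- matrix(0, g, g)
  for (off in offs) {
    for (r in seq_len(nrow(lev))) {
      for (c in seq_len(ncol(lev))) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 < 1 || r2 > nrow(lev) || c2 < 1 || c2 > ncol(lev)) next
        a <- lev[r, c]; b <- lev[r2, c2]
        if (is.na(a) || is.na(b)) next
        counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
        counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
      }
    }
  }
  counts / sum(counts)
}

# Literal-formula co-occurrence features, grey levels indexed 1..G.
oracle_glcm_features <- function(p) {
  g <- nrow(p)
  energy <- 0; entropy <- 0; contrast <- 0; homog <- 0; idm <- 0
  mu_x <- 0; mu_y <- 0
  for (i in 1:g) for (j in 1:g) {
    energy <- energy + p[i, j]^2
    if (p[i, j] > 0) entropy <- entropy - p[i, j] * log2(p[i, j])
    contrast <- contrast + (i - j)^2 * p[i, j]
    homog <- homog + p[i, j] / (1 + abs(i - j))
    idm <- idm + p[i, j] / (1 + (i - j)^2)
    mu_x <- mu_x + i * p[i, j]
    mu_y <- mu_y + j * p[i, j]
  }
  sx <- 0; sy <- 0; corr_num <- 0
  for (i in 1:g) for (j in 1:g) {
    sx <- sx + (i - mu_x)^2 * p[i, j]
    sy <- sy + (j - mu_y)^2 * p[i, j]
    corr_num <- corr_num + (i - mu_x) * (j - mu_y) * p[i, j]
  }
  correlation <- if (sx * sy == 0) 0 else corr_num / sqrt(sx * sy)
  psum <- rep(0, 2 * g); pdiff <- rep(0, g)     # indices k and k+1
  for (i in 1:g) for (j in 1:g) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }
  sum_average <- 0
  for (k in 2:(2 * g)) sum_average <- sum_average + k * psum[k]
  sum_variance <- 0
  for (k in 2:(2 * g)) sum_variance <- sum_variance + (k - sum_average)^2 * psum[k]
  dmean <- 0; dvar <- 0
  for (k in 0:(g - 1)) dmean <- dmean + k * pdiff[k + 1]
  for (k in 0:(g - 1)) dvar <- dvar + k^2 * pdiff[k + 1]
  c(energy = energy, entropy = entropy, contrast = contrast,
    homogeneity = homog, correlation = correlation, inv_diff_moment = idm,
    sum_average = sum_average, sum_variance = sum_variance,
    difference_variance = dvar - dmean^2)
}

# RLM by explicit line walking in each direction, breaking runs at mask
# exits (NA) and at level changes.
oracle_rlm <- function(lev, g) {
  h <- nrow(lev); w <- ncol(lev)
  lmax <- max(h, w)
  r <- matrix(0, g, lmax)
  add_line <- function(cells) {
    cur_lev <- NA; cur_len <- 0
    flush <- function() {
      if (!is.na(cur_lev) && cur_len > 0)
        r[cur_lev + 1, cur_len] <<- r[cur_lev + 1, cur_len] + 1
    }
    for (v in cells) {
      if (is.na(v)) { flush(); cur_lev <- NA; cur_len <- 0 }
      else if (!is.na(cur_lev) && v == cur_lev) cur_len <- cur_len + 1
      else { flush(); cur_lev <- v; cur_len <- 1 }
    }
    flush()
  }
  for (i in 1:h) add_line(lev[i, ])                       # horizontal
  for (j in 1:w) add_line(lev[, j])                       # vertical
  for (d in (1 - h):(w - 1)) {                            # diagonals  \
    cells <- c()
    for (i in 1:h) { j <- i + d; if (j >= 1 && j <= w) cells <- c(cells, lev[i, j]) }
    add_line(cells)
  }
  for (s in 2:(h + w)) {                                  # anti-diagonals /
    cells <- c()
    for (i in h:1) { j <- s - i; if (j >= 1 && j <= w) cells <- c(cells, lev[i, j]) }
    add_line(cells)
  }
  r
}

# Literal-formula run-length features from a count matrix.
oracle_rlm_features <- function(r) {
  g <- nrow(r); lmax <- ncol(r)
  N <- sum(r); basis <- 0
  sre <- lre <- lgre <- hgre <- srlge <- srhge <- lrlge <- lrhge <- 0
  for (i in 1:g) for (j in 1:lmax) {
    basis <- basis + j * r[i, j]
    sre <- sre + r[i, j] / j^2
    lre <- lre + r[i, j] * j^2
    lgre <- lgre + r[i, j] / i^2
    hgre <- hgre + r[i, j] * i^2
    srlge <- srlge + r[i, j] / (i^2 * j^2)
    srhge <- srhge + r[i, j] * i^2 / j^2
    lrlge <- lrlge + r[i, j] * j^2 / i^2
    lrhge <- lrhge + r[i, j] * i^2 * j^2
  }
  gln <- sum(sapply(1:g, function(i) sum(r[i, ])^2))
  rln <- sum(sapply(1:lmax, function(j) sum(r[, j])^2))
  c(sre = sre / N, lre = lre / N, gln = gln / N, rln = rln / N,
    rp = N / basis, lgre = lgre / N, hgre = hgre / N, srlge = srlge / N,
    srhge = srhge / N, lrlge = lrlge / N, lrhge = lrhge / N)
}

# Random masked test image (values + mask guaranteed to contain at
# least one adjacent in-mask pair).
random_masked_image <- function(h, w, p_mask = 0.8) {
  repeat {
    img <- matrix(rnorm(h * w), h, w)
    mask <- matrix(runif(h * w) < p_mask, h, w)
    if (sum(mask) >= 4 &&
        any(mask[, -1] & mask[, -w])) return(list(img = img, mask = mask))
  }
}

# Small noise-free phantom configs reused across tests.
exact_phantom_config <- function(...) {
  phantom_config(grid_size = c(40, 40), lesion_radii = c(8, 6),
                 lesion_kinetics = c(amplitude = 80, wash_in = 0.5,
                                     wash_out = -0.1),
                 lesion_texture_corr_len = 0, fat_fraction = 0,
                 noise_sd = 0, seed = 1, ...)
}
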