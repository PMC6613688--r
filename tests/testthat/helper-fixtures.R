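# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small default-contrast phantom cohort (4 patients, 6 lesions, drift 0.3).
test_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generate_cohort(4, seed = 42,
                                        lesion_counts = c(2, 1, 2, 1))
  .fixtures$cohort
}

# Compact protocol for cohort-level tests where volume size is irrelevant.
small_protocol <- function() {
  acquisition_protocol(dwi_dim = c(16L, 16L, 4L), t2_dim = c(16L, 16L, 4L),
                       t2w_dim = c(20L, 20L, 4L))
}

# Gaussian feature table: n lesions, p noise features, optional mean shift
# `effect` added to the high class on the first feature.
toy_table <- function(n, p, seed, effect = 0, low_fraction = 0.2) {
  set.seed(seed)
  n_low <- round(low_fraction * n)
  label <- sample(c(rep(-1, n_low), rep(1, n - n_low)))
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  x[label > 0, 1] <- x[label > 0, 1] + effect
  feature_table(seq_len(n), label, x)
}

random_patch <- function(w, seed) {
  set.seed(seed)
  matrix(runif(w * w), w, w)
}

# literal pair-enumeration GLCM oracle: walks every pixel pair at offset
# (dr, dc) in both directions and accumulates the co-occurrence matrix
oracle_glcm <- function(q, d, n_levels = 32L, mask = NULL) {
  offsets <- list(c(0, d), c(-d, d), c(-d, 0), c(-d, -d))
  feats <- matrix(0, 4, 6)
  for (o in seq_along(offsets)) {
    dr <- offsets[[o]][1]; dc <- offsets[[o]][2]
    P <- matrix(0, n_levels, n_levels)
    for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
      if (!is.null(mask) && (!mask[r, cc] || !mask[r2, c2])) next
      i <- q[r, cc] + 1L; j <- q[r2, c2] + 1L
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1
    }
    if (sum(P) == 0) next
    P <- P / sum(P)
    lev <- 0:(n_levels - 1)
    im <- matrix(lev, n_levels, n_levels)
    jm <- t(im)
    mu_i <- sum(P * im); mu_j <- sum(P * jm)
    sd_i <- sqrt(sum(P * (im - mu_i)^2)); sd_j <- sqrt(sum(P * (jm - mu_j)^2))
    feats[o, ] <- c(sum(P * (im - jm)^2),
                    sum(P * abs(im - jm)),
                    sum(P / (1 + (im - jm)^2)),
                    sqrt(sum(P^2)),
                    if (sd_i * sd_j == 0) 1 else
                      sum(P * (im - mu_i) * (jm - mu_j)) / (sd_i * sd_j),
                    sum(P^2))
  }
  means <- colMeans(feats)
  ranges <- apply(feats, 2, function(v) max(v) - min(v))
  as.numeric(rbind(means, ranges))
}

# exhaustive pair-counting AUC oracle (concordant + half ties)
oracle_auc <- function(values, labels) {
  pos <- which(labels > 0); neg <- which(labels < 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (values[i] > values[j]) + 0.5 * (values[i] == values[j])
  tot / (length(pos) * length(neg))
}
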