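# Shared fixtures, built in code. The heavy default objects are created
# once per test run and memoised here.

.fixtures <- new.env(parent = emptyenv())

# An ideal (noise-free, no partial volume, exact R1 coupling) world.
ideal_config <- function(n = 10L, seed = 101L, ...) {
  cohort_config(n_subjects = n, seed = seed, noise_sd_fraction = 0,
                partial_volume = FALSE, blood_r1_noise_sd = 0, ...)
}

# One rendered subject: truth, labels, map pair, oracle masks.
make_case <- function(config, index = 1L) {
  s <- sample_subject(config, index)
  lab <- build_geometry(s)
  maps <- render_t1_pair(lab, s, config)
  list(subject = s, labels = lab, native = maps$native, post = maps$post,
       oracle = segment_oracle(lab))
}

ideal_case <- function() {
  if (is.null(.fixtures$ideal_case))
    .fixtures$ideal_case <- make_case(ideal_config())
  .fixtures$ideal_case
}

noisy_case <- function() {
  if (is.null(.fixtures$noisy_case))
    .fixtures$noisy_case <- make_case(cohort_config(n_subjects = 10L,
                                                    seed = 101L))
  .fixtures$noisy_case
}

# Random binary mask with tunable density.
random_mask <- function(nr, nc, p = 0.5) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# Brute-force 3x3 erosion straight from the definition: keep a voxel iff
# its full 8-neighborhood (raster edge = outside) lies in the mask.
erode_bruteforce <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj])
        ok <- FALSE
    }
    out[i, j] <- ok
  }
  out
}

# Exhaustive Otsu oracle: scan the same 256-bin edge candidates but score
# each split on the raw values (no histogram approximation).
otsu_bruteforce <- function(x, bins = 256L) {
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)[2:bins]
  best <- -Inf; tbest <- NA_real_
  for (t in edges) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(x)
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best + 1e-12) { best <- s; tbest <- t }
  }
  tbest
}

# Hausdorff oracle: explicit loops over boundary voxels.
hausdorff_bruteforce <- function(a, b, spacing_mm = 1) {
  bnd <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    out <- NULL
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!m[i, j]) next
      edge <- FALSE
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || !m[ii, jj])
          edge <- TRUE
      }
      if (edge) out <- rbind(out, c(i, j))
    }
    out
  }
  pa <- bnd(a); pb <- bnd(b)
  directed <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q)))
        best <- min(best, sum((p[i, ] - q[j, ])^2))
      worst <- max(worst, best)
    }
    sqrt(worst)
  }
  spacing_mm * max(directed(pa, pb), directed(pb, pa))
}
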