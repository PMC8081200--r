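# Shared fixtures and independent oracles, all built in code.

# cache expensive fixtures across test files within one run
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# deterministic pseudo-random matrix
rmat <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(runif(nr * nc), nr, nc)
}

random_mask <- function(nr, nc, seed, p = 0.3) {
  set.seed(seed)
  binary_mask(matrix(runif(nr * nc) < p, nr, nc), baseline_row = nr %/% 2L)
}

# two-level "object on background" image with a filled rectangle
two_level_image <- function(nr = 40, nc = 60, lo = 0.1, hi = 0.9,
                            rows = 10:25, cols = 20:45) {
  img <- matrix(lo, nr, nc)
  img[rows, cols] <- hi
  img
}

clean_params <- function(...) {
  synth_params(speckle_sd = 0, bg_noise_sd = 0, salt_frac = 0,
               malform_rate = 0, ...)
}

# one small noisy strip reused across files
small_strip <- function() fixture("small_strip", function() {
  render_strip(synth_params(n_subjects = 1, beats_per_subject = 6, seed = 5),
               subject_seed = 501, subject_id = "S01")
})

clean_strip <- function() fixture("clean_strip", function() {
  render_strip(clean_params(n_subjects = 1, beats_per_subject = 8, seed = 5),
               subject_seed = 777, subject_id = "S01")
})

tiny_cohort <- function() fixture("tiny_cohort", function() {
  generate_cohort(synth_params(n_subjects = 4, beats_per_subject = 4,
                               seed = 23))
})

# ---- independent oracles -------------------------------------------------

# exhaustive Otsu: minimise within-class variance over all 256 bin splits
otsu_oracle_threshold <- function(img) {
  v <- as.vector(img)
  bins <- pmin(pmax(floor(v * 256) + 1L, 1L), 256L)
  h <- tabulate(bins, 256L)
  lev <- (seq_len(256L) - 0.5) / 256
  best_k <- NA_integer_; best <- Inf
  for (k in 1:255) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:k] * lev[1:k]) / w0
    m1 <- sum(h[(k + 1):256] * lev[(k + 1):256]) / w1
    v0 <- sum(h[1:k] * (lev[1:k] - m0)^2) / w0
    v1 <- sum(h[(k + 1):256] * (lev[(k + 1):256] - m1)^2) / w1
    within <- (w0 * v0 + w1 * v1) / sum(h)
    if (within < best) { best <- within; best_k <- k }
  }
  best_k / 256
}

# stack-based flood fill labelling, the reference for component ops
floodfill_oracle <- function(bits, connectivity = 4L) {
  nr <- nrow(bits); nc <- ncol(bits)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4L)
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  else
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!bits[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in nb) {
        r <- p[1] + d[1]; c <- p[2] + d[2]
        if (r >= 1L && r <= nr && c >= 1L && c <= nc &&
            bits[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

remove_small_oracle <- function(bits, min_pixels, connectivity = 4L) {
  lab <- floodfill_oracle(bits, connectivity)
  if (max(lab) == 0L) return(bits)
  sizes <- tabulate(lab[lab > 0L])
  matrix(lab %in% which(sizes >= min_pixels), nrow(bits), ncol(bits))
}

# brute-force per-column envelope scan
contour_oracle <- function(mask) {
  bits <- mask$bits; yb <- mask$baseline_row
  up <- lo <- numeric(ncol(bits))
  for (x in seq_len(ncol(bits))) {
    rows <- which(bits[, x])
    if (length(rows)) {
      vals <- yb - rows
      up[x] <- max(vals); lo[x] <- min(vals)
    }
  }
  list(upper = up, lower = lo)
}
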