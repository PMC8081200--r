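all_binarizers <- function(img, yb = nrow(img) %/% 2L) {
  list(
    otsu = binarize_otsu(img, yb),
    otsu2d = binarize_otsu2d(img, baseline_row = yb),
    steepest = binarize_steepest_gradient(img, yb),
    adaptive = binarize_adaptive(img, baseline_row = yb),
    canny = binarize_canny(img, baseline_row = yb),
    nllap = binarize_nllap(img, baseline_row = yb),
    nllap_sobel = binarize_nllap_sobel(img, baseline_row = yb))
}

test_that("nllap_response matches hand evaluation of the 4-neighbour rule", {
  expect_true(all(nllap_response(matrix(0.5, 8, 8)) == 0))
  # single bright pixel: at the peak grandmax = grandmin = -1, response -2
  img <- matrix(0, 7, 7); img[4, 4] <- 1
  r <- nllap_response(img)
  expect_equal(r[4, 4], -2)
  expect_equal(r[4, 3], 1)    # neighbour: grandmax = +1, grandmin = 0
  # vertical step: opposite signs astride the edge, zero elsewhere
  step <- cbind(matrix(0, 4, 2), matrix(1, 4, 2))
  rs <- nllap_response(step)
  expect_true(all(rs[, 2] > 0))
  expect_true(all(rs[, 3] < 0))
  expect_true(all(rs[, c(1, 4)] == 0))
})

test_that("NLLAP binarisation keeps a high-contrast edge and drops flats", {
  expect_equal(sum(binarize_nllap(matrix(0.3, 20, 20))$bits), 0)
  img <- cbind(matrix(0.05, 30, 15), matrix(0.9, 30, 15))
  m <- binarize_nllap(img)
  expect_gt(sum(m$bits), 0)
  # retained pixels hug the step boundary
  expect_true(all(which(colSums(m$bits) > 0) %in% 14:17))
})

test_that("the NLLAP threshold rule picks l1 on noisy backgrounds", {
  set.seed(8)
  img <- cbind(matrix(0.05, 30, 15), matrix(0.9, 30, 15)) +
    matrix(rnorm(900, 0, 0.05), 30)
  img <- pmin(pmax(img, 0), 1)
  # sigma_th forced below the observed noise -> the strict threshold applies,
  # so the mask is no larger than under the permissive threshold
  strict <- binarize_nllap(img, nllap_config(l1 = 0.5, l2 = 0.1,
                                             m_th = -1, sigma_th = 1e-6))
  loose <- binarize_nllap(img, nllap_config(l1 = 0.5, l2 = 0.1,
                                            m_th = -1, sigma_th = 10))
  expect_lte(sum(strict$bits), sum(loose$bits))
  expect_true(all(loose$bits[strict$bits]))
})

test_that("NLLAP+Sobel is a pixelwise superset of NLLAP alone", {
  img <- small_strip()$strip$pixels[, 1:150]
  a <- binarize_nllap(img)
  b <- binarize_nllap_sobel(img)
  expect_true(all(b$bits[a$bits]))
  expect_equal(sum(binarize_nllap_sobel(matrix(0.2, 10, 10))$bits), 0)
  # Sobel magnitude on a unit step is maximal along the edge columns
  step <- cbind(matrix(0, 10, 8), matrix(1, 10, 8))
  m <- binarize_nllap_sobel(step)
  expect_true(all(colSums(m$bits)[c(8, 9)] > 0))
})

test_that("Canny yields thin connected edges around a bright disk", {
  img <- matrix(0, 64, 64)
  ctr <- 32; rad <- 18
  for (i in 1:64) for (j in 1:64)
    if ((i - ctr)^2 + (j - ctr)^2 <= rad^2) img[i, j] <- 0.9
  m <- binarize_canny(img)
  expect_gt(sum(m$bits), 0)
  # every edge pixel lies within 2 px of the true circle
  idx <- which(m$bits, arr.ind = TRUE)
  dist <- abs(sqrt((idx[, 1] - ctr)^2 + (idx[, 2] - ctr)^2) - rad)
  expect_lt(max(dist), 2.5)
  # the ring forms one closed 8-connected component
  expect_equal(max(label_components(m$bits, 8L)), 1L)
  expect_equal(sum(binarize_canny(matrix(0.5, 20, 20))$bits), 0)
})

test_that("Canny marks a vertical step with a single-pixel line per row", {
  img <- cbind(matrix(0.1, 20, 10), matrix(0.9, 20, 10))
  m <- binarize_canny(img)
  inner <- 3:18                        # away from replicated borders
  expect_true(all(rowSums(m$bits)[inner] == 1))
})

test_that("binarize_otsu equals the exhaustive threshold-search oracle", {
  imgs <- list(
    two_level_image(),
    rmat(40, 40, 3),
    { set.seed(10); matrix(pmin(pmax(c(rnorm(5000, 0.2, 0.05),
                                       rnorm(5000, 0.8, 0.05)), 0), 1), 100) },
    small_strip()$strip$pixels[, 1:120])
  for (img in imgs) {
    m <- binarize_otsu(img)
    thr <- otsu_oracle_threshold(img)
    expect_identical(m$bits, img > thr)
  }
})

test_that("binarize_otsu separates a clean two-level image exactly", {
  img <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
  m <- binarize_otsu(img)
  expect_identical(m$bits, img > 0.5)
  # the bimodal mixture threshold lands between the modes
  thr <- otsu_oracle_threshold(
    { set.seed(2); matrix(pmin(pmax(c(rnorm(5000, 0.2, 0.05),
                                      rnorm(5000, 0.8, 0.05)), 0), 1), 100) })
  expect_gt(thr, 0.35); expect_lt(thr, 0.65)
})

test_that("2D Otsu matches 1D Otsu on noiseless bimodal images", {
  img <- two_level_image()
  expect_identical(binarize_otsu2d(img)$bits, binarize_otsu(img)$bits)
})

test_that("2D Otsu rejects salt noise that fools the 1D threshold", {
  set.seed(21)
  img <- two_level_image(60, 80, lo = 0.1, hi = 0.85,
                         rows = 15:40, cols = 20:60)
  truth <- img > 0.5
  # candidate background at distance > 1 from the object (a bright pixel
  # touching the object legitimately inherits a high neighbourhood median)
  far_bg <- which(!truth &
                    !(row(img) %in% 14:41 & col(img) %in% 19:61))
  salt <- sample(far_bg, round(0.01 * length(far_bg)))
  # keep the salt isolated: drop pixels with another salt pixel in their 3x3
  rc <- arrayInd(salt, dim(img))
  iso <- vapply(seq_along(salt), function(i) {
    d <- abs(rc[, 1] - rc[i, 1]) <= 1 & abs(rc[, 2] - rc[i, 2]) <= 1
    sum(d) == 1
  }, logical(1))
  img[salt[iso]] <- 1
  m2 <- binarize_otsu2d(img)
  m1 <- binarize_otsu(img)
  # isolated salt pixels keep a low neighbourhood median -> excluded in 2D
  expect_equal(sum(m2$bits & !truth), 0)
  expect_gt(sum(m1$bits & !truth), 0)
  expect_gt(sum(m2$bits & truth) / sum(truth), 0.99)
})

test_that("steepest-gradient threshold sits just past the background spike", {
  set.seed(6)
  img <- matrix(0, 50, 40)
  img[sample(2000, 200)] <- 0.8
  m <- binarize_steepest_gradient(img)
  expect_equal(mean(m$bits), 0.1, tolerance = 0.01)
  # generator strip (no blur/noise): foreground tracks the signal fraction
  rs <- render_strip(clean_params(n_subjects = 1, beats_per_subject = 8,
                                  blur_sigma = 0, seed = 5), 777, "S01")
  u <- rs$truth$upper_true; l <- rs$truth$lower_true
  truth_frac <- (sum(round(u)) + sum(round(-l)) + length(u)) /
    length(rs$strip$pixels)
  got_frac <- mean(binarize_steepest_gradient(rs$strip$pixels)$bits)
  expect_lt(abs(got_frac - truth_frac), 0.05)
})

test_that("adaptive percentile threshold equals the global rule on uniform images", {
  img <- rmat(40, 90, 33)
  m <- binarize_adaptive(img, n_regions = 3, pct = 25)
  expect_equal(mean(m$bits), 0.25, tolerance = 0.03)
  gl <- quantile(img, 0.75, names = FALSE)
  expect_gt(mean(m$bits == (img > gl)), 0.95)
})

test_that("adaptive threshold preserves structure across an illumination gap", {
  set.seed(14)
  left <- matrix(runif(40 * 45, 0.5, 0.7), 40)   # bright half
  right <- matrix(runif(40 * 45, 0.0, 0.2), 40)  # dim half, same contrast
  img <- cbind(left, right)
  m <- binarize_adaptive(img)
  fr_left <- mean(m$bits[, 1:40]); fr_right <- mean(m$bits[, 51:90])
  expect_gt(fr_right, 0.10)   # a global threshold would zero the dim half
  expect_lt(abs(fr_left - fr_right), 0.25)
})

test_that("every binarizer maps a constant image to an empty mask", {
  img <- matrix(0.42, 24, 36)
  for (m in all_binarizers(img)) expect_equal(sum(m$bits), 0)
})

test_that("on a noiseless two-level image every method marks the object", {
  img <- two_level_image(40, 60, rows = 12:28, cols = 18:45)
  truth <- img > 0.5
  masks <- all_binarizers(img)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (nm %in% c("canny", "nllap", "nllap_sobel")) {
      # edge methods: the object boundary is covered
      idx <- which(m$bits, arr.ind = TRUE)
      expect_gt(nrow(idx), 0)
      expect_true(all(vapply(seq_len(nrow(idx)), function(i) {
        r <- idx[i, 1]; c <- idx[i, 2]
        any(truth[max(1, r - 1):min(40, r + 1), max(1, c - 1):min(60, c + 1)]) &&
          !all(truth[max(1, r - 2):min(40, r + 2), max(1, c - 2):min(60, c + 2)])
      }, logical(1))))
    } else {
      expect_true(all(m$bits[truth]))
    }
  }
})
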