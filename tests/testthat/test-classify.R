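test_that("one interior beat yields 31 positive windows and a balanced set", {
  p <- clean_params(n_subjects = 1, beats_per_subject = 5, seed = 2)
  rs <- render_strip(p, 99, "S01")
  env <- envelope_pair(rs$truth$upper_true, rs$truth$lower_true,
                       230, p$baseline_row)
  centers <- rs$truth$beat_centers
  interior <- centers[centers > 100 & centers < nrow(env) - 100]
  w <- slide_windows(env, rs$strip, interior[1], shift = 15, seed = 3)
  expect_equal(sum(w$label == "complete"), 31L)    # 1 + 2 x 15
  expect_equal(abs(sum(w$label == "complete") - sum(w$label == "incomplete")),
               0L)
})

test_that("windows truncate at the strip edge and stay in bounds", {
  p <- clean_params(n_subjects = 1, beats_per_subject = 5, seed = 2)
  rs <- render_strip(p, 99, "S01")
  env <- envelope_pair(rs$truth$upper_true, rs$truth$lower_true,
                       230, p$baseline_row)
  w <- slide_windows(env, rs$strip, 60L, shift = 15, seed = 3)  # near left edge
  pos <- w[w$label == "complete", ]
  expect_lt(nrow(pos), 31L)
  expect_true(all(pos$start_col >= 1))
  expect_true(all(pos$start_col + 127 <= nrow(env)))
  expect_error(slide_windows(env[1:100, ], rs$strip, 50L), "128")
})

test_that("per-subject window sets are balanced across a cohort", {
  coh <- generate_cohort(synth_params(n_subjects = 10, beats_per_subject = 4,
                                      seed = 31))
  for (su in coh$subjects) {
    tab <- table(su$windows$label)
    expect_lte(abs(tab[["complete"]] - tab[["incomplete"]]), 1L)
  }
})

test_that("negative windows never coincide with positive window starts", {
  su <- tiny_cohort()$subjects[[1]]
  pos <- su$windows$start_col[su$windows$label == "complete"]
  neg <- su$windows$start_col[su$windows$label == "incomplete"]
  expect_true(all(vapply(neg, function(s) min(abs(s - pos)) > 15, logical(1))))
})

test_that("feature vectors have 264 elements with the documented layout", {
  su <- tiny_cohort()$subjects[[1]]
  tr <- run_chain(mc_chain(), su$strip, keep = TRUE)
  for (s in su$windows$start_col[c(1, 5, 10)]) {
    f <- extract_features(s, tr$envelope, tr$preprocessed,
                          su$strip$baseline_row)
    expect_length(f, 264L)
    expect_true(all(f[1:128] >= 0 & f[1:128] <= 1))     # upper_norm
    expect_true(all(f[129:256] >= -1 & f[129:256] <= 0)) # lower_norm
  }
})

test_that("degenerate and rectangular envelopes give hand-computed features", {
  img <- matrix(0.5, 100, 200)
  env0 <- envelope_pair(numeric(200), numeric(200), 230, 50L)
  f0 <- extract_features(10L, env0, img, 50L)
  expect_equal(f0, rep(0, 264))
  # upper envelope = 20 rows over the first half-window only
  u <- numeric(200); u[10:73] <- 20
  env <- envelope_pair(u, numeric(200), 230, 50L)
  f <- extract_features(10L, env, img, 50L)
  expect_equal(unname(f[257]), 1)        # A1: normalized mean of first half
  expect_equal(unname(f[258]), 0)        # A2
  expect_equal(unname(f[261]), 0.5)      # P1: mean intensity of filled region
  expect_equal(unname(f[262]), 0)        # P2: empty region
})

test_that("the MLP separates constructed blobs and is seed-deterministic", {
  set.seed(12)
  n <- 400
  x <- matrix(rnorm(n * 264, 0, 0.3), n, 264)
  y <- factor(rep(c("incomplete", "complete"), each = n / 2),
              levels = c("incomplete", "complete"))
  x[y == "complete", 1:10] <- x[y == "complete", 1:10] + 2
  m1 <- train_mlp(x, y, seed = 5)
  expect_gte(mean(predict(m1, x) == y) * 100, 99)
  m2 <- train_mlp(x, y, seed = 5)
  expect_identical(predict(m1, x), predict(m2, x))
  expect_true(all(predict(m1, x) %in% c("complete", "incomplete")))
  expect_error(train_mlp(x[y == "complete", ], y[y == "complete"]),
               "single class")
})

test_that("label permutation drives held-out accuracy to chance", {
  set.seed(77)
  n <- 600
  x <- matrix(rnorm(n * 264, 0, 0.3), n, 264)
  x[1:(n / 2), 1:10] <- x[1:(n / 2), 1:10] + 2
  y_perm <- factor(sample(rep(c("incomplete", "complete"), each = n / 2)),
                   levels = c("incomplete", "complete"))
  tr <- 1:400; te <- 401:600
  m <- train_mlp(x[tr, ], y_perm[tr], seed = 9)
  acc <- mean(predict(m, x[te, ]) == y_perm[te]) * 100
  expect_gte(acc, 40); expect_lte(acc, 60)
})

test_that("an independent single-hidden-layer fit agrees on separable data", {
  skip_if_not_installed("nnet")
  set.seed(3)
  n <- 300
  x <- matrix(rnorm(n * 30, 0, 0.3), n, 30)
  y <- factor(rep(c("a", "b"), each = n / 2))
  x[y == "b", 1:5] <- x[y == "b", 1:5] + 2
  te <- sample(n, 100); tr <- setdiff(1:n, te)
  ours <- train_mlp(x[tr, ], y[tr], seed = 2)
  acc_ours <- mean(predict(ours, x[te, ]) == y[te])
  ref <- nnet::nnet(x[tr, ], nnet::class.ind(y[tr]), size = 10,
                    softmax = TRUE, decay = 1e-4, maxit = 200,
                    MaxNWts = 5000, trace = FALSE)
  acc_ref <- mean(levels(y)[max.col(predict(ref, x[te, ]))] == y[te])
  expect_gte(acc_ours, 0.97)
  expect_lt(abs(acc_ours - acc_ref), 0.05)
})

test_that("accuracy implements the confusion-count formula", {
  expect_equal(accuracy(tp = 45, tn = 45, fp = 5, fn = 5), 90)
  expect_equal(accuracy(tp = 50, tn = 50, fp = 0, fn = 0), 100)
  expect_equal(accuracy(tp = 3, tn = 2, fp = 3, fn = 2), 50)
  expect_error(accuracy(tp = 0, tn = 0, fp = 0, fn = 0), "empty")
  expect_error(accuracy(tp = -1, tn = 2, fp = 0, fn = 0), "non-negative")
})
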