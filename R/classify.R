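# Windowing, 264-feature extraction, the 264-10-2 MLP, and accuracy.

WINDOW_WIDTH <- 128L

#' Build labelled beat windows over a traced envelope
#'
#' Positives: for every annotated beat centre, the 128-column window centred
#' on it plus up to 15 windows shifted by one column at a time on either side
#' (windows falling off the strip edge are dropped). Negatives: window start
#' columns farther than the shift radius from every positive window start,
#' sampled uniformly without replacement and count-matched to the positives
#' (so the per-subject set is balanced to within one window when enough
#' candidates exist).
#'
#' @param env an [envelope_pair()] traced over the strip.
#' @param strip the source [doppler_strip()].
#' @param beat_centers integer columns of complete, measurable beats.
#' @param shift maximum positive-window shift (default 15).
#' @param seed seed for the negative sampling.
#' @param stride reserved for inference over unlabeled traces (default 1).
#' @return a tibble with columns `subject_id`, `start_col`, `center_col`,
#'   `label` (`"complete"` / `"incomplete"`).
#' @export
slide_windows <- function(env, strip, beat_centers, shift = 15L, seed = 1L,
                          stride = 1L) {
  n <- nrow(env)
  if (n < WINDOW_WIDTH)
    stop("strip shorter than ", WINDOW_WIDTH, " columns")
  max_start <- n - WINDOW_WIDTH + 1L
  pos_starts <- integer(0)
  for (c0 in beat_centers) {
    base <- c0 - WINDOW_WIDTH %/% 2L + 1L       # centred window start
    s <- (base - shift):(base + shift)
    pos_starts <- c(pos_starts, s[s >= 1L & s <= max_start])
  }
  pos_starts <- sort(unique(pos_starts))
  all_starts <- seq(1L, max_start, by = stride)
  if (length(pos_starts)) {
    near <- vapply(all_starts,
                   function(s) min(abs(s - pos_starts)) <= shift, logical(1))
    neg_cand <- all_starts[!near]
  } else neg_cand <- all_starts
  n_neg <- min(length(pos_starts), length(neg_cand))
  neg_starts <- if (n_neg > 0)
    with_local_seed(seed, sort(sample(neg_cand, n_neg))) else integer(0)
  tibble::tibble(
    subject_id = strip$subject_id,
    start_col = c(pos_starts, neg_starts),
    center_col = c(pos_starts, neg_starts) + WINDOW_WIDTH %/% 2L - 1L,
    label = factor(rep(c("complete", "incomplete"),
                       c(length(pos_starts), length(neg_starts))),
                   levels = c("incomplete", "complete")))
}

# window-local normalization of the two envelopes
normalize_window <- function(u, l) {
  un <- if (max(u) > 0) pmin(pmax(u / max(u), 0), 1) else numeric(length(u))
  ln <- if (min(l) < 0) pmin(pmax(l / abs(min(l)), -1), 0) else
    numeric(length(l))
  list(upper = un, lower = ln)
}

#' Extract the 264-element feature vector of one window
#'
#' Concatenates the window-normalised upper envelope (128 values in \[0,1\]),
#' the normalised lower envelope (128 values in \[-1,0\]), four area features
#' `A1..A4` (mean of the normalised envelope over each half-window: upper
#' first half, upper second half, lower first half, lower second half), and
#' four pixel features `P1..P4` (mean intensity of the strip pixels enclosed
#' between the baseline and the raw envelope in the corresponding half and
#' side, 0 when the region is empty). Pixel means are computed on the image
#' as it enters the binarisation slot (i.e. after preprocessing).
#'
#' @param start_col first column of the 128-wide window.
#' @param env the traced [envelope_pair()].
#' @param img intensity matrix the pixel features are read from.
#' @param baseline_row baseline row index of the strip.
#' @return numeric vector of length 264.
#' @export
extract_features <- function(start_col, env, img, baseline_row) {
  cols <- start_col:(start_col + WINDOW_WIDTH - 1L)
  u <- env$upper[cols]; l <- env$lower[cols]
  nw <- normalize_window(u, l)
  h1 <- seq_len(WINDOW_WIDTH %/% 2L); h2 <- h1 + WINDOW_WIDTH %/% 2L
  a <- c(mean(nw$upper[h1]), mean(nw$upper[h2]),
         mean(nw$lower[h1]), mean(nw$lower[h2]))
  cs <- envelope_pixel_sums(img, baseline_row)
  p <- c(region_pixel_mean(cs$up, u[h1], cols[h1]),
         region_pixel_mean(cs$up, u[h2], cols[h2]),
         region_pixel_mean(cs$down, -l[h1], cols[h1]),
         region_pixel_mean(cs$down, -l[h2], cols[h2]))
  c(nw$upper, nw$lower, a, p)
}

# cumulative column sums moving away from the baseline; cached on the image
envelope_pixel_sums <- function(img, baseline_row) {
  key <- attr(img, "pwd_cs_key")
  cached <- attr(img, "pwd_cs")
  if (!is.null(cached)) return(cached)
  nr <- nrow(img)
  up <- if (baseline_row > 1L)
    apply(img[(baseline_row - 1L):1L, , drop = FALSE], 2, cumsum)
  else matrix(0, 0, ncol(img))
  down <- if (baseline_row < nr)
    apply(img[(baseline_row + 1L):nr, , drop = FALSE], 2, cumsum)
  else matrix(0, 0, ncol(img))
  if (!is.matrix(up)) up <- matrix(up, nrow = 1)
  if (!is.matrix(down)) down <- matrix(down, nrow = 1)
  list(up = up, down = down)
}

# mean intensity between baseline and envelope (inclusive) over a half-window
region_pixel_mean <- function(cs, depth, cols) {
  d <- pmin(pmax(round(depth), 0L), nrow(cs))
  nz <- d > 0
  if (!any(nz)) return(0)
  tot <- sum(cs[cbind(d[nz], cols[nz])])
  tot / sum(d[nz])
}

# feature matrix for a whole window set (rows = windows)
window_feature_matrix <- function(windows, env, img, baseline_row) {
  cs <- envelope_pixel_sums(img, baseline_row)
  attr(img, "pwd_cs") <- cs
  t(vapply(windows$start_col,
           function(s) extract_features(s, env, img, baseline_row),
           numeric(264L)))
}

#' Train the 264-10-2 beat classifier
#'
#' A multi-layer perceptron with 264 inputs, one hidden layer of 10 tanh
#' units, and a two-way softmax output trained by full-batch quasi-Newton
#' minimisation (L-BFGS) of the cross-entropy with a small L2 penalty.
#' Training runs in chunks of iterations with early stopping on a 15%
#' validation split carved from the training data: when the validation
#' cross-entropy stops improving the best-scoring weights are kept. Fully
#' seeded (initial weights and validation split), so identical calls yield
#' identical models.
#'
#' @param x numeric matrix, rows = windows, 264 columns.
#' @param y factor with the two window labels.
#' @param seed integer seed.
#' @param hidden hidden-layer width (fixed at 10 in the study design).
#' @param decay L2 penalty on the weights.
#' @param max_epochs iteration ceiling across all chunks (default 1000).
#' @param chunk_iters iterations per early-stopping chunk.
#' @param patience chunks without validation improvement tolerated.
#' @param val_frac validation fraction (default 0.15).
#' @return an object of class `pwd_mlp`.
#' @export
train_mlp <- function(x, y, seed = 1L, hidden = 10L, decay = 1e-4,
                      max_epochs = 1000L, chunk_iters = 100L, patience = 2L,
                      val_frac = 0.15) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("training set holds a single class; cannot fit the classifier")
  lev <- levels(y)
  n <- nrow(x); d <- ncol(x); k <- nlevels(y)
  split <- with_local_seed(seed, {
    nv <- max(1L, round(val_frac * n))
    sample(n, nv)
  })
  has_val <- length(split) < n && length(split) > 0
  if (has_val) {
    xv <- x[split, , drop = FALSE]; yv <- y[split]
    xt <- x[-split, , drop = FALSE]; yt <- y[-split]
    if (nlevels(droplevels(yt)) < 2L) { xt <- x; yt <- y; has_val <- FALSE }
  } else { xt <- x; yt <- y }
  np <- d * hidden + hidden + hidden * k + k
  theta <- with_local_seed(seed + 1L, stats::runif(np, -0.5, 0.5) / sqrt(d))
  Yt <- stats::model.matrix(~ yt - 1)
  obj <- mlp_objective(xt, Yt, d, hidden, k, decay)
  best <- list(theta = theta,
               val = if (has_val) mlp_val_ce(theta, xv, yv, d, hidden, k)
                     else obj$fn(theta))
  used <- 0L; bad <- 0L
  while (used < max_epochs) {
    it <- min(chunk_iters, max_epochs - used)
    opt <- stats::optim(theta, obj$fn, obj$gr, method = "L-BFGS-B",
                        control = list(maxit = it))
    theta <- opt$par
    used <- used + it
    cur <- if (has_val) mlp_val_ce(theta, xv, yv, d, hidden, k) else opt$value
    if (cur < best$val - 1e-6) {
      best <- list(theta = theta, val = cur); bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
    if (opt$convergence == 0 && !has_val) break
  }
  w <- mlp_unpack(best$theta, d, hidden, k)
  structure(list(W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
                 levels = lev, seed = seed, decay = decay,
                 epochs_used = used, val_ce = best$val,
                 optimizer = "L-BFGS-B"),
            class = "pwd_mlp")
}

mlp_unpack <- function(th, d, h, k) {
  i <- 0L
  W1 <- matrix(th[i + seq_len(d * h)], d, h); i <- i + d * h
  b1 <- th[i + seq_len(h)]; i <- i + h
  W2 <- matrix(th[i + seq_len(h * k)], h, k); i <- i + h * k
  b2 <- th[i + seq_len(k)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

mlp_forward <- function(x, W1, b1, W2, b2) {
  H <- tanh(sweep(x %*% W1, 2, b1, `+`))
  Z <- sweep(H %*% W2, 2, b2, `+`)
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  list(H = H, P = E / rowSums(E))
}

mlp_objective <- function(x, Y, d, h, k, decay) {
  n <- nrow(x)
  fn <- function(th) {
    w <- mlp_unpack(th, d, h, k)
    P <- mlp_forward(x, w$W1, w$b1, w$W2, w$b2)$P
    -sum(Y * log(pmax(P, 1e-12))) / n + decay * sum(th^2)
  }
  gr <- function(th) {
    w <- mlp_unpack(th, d, h, k)
    fw <- mlp_forward(x, w$W1, w$b1, w$W2, w$b2)
    D2 <- (fw$P - Y) / n
    gW2 <- crossprod(fw$H, D2); gb2 <- colSums(D2)
    D1 <- (D2 %*% t(w$W2)) * (1 - fw$H^2)
    gW1 <- crossprod(x, D1); gb1 <- colSums(D1)
    c(as.vector(gW1), gb1, as.vector(gW2), gb2) + 2 * decay * th
  }
  list(fn = fn, gr = gr)
}

mlp_val_ce <- function(th, xv, yv, d, h, k) {
  w <- mlp_unpack(th, d, h, k)
  P <- mlp_forward(xv, w$W1, w$b1, w$W2, w$b2)$P
  Yv <- stats::model.matrix(~ yv - 1)
  -sum(Yv * log(pmax(P, 1e-12))) / nrow(xv)
}

#' @export
print.pwd_mlp <- function(x, ...) {
  cat(sprintf("<pwd_mlp> %d-%d-%d, %s, %d epochs, val CE %.4f\n",
              nrow(x$W1), ncol(x$W1), ncol(x$W2), x$optimizer,
              x$epochs_used, x$val_ce))
  invisible(x)
}

#' Predict window labels
#'
#' @param object a [train_mlp()] model.
#' @param newdata numeric feature matrix.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... unused.
#' @return factor of labels, or a probability matrix.
#' @export
predict.pwd_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  P <- mlp_forward(as.matrix(newdata), object$W1, object$b1,
                   object$W2, object$b2)$P
  colnames(P) <- object$levels
  if (type == "prob") return(P)
  factor(object$levels[max.col(P, ties.method = "first")],
         levels = object$levels)
}

#' Classification accuracy from confusion counts
#'
#' `Acc = 100 * (TP + TN) / (P + N)` where `P = TP + FN` positives and
#' `N = TN + FP` negatives.
#'
#' @param tp,tn,fp,fn non-negative confusion counts; alternatively `tp` may be
#'   a list or one-row data frame with those fields.
#' @return accuracy as a percentage.
#' @export
accuracy <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp)) { c_ <- tp; tp <- c_$tp; tn <- c_$tn; fp <- c_$fp; fn <- c_$fn }
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  total <- tp + fn + tn + fp
  if (total == 0) stop("empty confusion table (P + N = 0)")
  100 * (tp + tn) / total
}

confusion_counts <- function(truth, pred, positive = "complete") {
  tibble::tibble(
    tp = sum(truth == positive & pred == positive),
    tn = sum(truth != positive & pred != positive),
    fp = sum(truth != positive & pred == positive),
    fn = sum(truth == positive & pred != positive))
}
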