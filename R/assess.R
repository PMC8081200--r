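# Leave-one-subject-out evaluation, per-step importance analysis, greedy
# near-optimal chain search, chain-set comparison, and the statistical
# decision logic.

#' Leave-one-subject-out evaluation of a chain
#'
#' Traces every subject's strip with the chain, extracts the 264 features of
#' each labelled window, then runs one cross-validation fold per subject:
#' train the classifier on all other subjects, test on the held-out one, and
#' score fold accuracy from the confusion counts. No test window ever comes
#' from a training subject. Subjects without windows are skipped with a
#' warning. To keep large cohorts tractable the per-fold training set may be
#' capped at `max_train` windows (a seeded uniform subsample); the held-out
#' test set is never subsampled.
#'
#' @param cohort a [generate_cohort()] result or any list of subjects, each a
#'   list with elements `strip` ([doppler_strip()]) and `windows` (tibble from
#'   [slide_windows()]).
#' @param chain a [chain_spec()].
#' @param seed integer seed driving classifier initialisation, validation
#'   splits and training subsamples.
#' @param max_train cap on training windows per fold (`Inf` to disable).
#' @param max_epochs,chunk_iters passed to [train_mlp()].
#' @param cache optional environment shared across chains to reuse
#'   preprocessed images (see [run_chain()]).
#' @return a `chain_evaluation`: fold results, quartiles, mean accuracy.
#' @export
loso_evaluate <- function(cohort, chain, seed = 1L, max_train = 3000L,
                          max_epochs = 300L, chunk_iters = 100L,
                          cache = NULL) {
  subjects <- cohort_subjects(cohort)
  if (length(subjects) < 3L) stop("LOSO needs at least 3 subjects")
  feats <- lapply(subjects, function(su) {
    if (is.null(su$windows) || nrow(su$windows) == 0L) return(NULL)
    tr <- run_chain(chain, su$strip, keep = TRUE, cache = cache)
    list(x = window_feature_matrix(su$windows, tr$envelope, tr$preprocessed,
                                   su$strip$baseline_row),
         y = su$windows$label)
  })
  names(feats) <- vapply(subjects, function(su) su$strip$subject_id, "")
  usable <- !vapply(feats, is.null, logical(1))
  if (any(!usable))
    warning("skipping subjects without windows: ",
            paste(names(feats)[!usable], collapse = ", "))
  feats <- feats[usable]
  folds <- purrr::imap(feats, function(te, sid) {
    tr_x <- do.call(rbind, lapply(feats[names(feats) != sid], `[[`, "x"))
    tr_y <- unlist(lapply(feats[names(feats) != sid],
                          function(f) as.character(f$y)))
    tr_y <- factor(tr_y, levels = levels(te$y))
    if (nrow(tr_x) > max_train) {
      idx <- with_local_seed(seed + match(sid, names(feats)),
                             sample(nrow(tr_x), max_train))
      tr_x <- tr_x[idx, , drop = FALSE]; tr_y <- tr_y[idx]
    }
    model <- train_mlp(tr_x, tr_y, seed = seed, max_epochs = max_epochs,
                       chunk_iters = chunk_iters)
    pred <- predict(model, te$x)
    cc <- confusion_counts(te$y, pred)
    cc$subject_id <- sid
    cc$acc <- accuracy(cc)
    cc
  })
  folds <- dplyr::bind_rows(folds)[, c("subject_id", "tp", "tn", "fp", "fn",
                                       "acc")]
  q <- stats::quantile(folds$acc, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(chain = chain$name, folds = folds,
                 quartiles = c(q1 = q[1], q2 = q[2], q3 = q[3]),
                 mean_acc = mean(folds$acc), seed = seed),
            class = "chain_evaluation")
}

cohort_subjects <- function(cohort) {
  if (inherits(cohort, "pwd_cohort")) cohort$subjects else cohort
}

#' @export
print.chain_evaluation <- function(x, ...) {
  cat(sprintf(
    "<chain_evaluation> %s: %d folds, mean %.1f%%, median %.1f%% [Q1 %.1f, Q3 %.1f]\n",
    x$chain, nrow(x$folds), x$mean_acc, x$quartiles[["q2"]],
    x$quartiles[["q1"]], x$quartiles[["q3"]]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname loso_evaluate
#' @param x a `chain_evaluation`.
#' @param ... unused.
#' @export
tidy.chain_evaluation <- function(x, ...) {
  dplyr::mutate(x$folds, chain = x$chain, .before = 1)
}

#' @rdname loso_evaluate
#' @export
glance.chain_evaluation <- function(x, ...) {
  tibble::tibble(chain = x$chain, n_folds = nrow(x$folds),
                 mean_acc = x$mean_acc, q1 = x$quartiles[["q1"]],
                 median_acc = x$quartiles[["q2"]], q3 = x$quartiles[["q3"]])
}

#' @rdname autoplot-pwdtrace
#' @export
autoplot.chain_evaluation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chain, y = .data$acc)) +
    ggplot2::geom_boxplot(width = 0.4, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "fold accuracy (%)") +
    ggplot2::theme_minimal()
}

# Lilliefors / Kruskal-Wallis / Wilcoxon / paired-t decision logic.
# Distributions first face a Lilliefors composite-normality check; if any is
# non-normal the slot goes nonparametric (Kruskal-Wallis omnibus + pairwise
# two-sided Wilcoxon signed-rank vs the reference), otherwise paired t-tests.
lilliefors_p <- function(x) {
  if (length(unique(x)) < 4L) return(0)          # degenerate: treat non-normal
  tryCatch(nortest::lillie.test(x)$p.value, error = function(e) 0)
}

paired_wilcoxon_p <- function(a, b) {
  if (all(a == b)) return(1)
  suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                      exact = FALSE)$p.value)
}

paired_t_p <- function(a, b) {
  d <- a - b
  if (all(d == 0)) return(1)
  if (stats::sd(d) == 0) return(0)      # constant non-zero shift: t -> infinity
  tryCatch(stats::t.test(a, b, paired = TRUE)$p.value,
           error = function(e) 1)
}

slot_decision <- function(acc_by_chain, ref_name, alpha = 0.05) {
  normal <- vapply(acc_by_chain, function(a) lilliefors_p(a) >= alpha,
                   logical(1))
  parametric <- all(normal)
  others <- setdiff(names(acc_by_chain), ref_name)
  ref <- acc_by_chain[[ref_name]]
  if (parametric) {
    omni_p <- if (length(acc_by_chain) > 2L)
      tryCatch(summary(stats::aov(acc ~ chain, data = data.frame(
        acc = unlist(acc_by_chain),
        chain = rep(names(acc_by_chain),
                    lengths(acc_by_chain)))))[[1]][["Pr(>F)"]][1],
        error = function(e) NA_real_)
    else NA_real_
    pw <- vapply(others, function(nm) paired_t_p(acc_by_chain[[nm]], ref),
                 numeric(1))
    test <- "paired-t"
  } else {
    omni_p <- if (length(acc_by_chain) > 2L)
      stats::kruskal.test(acc_by_chain)$p.value else NA_real_
    pw <- vapply(others, function(nm)
      paired_wilcoxon_p(acc_by_chain[[nm]], ref), numeric(1))
    test <- "wilcoxon"
  }
  list(parametric = parametric, omnibus_p = omni_p, test = test,
       pairwise = tibble::tibble(chain = others, p = unname(pw),
                                 significant = unname(pw) < alpha))
}

#' Assess the importance of every individual step
#'
#' Evaluates the reference chain and its 17 single-substitution chains under
#' leave-one-subject-out cross-validation, groups the fold-accuracy
#' distributions by workflow slot, and applies the statistical decision
#' logic per slot: Lilliefors normality on each distribution; if any is
#' non-normal, a Kruskal-Wallis omnibus over the slot's chains (reference
#' included) plus pairwise two-sided Wilcoxon signed-rank tests against the
#' reference; if all normal, paired t-tests. Significance at p < 0.05.
#'
#' @param cohort a [generate_cohort()] result.
#' @param registry a [build_registry()].
#' @param mc the reference chain.
#' @param seed integer seed.
#' @param ... passed to [loso_evaluate()] (training caps etc.).
#' @return a `step_assessment`: named evaluations (`MC`, `"1"`..`"17"`), a
#'   quartile summary table with one row per chain, and per-slot test
#'   decisions.
#' @export
assess_individual_steps <- function(cohort, registry = build_registry(),
                                    mc = mc_chain(registry), seed = 1L, ...) {
  subs <- enumerate_single_substitutions(registry, mc)
  cache <- new.env(parent = emptyenv())
  evals <- vector("list", length(subs) + 1L)
  names(evals) <- c("MC", names(subs))
  evals[["MC"]] <- loso_evaluate(cohort, mc, seed = seed, cache = cache, ...)
  for (nm in names(subs))
    evals[[nm]] <- loso_evaluate(cohort, subs[[nm]], seed = seed,
                                 cache = cache, ...)
  summary_tbl <- dplyr::bind_rows(lapply(evals, glance))
  # which slot each substitution touches
  mk <- chain_keys(mc)
  slot_of <- vapply(subs, function(ch) {
    SLOT_NAMES[which(chain_keys(ch) != mk)]
  }, "")
  acc_of <- function(nm) evals[[nm]]$folds$acc
  slot_tests <- purrr::map(SLOT_NAMES, function(s) {
    members <- names(slot_of)[slot_of == s]
    dists <- c(list(MC = acc_of("MC")),
               stats::setNames(lapply(members, acc_of), members))
    dec <- slot_decision(dists, "MC")
    tibble::tibble(slot = s, test = dec$test, omnibus_p = dec$omnibus_p,
                   pairwise = list(dec$pairwise))
  })
  slot_tests <- dplyr::bind_rows(slot_tests)
  structure(list(evaluations = evals, summary = summary_tbl,
                 slot_tests = slot_tests, mc = mc, seed = seed),
            class = "step_assessment")
}

#' @export
print.step_assessment <- function(x, ...) {
  cat("<step_assessment>", length(x$evaluations), "chains\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @rdname assess_individual_steps
#' @param x a `step_assessment`.
#' @export
tidy.step_assessment <- function(x, ...) x$summary

#' Greedy near-optimal chain search
#'
#' Walks the six slots in order. For each slot, the current chain is
#' re-evaluated with every pool option in that slot and the option with the
#' highest mean LOSO accuracy is kept (ties favour the incumbent option),
#' after which the search moves to the next slot. With slot sizes
#' (2, 3, 7, 5, 2, 4) this costs exactly 23 chain evaluations and returns a
#' near-optimal ("sub-optimal") chain without exploring all 1680
#' combinations.
#'
#' @inheritParams assess_individual_steps
#' @return a list with elements `chain` (the selected `chain_spec`, named
#'   `"SOC"`), `trace` (per-slot score table) and `evaluation` (the final
#'   chain's `chain_evaluation`).
#' @export
greedy_soc_search <- function(cohort, registry = build_registry(),
                              mc = mc_chain(registry), seed = 1L, ...) {
  keys <- as.list(chain_keys(mc))
  cache <- new.env(parent = emptyenv())
  trace <- list()
  last_eval <- NULL
  for (s in SLOT_NAMES) {
    incumbent <- keys[[s]]
    scores <- numeric(0); evs <- list()
    for (key in names(registry[[s]])) {
      trial <- keys; trial[[s]] <- key
      ch <- chain_spec(trial$pre1, trial$pre2, trial$bin, trial$post,
                       trial$env, trial$envpost,
                       name = paste0(s, "=", key), registry = registry)
      ev <- loso_evaluate(cohort, ch, seed = seed, cache = cache, ...)
      scores[key] <- ev$mean_acc
      evs[[key]] <- ev
    }
    best <- max(scores)
    winner <- if (scores[incumbent] >= best - 1e-12) incumbent
              else names(scores)[which.max(scores)]
    keys[[s]] <- winner
    last_eval <- evs[[winner]]
    trace[[s]] <- tibble::tibble(slot = s, option = names(scores),
                                 mean_acc = unname(scores),
                                 selected = names(scores) == winner)
  }
  soc <- chain_spec(keys$pre1, keys$pre2, keys$bin, keys$post, keys$env,
                    keys$envpost, name = "SOC", registry = registry)
  last_eval$chain <- "SOC"
  list(chain = soc, trace = dplyr::bind_rows(trace), evaluation = last_eval)
}

#' Compare a set of chain evaluations
#'
#' Kruskal-Wallis omnibus across all chains plus pairwise two-sided Wilcoxon
#' signed-rank tests of each chain against a reference (typically the
#' greedy-search chain), on matched LOSO folds. All evaluations must share
#' the same fold structure.
#'
#' @param evals named list of `chain_evaluation`s.
#' @param reference name of the reference evaluation (default the first).
#' @param alpha significance level (default 0.05).
#' @return a list with `omnibus_p` and a tibble `pairwise` (chain, median,
#'   p, significant) including one row per input chain.
#' @export
compare_chain_sets <- function(evals, reference = names(evals)[1],
                               alpha = 0.05) {
  stopifnot(length(evals) >= 2L, reference %in% names(evals))
  subj <- lapply(evals, function(e) e$folds$subject_id)
  if (length(unique(lengths(subj))) != 1L ||
      !all(vapply(subj, function(s) identical(sort(s), sort(subj[[1]])),
                  logical(1))))
    stop("chain evaluations have mismatched fold structures")
  acc <- lapply(evals, function(e)
    e$folds$acc[order(e$folds$subject_id)])
  omni <- stats::kruskal.test(acc)$p.value
  ref <- acc[[reference]]
  pw <- purrr::imap(acc, function(a, nm) {
    p <- if (nm == reference) 1 else paired_wilcoxon_p(a, ref)
    tibble::tibble(chain = nm, median_acc = stats::median(a), p = p,
                   significant = p < alpha)
  })
  list(omnibus_p = omni, pairwise = dplyr::bind_rows(pw),
       reference = reference)
}
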