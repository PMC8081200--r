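# small evaluation settings reused throughout (tiny cohorts, capped training)
fast_opts <- list(max_train = 400L, max_epochs = 80L, chunk_iters = 40L)

fast_eval <- function(cohort, chain, seed = 1L, cache = NULL) {
  loso_evaluate(cohort, chain, seed = seed, max_train = fast_opts$max_train,
                max_epochs = fast_opts$max_epochs,
                chunk_iters = fast_opts$chunk_iters, cache = cache)
}

test_that("LOSO produces one disjoint fold per subject", {
  coh <- tiny_cohort()
  ev <- fast_eval(coh, mc_chain())
  ids <- vapply(coh$subjects, function(s) s$strip$subject_id, "")
  expect_equal(nrow(ev$folds), length(ids))
  expect_setequal(ev$folds$subject_id, ids)
  expect_equal(anyDuplicated(ev$folds$subject_id), 0L)
  # fold accuracy is consistent with its confusion counts
  expect_equal(ev$folds$acc,
               100 * (ev$folds$tp + ev$folds$tn) /
                 (ev$folds$tp + ev$folds$tn + ev$folds$fp + ev$folds$fn))
  expect_true(all(diff(unname(ev$quartiles)) >= 0))
})

test_that("LOSO on a clean, separable cohort scores near-perfect folds", {
  coh <- fixture("clean_cohort", function()
    generate_cohort(clean_params(n_subjects = 5, beats_per_subject = 6,
                                 seed = 41)))
  ev <- fast_eval(coh, mc_chain())
  expect_gte(min(ev$folds$acc), 95)
  expect_equal(unname(ev$quartiles[["q2"]]), 100, tolerance = 0.03)
})

test_that("tidy and glance expose fold results and quartiles", {
  coh <- tiny_cohort()
  ev <- fast_eval(coh, mc_chain())
  td <- tidy(ev)
  expect_true(all(c("chain", "subject_id", "tp", "tn", "fp", "fn", "acc")
                  %in% names(td)))
  gl <- glance(ev)
  expect_equal(gl$n_folds, nrow(ev$folds))
  expect_equal(gl$median_acc, unname(ev$quartiles[["q2"]]))
})

test_that("the paired-test decision logic behaves on constructed vectors", {
  a <- c(90, 92, 95, 91, 97, 93, 96, 94, 92, 95, 98, 91, 90, 96, 93,
         94, 92, 97, 95, 93, 91, 96, 94, 92, 95)
  dec_same <- pwdtrace:::slot_decision(list(MC = a, x = a), "MC")
  expect_false(dec_same$pairwise$significant[1])
  expect_equal(dec_same$pairwise$p[1], 1)
  dec_shift <- pwdtrace:::slot_decision(list(MC = a, x = a - 10), "MC")
  expect_true(dec_shift$pairwise$significant[1])
  expect_lt(dec_shift$pairwise$p[1], 0.05)
})

test_that("step assessment covers the 18 chains with per-slot decisions", {
  coh <- tiny_cohort()
  asmt <- assess_individual_steps(coh, seed = 2, max_train = fast_opts$max_train,
                                  max_epochs = fast_opts$max_epochs,
                                  chunk_iters = fast_opts$chunk_iters)
  expect_equal(nrow(asmt$summary), 18L)
  expect_setequal(asmt$summary$chain, c("MC", as.character(1:17)))
  expect_true(all(c("q1", "median_acc", "q3") %in% names(asmt$summary)))
  expect_equal(nrow(asmt$slot_tests), 6L)
  # pairwise tables cover the slot's substitutions
  sizes <- vapply(asmt$slot_tests$pairwise, nrow, integer(1))
  expect_equal(unname(sizes), c(1L, 2L, 6L, 4L, 1L, 3L))
})

test_that("greedy search spends 23 evaluations, never regresses, keeps the best", {
  coh <- fixture("clean_cohort", function()
    generate_cohort(clean_params(n_subjects = 5, beats_per_subject = 6,
                                 seed = 41)))
  soc <- greedy_soc_search(coh, seed = 2, max_train = fast_opts$max_train,
                           max_epochs = fast_opts$max_epochs,
                           chunk_iters = fast_opts$chunk_iters)
  expect_equal(nrow(soc$trace), 23L)    # 2+3+7+5+2+4 chain evaluations
  expect_equal(sum(soc$trace$selected), 6L)
  sel <- soc$trace[soc$trace$selected, ]
  expect_true(all(diff(sel$mean_acc) >= -1e-9))  # keep-best never decreases
  expect_s3_class(soc$chain, "chain_spec")
  expect_equal(soc$chain$name, "SOC")
  # selected options are drawn from their slots and score at the slot maximum
  reg <- build_registry()
  for (i in seq_len(nrow(sel)))
    expect_true(sel$option[i] %in% names(reg[[sel$slot[i]]]))
  for (s in unique(soc$trace$slot)) {
    sc <- soc$trace[soc$trace$slot == s, ]
    expect_gte(sc$mean_acc[sc$selected], max(sc$mean_acc) - 1e-9)
  }
})

test_that("chain-set comparison flags chance-level chains against the best", {
  coh <- tiny_cohort()
  cache <- new.env(parent = emptyenv())
  ev_mc <- fast_eval(coh, mc_chain(), seed = 4, cache = cache)
  ev_canny <- fast_eval(coh, enumerate_single_substitutions()[["4"]],
                        seed = 4, cache = cache)
  cmp <- compare_chain_sets(list(MC = ev_mc, MC2 = ev_mc, canny = ev_canny),
                            reference = "MC")
  expect_equal(nrow(cmp$pairwise), 3L)
  expect_false(cmp$pairwise$significant[cmp$pairwise$chain == "MC"])
  expect_false(cmp$pairwise$significant[cmp$pairwise$chain == "MC2"])
  # mismatched fold structures are refused
  ev_short <- ev_canny
  ev_short$folds <- ev_short$folds[-1, ]
  expect_error(compare_chain_sets(list(MC = ev_mc, bad = ev_short)),
               "mismatched")
})
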