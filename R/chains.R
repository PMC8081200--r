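# The six-slot registry, the main work chain (MC), substitution enumeration,
# literature chains, random chains, and chain execution.

SLOT_NAMES <- c("pre1", "pre2", "bin", "post", "env", "envpost")

step_option <- function(slot, key, params = list()) {
  list(slot = slot, key = key, params = params)
}

#' Build the six-slot step registry
#'
#' The pool of 23 interchangeable processing options drawn from the published
#' Doppler-envelope tracing methods, organised by workflow slot:
#' slot 1 smoothing (2 options), slot 2 contrast (3), slot 3 binarisation (7),
#' slot 4 mask clean-up (5), slot 5 envelope extraction (2), slot 6 envelope
#' smoothing (4). Identity ("none") options count as pool members in slots
#' 1, 2 and 4, matching the published chains that skip those phases.
#'
#' @return a `step_registry`: a named list of slots, each a named list of
#'   option descriptors with their frozen default parameters.
#' @export
build_registry <- function() {
  reg <- list(
    pre1 = list(
      gaussian = step_option("pre1", "gaussian", list(sigma = 1.5)),
      none = step_option("pre1", "none")),
    pre2 = list(
      kmeans = step_option("pre2", "kmeans", list(k = 3L)),
      intensity_adjust = step_option("pre2", "intensity_adjust",
                                     list(disk_radius = 5L)),
      none = step_option("pre2", "none")),
    bin = list(
      otsu2d = step_option("bin", "otsu2d", list(neighborhood = 3L)),
      canny = step_option("bin", "canny", list(sigma = 0.5)),
      nllap = step_option("bin", "nllap", list()),
      nllap_sobel = step_option("bin", "nllap_sobel", list()),
      adaptive = step_option("bin", "adaptive",
                             list(n_regions = 3L, pct = 25)),
      steepest = step_option("bin", "steepest", list()),
      otsu = step_option("bin", "otsu", list())),
    post = list(
      mo70 = step_option("post", "mo70",
                         list(min_pixels = 70L, connectivity = 4L)),
      region_grow = step_option("post", "region_grow",
                                list(min_pixels = 70L)),
      mo500 = step_option("post", "mo500",
                          list(min_pixels = 500L, connectivity = 4L)),
      mo50 = step_option("post", "mo50",
                         list(min_pixels = 50L, connectivity = 4L)),
      none = step_option("post", "none")),
    env = list(
      contour = step_option("env", "contour"),
      biggest_gap = step_option("env", "biggest_gap")),
    envpost = list(
      median3 = step_option("envpost", "median3", list(taps = 3L)),
      avg5 = step_option("envpost", "avg5", list(taps = 5L)),
      median15 = step_option("envpost", "median15", list(taps = 15L)),
      butterworth = step_option("envpost", "butterworth",
                                list(cutoff_hz = 70))))
  structure(reg, class = "step_registry")
}

#' @export
print.step_registry <- function(x, ...) {
  cat("<step_registry> 6 slots,", sum(lengths(x)), "options\n")
  for (s in names(x))
    cat(sprintf("  %-8s: %s\n", s, paste(names(x[[s]]), collapse = ", ")))
  invisible(x)
}

#' Assemble a processing chain
#'
#' A `chain_spec` fills all six workflow slots with one option each; outside
#' the registry pool, the identity option `"none"` is additionally accepted in
#' the envelope-smoothing slot so that literature chains lacking that phase
#' can be expressed.
#'
#' @param pre1,pre2,bin,post,env,envpost option keys per slot.
#' @param name chain label.
#' @param registry a [build_registry()] supplying default parameters.
#' @param params named list of per-slot parameter overrides, e.g.
#'   `list(post = list(dilate_first = TRUE))`.
#' @return a `chain_spec`.
#' @export
chain_spec <- function(pre1, pre2, bin, post, env, envpost, name = "chain",
                       registry = build_registry(), params = list()) {
  keys <- list(pre1 = pre1, pre2 = pre2, bin = bin, post = post,
               env = env, envpost = envpost)
  opts <- lapply(SLOT_NAMES, function(s) {
    key <- keys[[s]]
    opt <- registry[[s]][[key]]
    if (is.null(opt)) {
      if (key == "none" && s == "envpost")
        opt <- step_option(s, "none")
      else stop("unknown option '", key, "' for slot ", s)
    }
    if (!is.null(params[[s]])) opt$params <- utils::modifyList(opt$params,
                                                               params[[s]])
    opt
  })
  names(opts) <- SLOT_NAMES
  structure(list(name = name, options = opts), class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("<chain_spec> %s: %s\n", x$name,
              paste(vapply(x$options, `[[`, "", "key"), collapse = " > ")))
  invisible(x)
}

#' @export
format.chain_spec <- function(x, ...) {
  paste(vapply(x$options, `[[`, "", "key"), collapse = ">")
}

chain_keys <- function(chain) vapply(chain$options, `[[`, "", "key")

#' The main work chain (MC)
#'
#' The reference chain against which every substitution is judged: Gaussian
#' smoothing (sigma 1.5), k-means contrast stretching, 2D Otsu binarisation,
#' removal of components below 70 four-connected pixels, white-region contour
#' extraction, and a 3-tap temporal median filter.
#'
#' @param registry a [build_registry()].
#' @return a `chain_spec` named `"MC"`.
#' @export
mc_chain <- function(registry = build_registry()) {
  chain_spec("gaussian", "kmeans", "otsu2d", "mo70", "contour", "median3",
             name = "MC", registry = registry)
}

#' Enumerate all single-substitution chains
#'
#' Every chain differing from the reference chain in exactly one slot, one
#' per non-reference pool option: with 23 pool options over 6 slots this
#' yields 23 - 6 = 17 chains, numbered by slot order and within-slot registry
#' order (the published numbering).
#'
#' @param registry a [build_registry()].
#' @param mc the reference chain (default [mc_chain()]).
#' @return a named list of 17 `chain_spec`s, names `"1"`..`"17"`.
#' @export
enumerate_single_substitutions <- function(registry = build_registry(),
                                           mc = mc_chain(registry)) {
  mk <- chain_keys(mc)
  out <- list()
  i <- 0L
  for (s in SLOT_NAMES) {
    for (key in names(registry[[s]])) {
      if (key == mk[[s]]) next
      i <- i + 1L
      keys <- as.list(mk)
      keys[[s]] <- key
      out[[as.character(i)]] <- chain_spec(
        keys$pre1, keys$pre2, keys$bin, keys$post, keys$env, keys$envpost,
        name = as.character(i), registry = registry)
    }
  }
  out
}

#' The seven literature chains
#'
#' The published tracing chains, assembled from registry options. Slots a
#' publication left unspecified are filled with the identity option, except
#' the envelope-extraction slot, which follows the contour method of the
#' latest published chain when unstated; the unspecified spurious-area size of
#' one chain maps to the smallest stated pool value (50 pixels).
#'
#' @param registry a [build_registry()].
#' @return a named list of `chain_spec`s.
#' @export
literature_chains <- function(registry = build_registry()) {
  list(
    tschirren = chain_spec("gaussian", "none", "nllap", "region_grow",
                           "biggest_gap", "avg5", name = "tschirren",
                           registry = registry),
    greenspan = chain_spec("gaussian", "kmeans", "nllap_sobel", "mo50",
                           "biggest_gap", "none", name = "greenspan",
                           registry = registry),
    syeda_mahmood = chain_spec("none", "none", "otsu", "mo50", "contour",
                               "median3", name = "syeda_mahmood",
                               registry = registry,
                               params = list(post = list(dilate_first = TRUE))),
    magagnin = chain_spec("none", "none", "adaptive", "none", "contour",
                          "median15", name = "magagnin", registry = registry),
    kiruthika = chain_spec("gaussian", "intensity_adjust", "canny", "none",
                           "contour", "none", name = "kiruthika",
                           registry = registry),
    zolgharni = chain_spec("none", "none", "steepest", "mo500", "biggest_gap",
                           "butterworth", name = "zolgharni",
                           registry = registry),
    sulas = chain_spec("none", "none", "otsu2d", "mo70", "contour", "none",
                       name = "sulas", registry = registry))
}

#' Draw a random chain from the registry pool
#'
#' One independent uniform draw per slot, reproducible by seed; used as the
#' "does composition even matter" control in chain comparisons.
#'
#' @param registry a [build_registry()].
#' @param seed integer seed.
#' @return a `chain_spec` named `"random:<seed>"`.
#' @export
random_chain <- function(registry = build_registry(), seed = 1L) {
  keys <- with_local_seed(seed, {
    vapply(SLOT_NAMES, function(s) sample(names(registry[[s]]), 1L), "")
  })
  chain_spec(keys[["pre1"]], keys[["pre2"]], keys[["bin"]], keys[["post"]],
             keys[["env"]], keys[["envpost"]],
             name = paste0("random:", seed), registry = registry)
}

# evaluate expr under a local RNG seed without touching the global stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Run a processing chain on a strip
#'
#' Applies the six slots in order: smoothing, contrast, binarisation, mask
#' clean-up, envelope extraction, envelope smoothing. Deterministic given the
#' chain parameters. Operator errors propagate with the slot name attached.
#'
#' @param chain a `chain_spec`.
#' @param strip a [doppler_strip()], already in positive balance.
#' @param keep also return the intermediate preprocessed image and mask.
#' @param cache optional environment reusing preprocessed images across chains
#'   sharing slots 1-2 (keyed by subject and slot keys); used by the
#'   assessment loops.
#' @return an [envelope_pair()]; with `keep = TRUE`, a list with elements
#'   `envelope`, `mask`, `preprocessed`.
#' @export
run_chain <- function(chain, strip, keep = FALSE, cache = NULL) {
  stopifnot(inherits(chain, "chain_spec"), inherits(strip, "doppler_strip"))
  o <- chain$options
  slot_try <- function(slot, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[slot %s:%s] %s", slot, o[[slot]]$key,
                   conditionMessage(e)), call. = FALSE))
  }
  ck <- if (!is.null(cache))
    paste(strip$subject_id, o$pre1$key, o$pre2$key,
          rlang::hash(list(o$pre1$params, o$pre2$params)), sep = "|")
  img <- if (!is.null(cache) && !is.null(cache[[ck]])) cache[[ck]] else {
    im <- strip$pixels
    im <- slot_try("pre1", switch(o$pre1$key,
      gaussian = gaussian_smooth(im, o$pre1$params$sigma),
      none = im,
      stop("unknown option")))
    im <- slot_try("pre2", switch(o$pre2$key,
      kmeans = contrast_stretch(im, fit_contrast_thresholds(im,
                                                            o$pre2$params$k)),
      intensity_adjust = intensity_adjust(im, o$pre2$params$disk_radius),
      none = im,
      stop("unknown option")))
    if (!is.null(cache)) cache[[ck]] <- im
    im
  }
  yb <- strip$baseline_row
  p <- o$bin$params
  mask <- slot_try("bin", switch(o$bin$key,
    otsu2d = binarize_otsu2d(img, p$neighborhood, baseline_row = yb),
    canny = binarize_canny(img, p$sigma, baseline_row = yb),
    nllap = binarize_nllap(img, baseline_row = yb),
    nllap_sobel = binarize_nllap_sobel(img, baseline_row = yb),
    adaptive = binarize_adaptive(img, p$n_regions, p$pct, baseline_row = yb),
    steepest = binarize_steepest_gradient(img, baseline_row = yb),
    otsu = binarize_otsu(img, baseline_row = yb),
    stop("unknown option")))
  p <- o$post$params
  mask <- slot_try("post", switch(o$post$key,
    mo70 = ,
    mo500 = ,
    mo50 = remove_small_components(mask, p$min_pixels, p$connectivity,
                                   dilate_first = isTRUE(p$dilate_first)),
    region_grow = region_growing_cleanup(mask, p$min_pixels),
    none = identity_post(mask),
    stop("unknown option")))
  env <- slot_try("env", switch(o$env$key,
    contour = extract_contour(mask, strip$column_rate),
    biggest_gap = extract_biggest_gap(mask, strip$column_rate),
    stop("unknown option")))
  p <- o$envpost$params
  env <- slot_try("envpost", switch(o$envpost$key,
    median3 = ,
    median15 = median_smooth(env, p$taps),
    avg5 = moving_average_smooth(env, p$taps),
    butterworth = butterworth_smooth(env, p$cutoff_hz),
    none = identity_envpost(env),
    stop("unknown option")))
  if (keep) list(envelope = env, mask = mask, preprocessed = img) else env
}

#' Serialise chains to JSON
#'
#' @param chains a `chain_spec` or list of them.
#' @param path optional output file.
#' @return the JSON string, invisibly when written to `path`.
#' @export
chains_to_json <- function(chains, path = NULL) {
  if (inherits(chains, "chain_spec")) chains <- list(chains)
  lst <- lapply(chains, function(ch) {
    c(list(name = ch$name), lapply(ch$options, function(o) o$key))
  })
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
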