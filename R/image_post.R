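# Slot-4 options: morphological clean-up of binary masks.

#' Label connected foreground components
#'
#' 4-connected labelling is delegated to `EBImage::bwlabel`; 8-connectivity is
#' obtained by merging 4-connected labels across diagonal adjacencies (via
#' graph components), since `bwlabel` itself is 4-connected.
#'
#' @param bits logical matrix (or a [binary_mask()]).
#' @param connectivity 4 or 8.
#' @return integer matrix of labels, 0 for background.
#' @export
label_components <- function(bits, connectivity = 4L) {
  if (inherits(bits, "binary_mask")) bits <- bits$bits
  stopifnot(connectivity %in% c(4L, 8L))
  lab <- matrix(as.integer(EBImage::bwlabel(bits * 1)), nrow(bits), ncol(bits))
  nmax <- max(lab)
  if (connectivity == 4L || nmax < 2L) return(lab)
  pairs <- NULL
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nrow(lab) - 1L),
             if (off[2] > 0) seq_len(ncol(lab) - 1L) else 2L:ncol(lab),
             drop = FALSE]
    b <- lab[2L:nrow(lab),
             if (off[2] > 0) 2L:ncol(lab) else seq_len(ncol(lab) - 1L),
             drop = FALSE]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (is.null(pairs)) return(lab)
  g <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nmax - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  remap <- c(0L, as.integer(comp[seq_len(nmax)]))
  matrix(remap[lab + 1L], nrow(lab), ncol(lab))
}

#' Remove small connected components
#'
#' Optionally dilates once with a 3x3 square element, then clears every
#' connected foreground component smaller than `min_pixels`. Components at or
#' above the size threshold pass through unchanged. The three literature
#' parameterisations of this step use 50, 70 and 500 pixels.
#'
#' @param mask a [binary_mask()].
#' @param min_pixels minimum component size kept (>= 1).
#' @param connectivity 4 (default) or 8.
#' @param dilate_first apply one 3x3 dilation before size filtering.
#' @return the cleaned [binary_mask()].
#' @export
remove_small_components <- function(mask, min_pixels, connectivity = 4L,
                                    dilate_first = FALSE) {
  stopifnot(inherits(mask, "binary_mask"), min_pixels >= 1)
  bits <- mask$bits
  if (dilate_first && any(bits)) {
    bits <- as.matrix(EBImage::dilate(bits * 1,
                                      matrix(1, 3, 3))) > 0.5
  }
  if (!any(bits)) return(binary_mask(bits, mask$baseline_row))
  lab <- label_components(bits, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_pixels)
  binary_mask(matrix(lab %in% keep, nrow(bits), ncol(bits)),
              mask$baseline_row)
}

#' Flood-fill (region growing) clean-up
#'
#' Labels every connected region by flood fill from raster-order seeds and
#' deletes foreground components smaller than `min_pixels`. Optionally, fully
#' enclosed background holes smaller than `min_pixels` are filled as well --
#' an extension beyond plain deletion, off by default.
#'
#' @param mask a [binary_mask()].
#' @param min_pixels size threshold (default 70).
#' @param connectivity 4 (default) or 8 for the foreground labelling.
#' @param fill_holes also fill small enclosed background holes.
#' @return the cleaned [binary_mask()].
#' @export
region_growing_cleanup <- function(mask, min_pixels = 70L, connectivity = 4L,
                                   fill_holes = FALSE) {
  stopifnot(inherits(mask, "binary_mask"))
  out <- remove_small_components(mask, min_pixels, connectivity)
  if (fill_holes && any(!out$bits)) {
    bg <- label_components(!out$bits, connectivity = 4L)
    border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    sizes <- tabulate(bg[bg > 0])
    hole <- setdiff(which(sizes < min_pixels), border_labels)
    if (length(hole))
      out$bits[matrix(bg %in% hole, nrow(bg), ncol(bg))] <- TRUE
  }
  out
}

#' Identity post-processing
#'
#' Some published tracing chains apply no clean-up between binarisation and
#' envelope extraction; this option passes the mask through untouched.
#'
#' @param mask a [binary_mask()].
#' @return `mask`, unchanged.
#' @export
identity_post <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  mask
}
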