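# Run-based 4-connected component labelling.  Rows are scanned once; runs
# of foreground within each row are merged with overlapping runs of the
# previous row through a union-find.  Exact 4-connectivity, fast because
# the number of runs is small compared to the number of pixels.

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Label 4-connected foreground components
#'
#' @param mask Logical matrix.
#' @return Integer matrix of component labels (0 = background), labelled
#'   in arbitrary but deterministic order.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  run_lab <- vector("list", nr)   # per row: matrix cols start,end,label
  for (i in seq_len(nr)) {
    rv <- mask[i, ]
    if (!any(rv)) { run_lab[[i]] <- NULL; next }
    r <- rle(rv)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    fg <- which(r$values)
    labs <- integer(length(fg))
    prev <- if (i > 1) run_lab[[i - 1]] else NULL
    for (k in seq_along(fg)) {
      s <- starts[fg[k]]; e <- ends[fg[k]]
      hit <- integer(0)
      if (!is.null(prev)) {
        ov <- prev[, 1] <= e & prev[, 2] >= s
        hit <- as.integer(prev[ov, 3])
      }
      if (length(hit) == 0) {
        parent[length(parent) + 1L] <- length(parent) + 1L
        labs[k] <- length(parent)
      } else {
        roots <- unique(vapply(hit, function(h) uf_find(parent, h), integer(1)))
        labs[k] <- roots[1]
        for (rt in roots[-1]) parent[rt] <- roots[1]
      }
      lab[i, s:e] <- labs[k]
    }
    run_lab[[i]] <- cbind(starts[fg], ends[fg], labs)
  }
  if (length(parent)) {
    roots <- vapply(seq_along(parent), function(j) uf_find(parent, j), integer(1))
    remap <- integer(length(parent))
    remap[unique(roots)] <- seq_along(unique(roots))
    nz <- lab != 0L
    lab[nz] <- remap[roots[lab[nz]]]
  }
  lab
}

#' Keep only the largest 4-connected foreground component
#'
#' @param mask Logical matrix.
#' @return Logical matrix; all-FALSE input is returned unchanged.
#' @export
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (!any(lab > 0L)) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Fill interior holes of a binary mask
#'
#' Background components (4-connected) that do not touch the raster border
#' are interior holes and become foreground.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  lab <- label_components(!mask)
  if (!any(lab > 0L)) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  hole <- lab > 0L & !(lab %in% border)
  mask | hole
}

#' Dice similarity coefficient of two binary masks
#'
#' @param a,b Logical matrices of identical shape.
#' @return `2 |a & b| / (|a| + |b|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop_ablashape("masks must have identical dimensions", "validation_error")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
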