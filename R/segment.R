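## Connected-component labelling and per-component statistics.
##
## EBImage::bwlabel provides fast 4-connected labelling; the 8-connected
## variant used throughout particle analysis here is obtained by merging
## label pairs that touch diagonally (vectorised shift comparison plus
## union-find over the handful of label ids).  Labels are renumbered in
## raster-scan order (row by row, left to right) to match sequential
## particle numbering.

#' Label connected foreground components
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of labels (0 = background), numbered in
#'   raster-scan order of first appearance.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8L) {
    nmax <- max(lab)
    parent <- seq_len(nmax)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    union2 <- function(a, b) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
    nr <- nrow(lab); nc <- ncol(lab)
    if (nr > 1L && nc > 1L) {
      a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]      # down-right diagonal
      a2 <- lab[-1, -nc]; b2 <- lab[-nr, -1]      # up-right diagonal
      pairs <- rbind(cbind(as.integer(a1), as.integer(b1)),
                     cbind(as.integer(a2), as.integer(b2)))
      pairs <- unique(pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                              pairs[, 1] != pairs[, 2], , drop = FALSE])
      for (i in seq_len(nrow(pairs))) union2(pairs[i, 1], pairs[i, 2])
    }
    root <- vapply(seq_len(nmax), find, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  ## renumber by raster order of first appearance (row-major)
  pos <- which(lab > 0L)
  r <- (pos - 1L) %% nrow(lab)
  c <- (pos - 1L) %/% nrow(lab)
  raster <- r * ncol(lab) + c
  ids <- lab[pos]
  first <- tapply(raster, ids, min)
  new_id <- integer(max(lab))
  new_id[as.integer(names(first))] <- rank(first, ties.method = "first")
  lab[pos] <- new_id[ids]
  lab
}

#' Per-component pixel coordinates and basic statistics
#'
#' @param lab label matrix from [label_components()].
#' @return list of per-component lists: `id`, `area`, `centroid` (0-based
#'   x, y), `pixels` (n x 2 matrix of 0-based x, y), `bbox`
#'   (x0, x1, y0, y1).
#' @export
component_stats <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(list())
  pos <- which(lab > 0L)
  ids <- lab[pos]
  x <- (pos - 1L) %/% nrow(lab)              # 0-based column
  y <- (pos - 1L) %% nrow(lab)               # 0-based row
  lapply(seq_len(n), function(i) {
    sel <- ids == i
    xi <- x[sel]; yi <- y[sel]
    list(id = i, area = length(xi),
         centroid = c(mean(xi), mean(yi)),
         pixels = cbind(x = xi, y = yi),
         bbox = c(x0 = min(xi), x1 = max(xi), y0 = min(yi), y1 = max(yi)))
  })
}

## 4-neighbour boundary-edge perimeter of one component (pixel edge count)
component_perimeter <- function(lab, id) {
  m <- lab == id
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(FALSE, m[-nr, , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, m[, -nc, drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], FALSE)
  sum(m & !up) + sum(m & !dn) + sum(m & !lf) + sum(m & !rt)
}
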