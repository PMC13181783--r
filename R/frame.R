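#' Construct a periodic snapshot of atomic coordinates
#'
#' A `hdo_frame` holds one snapshot of an orthorhombic, periodic simulation
#' box: element symbols, Cartesian coordinates in Angstrom, the three box
#' lengths, and a time stamp in picoseconds.
#'
#' @param elements character vector of element symbols (e.g. `"O"`, `"H"`).
#' @param xyz numeric matrix with one row per atom and columns x, y, z (Å).
#' @param box numeric vector of three strictly positive box lengths (Å).
#' @param time_ps non-negative snapshot time stamp (ps).
#' @return An object of class `hdo_frame`.
#' @examples
#' fr <- hdo_frame(c("O", "H", "H"),
#'                 rbind(c(0, 0, 0), c(0.9572, 0, 0), c(-0.24, 0.927, 0)),
#'                 box = c(20, 20, 20))
#' @export
hdo_frame <- function(elements, xyz, box, time_ps = 0) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  if (ncol(xyz) != 3L)
    stop("`xyz` must have three columns (x, y, z)")
  if (length(elements) != nrow(xyz))
    stop("element count (", length(elements), ") does not match coordinate rows (",
         nrow(xyz), ")")
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3L)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("`box` must be three strictly positive lengths (orthorhombic)")
  if (!is.finite(time_ps) || time_ps < 0)
    stop("`time_ps` must be non-negative")
  structure(
    list(elements = as.character(elements), xyz = xyz, box = box,
         time_ps = as.numeric(time_ps)),
    class = "hdo_frame")
}

#' @export
print.hdo_frame <- function(x, ...) {
  cat(sprintf("<hdo_frame> %d atoms, box %.2f x %.2f x %.2f A, t = %.4f ps\n",
              nrow(x$xyz), x$box[1], x$box[2], x$box[3], x$time_ps))
  invisible(x)
}

# Minimum-image displacement vectors dx = a - b (rows), wrapped into
# [-L/2, L/2) per dimension. `a`, `b` are n x 3 matrices (or vectors).
min_image_disp <- function(a, b, box) {
  a <- matrix(a, ncol = 3L)
  b <- matrix(b, ncol = 3L)
  d <- sweep(a, 2L, b[1L, ], "-")
  if (nrow(b) > 1L) d <- a - b
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# Minimum-image distances between one reference point `p` (length 3) and the
# rows of `pts`.
min_image_dist <- function(p, pts, box) {
  pts <- matrix(pts, ncol = 3L)
  d <- sweep(pts, 2L, as.numeric(p), "-")
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  sqrt(rowSums(d * d))
}

# All pairwise minimum-image distances among rows of `pts` (upper triangle,
# as a flat vector). Used by the RDF accumulator.
min_image_pdist <- function(pts, box) {
  n <- nrow(pts)
  if (n < 2L) return(numeric(0))
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    out[[i]] <- min_image_dist(pts[i, ], pts[(i + 1L):n, , drop = FALSE], box)
  }
  unlist(out, use.names = FALSE)
}
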