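#' Construct and validate a spot table
#'
#' A spot table describes a Visium-style pseudo-hexagonal capture lattice:
#' one row per spot with its barcode, array indices, planar coordinates and
#' in-tissue flag. On the pseudo-hex convention, `array_row` and `array_col`
#' share parity at every spot, each interior spot has six equidistant
#' neighbours, and the centre-to-centre distance ("pitch") is a single
#' constant recoverable from the coordinates.
#'
#' @param spot_id character barcodes, unique.
#' @param array_row,array_col non-negative integer array indices; the pair
#'   must be unique per spot and the two indices must have equal parity.
#' @param x,y planar coordinates in one consistent (abstract) unit.
#' @param in_tissue logical flag per spot.
#' @return A `data.frame` of class `spot_table`.
#' @examples
#' st <- spot_table("s1", 0L, 0L, 0, 0, TRUE)
#' @export
spot_table <- function(spot_id, array_row, array_col, x, y, in_tissue = TRUE) {
  st <- data.frame(
    spot_id   = as.character(spot_id),
    array_row = as.integer(array_row),
    array_col = as.integer(array_col),
    x = as.numeric(x),
    y = as.numeric(y),
    in_tissue = rep_len(as.logical(in_tissue), length(spot_id)),
    stringsAsFactors = FALSE
  )
  validate_spot_table(st)
}

#' @rdname spot_table
#' @param st a data.frame with the spot-table columns.
#' @export
validate_spot_table <- function(st) {
  req <- c("spot_id", "array_row", "array_col", "x", "y", "in_tissue")
  miss <- setdiff(req, names(st))
  if (length(miss)) stop("spot table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(st$spot_id)) stop("spot_id barcodes must be unique")
  if (any(st$array_row < 0) || any(st$array_col < 0)) {
    stop("array indices must be non-negative")
  }
  key <- paste(st$array_row, st$array_col)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicated (array_row, array_col) pair: (", sub(" ", ", ", dup), ")")
  }
  if (any((st$array_row %% 2L) != (st$array_col %% 2L))) {
    stop("array_row and array_col must have equal parity at every spot ",
         "(Visium pseudo-hex convention)")
  }
  if (!all(is.finite(st$x)) || !all(is.finite(st$y))) stop("coordinates must be finite")
  class(st) <- unique(c("spot_table", class(st)))
  st
}

#' Estimate the lattice pitch from spot coordinates
#'
#' The pitch is the centre-to-centre distance of adjacent spots. It is
#' estimated as the median planar distance between spots that are hex
#' neighbours by array index; if no such pair exists it falls back to the
#' median nearest-neighbour distance.
#'
#' @param st a [spot_table()].
#' @return A single positive number.
#' @export
spot_pitch <- function(st) {
  st <- validate_spot_table(st)
  idx <- spot_index(st)
  d <- numeric(0)
  take <- seq_len(min(nrow(st), 1000L))
  for (off in hex_offsets()) {
    j <- idx_lookup(idx, st$array_row[take] + off[1], st$array_col[take] + off[2])
    ok <- !is.na(j)
    if (any(ok)) {
      d <- c(d, sqrt((st$x[take][ok] - st$x[j[ok]])^2 +
                     (st$y[take][ok] - st$y[j[ok]])^2))
    }
  }
  if (!length(d)) {
    if (nrow(st) < 2) stop("cannot estimate pitch from fewer than 2 spots")
    xy <- as.matrix(st[take, c("x", "y")])
    dm <- as.matrix(stats::dist(xy))
    diag(dm) <- Inf
    d <- apply(dm, 1, min)
  }
  stats::median(d)
}

## The six (drow, dcol) hex-neighbour offsets of the doubled-column layout.
hex_offsets <- function() {
  list(c(0L, 2L), c(0L, -2L), c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
}

## O(1) lookup from (array_row, array_col) to row index of the table.
spot_index <- function(st) {
  e <- new.env(hash = TRUE, parent = emptyenv(), size = nrow(st))
  key <- paste(st$array_row, st$array_col, sep = "_")
  for (i in seq_along(key)) assign(key[i], i, envir = e)
  e
}

idx_lookup <- function(idx, rows, cols) {
  key <- paste(rows, cols, sep = "_")
  vapply(key, function(k) {
    v <- get0(k, envir = idx, inherits = FALSE)
    if (is.null(v)) NA_integer_ else v
  }, integer(1), USE.NAMES = FALSE)
}

#' Hex-step distance between lattice positions
#'
#' Number of hex steps between two spots of the doubled-column lattice
#' (`array_col` advances by 2 within a row, diagonal steps change both
#' indices by 1).
#'
#' @param r1,c1,r2,c2 array indices (vectorised).
#' @return Integer vector of hex distances.
#' @export
hex_distance <- function(r1, c1, r2, c2) {
  dr <- abs(r1 - r2)
  dc <- abs(c1 - c2)
  as.integer(dr + pmax(0, (dc - dr) %/% 2L + ((dc - dr) %% 2L > 0)))
}
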