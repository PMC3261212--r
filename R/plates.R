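# 384-well plate geometry: 16 rows (A-P) x 24 columns, row-major filling.

PLATE_ROWS <- 16L
PLATE_COLS <- 24L

#' Well id for a 0-based well index on a 384-well plate
#' @param idx 0-based index, row-major (0 = A01, 23 = A24, 24 = B01, ...)
#' @return character well ids like "A01".."P24"
#' @keywords internal
well_id <- function(idx) {
  stopifnot(all(idx >= 0L & idx < PLATE_ROWS * PLATE_COLS))
  r <- idx %/% PLATE_COLS
  c <- idx %% PLATE_COLS
  sprintf("%s%02d", LETTERS[r + 1L], c + 1L)
}

#' Parse well ids into 1-based row/column indices
#' @param well character vector like "F12"
#' @return list(row, col), 1-based
#' @keywords internal
well_to_rowcol <- function(well) {
  row <- match(substr(well, 1L, 1L), LETTERS)
  col <- as.integer(substring(well, 2L))
  bad <- is.na(row) | is.na(col) | row > PLATE_ROWS | col < 1L | col > PLATE_COLS
  if (any(bad)) stop("invalid 384-well id: ", well[bad][1L])
  list(row = row, col = col)
}

#' Quarter-plate pool id of a library well
#'
#' A 96-pin replicator samples each 384-well plate four times in a 2x2
#' interleave, so the quarter is determined by the row and column parities:
#' `Q = 1 + 2*(row%%2) + (col%%2)` with 0-based row/column indices. Well F12
#' of plate 42 therefore maps to pool `"042Q4"`.
#'
#' @param plate plate number (1-based)
#' @param well well id like "F12"
#' @return qpp ids formatted `"%03dQ%d"`
#' @export
clone_to_qpp <- function(plate, well) {
  rc <- well_to_rowcol(well)
  if (any(plate < 1L)) stop("plate numbers are 1-based")
  q <- 1L + 2L * ((rc$row - 1L) %% 2L) + ((rc$col - 1L) %% 2L)
  sprintf("%03dQ%d", as.integer(plate), q)
}
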