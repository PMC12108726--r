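# Shared direction conventions for the eight-direction retina model.
#
# Direction index d runs 0..7.  d = 0 is rightward (0 degrees) and each
# increment rotates counterclockwise by 45 degrees.  Image rows increase
# downward, so "upward" motion is a row offset of -1.

# row/col offset per direction index (row 1 of the matrix is d = 0)
.dir_offsets <- matrix(
  c( 0L,  1L,   # 0:   0 deg, rightward
    -1L,  1L,   # 1:  45 deg, upper-right
    -1L,  0L,   # 2:  90 deg, upward
    -1L, -1L,   # 3: 135 deg, upper-left
     0L, -1L,   # 4: 180 deg, leftward
     1L, -1L,   # 5: 225 deg, lower-left
     1L,  0L,   # 6: 270 deg, downward
     1L,  1L),  # 7: 315 deg, lower-right
  ncol = 2L, byrow = TRUE,
  dimnames = list(NULL, c("drow", "dcol"))
)

.dir_names <- c("right", "upper-right", "up", "upper-left",
                "left", "lower-left", "down", "lower-right")

#' Direction conventions of the eight-direction retina
#'
#' The model's eight motion directions are indexed `0..7`, starting at
#' rightward (0 degrees) and rotating counterclockwise in 45-degree steps.
#' Rows of the image grid increase downward, so upward motion corresponds to
#' a row offset of -1.
#'
#' @param d Integer vector of direction indices in `0..7`.
#' @return A data frame with one row per requested direction and columns
#'   `d`, `angle` (degrees), `drow`, `dcol` (the grid offset of one pixel of
#'   motion) and `name`.
#' @examples
#' direction_offsets()            # the full table
#' direction_offsets(2)$drow      # upward motion decreases the row index
#' @export
direction_offsets <- function(d = 0:7) {
  d <- as.integer(d)
  if (any(d < 0L | d > 7L)) {
    stop("direction index must lie in 0..7", call. = FALSE)
  }
  data.frame(
    d = d,
    angle = 45 * d,
    drow = .dir_offsets[d + 1L, "drow"],
    dcol = .dir_offsets[d + 1L, "dcol"],
    name = .dir_names[d + 1L],
    row.names = NULL
  )
}
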