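#' Supported maps
#'
#' Square battle-royale maps with side lengths in centimeters. Coordinates on
#' a map run from 0 to the side length on both axes.
#'
#' @format A data frame with columns `map_name` and `side_cm`.
#' @export
MAP_TABLE <- data.frame(
  map_name = c("Miramar", "Erangel", "Sanhok", "Karakin"),
  side_cm  = c(816000L, 816000L, 408000L, 204000L),
  stringsAsFactors = FALSE
)

#' Side length of a map in centimeters
#'
#' @param map_name One of `"Miramar"`, `"Erangel"`, `"Sanhok"`, `"Karakin"`.
#' @return Side length in cm (both axes; maps are square).
#' @examples
#' map_side_cm("Karakin")
#' @export
map_side_cm <- function(map_name) {
  i <- match(map_name, MAP_TABLE$map_name)
  if (anyNA(i)) {
    stop("unknown map_name: ", paste(map_name[is.na(i)], collapse = ", "),
         " (known: ", paste(MAP_TABLE$map_name, collapse = ", "), ")")
  }
  MAP_TABLE$side_cm[i]
}
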