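## Plain-text I/O for sensor layouts.

#' Write or read a sensor layout TSV
#'
#' Columns: `pair_id`, `name`, `name_a`, `name_b`, `x`, `y`, `z`,
#' `hemisphere`, `psi`.
#'
#' @param layout A [SensorLayout-class].
#' @param path TSV path.
#' @return `writeLayout` returns `path` invisibly; `readLayout` a
#'   [SensorLayout-class] (hotspot centers are recomputed from the stored
#'   radius).
#' @export
writeLayout <- function(layout, path) {
  utils::write.table(cbind(layout@pairs, radius = layout@radius,
                           seed = layout@seed),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLayout
#' @export
readLayout <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  radius <- df$radius[1]
  seed <- as.integer(df$seed[1])
  el <- 20 * pi / 180
  df$radius <- NULL
  df$seed <- NULL
  methods::new("SensorLayout", pairs = df, radius = radius,
               hotspots = list(left = c(-radius * cos(el), 0,
                                        radius * sin(el)),
                               right = c(radius * cos(el), 0,
                                         radius * sin(el))),
               seed = seed)
}
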