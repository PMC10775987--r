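#' Read and write maze specifications as JSON
#'
#' The on-disk format is a JSON document with top-level keys `corners`,
#' `segments`, `wormholes` and `objects`, mirroring the [maze_spec()]
#' fields. Numbers are written at full precision so that finite decimal
#' inputs round-trip exactly.
#'
#' @param spec a [maze_spec()].
#' @param path file path.
#' @return `write_maze_json()` returns `path` invisibly;
#'   `read_maze_json()` returns a `maze_spec`.
#' @export
write_maze_json <- function(spec, path) {
  doc <- list(
    corners = spec$corners,
    segments = spec$segments,
    wormholes = lapply(spec$wormholes, function(w)
      list(from = w$from, to = w$to,
           entry = w$entry, exit = w$exit, rotation = w$rotation)),
    objects = spec$objects
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @rdname write_maze_json
#' @export
read_maze_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE,
                             simplifyMatrix = FALSE)
  wh <- doc$wormholes
  if (is.data.frame(wh)) {
    wh <- lapply(seq_len(nrow(wh)), function(i) {
      w <- wh[i, ]
      list(from = w$from, to = w$to,
           entry = as.list(w$entry), exit = as.list(w$exit),
           rotation = w$rotation)
    })
  } else if (is.null(wh)) wh <- list()
  obj <- doc$objects
  if (!is.null(obj) && !is.data.frame(obj)) obj <- as.data.frame(obj)
  maze_spec(doc$corners, doc$segments, wh, obj)
}
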