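# Camera parameter files: JSON, one record per camera
# {id, P (12 floats, row-major), image_width, image_height}.

#' Write camera models to a JSON file
#'
#' Full double precision is kept so that [read_cameras()] recovers the
#' projection matrices bit-exactly.
#'
#' @param cameras List of [camera_model()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cameras <- function(cameras, path) {
  # numbers are written with 17 significant digits (%.17g), which
  # round-trips IEEE doubles exactly; jsonlite truncates to 15
  recs <- vapply(cameras, function(cm) {
    pvals <- paste(sprintf("%.17g", as.numeric(t(cm$P))), collapse = ", ")
    sprintf("  {\"id\": %s, \"P\": [%s], \"image_width\": %d, \"image_height\": %d}",
            jsonlite::toJSON(cm$id, auto_unbox = TRUE), pvals,
            cm$image_width, cm$image_height)
  }, character(1))
  writeLines(c("[", paste(recs, collapse = ",\n"), "]"), path)
  invisible(path)
}

#' Read camera models from a JSON file
#'
#' @param path File written by [write_cameras()].
#' @return List of [camera_model()] objects, named by camera id.
#' @export
read_cameras <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  cams <- lapply(recs, function(r) {
    camera_model(r$id, as.numeric(unlist(r$P)),
                 r$image_width, r$image_height,
                 canonicalize = FALSE)
  })
  names(cams) <- vapply(cams, `[[`, character(1), "id")
  cams
}
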