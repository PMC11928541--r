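#' TLS annotation objects
#'
#' One annotated tertiary lymphoid structure: a single simple polygon in
#' pixel coordinates (0-based, y-down) with slide/patient identity and a
#' maturation class.
#'
#' @param tls_id,slide_id,patient_id identifiers (strings).
#' @param polygon an `n x 2` numeric matrix of (x, y) vertices; the closing
#'   vertex may be repeated or omitted.
#' @param true_class maturation class (label or code 0/1/2).
#' @return an object of class `tls_annotation`.
#' @export
tls_annotation <- function(tls_id, slide_id, patient_id, polygon, true_class) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L || anyNA(polygon)) {
    stopf("annotation '%s': polygon must be an n x 2 numeric matrix (n >= 3)",
          tls_id)
  }
  # drop an explicit closing vertex
  n <- nrow(polygon)
  if (all(polygon[1L, ] == polygon[n, ])) polygon <- polygon[-n, , drop = FALSE]
  if (polygon_area(polygon) <= 0) {
    stopf("annotation '%s': polygon has zero area", tls_id)
  }
  structure(list(tls_id = as.character(tls_id),
                 slide_id = as.character(slide_id),
                 patient_id = as.character(patient_id),
                 polygon = unname(polygon),
                 true_class = class_code(true_class)),
            class = "tls_annotation")
}

#' @export
print.tls_annotation <- function(x, ...) {
  cat(sprintf("TLS annotation %s (slide %s, patient %s): %s, %d vertices, area %.0f px^2\n",
              x$tls_id, x$slide_id, x$patient_id, class_label(x$true_class),
              nrow(x$polygon), polygon_area(x$polygon)))
  invisible(x)
}

#' Read TLS annotations from QuPath-style GeoJSON
#'
#' Parses a GeoJSON FeatureCollection in the dialect exported by QuPath:
#' each feature is a `Polygon` geometry whose maturation class is carried in
#' `properties.classification.name` (one of `"Aggregate"`, `"Non-GC"`,
#' `"GC"`).  Features with an unknown or absent class are skipped with a
#' warning by default, or rejected when `on_unknown_class = "error"`.
#'
#' @param path path to a GeoJSON file (or a JSON string).
#' @param slide_id,patient_id identity attached to the annotations when the
#'   file's feature properties do not carry `slide_id` / `patient_id` fields.
#' @param on_unknown_class `"skip"` (default) or `"error"`.
#' @return list of [tls_annotation()] objects.
#' @export
read_annotations <- function(path, slide_id = "S1", patient_id = "P001",
                             on_unknown_class = c("skip", "error")) {
  on_unknown_class <- match.arg(on_unknown_class)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stopf("malformed GeoJSON: %s",
                                            conditionMessage(e)))
  if (is.null(doc$type) || !identical(doc$type, "FeatureCollection")) {
    stop("document is not a GeoJSON FeatureCollection", call. = FALSE)
  }
  feats <- doc$features
  out <- list()
  skipped <- character(0)
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) {
      stopf("feature %d: geometry is not a Polygon", i)
    }
    ring <- geom$coordinates[[1L]]
    poly <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
    cls <- f$properties$classification$name
    if (is.null(cls) || !(cls %in% TLS_CLASS_LABELS)) {
      if (on_unknown_class == "error") {
        stopf("feature %d: unknown or absent maturation class '%s'",
              i, if (is.null(cls)) "<none>" else cls)
      }
      skipped <- c(skipped, sprintf("feature %d (%s)", i,
                                    if (is.null(cls)) "<none>" else cls))
      next
    }
    props <- f$properties
    out[[length(out) + 1L]] <- tls_annotation(
      tls_id = if (!is.null(props$tls_id)) props$tls_id
               else sprintf("TLS_%04d", i),
      slide_id = if (!is.null(props$slide_id)) props$slide_id else slide_id,
      patient_id = if (!is.null(props$patient_id)) props$patient_id
                   else patient_id,
      polygon = poly, true_class = cls)
  }
  if (length(skipped)) {
    warning("skipped ", length(skipped), " feature(s) without a known class: ",
            paste(skipped, collapse = "; "), call. = FALSE)
  }
  out
}

#' Write TLS annotations as QuPath-style GeoJSON
#'
#' Serializes annotations to a GeoJSON FeatureCollection with closed polygon
#' rings and `properties.classification.name` set to the class label, plus
#' `tls_id`, `slide_id` and `patient_id` properties so a round-trip through
#' [read_annotations()] preserves identity.
#'
#' @param annotations list of [tls_annotation()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  feats <- lapply(annotations, function(a) {
    stopifnot(inherits(a, "tls_annotation"))
    ring <- rbind(a$polygon, a$polygon[1L, ])  # closed ring
    list(
      type = "Feature",
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(i) ring[i, ]))),
      properties = list(
        objectType = "annotation",
        classification = list(name = class_label(a$true_class)),
        tls_id = a$tls_id, slide_id = a$slide_id, patient_id = a$patient_id))
  })
  doc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
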