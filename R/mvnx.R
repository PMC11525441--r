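# MVNX-style XML reading and writing.
#
# The dialect accepted here is a documented minimal subset of the vendor
# schema: a <segments> list naming the keypoints, and per-frame elements
# carrying whitespace-separated numbers for position, orientation (Euler
# XYZ triplets in radians), centerOfMass, optional derivative channels and
# footContacts. Unknown elements are ignored with a warning. Units are
# preserved: meters and radians throughout.

.mvnx_channel_tags <- c(position = "position", orientation = "orientation",
                        velocity = "velocity", acceleration = "acceleration",
                        angular_velocity = "angularVelocity",
                        angular_acceleration = "angularAcceleration")

.known_frame_tags <- c(unname(.mvnx_channel_tags), "centerOfMass",
                       "footContacts")

#' Parse an MVNX-style XML document
#'
#' Reads a motion-capture recording into a [keypoint_series]: segment labels
#' in document order, positions and Euler orientations per frame, the center
#' of mass, foot contacts, and any derivative channels present in the file
#' (retained as auxiliary channels that the feature extractors prefer over
#' recomputation).
#'
#' @param document path to an XML file, or a string of XML text.
#' @return A [keypoint_series].
#' @export
parse_mvnx <- function(document) {
  doc <- tryCatch(xml2::read_xml(document), error = function(e)
    stop(sprintf("malformed MVNX XML: %s", conditionMessage(e)), call. = FALSE))
  xml2::xml_ns_strip(doc)
  subject <- xml2::xml_find_first(doc, ".//subject")
  if (inherits(subject, "xml_missing"))
    stop("malformed MVNX document: missing <subject> element")
  framerate <- as.numeric(xml2::xml_attr(subject, "frameRate"))
  if (!is.finite(framerate) || framerate <= 0)
    stop("malformed MVNX document: <subject> lacks a positive frameRate")
  seg_nodes <- xml2::xml_find_all(subject, ".//segments/segment")
  if (!length(seg_nodes))
    stop("malformed MVNX document: missing <segments> list")
  labels <- xml2::xml_attr(seg_nodes, "label")
  k <- length(labels)
  frames <- xml2::xml_find_all(subject, ".//frames/frame")
  frames <- frames[xml2::xml_attr(frames, "type") %in% c(NA, "normal")]
  n <- length(frames)
  if (n == 0L) stop("malformed MVNX document: no <frame> elements")
  unknown <- character(0)
  read_channel <- function(tag, width) {
    nodes <- lapply(frames, function(f) xml2::xml_find_first(f, tag))
    present <- !vapply(nodes, inherits, logical(1), "xml_missing")
    if (!any(present)) return(NULL)
    if (!all(present))
      stop(sprintf("frame-count mismatch: <%s> present in %d of %d frames",
                   tag, sum(present), n))
    vals <- lapply(nodes, function(nd) {
      v <- as.numeric(strsplit(trimws(xml2::xml_text(nd)), "\\s+")[[1]])
      if (length(v) != width)
        stop(sprintf("malformed <%s>: expected %d values, got %d",
                     tag, width, length(v)))
      v
    })
    do.call(rbind, vals)
  }
  # channels are stored segment-major: x1 y1 z1 x2 y2 z2 ...
  seg_channel <- function(tag) {
    m <- read_channel(tag, 3L * k)
    if (is.null(m)) return(NULL)
    arr <- array(NA_real_, c(n, k, 3))
    for (ax in 1:3) arr[, , ax] <- m[, seq(ax, 3L * k, by = 3L)]
    arr
  }
  pos <- seg_channel("position")
  if (is.null(pos)) stop("malformed MVNX document: frames carry no <position>")
  ori <- seg_channel("orientation")
  com <- read_channel("centerOfMass", 3L)
  fc <- read_channel("footContacts", 4L)
  if (!is.null(fc)) fc <- fc != 0
  aux <- lapply(.mvnx_channel_tags[c("velocity", "acceleration",
                                     "angular_velocity",
                                     "angular_acceleration")], seg_channel)
  kids <- unique(unlist(lapply(frames, function(f)
    xml2::xml_name(xml2::xml_children(f)))))
  unknown <- setdiff(kids, .known_frame_tags)
  if (length(unknown))
    warning(sprintf("ignoring unknown frame element(s): %s",
                    paste(unknown, collapse = ", ")))
  keypoint_series(positions = pos, orientations = ori, com = com,
                  framerate = framerate, keypoint_labels = labels,
                  foot_contacts = fc,
                  velocity = aux$velocity, acceleration = aux$acceleration,
                  angular_velocity = aux$angular_velocity,
                  angular_acceleration = aux$angular_acceleration)
}

# flatten an [n, k, 3] array to segment-major rows "x1 y1 z1 x2 y2 z2 ..."
.seg_rows <- function(arr) {
  n <- dim(arr)[1]; k <- dim(arr)[2]
  m <- matrix(NA_real_, n, 3 * k)
  for (ax in 1:3) m[, seq(ax, 3 * k, by = 3)] <- arr[, , ax]
  apply(m, 1, function(r) paste(sprintf("%.12g", r), collapse = " "))
}

#' Serialise a keypoint series to MVNX-style XML
#'
#' Writes the minimal dialect read by [parse_mvnx()]; the round trip is
#' lossless to better than 1e-9 in positions and orientations.
#'
#' @param series a [keypoint_series].
#' @param path optional output file; when NULL the XML text is returned.
#' @return `path` (invisibly) when writing to a file, else a character
#'   scalar of XML text.
#' @export
write_mvnx <- function(series, path = NULL) {
  stopifnot(inherits(series, "keypoint_series"))
  k <- length(series$keypoint_labels)
  segs <- paste(sprintf('      <segment id="%d" label="%s"/>',
                        seq_len(k), series$keypoint_labels),
                collapse = "\n")
  pos_rows <- .seg_rows(series$positions)
  ori_rows <- .seg_rows(series$orientations)
  com_rows <- apply(series$com, 1, function(r)
    paste(sprintf("%.12g", r), collapse = " "))
  fc_rows <- apply(series$foot_contacts, 1, function(r)
    paste(as.integer(r), collapse = " "))
  aux_rows <- lapply(c(velocity = "velocity", acceleration = "acceleration",
                       angular_velocity = "angular_velocity",
                       angular_acceleration = "angular_acceleration"),
                     function(ch) {
    if (is.null(series[[ch]])) NULL else .seg_rows(series[[ch]])
  })
  n <- series$frame_count
  frame_xml <- vapply(seq_len(n), function(t) {
    parts <- c(
      sprintf("      <frame time=\"%.12g\" type=\"normal\">", (t - 1) /
                series$framerate * 1000),
      sprintf("        <position>%s</position>", pos_rows[t]),
      sprintf("        <orientation>%s</orientation>", ori_rows[t]),
      sprintf("        <centerOfMass>%s</centerOfMass>", com_rows[t]),
      if (!is.null(aux_rows$velocity))
        sprintf("        <velocity>%s</velocity>", aux_rows$velocity[t]),
      if (!is.null(aux_rows$acceleration))
        sprintf("        <acceleration>%s</acceleration>",
                aux_rows$acceleration[t]),
      if (!is.null(aux_rows$angular_velocity))
        sprintf("        <angularVelocity>%s</angularVelocity>",
                aux_rows$angular_velocity[t]),
      if (!is.null(aux_rows$angular_acceleration))
        sprintf("        <angularAcceleration>%s</angularAcceleration>",
                aux_rows$angular_acceleration[t]),
      sprintf("        <footContacts>%s</footContacts>", fc_rows[t]),
      "      </frame>")
    paste(parts, collapse = "\n")
  }, character(1))
  xml <- paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mvnx version="4">',
    sprintf('  <subject label="synthetic" frameRate="%.12g">',
            series$framerate),
    "    <segments>", segs, "    </segments>",
    "    <frames>", frame_xml, "    </frames>",
    "  </subject>", "</mvnx>"), collapse = "\n")
  if (is.null(path)) return(xml)
  writeLines(xml, path)
  invisible(path)
}
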