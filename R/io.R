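## readers/writers: Pascal VOC XML, MOT-Challenge CSV, PNG frames, JSON

#' Read a Pascal VOC annotation file
#'
#' Parses one per-frame XML annotation (the format the study's frames were
#' annotated in with CVAT) into the package's box table. Object names must
#' come from the three-posture set; box coordinates are taken as-is into
#' the continuous corner convention.
#'
#' @param path path to the XML file.
#' @return A list with \code{filename}, \code{size} (width, height,
#'   depth) and \code{objects}, a \code{\link{boundingBoxes}} data.frame
#'   with confidence 1.
#' @export
readVocXml <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    doc <- xml2::read_xml(path)
    size <- xml2::xml_find_first(doc, "size")
    dims <- c(width = xml2::xml_double(xml2::xml_find_first(size, "width")),
              height = xml2::xml_double(xml2::xml_find_first(size, "height")),
              depth = xml2::xml_double(xml2::xml_find_first(size, "depth")))
    objs <- xml2::xml_find_all(doc, "object")
    if (length(objs)) {
        name <- vapply(objs, function(o)
            xml2::xml_text(xml2::xml_find_first(o, "name")), character(1))
        .checkPosture(name)
        getnum <- function(o, q)
            xml2::xml_double(xml2::xml_find_first(o, q))
        boxes <- boundingBoxes(
            vapply(objs, getnum, numeric(1), "bndbox/xmin"),
            vapply(objs, getnum, numeric(1), "bndbox/ymin"),
            vapply(objs, getnum, numeric(1), "bndbox/xmax"),
            vapply(objs, getnum, numeric(1), "bndbox/ymax"),
            label = name, confidence = 1)
        if (any(boxes$x_min < 0 | boxes$y_min < 0 |
                boxes$x_max > dims["width"] |
                boxes$y_max > dims["height"]))
            stop("box outside image bounds in ", path)
    } else {
        boxes <- boundingBoxes(numeric(0), numeric(0), numeric(0),
                               numeric(0), label = character(0),
                               confidence = numeric(0))
    }
    list(filename = xml2::xml_text(xml2::xml_find_first(doc, "filename")),
         size = dims, objects = boxes)
}

#' Write a Pascal VOC annotation file
#'
#' @param annotation a list as returned by \code{\link{readVocXml}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVocXml <- function(annotation, path) {
    .checkPosture(annotation$objects$label)
    doc <- xml2::xml_new_root("annotation")
    xml2::xml_add_child(doc, "filename", annotation$filename)
    size <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(size, "width",
                        format(annotation$size[["width"]], digits = 12))
    xml2::xml_add_child(size, "height",
                        format(annotation$size[["height"]], digits = 12))
    xml2::xml_add_child(size, "depth",
                        format(annotation$size[["depth"]], digits = 12))
    b <- annotation$objects
    for (i in seq_len(nrow(b))) {
        o <- xml2::xml_add_child(doc, "object")
        xml2::xml_add_child(o, "name", b$label[i])
        bb <- xml2::xml_add_child(o, "bndbox")
        xml2::xml_add_child(bb, "xmin", format(b$x_min[i], digits = 12))
        xml2::xml_add_child(bb, "ymin", format(b$y_min[i], digits = 12))
        xml2::xml_add_child(bb, "xmax", format(b$x_max[i], digits = 12))
        xml2::xml_add_child(bb, "ymax", format(b$y_max[i], digits = 12))
    }
    xml2::write_xml(doc, path)
    invisible(path)
}

.motCols <- c("frame", "id", "bb_left", "bb_top", "bb_width", "bb_height",
              "conf", "class", "visibility")

#' Read a MOT-Challenge-style CSV
#'
#' Reads the benchmark CSV dialect (columns frame, id, bb_left, bb_top,
#' bb_width, bb_height, conf, class, visibility; id = -1 for
#' identity-free detections; the class column carries the posture label)
#' and converts width/height to the internal corner convention.
#' Out-of-order rows are re-sorted stably with a warning.
#'
#' @param path path to the CSV (with header).
#' @return data.frame with \code{frame}, \code{id}, corner columns,
#'   \code{label}, \code{confidence}, \code{visibility}.
#' @export
readMotCsv <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(.motCols, names(df))
    if (length(missing))
        stop("MOT CSV ", path, " lacks column(s): ",
             paste(missing, collapse = ", "))
    bad <- which(df$bb_width <= 0 | df$bb_height <= 0)
    if (length(bad))
        stop("nonpositive box size in MOT CSV row(s) ",
             paste(head(bad, 5), collapse = ", "))
    .checkPosture(df$class)
    if (is.unsorted(df$frame)) {
        warning("MOT CSV rows out of frame order; re-sorting stably")
        df <- df[order(df$frame), , drop = FALSE]
    }
    data.frame(frame = as.integer(df$frame), id = as.integer(df$id),
               x_min = df$bb_left, y_min = df$bb_top,
               x_max = df$bb_left + df$bb_width,
               y_max = df$bb_top + df$bb_height,
               label = df$class, confidence = df$conf,
               visibility = df$visibility)
}

#' Write a MOT-Challenge-style CSV
#'
#' Inverse of \code{\link{readMotCsv}}: internal corner boxes go to disk
#' as top-left + width/height. Missing \code{id} becomes -1 (raw
#' detections), missing \code{visibility} becomes 1. Output is
#' deterministic: fixed column order, 6 significant digits.
#'
#' @param records data.frame with \code{frame}, corner columns,
#'   \code{label}, \code{confidence}, and optionally \code{id} (or
#'   \code{track_id}) and \code{visibility}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMotCsv <- function(records, path) {
    df <- as.data.frame(records)
    if (!"id" %in% names(df) && "track_id" %in% names(df))
        names(df)[names(df) == "track_id"] <- "id"
    if (!"id" %in% names(df)) df$id <- -1L
    if (!"visibility" %in% names(df)) df$visibility <- 1
    if (!"confidence" %in% names(df)) df$confidence <- 1
    out <- data.frame(
        frame = as.integer(df$frame), id = as.integer(df$id),
        bb_left = signif(df$x_min, 6), bb_top = signif(df$y_min, 6),
        bb_width = signif(df$x_max - df$x_min, 6),
        bb_height = signif(df$y_max - df$y_min, 6),
        conf = signif(df$confidence, 6), class = df$label,
        visibility = signif(df$visibility, 6))
    out <- out[order(out$frame, out$id, out$bb_top, out$bb_left), ]
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a PNG frame as a grayscale matrix
#'
#' @param path path to a PNG image.
#' @return Numeric matrix (rows = y) of luminance in [0, 1].
#' @export
readFramePng <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    .toGray(png::readPNG(path))
}

#' @rdname readFramePng
#' @param image numeric matrix in [0, 1].
#' @export
writeFramePng <- function(image, path) {
    png::writePNG(pmin(pmax(image, 0), 1), path)
    invisible(path)
}

## ---- run configuration -----------------------------------------------------

.configSchema <- function() list(
    tracker = c("maxAge", "iouGate", "clipLength", "fps", "posWeight",
                "velWeight", "appearanceWeight"),
    activity = c("walkThreshold", "fps"),
    pen = c("width", "height", "nAnimals", "fps", "duration", "transition",
            "walkSpeedMean", "walkSpeedSd", "headingSd", "feeder",
            "boxSizes", "initPosture", "seed"),
    noise = c("missRate", "fpRate", "jitterSd", "labelFlipRate", "seed"),
    io = c("input", "output", "logLevel"))

#' Read and validate a JSON run configuration
#'
#' A run configuration is a JSON object with any of the sections
#' \code{tracker}, \code{activity}, \code{pen}, \code{noise}, \code{io};
#' unknown sections or keys are rejected rather than silently ignored.
#' Parsed sections are turned into the corresponding parameter objects.
#'
#' @param path path to a JSON file.
#' @return A list with the parameter objects that were present
#'   (\code{tracker}, \code{activity}, \code{pen}, \code{noise}) plus the
#'   raw \code{io} section.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    schema <- .configSchema()
    extraSec <- setdiff(names(cfg), names(schema))
    if (length(extraSec))
        stop("unknown config section(s): ", paste(extraSec, collapse = ", "))
    for (sec in names(cfg)) {
        extra <- setdiff(names(cfg[[sec]]), schema[[sec]])
        if (length(extra))
            stop("unknown key(s) in section '", sec, "': ",
                 paste(extra, collapse = ", "))
    }
    out <- list()
    if (!is.null(cfg$tracker)) out$tracker <- do.call(trackerParam, cfg$tracker)
    if (!is.null(cfg$activity))
        out$activity <- do.call(activityParam, cfg$activity)
    if (!is.null(cfg$pen)) {
        p <- cfg$pen
        asMat <- function(x, nc, dn) {
            m <- if (is.matrix(x)) x
                 else matrix(unlist(x), ncol = nc, byrow = TRUE)
            dimnames(m) <- dn
            m
        }
        if (!is.null(p$transition))
            p$transition <- asMat(p$transition, 3,
                                  list(postureLabels(), postureLabels()))
        if (!is.null(p$boxSizes))
            p$boxSizes <- asMat(p$boxSizes, 2,
                                list(postureLabels(), c("w", "h")))
        if (!is.null(p$feeder)) p$feeder <- as.numeric(unlist(p$feeder))
        out$pen <- do.call(penParam, p)
    }
    if (!is.null(cfg$noise)) out$noise <- do.call(noiseParam, cfg$noise)
    out$io <- cfg$io
    out
}

#' Serialise a run configuration to JSON
#'
#' Round-trips with \code{\link{readRunConfig}}.
#'
#' @param config list of parameter objects as returned by
#'   \code{\link{readRunConfig}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRunConfig <- function(config, path) {
    enc <- list()
    if (!is.null(config$tracker)) {
        p <- config$tracker
        enc$tracker <- list(maxAge = p@maxAge, iouGate = p@iouGate,
                            clipLength = p@clipLength, fps = p@fps,
                            posWeight = p@posWeight, velWeight = p@velWeight,
                            appearanceWeight = p@appearanceWeight)
    }
    if (!is.null(config$activity)) {
        p <- config$activity
        enc$activity <- list(walkThreshold = p@walkThreshold, fps = p@fps)
    }
    if (!is.null(config$pen)) {
        p <- config$pen
        enc$pen <- list(width = p@width, height = p@height,
                        nAnimals = p@nAnimals, fps = p@fps,
                        duration = p@duration,
                        transition = apply(p@transition, 1, as.list,
                                           simplify = FALSE),
                        walkSpeedMean = p@walkSpeedMean,
                        walkSpeedSd = p@walkSpeedSd,
                        headingSd = p@headingSd,
                        feeder = p@feeder,
                        boxSizes = apply(p@boxSizes, 1, as.list,
                                         simplify = FALSE),
                        initPosture = as.list(p@initPosture),
                        seed = p@seed)
    }
    if (!is.null(config$noise)) {
        p <- config$noise
        enc$noise <- list(missRate = p@missRate, fpRate = p@fpRate,
                          jitterSd = p@jitterSd,
                          labelFlipRate = p@labelFlipRate, seed = p@seed)
    }
    if (!is.null(config$io)) enc$io <- config$io
    jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
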