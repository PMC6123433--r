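#' Construct a TissueSnapshot
#'
#' @param specimenId single character identifier.
#' @param nuclei data.frame with columns
#'   `x, y, major, minor, ratio, area, perimeter, circularity, theta`
#'   (micrometre units; `theta` degrees in `(0, 180]`). Extra columns
#'   are dropped.
#' @param width,height image extent in micrometres.
#' @param resolution source-image resolution in micrometres per pixel.
#' @param label `1` (ER-negative), `0` (ER-positive) or `NA`.
#' @return a validated [TissueSnapshot-class].
#' @examples
#' nuc <- data.frame(x = 10, y = 12, major = 8, minor = 4, ratio = 2,
#'                   area = 25.1, perimeter = 19.3, circularity = 0.84,
#'                   theta = 40)
#' TissueSnapshot("demo", nuc, width = 100, height = 100)
#' @export
TissueSnapshot <- function(specimenId, nuclei = .emptyNuclei(),
                           width, height, resolution = 0.5, label = NA) {
    if (!nrow(nuclei)) nuclei <- .emptyNuclei()
    nuclei <- as.data.frame(nuclei)[, .nucleusCols, drop = FALSE]
    rownames(nuclei) <- NULL
    new("TissueSnapshot", specimenId = as.character(specimenId),
        label = as.integer(label), resolution = as.numeric(resolution),
        width = as.numeric(width), height = as.numeric(height),
        nuclei = nuclei)
}

#' Image extent of a snapshot
#'
#' @param snapshot a [TissueSnapshot-class].
#' @return named numeric vector `c(width, height)` in micrometres.
#' @export
snapshotExtent <- function(snapshot) {
    c(width = snapshot@width, height = snapshot@height)
}

## 12 decimals: keeps the ratio = major/minor invariant (1e-9) intact
## through serialisation while staying well inside the 1e-6 um
## round-trip guarantee
.num <- function(x) sprintf("%.12f", x)

## XML field names: snapshot attributes + one <cell> per nucleus
.xmlCellFields <- c(major = "major_axis", minor = "minor_axis",
                    ratio = "axis_ratio", area = "area",
                    perimeter = "perimeter", circularity = "circularity",
                    theta = "theta")

#' Write / read a tissue snapshot as XML
#'
#' Serialises a [TissueSnapshot-class] to a minimal digital tissue
#' snapshot dialect: a `<tissue_snapshot>` root carrying the specimen
#' metadata, one `<cell_population>` and one `<cell>` element per
#' nucleus with a `<center>` and a `<shape>` child holding all nine
#' per-nucleus fields. Round-trips are lossless to 1e-6 micrometres.
#' The dialect is a faithful minimal container, not a full standard
#' implementation (no phenotype trees, compartments or time series).
#'
#' @param snapshot a [TissueSnapshot-class].
#' @param path file path.
#' @return `writeSnapshotXML()` returns `path` invisibly;
#'   `readSnapshotXML()` returns a validated [TissueSnapshot-class]
#'   (invariant violations raise errors naming the offending field and
#'   nucleus index).
#' @examples
#' s <- TissueSnapshot("demo", width = 50, height = 50)
#' f <- tempfile(fileext = ".xml")
#' writeSnapshotXML(s, f)
#' readSnapshotXML(f)
#' @export
writeSnapshotXML <- function(snapshot, path) {
    stopifnot(is(snapshot, "TissueSnapshot"))
    validObject(snapshot)
    doc <- xml2::xml_new_root("tissue_snapshot",
        specimen_id = snapshot@specimenId,
        label = if (is.na(snapshot@label)) "unknown"
                else as.character(snapshot@label),
        resolution_um_per_px = .num(snapshot@resolution),
        width_um = .num(snapshot@width),
        height_um = .num(snapshot@height))
    pop <- xml2::xml_add_child(doc, "cell_population")
    df <- snapshot@nuclei
    for (i in seq_len(nrow(df))) {
        cell <- xml2::xml_add_child(pop, "cell", id = as.character(i))
        xml2::xml_add_child(cell, "center",
                            x = .num(df$x[i]), y = .num(df$y[i]))
        shape <- xml2::xml_add_child(cell, "shape")
        for (col in names(.xmlCellFields))
            xml2::xml_set_attr(shape, .xmlCellFields[[col]], .num(df[[col]][i]))
    }
    xml2::write_xml(doc, path)
    invisible(path)
}

#' @rdname writeSnapshotXML
#' @export
readSnapshotXML <- function(path) {
    doc <- tryCatch(xml2::read_xml(path),
                    error = function(e) stop("malformed XML: ",
                                             conditionMessage(e), call. = FALSE))
    root <- xml2::xml_find_first(doc, "/tissue_snapshot")
    if (inherits(root, "xml_missing"))
        stop("not a tissue_snapshot document", call. = FALSE)
    attr1 <- function(a) xml2::xml_attr(root, a)
    lab <- attr1("label")
    lab <- if (is.na(lab) || lab == "unknown") NA_integer_ else as.integer(lab)
    cells <- xml2::xml_find_all(doc, "//cell")
    n <- length(cells)
    df <- .emptyNuclei()
    if (n) {
        centers <- xml2::xml_find_first(cells, "center")
        shapes <- xml2::xml_find_first(cells, "shape")
        df <- data.frame(
            x = as.numeric(xml2::xml_attr(centers, "x")),
            y = as.numeric(xml2::xml_attr(centers, "y")))
        for (col in names(.xmlCellFields))
            df[[col]] <- as.numeric(xml2::xml_attr(shapes,
                                                   .xmlCellFields[[col]]))
    }
    snap <- TissueSnapshot(attr1("specimen_id"), df,
                           width = as.numeric(attr1("width_um")),
                           height = as.numeric(attr1("height_um")),
                           resolution = as.numeric(attr1("resolution_um_per_px")),
                           label = lab)
    snap
}

.csvCols <- c("specimen_id", "x_um", "y_um", "major_um", "minor_um",
              "ratio", "area_um2", "perimeter_um", "circularity",
              "theta_deg")

#' Write / read a tissue snapshot as CSV
#'
#' One row per nucleus with canonical columns
#' `specimen_id, x_um, y_um, major_um, minor_um, ratio, area_um2,
#' perimeter_um, circularity, theta_deg`; snapshot metadata (label,
#' resolution, extent) is stored in `#key=value` comment lines before
#' the header. Round-trips are lossless to 1e-6 micrometres.
#'
#' @inheritParams writeSnapshotXML
#' @return `writeSnapshotCSV()` returns `path` invisibly;
#'   `readSnapshotCSV()` a validated [TissueSnapshot-class]. A missing
#'   required column raises an error naming it.
#' @export
writeSnapshotCSV <- function(snapshot, path) {
    stopifnot(is(snapshot, "TissueSnapshot"))
    validObject(snapshot)
    df <- snapshot@nuclei
    out <- data.frame(specimen_id = rep(snapshot@specimenId, nrow(df)))
    src <- c("x", "y", "major", "minor", "ratio", "area", "perimeter",
             "circularity", "theta")
    for (i in seq_along(src)) out[[.csvCols[i + 1L]]] <- .num(df[[src[i]]])
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        sprintf("#specimen_id=%s", snapshot@specimenId),
        sprintf("#label=%s", if (is.na(snapshot@label)) "unknown"
                             else snapshot@label),
        sprintf("#resolution_um_per_px=%s", .num(snapshot@resolution)),
        sprintf("#width_um=%s", .num(snapshot@width)),
        sprintf("#height_um=%s", .num(snapshot@height))), con)
    write.csv(out, con, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeSnapshotCSV
#' @export
readSnapshotCSV <- function(path) {
    lines <- readLines(path)
    metaLines <- grep("^#", lines, value = TRUE)
    kv <- strsplit(sub("^#", "", metaLines), "=", fixed = TRUE)
    meta <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    for (key in c("resolution_um_per_px", "width_um", "height_um"))
        if (!key %in% names(meta))
            stop("missing metadata line: ", key, call. = FALSE)
    tab <- read.csv(text = lines[!grepl("^#", lines)],
                    colClasses = c(specimen_id = "character"))
    missing <- setdiff(.csvCols, names(tab))
    if (length(missing))
        stop("missing required column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    df <- data.frame(x = tab$x_um, y = tab$y_um, major = tab$major_um,
                     minor = tab$minor_um, ratio = tab$ratio,
                     area = tab$area_um2, perimeter = tab$perimeter_um,
                     circularity = tab$circularity, theta = tab$theta_deg)
    id <- if (nrow(tab)) tab$specimen_id[1L] else meta[["specimen_id"]]
    if (is.null(id) || is.na(id)) id <- "unknown"
    lab <- meta[["label"]]
    lab <- if (is.null(lab) || lab == "unknown") NA_integer_
           else as.integer(lab)
    TissueSnapshot(id, df,
                   width = as.numeric(meta[["width_um"]]),
                   height = as.numeric(meta[["height_um"]]),
                   resolution = as.numeric(meta[["resolution_um_per_px"]]),
                   label = lab)
}
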