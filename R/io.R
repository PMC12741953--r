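# Delimited-matrix input and result-bundle output.

.guessDelimiter <- function(path) {
    if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a delimited feature matrix
#'
#' Parses a CSV/TSV numeric grid (optional header row with sample names and
#' first column with feature names) into a validated [MixedMatrix].  Cells
#' equal to `naToken` (or empty) become missing; any other non-numeric cell
#' is an error reporting its row and column.
#'
#' @param path file path; the delimiter defaults to tab for `.tsv`/`.txt`
#'   and comma otherwise.
#' @param kind,naValue,featureAxis passed to [MixedMatrix()].
#' @param delimiter field separator override.
#' @param naToken textual missing-data token (default `"NA"`).
#' @param header does the first row hold sample names? (default `TRUE`)
#' @param rowNames does the first column hold feature names? (default `TRUE`)
#' @return a [MixedMatrix].
#' @export
readMatrix <- function(path,
                       kind = c("continuous", "dichotomous", "categorical"),
                       naValue = NaN,
                       featureAxis = c("rows", "columns"),
                       delimiter = NULL, naToken = "NA",
                       header = TRUE, rowNames = TRUE) {
    kind <- match.arg(kind)
    featureAxis <- match.arg(featureAxis)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (is.null(delimiter))
        delimiter <- .guessDelimiter(path)
    nf <- utils::count.fields(path, sep = delimiter, quote = "\"",
                              blank.lines.skip = TRUE)
    if (length(unique(nf)) > 1L)
        stop("ragged input: line ", which(nf != nf[1L])[1L], " of '", path,
             "' has ", nf[which(nf != nf[1L])[1L]], " fields, expected ",
             nf[1L])
    dt <- tryCatch(
        data.table::fread(path, sep = delimiter, header = header,
                          colClasses = "character", data.table = FALSE,
                          na.strings = NULL, fill = FALSE),
        error = function(e) stop("failed to parse '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    if (nrow(dt) == 0L || ncol(dt) == 0L)
        stop("'", path, "' contains no data")
    fn <- NULL
    if (rowNames) {
        fn <- dt[[1L]]
        dt <- dt[, -1L, drop = FALSE]
        if (ncol(dt) == 0L)
            stop("'", path, "' has no data columns beyond the feature names")
    }
    sn <- if (header) colnames(dt) else NULL
    chr <- as.matrix(dt)
    missTok <- chr == naToken | chr == "" | is.na(chr)
    num <- suppressWarnings(array(as.numeric(chr), dim = dim(chr)))
    bad <- is.na(num) & !missTok
    if (any(bad)) {
        idx <- which(bad, arr.ind = TRUE)[1L, ]
        stop(sprintf(
            "non-numeric cell '%s' at data row %d, column %d of '%s'",
            chr[idx[1L], idx[2L]], idx[1L], idx[2L], path))
    }
    num[missTok] <- naValue
    if (is.na(naValue))  # keep NaN representable even when sentinel is NA
        num[missTok] <- NaN
    if (featureAxis == "rows") {
        MixedMatrix(num, kind = kind, naValue = naValue,
                    featureAxis = "rows", featureNames = fn,
                    sampleNames = sn)
    } else {
        MixedMatrix(num, kind = kind, naValue = naValue,
                    featureAxis = "columns", featureNames = sn,
                    sampleNames = fn)
    }
}

#' Write a result bundle to delimited files
#'
#' Writes one CSV per result matrix (`<prefix>_<result>.csv`, feature names
#' as row/column labels, `NaN` as `naString`) plus a JSON sidecar
#' (`<prefix>_run_metadata.json`) recording the test, package version and
#' any extra configuration supplied.
#'
#' @param bundle a [ResultBundle].
#' @param outPrefix output path prefix.
#' @param naString text used for undefined results (default `"NA"`).
#' @param metadata named list merged into the JSON sidecar.
#' @return invisibly, the paths written.
#' @export
writeBundle <- function(bundle, outPrefix, naString = "NA",
                        metadata = list()) {
    stopifnot(is(bundle, "ResultBundle"))
    dir <- dirname(outPrefix)
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    paths <- character(0L)
    for (nm in resultNames(bundle)) {
        p <- paste0(outPrefix, "_", nm, ".csv")
        write.csv(bundle[[nm]], p, na = naString)
        paths <- c(paths, p)
    }
    meta <- c(list(test = bundle@test,
                   homogeneous = bundle@homogeneous,
                   results = as.list(resultNames(bundle)),
                   package = "pairstat",
                   version = as.character(packageVersion("pairstat")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
              metadata)
    mp <- paste0(outPrefix, "_run_metadata.json")
    jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(c(paths, mp))
}
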