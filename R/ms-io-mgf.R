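## MGF reader/writer.
##
## Dialect: records delimited by BEGIN IONS / END IONS. The scan number is
## taken from a SCANS= line when present, otherwise from the trailing integer
## of the TITLE. RTINSECONDS is converted to minutes internally; RTINMINUTES
## is accepted as-is. PEPMASS carries the precursor m/z (first token);
## CHARGE is "<z>+".

#' Read an MGF file of MS2 spectra
#'
#' @param path Path to an MGF file.
#' @return A list of [Spectrum-class] objects, peaks sorted ascending by m/z,
#'   retention times in minutes. An empty file yields an empty list.
#' @details A record missing PEPMASS or any scan identifier raises an error
#'   naming the record index.
#' @export
readMgf <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  }
  src <- basename(path)
  out <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    isHeader <- grepl("=", block, fixed = TRUE)
    hdr <- block[isHeader]
    keys <- sub("=.*$", "", hdr)
    vals <- sub("^[^=]*=", "", hdr)
    getv <- function(key) if (key %in% keys) vals[match(key, keys)] else NA
    scan <- NA_integer_
    if (!is.na(getv("SCANS"))) {
      scan <- suppressWarnings(as.integer(getv("SCANS")))
    } else if (!is.na(getv("TITLE"))) {
      m <- regmatches(getv("TITLE"),
                      regexpr("[0-9]+\\s*$", getv("TITLE")))
      if (length(m)) scan <- suppressWarnings(as.integer(trimws(m)))
    }
    if (is.na(scan)) {
      stop("MGF record ", k, " in ", path,
           ": no scan identifier (SCANS or trailing integer in TITLE)")
    }
    pepmass <- getv("PEPMASS")
    if (is.na(pepmass)) {
      stop("MGF record ", k, " in ", path, ": missing PEPMASS")
    }
    precursorMz <- as.numeric(strsplit(trimws(pepmass), "\\s+")[[1]][1])
    chargeStr <- getv("CHARGE")
    charge <- if (is.na(chargeStr)) 2L else
      as.integer(sub("\\+$", "", trimws(chargeStr)))
    rt <- NA_real_
    if (!is.na(getv("RTINSECONDS"))) {
      rt <- as.numeric(getv("RTINSECONDS")) / 60
    } else if (!is.na(getv("RTINMINUTES"))) {
      rt <- as.numeric(getv("RTINMINUTES"))
    }
    peakLines <- trimws(block[!isHeader])
    peakLines <- peakLines[nzchar(peakLines)]
    if (length(peakLines)) {
      fields <- strsplit(peakLines, "\\s+")
      pkmat <- matrix(as.numeric(unlist(lapply(fields, `[`, 1:2))),
                      ncol = 2, byrow = TRUE)
      if (any(!is.finite(pkmat))) {
        stop("MGF record ", k, " in ", path, ": unparseable peak line")
      }
    } else {
      pkmat <- matrix(numeric(0), ncol = 2)
    }
    out[[k]] <- Spectrum(src, scan, precursorMz, charge, rt, pkmat)
  }
  out
}

#' Write spectra to an MGF file
#'
#' Inverse of [readMgf()] for the package's MGF dialect. Retention times are
#' written as RTINSECONDS.
#'
#' @param spectra List of [Spectrum-class] objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeMgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    pk <- peaks(sp)
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", sp@sourceFile, " scan=", sp@scanNumber),
      paste0("SCANS=", sp@scanNumber),
      paste0("PEPMASS=", sprintf("%.6f", sp@precursorMz)),
      paste0("CHARGE=", sp@precursorCharge, "+"),
      paste0("RTINSECONDS=", sprintf("%.4f", sp@retentionTime * 60)),
      if (nrow(pk)) sprintf("%.6f %.6f", pk[, 1L], pk[, 2L]),
      "END IONS"
    ), con)
  }
  invisible(path)
}
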