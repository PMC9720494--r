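## MSP spectral-library reader/writer.
##
## Dialect (as exported by spectral predictors):
##   Name: PEPTIDE/2
##   Comment: CollisionEnergy=28 iRT=12.345
##   Num peaks: 3
##   mz intensity "annotation"
## Annotations are b/y series tokens: y3, b5^2 (ordinal, optional fragment
## charge after "^").

#' Read an MSP spectral library
#'
#' @param path Path to an MSP text file.
#' @return A named list of [PredictedSpectrum-class] objects; names are
#'   \code{"<peptide>/<charge>/<ce>"}. Duplicate (peptide, charge, CE)
#'   records are an error.
#' @details An annotation token not matching \code{^[by][0-9]+(\\^[0-9]+)?$}
#'   raises an error quoting the token.
#' @export
readMsp <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  lines <- readLines(path)
  starts <- grep("^Name:", lines)
  if (!length(starts)) {
    return(structure(list(), names = character(0)))
  }
  bounds <- c(starts, length(lines) + 1L)
  out <- list()
  for (k in seq_along(starts)) {
    block <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    nameVal <- trimws(sub("^Name:", "", block[1]))
    parts <- strsplit(nameVal, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("MSP record ", k, ": malformed Name line '", nameVal, "'")
    }
    peptide <- parts[1]
    charge <- as.integer(parts[2])
    commentLine <- grep("^Comment:", block, value = TRUE)
    ce <- NA_integer_
    irt <- NA_real_
    if (length(commentLine)) {
      tokens <- strsplit(trimws(sub("^Comment:", "", commentLine[1])),
                         "\\s+")[[1]]
      kv <- strsplit(tokens, "=", fixed = TRUE)
      for (t in kv) {
        if (length(t) == 2L && t[1] == "CollisionEnergy") {
          ce <- as.integer(t[2])
        }
        if (length(t) == 2L && t[1] == "iRT") irt <- as.numeric(t[2])
      }
    }
    if (is.na(ce)) {
      stop("MSP record ", k, " ('", nameVal,
           "'): Comment must carry CollisionEnergy=")
    }
    npLine <- grep("^Num peaks:", block, value = TRUE)
    if (!length(npLine)) {
      stop("MSP record ", k, " ('", nameVal, "'): missing 'Num peaks:'")
    }
    np <- as.integer(trimws(sub("^Num peaks:", "", npLine[1])))
    npIdx <- grep("^Num peaks:", block)[1]
    peakLines <- block[seq(npIdx + 1L, length.out = np)]
    series <- character(np); ordinal <- integer(np)
    fcharge <- integer(np); mz <- numeric(np); intensity <- numeric(np)
    if (np > 0L) {
      for (i in seq_len(np)) {
        f <- strsplit(trimws(peakLines[i]), "\\s+")[[1]]
        if (length(f) < 3L) {
          stop("MSP record '", nameVal, "': malformed peak line '",
               peakLines[i], "'")
        }
        ann <- gsub('"', "", f[3])
        if (!grepl("^[by][0-9]+(\\^[0-9]+)?$", ann)) {
          stop("MSP record '", nameVal,
               "': annotation token '", ann, "' not recognised")
        }
        series[i] <- substr(ann, 1, 1)
        rest <- substring(ann, 2)
        if (grepl("^", rest, fixed = TRUE)) {
          bits <- strsplit(rest, "^", fixed = TRUE)[[1]]
          ordinal[i] <- as.integer(bits[1])
          fcharge[i] <- as.integer(bits[2])
        } else {
          ordinal[i] <- as.integer(rest)
          fcharge[i] <- 1L
        }
        mz[i] <- as.numeric(f[1])
        intensity[i] <- as.numeric(f[2])
      }
    }
    key <- paste(peptide, charge, ce, sep = "/")
    if (key %in% names(out)) {
      stop("duplicate MSP record for (", key, ")")
    }
    out[[key]] <- PredictedSpectrum(
      peptide, charge, ce,
      data.frame(series = series, ordinal = ordinal, charge = fcharge,
                 intensity = intensity, mz = mz, stringsAsFactors = FALSE),
      irt = irt
    )
  }
  out
}

#' Write predicted spectra to an MSP spectral library
#'
#' Inverse of [readMsp()]. Fragment m/z values are computed from the peptide
#' when the prediction does not carry them.
#'
#' @param predictions List of [PredictedSpectrum-class] objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeMsp <- function(predictions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ps in predictions) {
    fr <- ps@fragments
    if (is.null(fr$mz)) {
      tab <- fragmentMzTable(ps@peptide, max(3L, ps@charge))
      key <- paste(tab$series, tab$ordinal, tab$charge)
      fr$mz <- tab$mz[match(paste(fr$series, fr$ordinal, fr$charge), key)]
    }
    ann <- paste0(fr$series, fr$ordinal,
                  ifelse(fr$charge > 1L, paste0("^", fr$charge), ""))
    writeLines(c(
      paste0("Name: ", ps@peptide, "/", ps@charge),
      paste0("Comment: CollisionEnergy=", ps@collisionEnergy,
             " iRT=", sprintf("%.6f", ps@irt)),
      paste0("Num peaks: ", nrow(fr)),
      if (nrow(fr)) sprintf('%.6f %.6f "%s"', fr$mz, fr$intensity, ann),
      ""
    ), con)
  }
  invisible(path)
}
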