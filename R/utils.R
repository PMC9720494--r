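## Internal utilities.

#' @noRd
## Scoped RNG: set the seed and return a function restoring the caller's RNG
## state, so package internals never clobber the user's random stream.
.restoreSeed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Version-pinned stable string hash
#'
#' A small explicit mixing function over character codes, mapped to [0, 1).
#' It is fixed by the package (never a runtime hash), so fixtures and the toy
#' predictor are byte-stable across platforms and R versions.
#'
#' @param ... Character/numeric components of the key (concatenated with
#'   "|").
#' @return A deterministic value in [0, 1).
#' @examples
#' stableHash("PEPTIDE", 2)
#' @export
stableHash <- function(...) {
  key <- paste(unlist(list(...)), collapse = "|")
  codes <- utf8ToInt(key)
  p <- 2147483647
  h <- 17
  for (c in codes) {
    h <- (h * 131 + c) %% p
  }
  ## second mixing pass for dispersion
  h2 <- (h * 48271 + 11) %% p
  h2 <- (h2 * 48271 + 7) %% p
  h2 / p
}

#' @noRd
## Stable non-negative integer hash below `mod`.
.stableHashInt <- function(key, mod) {
  floor(stableHash(key) * mod)
}

#' @noRd
.spectrumKey <- function(spectra) {
  vapply(spectra, function(s) paste(s@sourceFile, s@scanNumber, sep = "/"),
         character(1))
}
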