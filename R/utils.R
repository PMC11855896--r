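#' Round half away from zero
#'
#' Fixed-point rounding used for printed percentages and thresholds, so that
#' e.g. 55.15 prints as 55.2 regardless of the IEC 60559 banker's rounding
#' used by [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up (away from zero for negatives).
#' @export
#' @examples
#' round_half_up(0.25, 1)   # 0.3
#' round(0.25, 1)           # 0.2
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Standard 20-letter amino-acid alphabet, alphabetical by one-letter code.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Letters tolerated on input beyond the standard 20.
AA_AMBIG <- c("B", "Z", "X")

#' @noRd
aa_validate <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence)) {
    stop("`sequence` must be a single character string", call. = FALSE)
  }
  if (!nzchar(sequence)) {
    stop("empty sequence", call. = FALSE)
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(AA20, AA_AMBIG))
  if (length(bad)) {
    stop(sprintf("illegal residue '%s' at position %d", chars[bad[1L]], bad[1L]),
         call. = FALSE)
  }
  chars
}

#' @noRd
as_aa_character <- function(x) {
  if (methods::is(x, "AAStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    out
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x
  } else {
    stop("expected a character vector or an AAStringSet", call. = FALSE)
  }
}
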