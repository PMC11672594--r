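#' Compile a degenerate active-site pattern to a regular expression
#'
#' The degenerate alphabet used throughout the package: `x` matches any
#' residue; a residue followed by a parenthesized list of alternatives,
#' e.g. `"I(V)"`, matches exactly one of the listed residues at that single
#' position (so `"GHSI(V)GE"` matches `GHSIGE` or `GHSVGE`). All other
#' letters match themselves.
#'
#' @param pattern degenerate pattern string.
#' @param anchored wrap in `^...$` so the regex must cover the whole window.
#' @return single regex string.
#' @examples
#' compile_pattern("GHSI(V)GE")   # "^GHS[IV]GE$"
#' compile_pattern("HxxxxxxxxP")  # "^H.{8}P$"
#' @export
compile_pattern <- function(pattern, anchored = TRUE) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  chars <- strsplit(pattern, "")[[1]]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      out <- c(out, ".")
      i <- i + 1L
    } else if (grepl("[A-WYZ]", ch)) {
      # letter, possibly followed by "(ALT...)" alternation for this position
      if (i < length(chars) && chars[i + 1L] == "(") {
        close <- which(chars == ")" & seq_along(chars) > i)
        if (!length(close)) stop("unbalanced '(' in pattern: ", pattern)
        close <- close[1L]
        alts <- chars[(i + 2L):(close - 1L)]
        if (!length(alts) || !all(grepl("[A-Z]", alts))) {
          stop("invalid alternation in pattern: ", pattern)
        }
        out <- c(out, paste0("[", ch, paste(alts, collapse = ""), "]"))
        i <- close + 1L
      } else {
        out <- c(out, ch)
        i <- i + 1L
      }
    } else {
      stop("invalid character '", ch, "' in pattern: ", pattern)
    }
  }
  # collapse runs of "." into ".{n}" for readability
  reps <- rle(out == ".")
  pieces <- character(0)
  idx <- 1L
  for (j in seq_along(reps$lengths)) {
    len <- reps$lengths[j]
    if (reps$values[j]) {
      pieces <- c(pieces, if (len == 1L) "." else paste0(".{", len, "}"))
    } else {
      pieces <- c(pieces, paste(out[idx:(idx + len - 1L)], collapse = ""))
    }
    idx <- idx + len
  }
  rx <- paste(pieces, collapse = "")
  if (anchored) paste0("^", rx, "$") else rx
}

#' Number of residues a degenerate pattern spans
#' @param pattern degenerate pattern string.
#' @return integer width.
#' @export
pattern_width <- function(pattern) {
  stripped <- gsub("\\([A-Z]+\\)", "", pattern)
  nchar(stripped)
}

#' Test whether a window matches a degenerate pattern
#' @param window amino-acid string.
#' @param pattern degenerate pattern.
#' @return logical.
#' @export
matches_pattern <- function(window, pattern) {
  grepl(compile_pattern(pattern), window)
}
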