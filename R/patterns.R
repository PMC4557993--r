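AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default hydrophobic residue class
#'
#' The degenerate-pattern symbol `h` denotes membership of this set. The
#' consensus notation only says "hydrophobic", so the set is configurable in
#' every function that interprets `h`; the default covers the aliphatic and
#' aromatic side chains A, V, L, I, M, F, W, Y.
#'
#' @return Character vector of one-letter residue codes.
#' @export
hydrophobic_residues <- function() {
  c("A", "V", "L", "I", "M", "F", "W", "Y")
}

#' Parse a degenerate consensus pattern
#'
#' Parses the block-consensus notation used throughout the package: an
#' uppercase residue letter is a fixed position, `[XY]` an alternative set,
#' lowercase `x` a wildcard and lowercase `h` a hydrophobic-class position
#' (see [hydrophobic_residues()]). Whitespace is ignored, so `"C [VA] FPFxY"`
#' and `"C[VA]FPFxY"` parse identically.
#'
#' @param text Consensus string, e.g. `"C[VA]FPFxY"`.
#' @return An object of class `bsp_pattern`: a list of position specs, each
#'   a list with elements `type` (one of `"fixed"`, `"alt"`, `"wildcard"`,
#'   `"hydrophobic"`) and `residues` (allowed residues, `NULL` for wildcard
#'   and hydrophobic positions, which are resolved at match time).
#' @seealso [format_pattern()], [match_at()]
#' @examples
#' p <- parse_pattern("C[VA]FPFxY")
#' length(p)           # 7 positions
#' format_pattern(p)   # round-trips
#' @export
parse_pattern <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("pattern text must be a single character string")
  }
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) stop("empty pattern")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  specs <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "[") {
      j <- i + 1L
      resid <- character()
      while (j <= length(chars) && chars[[j]] != "]") {
        if (!chars[[j]] %in% AA_ALPHABET) {
          stop(sprintf("unknown character '%s' at position %d of pattern",
                       chars[[j]], j))
        }
        resid <- c(resid, chars[[j]])
        j <- j + 1L
      }
      if (j > length(chars)) stop("unterminated alternative set '[' in pattern")
      if (length(resid) == 0L) stop("empty alternative set in pattern")
      specs[[length(specs) + 1L]] <- list(type = "alt", residues = resid)
      i <- j + 1L
    } else if (ch == "x") {
      specs[[length(specs) + 1L]] <- list(type = "wildcard", residues = NULL)
      i <- i + 1L
    } else if (ch == "h") {
      specs[[length(specs) + 1L]] <- list(type = "hydrophobic", residues = NULL)
      i <- i + 1L
    } else if (ch %in% AA_ALPHABET) {
      specs[[length(specs) + 1L]] <- list(type = "fixed", residues = ch)
      i <- i + 1L
    } else {
      stop(sprintf("unknown character '%s' at position %d of pattern", ch, i))
    }
  }
  structure(specs, class = "bsp_pattern")
}

#' Format a degenerate pattern back to its consensus notation
#'
#' @param pattern A `bsp_pattern` from [parse_pattern()].
#' @return Single normalized consensus string.
#' @export
format_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "bsp_pattern"))
  paste(vapply(pattern, function(s) {
    switch(s$type,
           fixed = s$residues,
           alt = paste0("[", paste(s$residues, collapse = ""), "]"),
           wildcard = "x",
           hydrophobic = "h")
  }, character(1)), collapse = "")
}

#' @export
print.bsp_pattern <- function(x, ...) {
  cat("<bsp_pattern> ", format_pattern(x), " (", length(x), " positions)\n",
      sep = "")
  invisible(x)
}

#' @export
length.bsp_pattern <- function(x) length(unclass(x))

#' Match a degenerate pattern at a given position
#'
#' Counts the pattern positions violated by the window of `sequence` starting
#' at `pos` (1-based, inclusive coordinates throughout).
#'
#' @param pattern A `bsp_pattern`.
#' @param sequence Protein sequence (single string, uppercase one-letter code).
#' @param pos 1-based start of the window.
#' @param tolerance Maximum number of violated positions still reported as a
#'   match.
#' @param hydrophobic Residue set the `h` symbol accepts.
#' @return List with `matched` (logical) and `mismatches` (integer).
#' @export
match_at <- function(pattern, sequence, pos, tolerance = 0L,
                     hydrophobic = hydrophobic_residues()) {
  stopifnot(inherits(pattern, "bsp_pattern"), pos >= 1L)
  n <- length(pattern)
  if (pos + n - 1L > nchar(sequence)) {
    stop(sprintf("window [%d,%d] overruns sequence end (length %d)",
                 pos, pos + n - 1L, nchar(sequence)))
  }
  window <- strsplit(substr(sequence, pos, pos + n - 1L), "", fixed = TRUE)[[1]]
  mism <- 0L
  for (k in seq_len(n)) {
    s <- pattern[[k]]
    ok <- switch(s$type,
                 fixed = window[[k]] == s$residues,
                 alt = window[[k]] %in% s$residues,
                 wildcard = TRUE,
                 hydrophobic = window[[k]] %in% hydrophobic)
    if (!ok) mism <- mism + 1L
  }
  list(matched = mism <= tolerance, mismatches = mism)
}

# Validate that a protein string only uses the 20 canonical residue letters;
# error lists every offending symbol.
check_protein <- function(sequence) {
  chars <- unique(strsplit(sequence, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("non-amino-acid characters in sequence: %s",
                 paste(sQuote(bad), collapse = ", ")))
  }
  invisible(TRUE)
}
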