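# Conserved-block definitions and the degenerate-pattern scanner.
#
# The nine blocks (I..IX) tile an 87-position core frame: four blocks per
# FN2 domain plus a short linker block (V) between the domains. Coordinates
# are 1-based and anchored at the Block I cysteine (= core position 1).

BLOCK_IDS <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX")

# Load and cache the shipped block resource (JSON, consensus notation).
block_resource <- function() {
  if (is.null(.bsp_cache$blocks_json)) {
    path <- system.file("extdata", "conserved_blocks.json", package = "bsptools")
    .bsp_cache$blocks_json <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  .bsp_cache$blocks_json
}

#' Definitions of the nine conserved blocks
#'
#' Returns the block table of the tandem-FN2 core: degenerate consensus
#' pattern, parent domain (`FN2_1`, `linker`, `FN2_2`), and canonical start
#' and length in the 87-position core frame. Definitions are shipped as a
#' versioned JSON resource (`inst/extdata/conserved_blocks.json`).
#'
#' @param relaxed_block2 If `TRUE`, Block II's terminal serine is generalized
#'   to the small-residue set `[SAGT]`, which accommodates the alanine seen
#'   at that position in BSPH1 proteins. Default keeps the strict consensus.
#' @return A data.frame with columns `block_id`, `domain`, `pattern`
#'   (consensus string), `canonical_start`, `canonical_length`, plus a list
#'   column `parsed` of `bsp_pattern` objects.
#' @examples
#' block_definitions()[, c("block_id", "pattern", "canonical_start")]
#' @export
block_definitions <- function(relaxed_block2 = FALSE) {
  res <- block_resource()
  df <- do.call(rbind, lapply(res$blocks, function(b) {
    data.frame(block_id = b$block_id, domain = b$domain, pattern = b$pattern,
               canonical_start = b$canonical_start,
               canonical_length = b$canonical_length,
               stringsAsFactors = FALSE)
  }))
  if (relaxed_block2) {
    df$pattern[df$block_id == "II"] <- res$block2_bsph1_pattern
  }
  df$parsed <- lapply(df$pattern, parse_pattern)
  stopifnot(identical(df$block_id, BLOCK_IDS),
            all(vapply(df$parsed, length, 1L) == df$canonical_length))
  df
}

# Canonical inter-block gaps (residues between end of block k and start of
# block k+1), derived from canonical coordinates.
canonical_gaps <- function(blocks = block_definitions()) {
  ends <- blocks$canonical_start + blocks$canonical_length - 1L
  blocks$canonical_start[-1L] - ends[-nrow(blocks)] - 1L
}

#' Scan a protein sequence for all nine conserved blocks
#'
#' Exhaustive position-by-position matching of each block's degenerate
#' pattern against the query: every window whose mismatch count is within
#' `tolerance` is reported. Use [assemble_architecture()] to reduce the raw
#' match list to a mutually consistent tandem-FN2 chain.
#'
#' @param sequence Protein sequence (single uppercase string). Sequences
#'   shorter than the 87-residue core frame are allowed and can only yield
#'   partial architectures.
#' @param tolerance Maximum mismatches per block (default 1: natural
#'   sequences deviate from the consensus at single positions, e.g. the
#'   Block IV aromatic position in ram RSVP20; set 0 for exact mode).
#' @param blocks Block table from [block_definitions()].
#' @param hydrophobic Residue set accepted by the `h` symbol.
#' @return A data.frame of matches sorted by start then block order, with
#'   columns `block_id`, `start`, `end`, `subsequence`, `mismatches`,
#'   `exact`. Zero rows when nothing matches.
#' @examples
#' hits <- scan_blocks(canonical_core(), tolerance = 0)
#' subset(hits, mismatches == 0)$block_id
#' @export
scan_blocks <- function(sequence, tolerance = 1L,
                        blocks = block_definitions(),
                        hydrophobic = hydrophobic_residues()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  check_protein(sequence)
  n <- nchar(sequence)
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    pat <- blocks$parsed[[i]]
    len <- length(pat)
    if (n < len) next
    for (pos in seq_len(n - len + 1L)) {
      m <- match_at(pat, sequence, pos, tolerance = tolerance,
                    hydrophobic = hydrophobic)
      if (m$matched) {
        out[[length(out) + 1L]] <- data.frame(
          block_id = blocks$block_id[[i]],
          start = pos, end = pos + len - 1L,
          subsequence = substr(sequence, pos, pos + len - 1L),
          mismatches = m$mismatches,
          exact = m$mismatches == 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(block_id = character(), start = integer(),
                      end = integer(), subsequence = character(),
                      mismatches = integer(), exact = logical(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, match(df$block_id, BLOCK_IDS), df$mismatches), ]
  rownames(df) <- NULL
  df
}

#' Deterministic canonical 87-residue core sequence
#'
#' Instantiates the consensus with a fixed rule (fixed residues kept, the
#' first residue of each alternative set, leucine for hydrophobic positions,
#' glycine for wildcards and inter-block gaps). The second cysteine of the
#' C-terminal domain's disulfide pair - which sits in the gap between
#' Blocks VI and VII and is not housed by any block - is placed at core
#' position 56, so both FN2 domains carry their two conserved bonds. Useful
#' as a noise-free test article; the synthetic panel generator
#' ([generate_panel()]) samples the free positions instead.
#'
#' @return 87-character protein string.
#' @export
canonical_core <- function() {
  blocks <- block_definitions()
  core <- rep("G", 87L)
  core[56L] <- "C"                      # unhoused 2FN2 disulfide partner
  for (i in seq_len(nrow(blocks))) {
    pat <- blocks$parsed[[i]]
    at <- blocks$canonical_start[[i]]
    for (k in seq_along(pat)) {
      s <- pat[[k]]
      core[at + k - 1L] <- switch(s$type,
                                  fixed = s$residues,
                                  alt = s$residues[[1]],
                                  wildcard = "G",
                                  hydrophobic = "L")
    }
  }
  paste(core, collapse = "")
}

#' Write a block-scan report as TSV
#'
#' @param matches Data.frame from [scan_blocks()] (a `seq_id` column is
#'   added if absent).
#' @param path Output file.
#' @param seq_id Identifier used when `matches` lacks a `seq_id` column.
#' @return Invisibly, the path.
#' @export
write_scan_report <- function(matches, path, seq_id = "query") {
  if (!"seq_id" %in% names(matches)) {
    matches <- cbind(seq_id = rep(seq_id, nrow(matches)), matches)
  }
  write_tsv_report(matches, path)
}
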