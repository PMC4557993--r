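# Assembly of raw block matches into a validated tandem-FN2 architecture.
#
# An architecture is the highest-scoring mutually consistent chain of block
# matches: blocks in order I < II < ... < IX, with inter-block spacing within
# a slack of the canonical gaps. Chain score is lexicographic:
# more blocks > fewer total mismatches > leftmost starts.

#' Assemble block matches into a tandem-FN2 architecture
#'
#' Selects, by dynamic programming over the per-block candidate matches, the
#' best chain of mutually compatible blocks. Two matches for blocks i < j are
#' compatible when they do not overlap and the observed start offset deviates
#' from the canonical offset by at most `gap_slack` per block step. The
#' architecture is `complete` when all nine blocks are chained.
#'
#' @param matches Data.frame from [scan_blocks()].
#' @param sequence The scanned protein sequence (used for the C-terminal
#'   extension and disulfide checks).
#' @param gap_slack Allowed deviation (residues) from each canonical
#'   inter-block gap; default 2 tolerates natural linker-length variation.
#' @param seq_id Identifier carried into reports.
#' @return An object of class `bsp_architecture`: list with `seq_id`,
#'   `chain` (the chosen matches, one row per chained block), `complete`,
#'   `fn2_1_span`, `linker_span`, `fn2_2_span` (1-based inclusive
#'   `c(start, end)` or `NULL`), `cter_extension` (residues after Block IX),
#'   `disulfides` (filled by [check_disulfides()]), and `sequence`.
#' @examples
#' seq <- canonical_core()
#' arch <- assemble_architecture(scan_blocks(seq, 0), seq)
#' arch$complete
#' arch$fn2_1_span
#' @export
assemble_architecture <- function(matches, sequence, gap_slack = 2L,
                                  seq_id = "query") {
  blocks <- block_definitions()
  cand <- lapply(BLOCK_IDS, function(b) {
    m <- matches[matches$block_id == b, , drop = FALSE]
    m[order(m$start, m$mismatches), , drop = FALSE]
  })
  names(cand) <- BLOCK_IDS

  # DP over blocks; state = (block index, candidate index).
  # best[[i]][[c]] = list(count, mism, starts, prev = c(i, c) or NULL)
  best <- vector("list", 9L)
  for (i in seq_len(9L)) {
    ci <- cand[[i]]
    if (nrow(ci) == 0L) next
    best[[i]] <- vector("list", nrow(ci))
    for (cc in seq_len(nrow(ci))) {
      cur <- list(count = 1L, mism = ci$mismatches[[cc]],
                  starts = ci$start[[cc]], prev = NULL)
      for (j in seq_len(i - 1L)) {
        cj <- cand[[j]]
        if (is.null(best[[j]])) next
        for (pc in seq_len(nrow(cj))) {
          if (!compatible_blocks(j, cj[pc, ], i, ci[cc, ], blocks, gap_slack)) next
          prev <- best[[j]][[pc]]
          cand_state <- list(count = prev$count + 1L,
                             mism = prev$mism + ci$mismatches[[cc]],
                             starts = c(prev$starts, ci$start[[cc]]),
                             prev = c(j, pc))
          if (chain_better(cand_state, cur)) cur <- cand_state
        }
      }
      best[[i]][[cc]] <- cur
    }
  }

  # Global best terminal state.
  top <- NULL; top_at <- NULL
  for (i in seq_len(9L)) {
    if (is.null(best[[i]])) next
    for (cc in seq_along(best[[i]])) {
      st <- best[[i]][[cc]]
      if (is.null(top) || chain_better(st, top)) { top <- st; top_at <- c(i, cc) }
    }
  }

  chain <- matches[0, , drop = FALSE]
  if (!is.null(top)) {
    idx <- top_at
    rows <- list()
    while (!is.null(idx)) {
      st <- best[[idx[[1]]]][[idx[[2]]]]
      rows[[length(rows) + 1L]] <- cand[[idx[[1]]]][idx[[2]], , drop = FALSE]
      idx <- st$prev
    }
    chain <- do.call(rbind, rev(rows))
    rownames(chain) <- NULL
  }

  arch_from_chain(chain, sequence, seq_id)
}

# Compatibility of candidate matches for blocks j < i: ordered, non
# overlapping, observed offset within canonical offset +/- slack per step.
compatible_blocks <- function(j, mj, i, mi, blocks, gap_slack) {
  if (mi$start <= mj$start) return(FALSE)
  if (mi$start <= mj$end) return(FALSE)                       # no overlap
  canon <- blocks$canonical_start[[i]] - blocks$canonical_start[[j]]
  abs((mi$start - mj$start) - canon) <= gap_slack * (i - j)
}

# Lexicographic chain comparison: block count desc, mismatches asc,
# starts vector lexicographically asc (leftmost wins).
chain_better <- function(a, b) {
  if (a$count != b$count) return(a$count > b$count)
  if (a$mism != b$mism) return(a$mism < b$mism)
  n <- min(length(a$starts), length(b$starts))
  for (k in seq_len(n)) {
    if (a$starts[[k]] != b$starts[[k]]) return(a$starts[[k]] < b$starts[[k]])
  }
  FALSE
}

arch_from_chain <- function(chain, sequence, seq_id) {
  get_span <- function(from, to) {
    a <- chain[chain$block_id == from, , drop = FALSE]
    b <- chain[chain$block_id == to, , drop = FALSE]
    if (nrow(a) == 1L && nrow(b) == 1L) c(a$start, b$end) else NULL
  }
  complete <- nrow(chain) == 9L
  ix <- chain[chain$block_id == "IX", , drop = FALSE]
  cter <- if (nrow(ix) == 1L && ix$end < nchar(sequence)) {
    substr(sequence, ix$end + 1L, nchar(sequence))
  } else ""
  arch <- structure(list(
    seq_id = seq_id,
    chain = chain,
    complete = complete,
    fn2_1_span = get_span("I", "IV"),
    linker_span = get_span("V", "V"),
    fn2_2_span = get_span("VI", "IX"),
    cter_extension = cter,
    disulfides = NULL,
    sequence = sequence
  ), class = "bsp_architecture")
  arch$disulfides <- check_disulfides(arch, sequence)
  arch
}

#' @export
print.bsp_architecture <- function(x, ...) {
  cat("<bsp_architecture> ", x$seq_id,
      if (x$complete) " [complete tandem FN2]" else
        sprintf(" [partial: %d/9 blocks]", nrow(x$chain)), "\n", sep = "")
  if (!is.null(x$fn2_1_span))
    cat("  FN2_1:", x$fn2_1_span[1], "-", x$fn2_1_span[2], "\n")
  if (!is.null(x$linker_span))
    cat("  linker:", x$linker_span[1], "-", x$linker_span[2], "\n")
  if (!is.null(x$fn2_2_span))
    cat("  FN2_2:", x$fn2_2_span[1], "-", x$fn2_2_span[2], "\n")
  invisible(x)
}

# Position of cysteine k within a block pattern, counted in the query frame.
block_pos <- function(chain, block_id, offset) {
  row <- chain[chain$block_id == block_id, , drop = FALSE]
  if (nrow(row) != 1L) return(NA_integer_)
  row$start + offset - 1L
}

#' Check the conserved disulfide topology of an architecture
#'
#' Each complete FN2 domain carries two conserved disulfide bonds with
#' 1-3 / 2-4 connectivity. In the N-terminal domain the four cysteines live
#' in Blocks I, II, III and IV; in the C-terminal domain the first and third
#' live in Blocks VI and VIII while the second is expected in the gap between
#' Blocks VI and VII (it is not housed by any block, so its absence is
#' reported as `incomplete`, not as a failure) and the fourth in Block IX.
#'
#' @param arch A `bsp_architecture`.
#' @param sequence Protein sequence (defaults to the one stored in `arch`).
#' @return Data.frame with columns `domain`, `pair` (1 or 2), `pos1`, `pos2`
#'   (query coordinates; `NA` when the partner is not locatable), `status`
#'   (`"confirmed"`, `"violated"`, `"incomplete"`), plus attribute `valid`:
#'   TRUE when every locatable required cysteine is indeed a cysteine.
#' @export
check_disulfides <- function(arch, sequence = arch$sequence) {
  chain <- arch$chain
  res <- list()
  is_c <- function(pos) {
    !is.na(pos) && pos >= 1L && pos <= nchar(sequence) &&
      substr(sequence, pos, pos) == "C"
  }
  add_pair <- function(domain, pair, p1, p2) {
    status <- if (is.na(p1) || is.na(p2)) "incomplete"
              else if (is_c(p1) && is_c(p2)) "confirmed" else "violated"
    res[[length(res) + 1L]] <<- data.frame(
      domain = domain, pair = pair, pos1 = p1, pos2 = p2, status = status,
      stringsAsFactors = FALSE)
  }
  has <- function(b) b %in% chain$block_id

  if (has("I") && has("III"))
    add_pair("FN2_1", 1L, block_pos(chain, "I", 1L), block_pos(chain, "III", 4L))
  if (has("II") && has("IV"))
    add_pair("FN2_1", 2L, block_pos(chain, "II", 1L), block_pos(chain, "IV", 8L))
  if (has("VI") && has("VIII"))
    add_pair("FN2_2", 1L, block_pos(chain, "VI", 1L), block_pos(chain, "VIII", 6L))
  if (has("VI") && has("VII") && has("IX")) {
    # search the VI -> VII gap for the unhoused second cysteine
    gap_from <- block_pos(chain, "VI", 7L) + 1L
    gap_to <- block_pos(chain, "VII", 1L) - 1L
    gap_c <- NA_integer_
    if (gap_from <= gap_to) {
      gap_res <- strsplit(substr(sequence, gap_from, gap_to), "")[[1]]
      hit <- which(gap_res == "C")
      if (length(hit) > 0L) gap_c <- gap_from + hit[[1]] - 1L
    }
    add_pair("FN2_2", 2L, gap_c, block_pos(chain, "IX", 10L))
  }
  df <- if (length(res) > 0L) do.call(rbind, res) else
    data.frame(domain = character(), pair = integer(), pos1 = integer(),
               pos2 = integer(), status = character(), stringsAsFactors = FALSE)
  attr(df, "valid") <- !any(df$status == "violated")
  df
}

#' Summarize architectures as a report table
#'
#' @param archs List of `bsp_architecture` objects.
#' @return Data.frame with one row per sequence: completeness, spans,
#'   number of confirmed disulfide pairs, and C-terminal extension.
#' @export
architecture_report <- function(archs) {
  do.call(rbind, lapply(archs, function(a) {
    span_str <- function(s) if (is.null(s)) "" else paste(s, collapse = "-")
    data.frame(seq_id = a$seq_id,
               complete = a$complete,
               n_blocks = nrow(a$chain),
               fn2_1 = span_str(a$fn2_1_span),
               linker = span_str(a$linker_span),
               fn2_2 = span_str(a$fn2_2_span),
               n_disulfides_confirmed = sum(a$disulfides$status == "confirmed"),
               cter_extension = a$cter_extension,
               stringsAsFactors = FALSE)
  }))
}
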