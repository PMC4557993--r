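# Gene-neighborhood (synteny) pattern matching.
#
# Three conserved gene-context patterns surround BSP-superfamily loci:
#   BSP             core BSP genes between the CD177/TEX101 cluster and the
#                   LYPD3/PHLDB3/ETHE1/ZNF575 cluster
#   BSPH_ELSPBP1    BSPH1 (with BSPH2) next to C19orf68/LIG1/CABP5/ELSPBP1
#                   and SULT2A1/CRX
#   BSPH_noELSPBP1  BSPH1/BSPH2 with PLA2G4C present and ELSPBP1 absent
# Matching is orientation-agnostic: gene order may be reversed.

#' The three synteny pattern definitions
#'
#' @return Named list of patterns; each has `pattern_id`, `anchors` (flank
#'   genes scored), `core_families` (family tokens accepted as core genes),
#'   `required` (anchors that must be present) and `forbidden` (genes that
#'   must be absent from the record).
#' @export
synteny_patterns <- function() {
  list(
    BSP = list(
      pattern_id = "BSP",
      anchors = c("CD177", "TEX101", "LYPD3", "PHLDB3", "ETHE1", "ZNF575"),
      core_families = "BSP",
      required = character(0),
      forbidden = character(0)),
    BSPH_ELSPBP1 = list(
      pattern_id = "BSPH_ELSPBP1",
      anchors = c("C19ORF68", "LIG1", "CABP5", "ELSPBP1",
                  "SULT2A1", "CRX"),
      core_families = c("BSPH1", "BSPH2"),
      required = character(0),
      forbidden = character(0)),
    BSPH_noELSPBP1 = list(
      pattern_id = "BSPH_noELSPBP1",
      anchors = c("PLA2G4C", "SULT2A1", "CRX"),
      core_families = c("BSPH1", "BSPH2"),
      required = "PLA2G4C",
      forbidden = "ELSPBP1")
  )
}

#' Build a neighborhood record
#'
#' @param symbols Ordered gene symbols along the scaffold.
#' @param scaffold_id,species,source Metadata.
#' @param strand Optional strand vector (`+`/`-`), same length as `symbols`.
#' @param calls Optional per-gene sequence-based family calls (`""`/`NA`
#'   where absent): family tokens or `bsp_family_call` objects.
#' @return Object of class `bsp_neighborhood`.
#' @export
neighborhood_record <- function(symbols, scaffold_id = "scaffold",
                                species = "", source = "", strand = NULL,
                                calls = NULL) {
  stopifnot(length(symbols) >= 1L)
  symbols <- toupper(trimws(symbols))
  if (!is.null(calls)) {
    calls <- vapply(calls, function(cl) {
      if (inherits(cl, "bsp_family_call")) cl$family
      else if (is.na(cl)) "" else as.character(cl)
    }, character(1))
    stopifnot(length(calls) == length(symbols))
  } else {
    calls <- rep("", length(symbols))
  }
  if (is.null(strand)) strand <- rep("", length(symbols))
  structure(list(scaffold_id = scaffold_id, species = species,
                 source = source,
                 genes = data.frame(rank = seq_along(symbols),
                                    symbol = symbols, strand = strand,
                                    call = calls, stringsAsFactors = FALSE)),
            class = "bsp_neighborhood")
}

#' Match a neighborhood against the three synteny patterns
#'
#' Core genes are those whose symbol carries a BSP-superfamily family token
#' (after synonym resolution). For each pattern whose core-family
#' requirement is met, forbidden genes absent and required anchors present,
#' the score is the fraction of pattern anchors found within `window` genes
#' of the outermost core genes (orientation-agnostic). The best pattern
#' with score >= `threshold` is returned.
#'
#' @param rec A `bsp_neighborhood` (or character vector of symbols).
#' @param window Genes searched on each side of the outermost core gene
#'   (default 10).
#' @param threshold Minimum anchor score (default 0.5).
#' @return List with `pattern_id` (`"none"` when no pattern fires),
#'   `score`, `anchor_hits` (anchors found, best pattern), `reason`
#'   (`"no core"` when the record has no BSP-superfamily gene), and
#'   `scores` for all patterns.
#' @export
match_pattern <- function(rec, window = 10L, threshold = 0.5) {
  if (!inherits(rec, "bsp_neighborhood")) rec <- neighborhood_record(rec)
  genes <- rec$genes
  fam <- vapply(genes$symbol, family_token, character(1))
  core_idx <- which(fam %in% c("BSP", "BSPH1", "BSPH2"))
  if (length(core_idx) == 0L) {
    return(list(pattern_id = "none", score = 0, anchor_hits = character(0),
                reason = "no core", scores = numeric(0)))
  }
  lo <- max(1L, min(core_idx) - window)
  hi <- min(nrow(genes), max(core_idx) + window)
  windowed <- genes$symbol[lo:hi]

  pats <- synteny_patterns()
  scores <- stats::setNames(rep(0, length(pats)), names(pats))
  hits <- stats::setNames(vector("list", length(pats)), names(pats))
  eligible <- stats::setNames(rep(FALSE, length(pats)), names(pats))
  for (pn in names(pats)) {
    p <- pats[[pn]]
    found <- intersect(p$anchors, windowed)
    scores[[pn]] <- length(found) / length(p$anchors)
    hits[[pn]] <- found
    eligible[[pn]] <- any(fam[core_idx] %in% p$core_families) &&
      all(p$required %in% windowed) &&
      !any(p$forbidden %in% genes$symbol)
  }
  ok <- eligible & scores >= threshold
  if (!any(ok)) {
    return(list(pattern_id = "none", score = max(scores),
                anchor_hits = character(0), reason = "below threshold",
                scores = scores))
  }
  best <- names(which(ok))[which.max(scores[ok])]
  list(pattern_id = best, score = scores[[best]],
       anchor_hits = hits[[best]], reason = "", scores = scores)
}

#' Cross-check gene symbols against sequence-based family calls
#'
#' @param rec A `bsp_neighborhood` whose `genes$call` column carries family
#'   calls for at least some genes.
#' @param window,threshold Passed to [match_pattern()] for the context note.
#' @return Data.frame with one row per gene whose symbol-derived family
#'   differs from its sequence-based call: `scaffold_id`, `rank`, `symbol`,
#'   `symbol_family`, `call_family`, `pattern_context`, `note`. Zero rows
#'   when everything is consistent (or no gene carries a call).
#' @export
cross_check <- function(rec, window = 10L, threshold = 0.5) {
  stopifnot(inherits(rec, "bsp_neighborhood"))
  genes <- rec$genes
  pat <- match_pattern(rec, window, threshold)$pattern_id
  out <- list()
  for (i in seq_len(nrow(genes))) {
    cl <- genes$call[[i]]
    if (!nzchar(cl)) next
    sym_fam <- family_token(genes$symbol[[i]])
    if (!sym_fam %in% c("BSP", "BSPH1", "BSPH2")) next
    if (sym_fam != cl) {
      out[[length(out) + 1L]] <- data.frame(
        scaffold_id = rec$scaffold_id, rank = genes$rank[[i]],
        symbol = genes$symbol[[i]], symbol_family = sym_fam,
        call_family = cl, pattern_context = pat,
        note = sprintf("labelled %s in a %s context, sequence says %s",
                       sym_fam, pat, cl),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(scaffold_id = character(), rank = integer(),
                      symbol = character(), symbol_family = character(),
                      call_family = character(), pattern_context = character(),
                      note = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read neighborhood records from a TSV file
#'
#' Expected columns: `scaffold_id`, `species`, `source`, `rank`, `symbol`,
#' optionally `strand` and `call`. One record is built per scaffold, genes
#' ordered by `rank`.
#'
#' @param path TSV file.
#' @return Named list of `bsp_neighborhood` objects.
#' @export
read_neighborhoods <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                          comment.char = "#")
  need <- c("scaffold_id", "species", "source", "rank", "symbol")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("neighborhood TSV %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  for (col in intersect(c("strand", "call"), names(df))) {
    df[[col]][is.na(df[[col]])] <- ""
  }
  recs <- lapply(split(df, df$scaffold_id), function(g) {
    g <- g[order(g$rank), ]
    neighborhood_record(
      g$symbol, scaffold_id = g$scaffold_id[[1]], species = g$species[[1]],
      source = g$source[[1]],
      strand = if ("strand" %in% names(g)) g$strand else NULL,
      calls = if ("call" %in% names(g)) g$call else NULL)
  })
  recs[unique(df$scaffold_id)]
}

#' Bundled synteny fixture neighborhoods
#'
#' Neighborhood records built from the published gene lists: a bovine-style
#' BSP context, an ovine-style BSPH1/ELSPBP1 context, a murine-style
#' BSPH1/BSPH2 context without ELSPBP1, and a ferret-style record whose
#' BSPH1-labelled gene carries a BSPH2 sequence call (the misannotation
#' case).
#'
#' @return Named list of `bsp_neighborhood` objects.
#' @export
fixture_neighborhoods <- function() {
  path <- system.file("extdata", "neighborhoods_fixture.tsv",
                      package = "bsptools")
  read_neighborhoods(path)
}
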