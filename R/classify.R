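# Family-level classification of tandem-FN2 architectures.
#
# BSPH1 and BSPH2 each carry diagnostic exact versions ("fingerprints") of
# particular blocks; BSP proteins carry none. A sequence with a complete
# architecture is called BSPH1 or BSPH2 when enough fingerprint components
# match, BSP when neither fingerprint reaches the threshold.

FAMILY_LEVELS <- c("BSP", "BSPH1", "BSPH2", "unclassified", "not_BSP_superfamily")
BSP_SUBFAMILIES <- c("BSP1", "BSP2", "BSP3", "BSP5")

#' Family fingerprints
#'
#' The diagnostic block-level fingerprints: BSPH1 has exact versions of
#' Blocks III (`HKWCSLN`), VI (`ChFPFWY`, `h` hydrophobic) and VIII
#' (`FGKKWCSLT`); BSPH2 has Block IX (`YNxDxKWKQC`), the linker Block V
#' (`DPP`), Block IV (`FxGRWRYC`) and a strictly conserved `SP` dipeptide
#' immediately after Block IX (`CTER` component).
#'
#' @return Named list (`BSPH1`, `BSPH2`) of named character vectors mapping
#'   component (block id or `"CTER"`) to the fingerprint string.
#' @export
family_fingerprints <- function() {
  fp <- block_resource()$fingerprints
  lapply(fp, function(x) unlist(x))
}

# Residues a position spec allows.
spec_residues <- function(s, hydrophobic = hydrophobic_residues()) {
  switch(s$type,
         fixed = s$residues,
         alt = s$residues,
         wildcard = AA_ALPHABET,
         hydrophobic = hydrophobic)
}

# Evaluate an observed segment against a fingerprint component.
#
# A fingerprint's diagnostic positions are those where it is strictly
# narrower than the superfamily block consensus (e.g. the H and K of the
# BSPH1 Block III fingerprint HKWCSLN, or the W of ChFPFWY): that is where
# the discriminating information lives, since the remaining scaffold
# positions are shared with every family. The component matches when all
# diagnostic positions are satisfied and at most `tolerance` scaffold
# positions deviate. Returns list(mismatches, diagnostic_ok, matched).
fingerprint_component <- function(segment, fingerprint, consensus = NULL,
                                  tolerance = 1L,
                                  hydrophobic = hydrophobic_residues()) {
  pat <- parse_pattern(fingerprint)
  if (is.na(segment) || nchar(segment) != length(pat)) {
    return(list(mismatches = length(pat), diagnostic_ok = FALSE,
                matched = FALSE))
  }
  res <- strsplit(segment, "", fixed = TRUE)[[1]]
  mism <- 0L
  diag_ok <- TRUE
  for (k in seq_along(pat)) {
    fp_set <- spec_residues(pat[[k]], hydrophobic)
    cons_set <- if (is.null(consensus)) AA_ALPHABET
                else spec_residues(consensus[[k]], hydrophobic)
    diagnostic <- is.null(consensus) ||
      (all(fp_set %in% cons_set) && length(fp_set) < length(cons_set))
    ok <- res[[k]] %in% fp_set
    if (!ok) {
      mism <- mism + 1L
      if (diagnostic) diag_ok <- FALSE
    }
  }
  list(mismatches = mism, diagnostic_ok = diag_ok,
       matched = diag_ok && mism <= tolerance)
}

#' Classify an architecture into BSP / BSPH1 / BSPH2
#'
#' Scores each family fingerprint as the fraction of its components matched
#' (a component matches when the corresponding chained block - or the
#' dipeptide after Block IX for the `CTER` component - deviates from the
#' fingerprint at no more than `component_tolerance` residues). The call is
#' `not_BSP_superfamily` for incomplete architectures; `BSPH1` (resp.
#' `BSPH2`) when that score reaches `theta` and exceeds the other;
#' `unclassified` on a tie at or above `theta`; otherwise `BSP`.
#'
#' @param arch A `bsp_architecture` from [assemble_architecture()].
#' @param sequence Protein sequence (defaults to the one in `arch`).
#' @param theta Fraction of fingerprint components required (default 2/3).
#' @param component_tolerance Residue mismatches tolerated inside a matched
#'   component (default 1).
#' @param hydrophobic Residue set for `h` positions.
#' @return Object of class `bsp_family_call`: list with `seq_id`, `family`,
#'   `subfamily` (filled by [assign_subfamily()], `"none"` here), `evidence`
#'   (data.frame of per-component mismatches), `score_BSPH1`, `score_BSPH2`.
#' @export
classify_family <- function(arch, sequence = arch$sequence, theta = 2 / 3,
                            component_tolerance = 1L,
                            hydrophobic = hydrophobic_residues()) {
  stopifnot(inherits(arch, "bsp_architecture"))
  fps <- family_fingerprints()
  evidence <- list()
  scores <- c(BSPH1 = 0, BSPH2 = 0)
  if (arch$complete) {
    blocks <- block_definitions()
    # Core-frame anchor: components are read both from the chained block
    # match and from the canonical coordinates relative to Block I. The
    # second view matters for fingerprints that deviate from the block
    # consensus itself (the BSPH2 linker DPP violates the consensus xxD, so
    # the best-scoring chain can place Block V one position off the
    # fingerprint); the better-matching view is kept as evidence.
    anchor <- arch$chain$start[arch$chain$block_id == "I"]
    canonical_seg <- function(from, len) {
      if (length(anchor) != 1L) return(NA_character_)
      start <- anchor + from - 1L
      if (start + len - 1L > nchar(sequence)) return(NA_character_)
      substr(sequence, start, start + len - 1L)
    }
    for (fam in names(fps)) {
      comp <- fps[[fam]]
      matched <- logical(length(comp))
      for (k in seq_along(comp)) {
        name <- names(comp)[[k]]
        fp_len <- length(parse_pattern(comp[[k]]))
        consensus <- NULL
        if (name == "CTER") {
          ix_end <- arch$chain$end[arch$chain$block_id == "IX"]
          segs <- c(substr(sequence, ix_end + 1L, ix_end + fp_len),
                    canonical_seg(88L, fp_len))
        } else {
          bi <- which(blocks$block_id == name)
          consensus <- blocks$parsed[[bi]]
          segs <- c(arch$chain$subsequence[arch$chain$block_id == name],
                    canonical_seg(blocks$canonical_start[[bi]], fp_len))
        }
        segs <- unique(segs[!is.na(segs)])
        fcs <- lapply(segs, fingerprint_component, fingerprint = comp[[k]],
                      consensus = consensus, tolerance = component_tolerance,
                      hydrophobic = hydrophobic)
        pick <- order(!vapply(fcs, `[[`, TRUE, "matched"),
                      vapply(fcs, `[[`, 0L, "mismatches"))[[1]]
        fc <- fcs[[pick]]
        matched[[k]] <- fc$matched
        evidence[[length(evidence) + 1L]] <- data.frame(
          family = fam, component = name, fingerprint = comp[[k]],
          observed = segs[[pick]], mismatches = fc$mismatches,
          diagnostic_ok = fc$diagnostic_ok, matched = fc$matched,
          stringsAsFactors = FALSE)
      }
      scores[[fam]] <- mean(matched)
    }
  }
  family <- if (!arch$complete) {
    "not_BSP_superfamily"
  } else if (scores[["BSPH1"]] >= theta && scores[["BSPH1"]] > scores[["BSPH2"]]) {
    "BSPH1"
  } else if (scores[["BSPH2"]] >= theta && scores[["BSPH2"]] > scores[["BSPH1"]]) {
    "BSPH2"
  } else if (scores[["BSPH1"]] < theta && scores[["BSPH2"]] < theta) {
    "BSP"
  } else {
    "unclassified"
  }
  structure(list(
    seq_id = arch$seq_id,
    family = family,
    subfamily = "none",
    evidence = if (length(evidence) > 0L) do.call(rbind, evidence) else NULL,
    score_BSPH1 = scores[["BSPH1"]],
    score_BSPH2 = scores[["BSPH2"]],
    ambiguous_subfamily = FALSE
  ), class = "bsp_family_call")
}

#' @export
print.bsp_family_call <- function(x, ...) {
  cat("<bsp_family_call> ", x$seq_id, ": ", x$family,
      if (x$subfamily != "none") paste0(" / ", x$subfamily) else "",
      sprintf("  (BSPH1 %.2f, BSPH2 %.2f)\n", x$score_BSPH1, x$score_BSPH2),
      sep = "")
  invisible(x)
}

# Pairwise-deletion identity between two equal-length (possibly gapped) rows.
pairwise_identity <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(av) == length(bv))
  keep <- av != "-" & bv != "-"
  if (!any(keep)) return(NA_real_)
  mean(av[keep] == bv[keep])
}

#' Assign a BSP subfamily by nearest labelled reference
#'
#' Subfamilies (BSP1, BSP2, BSP3, BSP5) are defined by tree clades, not by
#' printed motifs, so assignment is by highest pairwise-deletion identity
#' over the 87-position core against a labelled reference panel. Ties are
#' broken toward the alphabetically first subfamily and flagged ambiguous.
#'
#' @param call A `bsp_family_call` with `family == "BSP"`.
#' @param core 87-residue core of the query (e.g. [extract_core()]).
#' @param references Data.frame with columns `subfamily` and `core`
#'   (87-residue reference cores), e.g. from [generate_reference_panel()].
#' @param floor Minimum identity for an assignment (default 0.40); below it
#'   the subfamily is `"none"`.
#' @return The input call with `subfamily` (and `ambiguous_subfamily`) set.
#' @export
assign_subfamily <- function(call, core, references, floor = 0.40) {
  stopifnot(inherits(call, "bsp_family_call"))
  if (call$family != "BSP") return(call)
  if (is.null(references) || nrow(references) == 0L) {
    stop("empty subfamily reference panel")
  }
  ident <- vapply(references$core, function(r) pairwise_identity(core, r),
                  numeric(1))
  by_sub <- tapply(ident, references$subfamily, max)
  best <- max(by_sub)
  if (is.na(best) || best < floor) {
    call$subfamily <- "none"
    return(call)
  }
  winners <- sort(names(by_sub)[by_sub == best])
  call$subfamily <- winners[[1]]
  call$ambiguous_subfamily <- length(winners) > 1L
  call
}

#' Extract the 87-position core frame of an architecture
#'
#' The core frame starts at the Block I cysteine. When Block I itself was
#' not matched the anchor is inferred from the first chained block's
#' canonical offset, so partial architectures still yield a core. Returns
#' `NA` when no block is chained or the frame runs past either end of the
#' sequence.
#'
#' @param arch A `bsp_architecture`.
#' @return 87-character string or `NA`.
#' @export
extract_core <- function(arch) {
  if (nrow(arch$chain) == 0L) return(NA_character_)
  blocks <- block_definitions()
  first <- arch$chain[1L, ]
  start <- first$start -
    (blocks$canonical_start[blocks$block_id == first$block_id] - 1L)
  if (start < 1L || start + 86L > nchar(arch$sequence)) return(NA_character_)
  substr(arch$sequence, start, start + 86L)
}

# ---- annotation reconciliation ------------------------------------------

# Load the editable symbol synonym table (symbol -> canonical token).
gene_synonyms <- function() {
  path <- system.file("extdata", "gene_synonyms.tsv", package = "bsptools")
  syn <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(toupper(syn$canonical), toupper(syn$symbol))
}

#' Extract the BSP-superfamily family token from a free-text gene symbol
#'
#' Case-insensitive longest match of `BSPH1`, `BSPH2`, `BSP1`..`BSP5`
#' (mapping to family `BSP`), bare `BSP`, and the ram trivial names
#' `RSVP14/20/22` (family `BSP`), after applying the shipped synonym table.
#' `ELSPBP1` (which contains the letters BSP) is explicitly excluded.
#'
#' @param symbol Gene symbol, possibly free text; empty or `NA` gives `""`.
#' @return One of `"BSP"`, `"BSPH1"`, `"BSPH2"`, `""` (empty symbol) or
#'   `"unknown"`.
#' @export
family_token <- function(symbol) {
  if (length(symbol) != 1L || is.na(symbol) || !nzchar(trimws(symbol))) {
    return("")
  }
  s <- toupper(trimws(symbol))
  syn <- gene_synonyms()
  if (s %in% names(syn)) s <- syn[[s]]
  if (grepl("ELSPBP", s)) return("unknown")
  if (grepl("BSPH1", s)) return("BSPH1")
  if (grepl("BSPH2", s)) return("BSPH2")
  if (grepl("BSP[1235]", s)) return("BSP")
  if (grepl("RSVP(14|20|22)", s)) return("BSP")
  if (grepl("BSP", s)) return("BSP")
  "unknown"
}

#' Reconcile an existing annotation against a sequence-based call
#'
#' @param existing_symbol Database gene symbol (may be empty).
#' @param call A `bsp_family_call`, or a character family token
#'   (`"BSP"`, `"BSPH1"`, `"BSPH2"`).
#' @return One of `"consistent"` (family tokens agree), `"misannotated"`
#'   (both defined, different), `"novel"` (no existing symbol, call
#'   defined), `"unresolved"` (call unclassified / not in the superfamily,
#'   or un-interpretable existing symbol).
#' @examples
#' reconcile_annotation("BSPH1", "BSPH2")  # the ferret M3XZ70 case
#' @export
reconcile_annotation <- function(existing_symbol, call) {
  call_family <- if (inherits(call, "bsp_family_call")) call$family else call
  tok <- family_token(existing_symbol)
  if (!call_family %in% c("BSP", "BSPH1", "BSPH2")) return("unresolved")
  if (tok == "") return("novel")
  if (tok == "unknown") return("unresolved")
  if (tok == call_family) "consistent" else "misannotated"
}

#' Reconcile a whole annotation table
#'
#' @param annotations Data.frame with columns `accession`, `species`,
#'   `existing_symbol`, and either `proposed_symbol` (whose family token is
#'   used as the call) or a `call` column of family tokens.
#' @return The table with added columns `existing_family`, `call_family`
#'   and `status`.
#' @export
reconcile_annotations <- function(annotations) {
  calls <- if ("call" %in% names(annotations)) {
    annotations$call
  } else {
    vapply(annotations$proposed_symbol, family_token, character(1))
  }
  annotations$existing_family <-
    vapply(annotations$existing_symbol, family_token, character(1))
  annotations$call_family <- unname(calls)
  annotations$status <- mapply(reconcile_annotation,
                               annotations$existing_symbol, calls,
                               USE.NAMES = FALSE)
  annotations
}

#' Bundled annotation table (updated BSP nomenclature)
#'
#' The shipped accession / species / existing symbol / proposed symbol table
#' used for nomenclature reconciliation.
#'
#' @return Data.frame with columns `accession`, `species`,
#'   `existing_symbol`, `proposed_symbol`.
#' @export
nomenclature_table <- function() {
  path <- system.file("extdata", "nomenclature_proposed.tsv", package = "bsptools")
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                    comment.char = "#")
}
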