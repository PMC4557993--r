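# Seeded synthetic data: labelled protein panels emulating the BSP
# superfamily's tandem-FN2 consensus structure, and gene-order files
# reproducing the three synteny patterns.
#
# Each family/subfamily group draws one "ancestor" core (consensus
# instantiated: fixed residues kept, alternatives sampled, wildcards from a
# background distribution, hydrophobic positions from the hydrophobic set;
# family fingerprints overwritten for BSPH1/BSPH2). Members are the ancestor
# plus i.i.d. per-position substitutions at rate epsilon - a star phylogeny
# per group, which is what makes subfamily labels recoverable both by
# nearest-reference identity and as clades of an NJ tree.

#' Specification for a synthetic protein panel
#'
#' @param counts Named integer vector of sequences per group; names from
#'   `BSP1`, `BSP2`, `BSP3`, `BSP5`, `BSPH1`, `BSPH2`.
#' @param epsilon Per-position substitution probability in `[0, 1]`.
#' @param seed Integer seed (mandatory; the whole panel is a deterministic
#'   function of the spec).
#' @param background Residue background for wildcard positions: `"uniform"`
#'   (default) or `"dayhoff"` (Dayhoff-1978 equilibrium frequencies).
#' @param prefix_range Length range of the signal-peptide-like N-terminal
#'   prefix (hydrophobic-rich, cosmetic only).
#' @param tail_length Residues appended after the core (after the `SP`
#'   extension for BSPH2).
#' @param n_decoy_single Decoys with only the first FN2 domain.
#' @param n_decoy_shuffled Decoys that are residue-shuffled full sequences.
#' @return Object of class `bsp_panel_spec`.
#' @export
panel_spec <- function(counts = c(BSP1 = 3, BSP2 = 3, BSP3 = 3, BSP5 = 3,
                                  BSPH1 = 3, BSPH2 = 3),
                       epsilon = 0, seed,
                       background = c("uniform", "dayhoff"),
                       prefix_range = c(15L, 25L), tail_length = 5L,
                       n_decoy_single = 0L, n_decoy_shuffled = 0L) {
  if (missing(seed)) stop("a seed is mandatory for panel generation")
  background <- match.arg(background)
  stopifnot(epsilon >= 0, epsilon <= 1, all(counts >= 0),
            all(names(counts) %in% c(BSP_SUBFAMILIES, "BSPH1", "BSPH2")))
  if (epsilon > 0.5) {
    warning("epsilon > 0.5: group labels may be unrecoverable")
  }
  structure(list(counts = counts, epsilon = epsilon, seed = as.integer(seed),
                 background = background, prefix_range = prefix_range,
                 tail_length = tail_length,
                 n_decoy_single = n_decoy_single,
                 n_decoy_shuffled = n_decoy_shuffled),
            class = "bsp_panel_spec")
}

background_freqs <- function(background) {
  if (background == "dayhoff") {
    m <- dayhoff_model()
    m$bf[AA_ALPHABET]
  } else {
    stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
}

# Deterministic ancestor core for a (seed, group) combination. Drawing each
# group ancestor from its own derived sub-seed (rather than the shared panel
# stream) lets generate_reference_panel() reproduce exactly the ancestors a
# panel with the same seed used, which is what nearest-reference subfamily
# assignment relies on.
GROUP_ORDER <- c("BSP1", "BSP2", "BSP3", "BSP5", "BSPH1", "BSPH2")

group_ancestor <- function(seed, group, freqs,
                           hydrophobic = hydrophobic_residues()) {
  family <- if (group %in% BSP_SUBFAMILIES) "BSP" else group
  sub_seed <- (as.integer(seed) %% 20000000L) * 100L +
    match(group, GROUP_ORDER)
  withr::with_seed(sub_seed, {
    apply_fingerprints(sample_core(freqs, hydrophobic), family, hydrophobic)
  })
}

# One consensus core instantiation (87 residues) under the current RNG.
# The unhoused second cysteine of the C-terminal domain (VI -> VII gap) is
# kept at core position 56, giving both FN2 domains their two conserved
# disulfide bonds.
sample_core <- function(freqs, hydrophobic = hydrophobic_residues()) {
  blocks <- block_definitions()
  core <- sample(AA_ALPHABET, 87L, replace = TRUE, prob = freqs)
  core[56L] <- "C"
  for (i in seq_len(nrow(blocks))) {
    pat <- blocks$parsed[[i]]
    at <- blocks$canonical_start[[i]]
    for (k in seq_along(pat)) {
      s <- pat[[k]]
      core[at + k - 1L] <- switch(
        s$type,
        fixed = s$residues,
        alt = sample(s$residues, 1L),
        wildcard = sample(AA_ALPHABET, 1L, prob = freqs),
        hydrophobic = sample(hydrophobic, 1L))
    }
  }
  core
}

# Overwrite the family fingerprint blocks in a core character vector.
apply_fingerprints <- function(core, family,
                               hydrophobic = hydrophobic_residues()) {
  if (!family %in% c("BSPH1", "BSPH2")) return(core)
  blocks <- block_definitions()
  fps <- family_fingerprints()[[family]]
  for (name in names(fps)) {
    if (name == "CTER") next                   # handled at sequence level
    pat <- parse_pattern(fps[[name]])
    at <- blocks$canonical_start[blocks$block_id == name]
    for (k in seq_along(pat)) {
      s <- pat[[k]]
      core[at + k - 1L] <- switch(
        s$type,
        fixed = s$residues,
        alt = sample(s$residues, 1L),
        wildcard = core[at + k - 1L],          # keep ancestral residue
        hydrophobic = sample(hydrophobic, 1L))
    }
  }
  core
}

sample_prefix <- function(range, hydrophobic = hydrophobic_residues()) {
  len <- sample(seq(range[[1]], range[[2]]), 1L)
  body <- vapply(seq_len(len - 1L), function(i) {
    if (stats::runif(1) < 0.6) sample(hydrophobic, 1L)
    else sample(AA_ALPHABET, 1L)
  }, character(1))
  c("M", body)
}

mutate_seq <- function(chars, epsilon) {
  if (epsilon <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < epsilon)
  for (i in hit) {
    chars[[i]] <- sample(setdiff(AA_ALPHABET, chars[[i]]), 1L)
  }
  chars
}

#' Generate a labelled synthetic protein panel
#'
#' @param spec A `bsp_panel_spec`.
#' @return List with `sequences` (named character vector) and `truth`
#'   (data.frame `seq_id`, `family`, `subfamily`, `is_decoy`). Byte-identical
#'   across calls with the same spec.
#' @examples
#' panel <- generate_panel(panel_spec(counts = c(BSP1 = 2), seed = 7))
#' panel$truth
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "bsp_panel_spec"))
  freqs <- background_freqs(spec$background)
  withr::with_seed(spec$seed, {
    seqs <- character(0)
    truth <- list()
    for (group in names(spec$counts)) {
      n <- spec$counts[[group]]
      if (n == 0L) next
      family <- if (group %in% BSP_SUBFAMILIES) "BSP" else group
      subfamily <- if (family == "BSP") group else "none"
      ancestor <- group_ancestor(spec$seed, group, freqs)
      for (m in seq_len(n)) {
        id <- sprintf("%s_%02d", group, m)
        prefix <- sample_prefix(spec$prefix_range)
        tail <- sample(AA_ALPHABET, spec$tail_length, replace = TRUE,
                       prob = freqs)
        ext <- if (family == "BSPH2") c("S", "P") else character(0)
        chars <- mutate_seq(c(prefix, ancestor, ext, tail), spec$epsilon)
        seqs[[id]] <- paste(chars, collapse = "")
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = id, family = family, subfamily = subfamily,
          is_decoy = FALSE, stringsAsFactors = FALSE)
      }
    }
    if (spec$n_decoy_single > 0L) {
      for (m in seq_len(spec$n_decoy_single)) {
        id <- sprintf("decoy_single_%02d", m)
        core <- sample_core(freqs)[1:38]       # first FN2 domain only
        chars <- mutate_seq(c(sample_prefix(spec$prefix_range), core,
                              sample(AA_ALPHABET, spec$tail_length,
                                     replace = TRUE, prob = freqs)),
                            spec$epsilon)
        seqs[[id]] <- paste(chars, collapse = "")
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = id, family = "decoy", subfamily = "none",
          is_decoy = TRUE, stringsAsFactors = FALSE)
      }
    }
    if (spec$n_decoy_shuffled > 0L) {
      for (m in seq_len(spec$n_decoy_shuffled)) {
        id <- sprintf("decoy_shuffled_%02d", m)
        chars <- c(sample_prefix(spec$prefix_range), sample_core(freqs),
                   sample(AA_ALPHABET, spec$tail_length, replace = TRUE,
                          prob = freqs))
        seqs[[id]] <- paste(sample(chars), collapse = "")
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = id, family = "decoy", subfamily = "none",
          is_decoy = TRUE, stringsAsFactors = FALSE)
      }
    }
    list(sequences = seqs, truth = do.call(rbind, truth))
  })
}

#' Generate a labelled reference panel of subfamily ancestor cores
#'
#' One noise-free ancestor core per BSP subfamily, for nearest-reference
#' subfamily assignment ([assign_subfamily()]). With the same `seed` and
#' `background` these are exactly the ancestors [generate_panel()] mutates
#' its members from, so generator truth labels are recoverable.
#'
#' @param seed Integer seed.
#' @param subfamilies Subfamily names.
#' @param background Background residue frequencies, as in [panel_spec()].
#' @return Data.frame with columns `subfamily` and `core`.
#' @export
generate_reference_panel <- function(seed, subfamilies = BSP_SUBFAMILIES,
                                     background = "uniform") {
  freqs <- background_freqs(background)
  data.frame(
    subfamily = subfamilies,
    core = vapply(subfamilies, function(s) {
      paste(group_ancestor(seed, s, freqs), collapse = "")
    }, character(1)),
    stringsAsFactors = FALSE)
}

#' Generate synthetic gene neighborhoods for the synteny patterns
#'
#' Emits one neighborhood per requested pattern, built from the published
#' flank/core gene lists, optionally with filler genes inserted.
#'
#' @param patterns Subset of `c("BSP", "BSPH_ELSPBP1", "BSPH_noELSPBP1")`.
#' @param n_filler Neutral filler genes (`FILLER01`, ...) inserted at random
#'   positions of each record.
#' @param seed Integer seed.
#' @return List with `records` (named list of `bsp_neighborhood`) and
#'   `truth` (data.frame `scaffold_id`, `pattern_id`). Empty request gives
#'   empty output.
#' @export
generate_neighborhoods <- function(patterns = c("BSP", "BSPH_ELSPBP1",
                                                "BSPH_noELSPBP1"),
                                   n_filler = 0L, seed = 1L) {
  stopifnot(all(patterns %in% c("BSP", "BSPH_ELSPBP1", "BSPH_noELSPBP1")))
  templates <- list(
    BSP = c("CD177", "TEX101", "BSP5", "BSP3", "BSP1",
            "LYPD3", "PHLDB3", "ETHE1", "ZNF575"),
    BSPH_ELSPBP1 = c("C19ORF68", "LIG1", "CABP5", "ELSPBP1",
                     "BSPH1", "BSPH2", "SULT2A1", "CRX"),
    BSPH_noELSPBP1 = c("PLA2G4C", "BSPH2", "BSPH1", "SULT2A1", "CRX"))
  if (length(patterns) == 0L) {
    return(list(records = list(),
                truth = data.frame(scaffold_id = character(),
                                   pattern_id = character(),
                                   stringsAsFactors = FALSE)))
  }
  withr::with_seed(as.integer(seed), {
    records <- list()
    truth <- list()
    for (p in patterns) {
      genes <- templates[[p]]
      if (n_filler > 0L) {
        for (f in seq_len(n_filler)) {
          at <- sample(0:length(genes), 1L)
          genes <- append(genes, sprintf("FILLER%02d", f), after = at)
        }
      }
      sid <- paste0("synth_", p)
      records[[sid]] <- neighborhood_record(genes, scaffold_id = sid,
                                            species = "synthetic",
                                            source = "synth")
      truth[[length(truth) + 1L]] <- data.frame(
        scaffold_id = sid, pattern_id = p, stringsAsFactors = FALSE)
    }
    list(records = records, truth = do.call(rbind, truth))
  })
}

#' Synthetic stand-in for the ram RSVP20 precursor
#'
#' A deterministic, synthetic 154-residue precursor built to honor the
#' published residue landmarks of the Ovis aries seminal-vesicle protein
#' RSVP20 (BSP5b): the tandem-FN2 core starts at precursor position 63
#' (the Block I cysteine C63), the conserved Block III tryptophan falls at
#' precursor position 86, the Block IV aromatic consensus position carries
#' the isoleucine deviation (I99), and the Block VIII tryptophan falls at
#' position 133. It is NOT the database sequence (which is not bundled);
#' every position not pinned by a published landmark is a plausible
#' consensus-compatible invention, so the object is only suitable for
#' testing coordinate arithmetic and scanner behaviour.
#'
#' @return Named character vector of length 1 (name
#'   `"synthetic_RSVP20_like"`).
#' @export
synthetic_rsvp20_like_precursor <- function() {
  core <- strsplit(canonical_core(), "", fixed = TRUE)[[1]]
  # published landmarks, core frame = precursor position - 62
  pin <- c("1" = "C",  "5" = "F",  "7" = "Y",   # C63, F67..Y69 (beta1)
           "10" = "R", "12" = "Y",              # R72..Y74 (beta2)
           "15" = "C", "19" = "N", "20" = "S",  # C77, N81-S82
           "22" = "R", "24" = "W", "25" = "C",  # R84, W86, C87
           "31" = "Y", "35" = "W", "37" = "I",  # Y93, W97, I99 (deviation)
           "38" = "C", "42" = "D",              # C100, D104
           "52" = "Y",                          # Y114
           "56" = "C",                          # free cysteine, VI-VII gap
           "64" = "G", "65" = "S",              # G126, S127
           "71" = "W",                          # W133
           "78" = "F", "84" = "W", "86" = "Y")  # F140, W146, Y148
  core[as.integer(names(pin))] <- unname(pin)
  prefix <- paste0("MKLSVLLLAILGLALA",                  # signal-like
                   "EQTDRAEVVPSAKSEELKQGTNDDSKTEGKPDLSHQEPKAGDSHAL")
  stopifnot(nchar(prefix) == 62L)
  seq <- paste0(prefix, paste(core, collapse = ""), "KKAED")
  stats::setNames(seq, "synthetic_RSVP20_like")
}
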