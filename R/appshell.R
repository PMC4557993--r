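# Pipeline shell: configuration, FASTA/TSV I/O, orchestration, and the
# spectrophotometric quantitation helper used when labelling purified
# protein.

#' Pipeline configuration
#'
#' Validated container of every tunable the pipeline exposes.
#'
#' @param fasta Path to the protein FASTA input (plain or gzip), or `NULL`
#'   when only non-sequence stages run.
#' @param neighborhoods Optional neighborhood TSV (see
#'   [read_neighborhoods()]).
#' @param annotations Optional annotation TSV with columns `accession`,
#'   `species`, `existing_symbol` and `proposed_symbol` or `call`.
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of `c("scan", "classify", "phylo",
#'   "genecontext", "reconcile")`.
#' @param tolerance Per-block mismatch tolerance for scanning.
#' @param gap_slack Inter-block gap slack for assembly.
#' @param theta Fingerprint component fraction for family calls.
#' @param identity_floor Minimum identity for subfamily assignment.
#' @param model Distance model (`"dayhoff"`, `"poisson"`, `"p"`).
#' @param replicates Bootstrap replicates.
#' @param seed Integer seed, recorded in every output header.
#' @param references Subfamily reference panel (data.frame with `subfamily`,
#'   `core`); defaults to [generate_reference_panel()] under `seed`.
#' @return Object of class `bsp_config`.
#' @export
pipeline_config <- function(fasta = NULL, neighborhoods = NULL,
                            annotations = NULL, out_dir = tempfile("bsp_out_"),
                            stages = c("scan", "classify", "phylo",
                                       "genecontext", "reconcile"),
                            tolerance = 1L, gap_slack = 2L, theta = 2 / 3,
                            identity_floor = 0.40,
                            model = c("dayhoff", "poisson", "p"),
                            replicates = 100L, seed = 1L,
                            references = NULL) {
  model <- match.arg(model)
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(tolerance >= 0L, gap_slack >= 0L, theta > 0, theta <= 1,
            identity_floor >= 0, identity_floor <= 1, replicates >= 1L)
  structure(list(fasta = fasta, neighborhoods = neighborhoods,
                 annotations = annotations, out_dir = out_dir,
                 stages = stages, tolerance = as.integer(tolerance),
                 gap_slack = as.integer(gap_slack), theta = theta,
                 identity_floor = identity_floor, model = model,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 references = references),
            class = "bsp_config")
}

# Stable hash of the analysis parameters (md5 of their JSON serialization).
# The output directory is excluded: it does not affect results.
config_hash <- function(config) {
  cfg <- config[setdiff(names(config), c("references", "out_dir"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file whose keys are
#'   [pipeline_config()] arguments.
#' @return A `bsp_config`.
#' @export
read_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipeline_config, lst)
}

#' Read protein sequences from FASTA
#'
#' Accepts wrapped or unwrapped, plain or gzip FASTA. Sequence ids are the
#' header up to the first whitespace; duplicate ids are an error, as is an
#' empty file.
#'
#' @param path FASTA file.
#' @return Named character vector of protein sequences (uppercased).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop(sprintf(
                    "malformed FASTA %s: %s", path, conditionMessage(e))))
  if (length(set) == 0L) stop(sprintf("empty FASTA: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate sequence id(s) in %s: %s", path,
                 paste(unique(dup), collapse = ", ")))
  }
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @param width Line wrap width.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(paste0(">", id), con)
    s <- sequences[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# TSV report writer; every report carries a header comment line with the
# tool version, seed and config hash so runs are attributable.
write_tsv_report <- function(df, path, seed = NULL, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("bsptools"))
  writeLines(sprintf("# bsptools %s%s%s", version,
                     if (!is.null(seed)) paste0(" seed=", seed) else "",
                     if (!is.null(hash)) paste0(" config=", hash) else ""),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates, per the configured stages: block scanning and architecture
#' assembly, family/subfamily classification, the NJ tree with bootstrap
#' supports over the extracted cores, synteny pattern matching with
#' cross-checks, and annotation reconciliation. All tabular outputs carry a
#' header line with package version, seed and config hash; identical
#' config + seed reproduce identical files.
#'
#' @param config A `bsp_config`.
#' @return Invisibly, a list with the in-memory results (`architectures`,
#'   `calls`, `classification`, `tree`, `supports`, `patterns`,
#'   `discrepancies`, `reconciliation`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bsp_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  files <- character(0)
  out <- list()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_tsv_report(df, path, seed = config$seed, hash = hash)
    files[[name]] <<- path
  }

  needs_seq <- any(c("scan", "classify", "phylo") %in% config$stages)
  if (needs_seq) {
    if (is.null(config$fasta)) stop("sequence stages need a FASTA input")
    seqs <- read_fasta(config$fasta)

    archs <- lapply(names(seqs), function(id) {
      m <- scan_blocks(seqs[[id]], tolerance = config$tolerance)
      assemble_architecture(m, seqs[[id]], gap_slack = config$gap_slack,
                            seq_id = id)
    })
    names(archs) <- names(seqs)
    out$architectures <- archs
    scan_df <- do.call(rbind, lapply(archs, function(a) {
      if (nrow(a$chain) == 0L) return(NULL)
      cbind(seq_id = a$seq_id, a$chain)
    }))
    if (is.null(scan_df)) {
      scan_df <- data.frame(seq_id = character(), block_id = character(),
                            start = integer(), end = integer(),
                            subsequence = character(), mismatches = integer(),
                            exact = logical())
    }
    emit(scan_df, "scan.tsv")
    emit(architecture_report(archs), "architecture.tsv")

    if ("classify" %in% config$stages) {
      refs <- config$references
      if (is.null(refs)) refs <- generate_reference_panel(config$seed)
      calls <- lapply(archs, function(a) {
        cl <- classify_family(a, theta = config$theta)
        if (cl$family == "BSP") {
          cl <- assign_subfamily(cl, extract_core(a), refs,
                                 floor = config$identity_floor)
        }
        cl
      })
      out$calls <- calls
      cls_df <- do.call(rbind, lapply(calls, function(cl) {
        data.frame(seq_id = cl$seq_id, family = cl$family,
                   subfamily = cl$subfamily,
                   score_BSPH1 = cl$score_BSPH1, score_BSPH2 = cl$score_BSPH2,
                   ambiguous_subfamily = cl$ambiguous_subfamily,
                   stringsAsFactors = FALSE)
      }))
      out$classification <- cls_df
      emit(cls_df, "classification.tsv")
    }

    if ("phylo" %in% config$stages) {
      cores <- vapply(archs, extract_core, character(1))
      cores <- cores[!is.na(cores)]
      if (length(cores) >= 3L) {
        bt <- bootstrap_supports(cores, model = config$model,
                                 replicates = config$replicates,
                                 seed = config$seed)
        out$tree <- bt$tree
        out$supports <- bt$supports
        tree_path <- file.path(config$out_dir, "tree.nwk")
        write_newick(bt$tree, tree_path)
        files[["tree.nwk"]] <- tree_path
        dist_path <- file.path(config$out_dir, "distances.tsv")
        write_distance_tsv(distance_matrix(cores, config$model), dist_path)
        files[["distances.tsv"]] <- dist_path
      } else {
        warning("fewer than 3 complete cores: phylogeny stage skipped")
      }
    }
  }

  if ("genecontext" %in% config$stages && !is.null(config$neighborhoods)) {
    recs <- read_neighborhoods(config$neighborhoods)
    pat_df <- do.call(rbind, lapply(recs, function(r) {
      m <- match_pattern(r)
      data.frame(scaffold_id = r$scaffold_id, species = r$species,
                 pattern_id = m$pattern_id, score = m$score,
                 reason = m$reason, stringsAsFactors = FALSE)
    }))
    out$patterns <- pat_df
    emit(pat_df, "patterns.tsv")
    disc <- do.call(rbind, lapply(recs, cross_check))
    out$discrepancies <- disc
    emit(disc, "discrepancies.tsv")
  }

  if ("reconcile" %in% config$stages && !is.null(config$annotations)) {
    ann <- utils::read.delim(config$annotations, stringsAsFactors = FALSE,
                             na.strings = NULL, comment.char = "#")
    rec <- reconcile_annotations(ann)
    out$reconciliation <- rec
    emit(rec, "reconciliation.tsv")
  }

  out$files <- files
  invisible(out)
}

#' Protein concentration from absorbance with fluorophore correction
#'
#' Computes the molar concentration of a labelled protein preparation as
#' `(A280 - correction * A494) * dilution / epsilon`. The defaults are the
#' values used for Alexa-488-labelled ram RSVP20: theoretical molar
#' extinction coefficient 45,380 /(M cm) at 280 nm, and 0.11 for the
#' fluorophore's own contribution at 280 nm.
#'
#' @param a280 Absorbance at 280 nm.
#' @param a494 Absorbance at 494 nm (fluorophore peak).
#' @param dilution Dilution factor.
#' @param epsilon Molar extinction coefficient, 1/(M cm); must be positive.
#' @param fluorophore_correction Fraction of `a494` subtracted from `a280`.
#' @return Concentration in mol/L. A negative corrected absorbance is
#'   returned as-is with a warning (flagged, not silently clipped).
#' @examples
#' protein_concentration(0.45380, 0, 1)   # 1e-5 M
#' @export
protein_concentration <- function(a280, a494 = 0, dilution = 1,
                                  epsilon = 45380,
                                  fluorophore_correction = 0.11) {
  stopifnot(epsilon > 0, a280 >= 0, a494 >= 0, dilution > 0)
  corrected <- a280 - fluorophore_correction * a494
  if (corrected < 0) {
    warning("corrected absorbance is negative; check the blank and dilution")
  }
  corrected * dilution / epsilon
}
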