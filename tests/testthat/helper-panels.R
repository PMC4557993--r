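# Shared helpers: end-to-end classification of a generated panel, and an
# independent brute-force pattern matcher used as the scanner oracle.

classify_panel <- function(panel, refs = NULL, tolerance = 1L) {
  vapply(names(panel$sequences), function(id) {
    s <- panel$sequences[[id]]
    arch <- assemble_architecture(scan_blocks(s, tolerance), s, seq_id = id)
    cl <- classify_family(arch)
    if (cl$family == "BSP" && !is.null(refs)) {
      cl <- assign_subfamily(cl, extract_core(arch), refs)
    }
    paste(cl$family, cl$subfamily)
  }, character(1))
}

panel_accuracy <- function(panel, refs) {
  calls <- classify_panel(panel, refs)
  truth <- paste(panel$truth$family, panel$truth$subfamily)
  mean(calls[panel$truth$seq_id] == truth)
}

# Independent oracle: expand a consensus string into per-position allowed
# residue sets (without parse_pattern) and count violations at every start.
oracle_scan <- function(sequence, pattern_text, tolerance,
                        hydro = c("A", "V", "L", "I", "M", "F", "W", "Y")) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sets <- list()
  i <- 1L
  chars <- strsplit(pattern_text, "")[[1]]
  while (i <= length(chars)) {
    if (chars[[i]] == "[") {
      j <- i + 1L
      while (chars[[j]] != "]") j <- j + 1L
      sets[[length(sets) + 1L]] <- chars[(i + 1L):(j - 1L)]
      i <- j + 1L
    } else {
      sets[[length(sets) + 1L]] <- switch(chars[[i]],
                                          x = aa20, h = hydro, chars[[i]])
      i <- i + 1L
    }
  }
  sv <- strsplit(sequence, "")[[1]]
  len <- length(sets)
  hits <- list()
  for (start in seq_len(max(0L, length(sv) - len + 1L))) {
    mm <- sum(vapply(seq_len(len), function(k) {
      !(sv[start + k - 1L] %in% sets[[k]])
    }, logical(1)))
    if (mm <= tolerance) {
      hits[[length(hits) + 1L]] <- c(start = start, mismatches = mm)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), mismatches = integer()))
  }
  as.data.frame(do.call(rbind, hits))
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
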