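# Distance-based phylogeny: pairwise-deletion protein distances (p, Poisson,
# Dayhoff PAM), Saitou-Nei neighbor-joining, and bootstrap supports.
#
# The NJ agglomeration, split extraction and bootstrap are implemented here;
# the Dayhoff-1978 empirical model (exchangeabilities + equilibrium
# frequencies) is taken from phangorn's amino-acid model set, and Newick
# serialization is delegated to ape.

GAP_CHARS <- c("-", ".")

# Dayhoff-1978 instantaneous rate matrix, scaled to 1 expected substitution
# per site per unit time, with its eigendecomposition (cached).
dayhoff_model <- function() {
  if (!is.null(.bsp_cache$dayhoff)) return(.bsp_cache$dayhoff)
  tmp <- get(".Dayhoff", environment(phangorn::pml))
  bf <- tmp$bf
  aa <- toupper(names(bf))
  n <- length(bf)                       # 20
  S <- matrix(0, n, n, dimnames = list(aa, aa))
  S[lower.tri(S)] <- tmp$Q              # symmetric exchangeabilities
  S <- S + t(S)
  Q <- S %*% diag(bf)
  diag(Q) <- -rowSums(Q)
  rate <- -sum(bf * diag(Q))
  Q <- Q / rate                          # mean rate 1 => t in subs/site
  # symmetrize for a stable eigendecomposition: B = D^1/2 Q D^-1/2
  dh <- sqrt(bf)
  B <- diag(dh) %*% Q %*% diag(1 / dh)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  .bsp_cache$dayhoff <- list(bf = stats::setNames(as.numeric(bf), aa),
                             Q = Q, eigval = eig$values,
                             left = diag(1 / dh) %*% eig$vectors,
                             right = t(eig$vectors) %*% diag(dh))
  .bsp_cache$dayhoff
}

# Expected residue identity E[ sum_i pi_i P(t)_ii ] under the Dayhoff model.
dayhoff_expected_identity <- function(t) {
  m <- dayhoff_model()
  # P(t) = left diag(exp(lambda t)) right ; we only need its diagonal
  pt_diag <- rowSums(m$left * t(exp(m$eigval * t) * m$right))
  sum(m$bf * pt_diag)
}

#' Pairwise distance between two aligned protein rows
#'
#' Columns gapped in either row are excluded (pairwise deletion); `p` is
#' the proportion of remaining columns that differ. Models: `"p"` returns
#' `p` itself; `"poisson"` the Poisson correction `-ln(1 - p)`; `"dayhoff"`
#' the PAM distance `t` (substitutions/site) solving
#' `expected_identity(t) = 1 - p` under the Dayhoff-1978 replacement model
#' (monotone root find).
#'
#' @param a,b Equal-length gapped rows (strings; gap = `-` or `.`).
#' @param model `"p"`, `"poisson"` or `"dayhoff"`.
#' @return List with `distance`, `n_sites`, `p`, and flags `undefined`
#'   (no comparable columns) and `saturated` (p beyond what the model can
#'   invert; `distance` is `NA` in either case).
#' @export
pairwise_distance <- function(a, b, model = c("dayhoff", "poisson", "p")) {
  model <- match.arg(model)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(av) != length(bv)) stop("rows differ in length")
  keep <- !(av %in% GAP_CHARS) & !(bv %in% GAP_CHARS)
  n_sites <- sum(keep)
  if (n_sites == 0L) {
    return(list(distance = NA_real_, n_sites = 0L, p = NA_real_,
                undefined = TRUE, saturated = FALSE))
  }
  p <- mean(av[keep] != bv[keep])
  out <- list(distance = NA_real_, n_sites = n_sites, p = p,
              undefined = FALSE, saturated = FALSE)
  if (model == "p") {
    out$distance <- p
  } else if (model == "poisson") {
    if (p >= 1) out$saturated <- TRUE else out$distance <- -log(1 - p)
  } else {
    d <- dayhoff_pam_distance(p)
    if (is.na(d)) out$saturated <- TRUE else out$distance <- d
  }
  out
}

# Invert expected identity to a PAM distance, memoized on p (bootstrap
# replicates revisit the same handful of p values).
dayhoff_pam_distance <- function(p) {
  key <- sprintf("%.12g", p)
  if (!is.null(.bsp_cache$pam_memo[[key]])) return(.bsp_cache$pam_memo[[key]])
  tmax <- 30
  d <- if (p == 0) {
    0
  } else if (1 - p <= dayhoff_expected_identity(tmax)) {
    NA_real_                            # saturated
  } else {
    stats::uniroot(function(t) dayhoff_expected_identity(t) - (1 - p),
                   lower = 0, upper = tmax, tol = 1e-10)$root
  }
  if (is.null(.bsp_cache$pam_memo)) .bsp_cache$pam_memo <- list()
  .bsp_cache$pam_memo[[key]] <- d
  d
}

#' Build a pairwise distance matrix from an alignment
#'
#' @param aln Named character vector of equal-length gapped rows (an
#'   alignment), or an `AAStringSet`.
#' @param model Distance model, see [pairwise_distance()].
#' @return Object of class `bsp_dist`: list with `ids`, `d` (symmetric
#'   matrix, `NA` where undefined/saturated), `n_sites` matrix, and logical
#'   matrices `undefined`, `saturated`.
#' @export
distance_matrix <- function(aln, model = c("dayhoff", "poisson", "p")) {
  model <- match.arg(model)
  aln <- as_alignment(aln)
  ids <- names(aln)
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  ns <- matrix(nchar(aln[[1]]), n, n, dimnames = list(ids, ids))
  und <- sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    ns[i, i] <- sum(!(strsplit(aln[[i]], "")[[1]] %in% GAP_CHARS))
    if (i == n) next
    for (j in seq((i + 1L), n)) {
      pd <- pairwise_distance(aln[[i]], aln[[j]], model)
      d[i, j] <- d[j, i] <- pd$distance
      ns[i, j] <- ns[j, i] <- pd$n_sites
      und[i, j] <- und[j, i] <- pd$undefined
      sat[i, j] <- sat[j, i] <- pd$saturated
    }
  }
  structure(list(ids = ids, d = d, n_sites = ns, undefined = und,
                 saturated = sat, model = model), class = "bsp_dist")
}

# Coerce input to a named character vector alignment, validating lengths.
as_alignment <- function(aln) {
  if (inherits(aln, "AAStringSet")) {
    aln <- stats::setNames(as.character(aln), names(aln))
  }
  if (is.list(aln)) aln <- unlist(aln)
  stopifnot(is.character(aln), !is.null(names(aln)),
            !anyDuplicated(names(aln)))
  if (length(unique(nchar(aln))) != 1L) {
    stop("alignment rows differ in length")
  }
  as.list(aln)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step join the pair minimizing
#' `Q(i,j) = (r - 2) d(i,j) - R(i) - R(j)`; branch lengths from the NJ
#' closed forms, with negative lengths clamped to zero (flagged via the
#' `"clamped"` attribute); ties broken toward the smallest index pair.
#' Returns an unrooted binary tree.
#'
#' @param D A `bsp_dist`, or a symmetric numeric matrix with dimnames.
#' @return An [ape::phylo] tree (unrooted), attribute `clamped` counting
#'   negative branch lengths clamped to 0.
#' @export
nj_tree <- function(D) {
  d <- if (inherits(D, "bsp_dist")) D$d else as.matrix(D)
  ids <- rownames(d)
  n <- length(ids)
  if (n < 3L) stop("neighbor-joining needs at least 3 taxa")
  if (any(is.na(d))) stop("distance matrix has undefined entries")

  # node bookkeeping: tips 1..n, internal nodes numbered n+1 .. 2n-2
  # (ape convention; node n+1 is the final unresolved trichotomy root)
  active <- seq_len(n)                  # current cluster -> node id
  node_of <- seq_len(n)
  next_node <- 2L * n - 2L              # assign internal ids downward;
  edges <- NULL; lens <- NULL; clamped <- 0L
  dm <- d

  add_edge <- function(parent, child, len) {
    if (len < 0) { clamped <<- clamped + 1L; len <- 0 }
    edges <<- rbind(edges, c(parent, child)); lens <<- c(lens, len)
  }

  while (length(active) > 3L) {
    r <- length(active)
    R <- rowSums(dm)
    qmin <- Inf; pick <- c(NA, NA)
    for (i in seq_len(r - 1L)) {
      for (j in seq((i + 1L), r)) {
        q <- (r - 2) * dm[i, j] - R[i] - R[j]
        if (q < qmin - 1e-12) { qmin <- q; pick <- c(i, j) }
      }
    }
    i <- pick[[1]]; j <- pick[[2]]
    vi <- 0.5 * dm[i, j] + (R[[i]] - R[[j]]) / (2 * (r - 2))
    vj <- dm[i, j] - vi
    new_id <- next_node; next_node <- next_node - 1L
    add_edge(new_id, node_of[[i]], vi)
    add_edge(new_id, node_of[[j]], vj)
    # distances from the new node to the remainder
    rest <- setdiff(seq_len(r), c(i, j))
    newd <- 0.5 * (dm[i, rest] + dm[j, rest] - dm[i, j])
    dm <- rbind(cbind(dm[rest, rest, drop = FALSE], newd),
                c(newd, 0))
    node_of <- c(node_of[rest], new_id)
    active <- c(active[rest], new_id)
  }

  # final three clusters joined at the root trichotomy (node n+1)
  root <- n + 1L
  stopifnot(next_node == root)
  da <- dm[1, 2]; db <- dm[1, 3]; dc <- dm[2, 3]
  add_edge(root, node_of[[1]], (da + db - dc) / 2)
  add_edge(root, node_of[[2]], (da + dc - db) / 2)
  add_edge(root, node_of[[3]], (db + dc - da) / 2)

  tree <- structure(list(edge = edges, edge.length = lens,
                         tip.label = ids, Nnode = n - 2L),
                    class = "phylo", order = NULL)
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "clamped") <- clamped
  tree
}

#' Non-trivial bipartitions (splits) of an unrooted tree
#'
#' @param tree An [ape::phylo] object.
#' @return Character vector; each split is the sorted tip labels of the side
#'   not containing the first tip label (alphabetically), joined with `|`.
#'   Only splits with at least two tips on each side are returned.
#' @export
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[[1]]
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(n))
  splits <- character(0)
  for (node in internal) {
    tips <- tip_descendants(tree, node)
    side <- if (ref %in% tips) setdiff(tree$tip.label, tips) else tips
    if (length(side) >= 2L && length(side) <= n - 2L) {
      splits <- c(splits, paste(sort(side), collapse = "|"))
    }
  }
  unique(splits)
}

# Tip labels descending from a node (node itself if a tip).
tip_descendants <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[[node]])
  out <- character(0)
  stack <- node
  while (length(stack) > 0L) {
    cur <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    tips <- kids[kids <= n]
    out <- c(out, tree$tip.label[tips])
    stack <- c(stack, kids[kids > n])
  }
  out
}

#' Whether a set of tips forms a clade (split) of an unrooted tree
#'
#' @param tree An [ape::phylo].
#' @param tips Character vector of tip labels.
#' @return TRUE when some internal edge separates exactly `tips` from the
#'   rest (also TRUE for trivial one-tip and (n-1)-tip sets).
#' @export
is_clade <- function(tree, tips) {
  n <- length(tree$tip.label)
  tips <- sort(tips)
  if (length(tips) <= 1L || length(tips) >= n - 1L) return(TRUE)
  ref <- sort(tree$tip.label)[[1]]
  key <- if (ref %in% tips) {
    paste(sort(setdiff(tree$tip.label, tips)), collapse = "|")
  } else {
    paste(tips, collapse = "|")
  }
  key %in% tree_splits(tree)
}

#' Bootstrap supports for the full-data NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the distance
#' matrix and NJ tree per replicate, and reports for each non-trivial split
#' of the full-data tree the percentage of replicates containing it.
#' Replicates in which any pairwise distance is undefined or saturated are
#' dropped (with a warning) and excluded from the denominator.
#'
#' @param aln Alignment (named character vector or `AAStringSet`).
#' @param model Distance model.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the same seed reproduces the same supports.
#' @return List with `tree` (full-data NJ tree, `node.label` set to the
#'   support of the split below each internal node, `""` where trivial),
#'   `supports` (named numeric, percentage per split), `n_used`,
#'   `n_dropped`.
#' @export
bootstrap_supports <- function(aln, model = "dayhoff", replicates = 100L,
                               seed = 1L) {
  stopifnot(replicates >= 1L)
  aln <- as_alignment(aln)
  full <- nj_tree(distance_matrix(aln, model))
  splits <- tree_splits(full)
  counts <- stats::setNames(numeric(length(splits)), splits)
  ncol <- nchar(aln[[1]])
  rows <- lapply(aln, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  dropped <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(replicates)) {
      cols <- sample.int(ncol, ncol, replace = TRUE)
      rep_aln <- lapply(rows, function(v) paste(v[cols], collapse = ""))
      D <- distance_matrix(rep_aln, model)
      if (any(is.na(D$d))) { dropped <- dropped + 1L; next }
      rep_splits <- tree_splits(nj_tree(D))
      hit <- splits %in% rep_splits
      counts[hit] <- counts[hit] + 1
    }
  })
  used <- replicates - dropped
  if (dropped > 0L) {
    warning(sprintf("%d bootstrap replicate(s) dropped (undefined distances)",
                    dropped))
  }
  supports <- if (used > 0L) 100 * counts / used else counts * NA_real_
  full <- annotate_supports(full, supports)
  list(tree = full, supports = supports, n_used = used, n_dropped = dropped)
}

# Write split supports into node labels of the tree they were computed on.
annotate_supports <- function(tree, supports) {
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[[1]]
  labels <- character(tree$Nnode)
  internal <- sort(setdiff(unique(tree$edge[, 2]), seq_len(n)))
  all_internal <- seq(n + 1L, n + tree$Nnode)
  for (node in all_internal) {
    tips <- tip_descendants(tree, node)
    side <- if (ref %in% tips) setdiff(tree$tip.label, tips) else tips
    key <- paste(sort(side), collapse = "|")
    labels[node - n] <- if (key %in% names(supports)) {
      format(round(supports[[key]]), trim = TRUE)
    } else ""
  }
  tree$node.label <- labels
  tree
}

#' Serialize a tree to Newick
#'
#' @param tree An [ape::phylo]; internal `node.label`s (e.g. bootstrap
#'   supports) are written as internal node labels.
#' @param path Optional file to write to.
#' @param with_supports Drop node labels when `FALSE`.
#' @return The Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, path = NULL, with_supports = TRUE) {
  if (!with_supports) tree$node.label <- NULL
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a Newick tree
#'
#' @param text Newick string, or `NULL` to read from `path`.
#' @param path File to read.
#' @return An [ape::phylo].
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
}

#' Write a distance matrix as square TSV
#'
#' @param D A `bsp_dist`.
#' @param path Output file.
#' @param phylip Prepend a PHYLIP-style taxon-count header line.
#' @return Invisibly, the path.
#' @export
write_distance_tsv <- function(D, path, phylip = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (phylip) writeLines(as.character(length(D$ids)), con)
  writeLines(paste(c("id", D$ids), collapse = "\t"), con)
  for (i in seq_along(D$ids)) {
    writeLines(paste(c(D$ids[[i]], format(D$d[i, ], digits = 10)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
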