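#' Read a rooted, node-labelled phylogeny from newick
#'
#' Thin wrapper over [ape::read.tree()] that validates the properties the
#' OGT-annotation step relies on: a single root and unique labels across
#' leaves and internal nodes (unlabelled internal nodes are allowed and
#' simply cannot be annotated).
#'
#' @param file Path to a newick file, or `NULL` when `text` is given.
#' @param text Newick string.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(file = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  ## protect single-quoted labels (spaces are stripped by the parser)
  quoted <- regmatches(text, gregexpr("'[^']*'", text))[[1]]
  for (q in quoted) {
    safe <- gsub(" ", "\x01", substr(q, 2L, nchar(q) - 1L), fixed = TRUE)
    text <- sub(q, safe, text, fixed = TRUE)
  }
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                 error = function(e) NULL)
  if (is.null(tr))
    stop("malformed newick: could not parse ",
         if (!is.null(file)) file else "input text")
  tr$tip.label <- gsub("\x01", " ", tr$tip.label, fixed = TRUE)
  if (!is.null(tr$node.label))
    tr$node.label <- gsub("\x01", " ", tr$node.label, fixed = TRUE)
  if (!ape::is.rooted(tr))
    stop("tree must be rooted")
  labs <- c(tr$tip.label, tr$node.label)
  labs <- labs[!is.na(labs) & labs != ""]
  if (anyDuplicated(labs))
    stop("duplicate node label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  tr
}

#' Write a phylogeny (with optional OGT annotations) to newick
#'
#' Annotations travel two ways: inline as extended-newick comment tags
#' (`[&ogt=...,lifestyle=...]` appended to the node label) and, when
#' `sidecar` is given, as a plain TSV with columns `node`, `ogt`,
#' `ci_lower`, `ci_upper`, `lifestyle`. Comment-tag dialects vary across
#' toolchains, so the sidecar is the authoritative record; the plain
#' topology (no tags) is written when `x` carries no annotations.
#'
#' @param x A `phylo` or an `ogt_tree` from [annotate_nodes()].
#' @param file Output newick path; `NULL` returns the newick string.
#' @param sidecar Optional TSV path for the annotation table.
#' @return The newick string, invisibly (or visibly when `file` is NULL).
#' @export
write_newick <- function(x, file = NULL, sidecar = NULL) {
  ann <- NULL
  if (inherits(x, "ogt_tree")) { ann <- x$annotations; x <- x$tree }
  ## labels with spaces survive as quoted tokens
  x$tip.label <- gsub(" ", "\x01", x$tip.label, fixed = TRUE)
  if (!is.null(x$node.label))
    x$node.label <- gsub(" ", "\x01", x$node.label, fixed = TRUE)
  txt <- ape::write.tree(x)
  txt <- gsub("([^(),:;]*\x01[^(),:;]*)", "'\\1'", txt)
  txt <- gsub("\x01", " ", txt, fixed = TRUE)
  if (!is.null(ann) && nrow(ann)) {
    for (i in seq_len(nrow(ann))) {
      tag <- sprintf("%s[&ogt=%g,lifestyle=%s]", ann$label[i], ann$ogt[i],
                     ann$lifestyle[i])
      ## label followed by a structural character; quote for literal regex
      txt <- sub(paste0("(?<![A-Za-z0-9_.])", gsub("([][{}()*+?.\\^$|])",
                                                   "\\\\\\1", ann$label[i]),
                        "(?=[:,);])"),
                 tag, txt, perl = TRUE)
    }
    if (!is.null(sidecar)) {
      d <- ann
      names(d)[names(d) == "label"] <- "node"
      utils::write.table(d, sidecar, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    }
  }
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

#' Attach OGT estimates to tree nodes
#'
#' Builds an annotated tree by matching OGT estimates to tip or internal
#' node labels. Only measured or fitted values are attached; nodes without
#' an estimate stay bare (no ancestral-state interpolation is performed).
#' Re-applying the same estimates is idempotent.
#'
#' @param tree A `phylo` (e.g. from [read_newick()]) with unique labels.
#' @param estimates A list of `ogt_estimate` objects ([infer_ogt()]) or a
#'   data frame with columns `label`, `ogt`, `ci_lower`, `ci_upper`,
#'   `lifestyle`. Labels must be unique and present in the tree.
#' @return An object of class `ogt_tree`: list with `tree` (the `phylo`)
#'   and `annotations` (the estimate data frame).
#' @examples
#' tr <- read_newick(text = "((MKD1:1,Loki3:1)Loki:1,Thor:2)LAsCA;")
#' est <- data.frame(label = c("LAsCA", "MKD1"), ogt = c(65.5, 20.5),
#'                   ci_lower = c(65.2, 19), ci_upper = c(65.7, 24.1),
#'                   lifestyle = classify_lifestyle(c(65.5, 20.5)))
#' annotate_nodes(tr, est)
#' @export
annotate_nodes <- function(tree, estimates) {
  if (inherits(tree, "ogt_tree")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  if (!is.data.frame(estimates)) estimates <- ogt_estimates_df(estimates)
  if (is.null(estimates) || nrow(estimates) == 0L) {
    return(structure(list(tree = tree,
                          annotations = data.frame(label = character(),
                                                   ogt = numeric(),
                                                   ci_lower = numeric(),
                                                   ci_upper = numeric(),
                                                   lifestyle = character())),
                     class = "ogt_tree"))
  }
  if (anyDuplicated(estimates$label))
    stop("duplicate labels in estimates: ",
         paste(unique(estimates$label[duplicated(estimates$label)]),
               collapse = ", "))
  labs <- c(tree$tip.label, tree$node.label)
  missing <- setdiff(estimates$label, labs)
  if (length(missing))
    stop("label(s) not in tree: ", paste(missing, collapse = ", "))
  rownames(estimates) <- NULL
  structure(list(tree = tree, annotations = estimates), class = "ogt_tree")
}

#' @export
print.ogt_tree <- function(x, ...) {
  cat(sprintf("OGT-annotated tree: %d tips, %d internal nodes, %d annotated\n",
              length(x$tree$tip.label), x$tree$Nnode, nrow(x$annotations)))
  if (nrow(x$annotations)) {
    cat(sprintf("  OGT range %g-%g degC\n", min(x$annotations$ogt),
                max(x$annotations$ogt)))
  }
  invisible(x)
}

## node number (ape convention) for each label; NA when absent
node_numbers <- function(tree, labels) {
  all_labs <- c(tree$tip.label,
                if (is.null(tree$node.label))
                  rep(NA_character_, tree$Nnode) else tree$node.label)
  match(labels, all_labs)
}

#' Evolutionary trajectory table of annotated OGTs
#'
#' For every annotated node that has an annotated ancestor, reports the
#' OGT change along the path from its nearest annotated ancestor (not
#' every intermediate node carries a measured protein, so unannotated
#' intermediates are skipped): `delta = ogt - parent_ogt`. Deltas
#' telescope exactly: along any fully annotated path they sum to
#' `terminal - root`.
#'
#' @param x An `ogt_tree` from [annotate_nodes()] with at least one
#'   annotation.
#' @return A data frame with columns `node`, `parent`, `ogt`,
#'   `parent_ogt`, `delta`, `lifestyle`, one row per annotated node with
#'   an annotated ancestor.
#' @export
trajectory_table <- function(x) {
  stopifnot(inherits(x, "ogt_tree"))
  ann <- x$annotations
  if (nrow(ann) == 0L) stop("no annotated nodes")
  tr <- x$tree
  num <- node_numbers(tr, ann$label)
  ogt_by_num <- stats::setNames(ann$ogt, num)
  lab_by_num <- stats::setNames(ann$label, num)
  parent_of <- integer(length(tr$tip.label) + tr$Nnode)
  parent_of[tr$edge[, 2L]] <- tr$edge[, 1L]

  rows <- list()
  for (i in seq_len(nrow(ann))) {
    v <- parent_of[num[i]]
    while (v != 0L && !(as.character(v) %in% names(ogt_by_num)))
      v <- parent_of[v]
    if (v == 0L) next  # no annotated ancestor (e.g. the annotated root)
    rows[[length(rows) + 1L]] <- data.frame(
      node = ann$label[i],
      parent = lab_by_num[[as.character(v)]],
      ogt = ann$ogt[i],
      parent_ogt = ogt_by_num[[as.character(v)]],
      delta = ann$ogt[i] - ogt_by_num[[as.character(v)]],
      lifestyle = ann$lifestyle[i])
  }
  if (!length(rows)) {
    return(data.frame(node = character(), parent = character(),
                      ogt = numeric(), parent_ogt = numeric(),
                      delta = numeric(), lifestyle = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot a phylogeny coloured by OGT
#'
#' Paints annotated nodes (and the branches leading to them) on a
#' cold-to-hot colour ramp over the annotated OGT range, the usual visual
#' summary of trait evolution across the tree.
#'
#' @param x An `ogt_tree`.
#' @param y Unused (graphics generic).
#' @param palette Colour ramp function built from low/high colours.
#' @param ... Passed to [ape::plot.phylo()].
#' @return `x`, invisibly.
#' @export
plot.ogt_tree <- function(x, y,
                          palette = grDevices::colorRampPalette(
                            c("steelblue", "gold", "firebrick")), ...) {
  tr <- x$tree
  ann <- x$annotations
  edge_col <- rep("grey60", nrow(tr$edge))
  node_col <- rep(NA, length(tr$tip.label) + tr$Nnode)
  if (nrow(ann)) {
    rng <- range(ann$ogt)
    if (diff(rng) == 0) rng <- rng + c(-1, 1)
    ramp <- palette(101L)
    num <- node_numbers(tr, ann$label)
    cols <- ramp[1L + round(100 * (ann$ogt - rng[1L]) / diff(rng))]
    node_col[num] <- cols
    for (k in seq_along(num)) {
      e <- which(tr$edge[, 2L] == num[k])
      if (length(e)) edge_col[e] <- cols[k]
    }
  }
  ape::plot.phylo(tr, edge.color = edge_col, show.node.label = TRUE, ...)
  nodes <- which(!is.na(node_col))
  if (length(nodes))
    ape::nodelabels(node = nodes[nodes > length(tr$tip.label)],
                    pch = 21, bg = node_col[nodes[nodes > length(tr$tip.label)]])
  invisible(x)
}
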