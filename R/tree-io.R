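#' Construct a labelled tree
#'
#' A species phylogeny (an `ape` `phylo`) together with the set of edges
#' flagged as the foreground of a branch-site test.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param foreground integer vector of edge indices (rows of `tree$edge`)
#'   flagged as foreground, possibly empty.
#' @return object of class `labeled_tree`: list with `tree`, `foreground`,
#'   and `missing_lengths` (TRUE if branch lengths were absent and set to 0).
#' @export
labeled_tree <- function(tree, foreground = integer(0)) {
  stopifnot(inherits(tree, "phylo"))
  missing_lengths <- is.null(tree$edge.length)
  if (missing_lengths) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    tree$edge.length[is.na(tree$edge.length)] <- 0
    missing_lengths <- TRUE
  }
  if (any(tree$edge.length < 0) || any(!is.finite(tree$edge.length))) {
    stop("branch lengths must be finite and non-negative")
  }
  foreground <- sort(unique(as.integer(foreground)))
  if (length(foreground) &&
      (min(foreground) < 1L || max(foreground) > nrow(tree$edge))) {
    stop("foreground edge index out of range")
  }
  structure(list(tree = tree, foreground = foreground,
                 missing_lengths = missing_lengths),
            class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("Labelled tree:", length(x$tree$tip.label), "tips,",
      nrow(x$tree$edge), "edges,", length(x$foreground),
      "foreground edge(s)\n")
  if (x$missing_lengths) cat("  (missing branch lengths were set to 0)\n")
  invisible(x)
}

#' Read a Newick tree with codeml-style foreground marks
#'
#' Parses a Newick file in which branches are flagged as foreground with a
#' `#1` mark after the tip or clade they lead to (codeml convention), e.g.
#' `((A:0.1,B:0.1):0.05 #1,C:0.2);`.  Missing branch lengths become 0 and
#' set the `missing_lengths` flag.
#'
#' @param path file path (or a Newick string via `text`).
#' @param text optional Newick string, overrides `path`.
#' @param token the foreground mark (default `"#1"`).
#' @return a [labeled_tree].
#' @export
read_labeled_tree <- function(path = NULL, text = NULL, token = "#1") {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE),
                                   collapse = "")
  mark <- "__FG__"
  esc <- gsub("([][{}()*+?.\\^$|])", "\\\\\\1", token)
  # codeml also allows the mark after the branch length
  # ("):0.05 #1"); relocate it in front of the colon first
  text <- gsub(paste0("(:[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)\\s*(",
                      esc, ")"),
               "\\3\\1", text)
  marked <- gsub(paste0("\\s*", esc), mark, text)
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = marked)),
                   error = function(e) NULL)
  if (is.null(tree)) {
    # locate the first character where a greedy prefix still parses
    off <- .newick_error_offset(marked)
    stop("malformed Newick near character ", off)
  }
  fg_nodes <- integer(0)
  strip <- function(labs) {
    hit <- grepl(mark, labs, fixed = TRUE)
    list(labs = gsub(mark, "", labs, fixed = TRUE), hit = hit)
  }
  tl <- strip(tree$tip.label)
  tree$tip.label <- tl$labs
  fg_nodes <- which(tl$hit)
  if (!is.null(tree$node.label)) {
    nl <- strip(tree$node.label)
    tree$node.label <- nl$labs
    fg_nodes <- c(fg_nodes, length(tree$tip.label) + which(nl$hit))
  }
  fg_edges <- which(tree$edge[, 2] %in% fg_nodes)
  if (length(fg_nodes) > length(fg_edges)) {
    stop("a foreground mark was placed on the root, which has no branch")
  }
  labeled_tree(tree, fg_edges)
}

.newick_error_offset <- function(text) {
  for (i in seq_len(nchar(text))) {
    ok <- tryCatch({
      ape::read.tree(text = paste0(substr(text, 1, i), ";"))
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) return(i)
  }
  nchar(text)
}

#' Write a labelled tree to Newick with foreground marks
#'
#' @param ltree a [labeled_tree].
#' @param path output file; if NULL the Newick string is returned.
#' @param token the foreground mark (default `"#1"`).
#' @return the Newick string, invisibly when written to a file.
#' @export
write_labeled_tree <- function(ltree, path = NULL, token = "#1") {
  stopifnot(inherits(ltree, "labeled_tree"))
  tree <- ltree$tree
  ntip <- length(tree$tip.label)
  fg_nodes <- tree$edge[ltree$foreground, 2]
  if (is.null(tree$node.label)) {
    tree$node.label <- rep("", tree$Nnode)
  }
  for (nd in fg_nodes) {
    if (nd <= ntip) {
      tree$tip.label[nd] <- paste0(tree$tip.label[nd], token)
    } else {
      tree$node.label[nd - ntip] <- paste0(tree$node.label[nd - ntip], token)
    }
  }
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
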