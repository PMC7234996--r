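#' Parse a Newick string into a validated time tree
#'
#' Reads a rooted, time-calibrated tree (branch lengths in time units, e.g.
#' Myr).  Polytomies are legal at parse time and can be binarized later with
#' [resolve_polytomies()].  Edges without a stated length default to 0 with a
#' warning; tip labels must be unique and non-empty and all branch lengths
#' finite and non-negative.
#'
#' @param text a Newick string (one tree).
#' @param file alternatively, path to a Newick file (one tree per file).
#' @return An object of class `"phylo"` (ape).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tip_depths(tr)
#' @seealso [write_newick()], [validate_timetree()]
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    .fail("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  .check_newick_syntax(text)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree))
    .fail("could not parse Newick string")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("edges without a branch length defaulted to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  validate_timetree(tree)
  tree
}

# cheap structural scan so malformed input reports a character offset
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        .fail("malformed Newick: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L)
    .fail("malformed Newick: ", depth, " unclosed '(' at character ",
          length(chars))
  if (!grepl(";", text, fixed = TRUE))
    .fail("malformed Newick: missing terminal ';' at character ",
          length(chars))
  invisible(TRUE)
}

#' Validate a time tree
#'
#' Checks the invariants assumed throughout the package: a rooted tree whose
#' tip labels are unique and non-empty and whose branch lengths are finite
#' and `>= 0` (zero-length edges are permitted; polytomy resolution relies
#' on them).
#'
#' @param tree a `"phylo"` object.
#' @return `tree`, invisibly; errors describe the violated invariant.
#' @export
validate_timetree <- function(tree) {
  if (!inherits(tree, "phylo")) .fail("'tree' must be a \"phylo\" object")
  if (is.null(tree$edge.length))
    .fail("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)))
    .fail("all branch lengths must be finite")
  if (any(tree$edge.length < 0))
    .fail("negative branch length(s): edge(s) ",
          paste(which(tree$edge.length < 0), collapse = ", "))
  lab <- tree$tip.label
  if (any(!nzchar(lab))) .fail("empty tip label(s)")
  dup <- unique(lab[duplicated(lab)])
  if (length(dup))
    .fail("duplicate tip label(s): ", paste(dup, collapse = ", "))
  roots <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  if (length(roots) != 1L)
    .fail("tree must have exactly one root (found ", length(roots), ")")
  invisible(tree)
}

#' Root-to-tip depths
#'
#' Path length from the root to every tip, in the tree's time units.  A
#' `root.edge` (basal stem retained by [prune_to()] so that absolute depths
#' are preserved) is included.
#'
#' @param tree a `"phylo"` object.
#' @return Named numeric vector, one entry per tip.
#' @export
tip_depths <- function(tree) {
  validate_timetree(tree)
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (!is.null(tree$root.edge)) d <- d + tree$root.edge
  names(d) <- tree$tip.label
  d
}

#' Prune a tree to a species subset
#'
#' Keeps exactly the requested tips, suppressing degree-2 internal nodes by
#' summing their incident branch lengths.  The root-to-tip depth of every
#' retained tip is preserved: if the subset's most recent common ancestor
#' sits below the original root, the pruned-away basal path is stored as the
#' tree's `root.edge`, which [tip_depths()], [shared_paths()] and
#' [simulate_bm()] all honour.
#'
#' @param tree a `"phylo"` object.
#' @param species character vector of tip labels to keep (at least 2).
#' @return A `"phylo"` object with `length(species)` tips.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' write_newick(prune_to(tr, c("A", "C")))
#' @export
prune_to <- function(tree, species) {
  validate_timetree(tree)
  species <- unique(as.character(species))
  missing <- setdiff(species, tree$tip.label)
  if (length(missing))
    .fail("species not in tree: ", paste(missing, collapse = ", "))
  if (length(species) < 2L)
    .fail("need at least 2 species to prune to (got ", length(species), ")")
  old_depth <- tip_depths(tree)[species[1L]]
  pruned <- ape::keep.tip(tree, species)
  pruned$root.edge <- NULL
  delta <- unname(old_depth -
                    ape::node.depth.edgelength(pruned)[match(species[1L],
                                                             pruned$tip.label)])
  if (delta > 1e-12) pruned$root.edge <- delta
  if (!is.null(tree$root.edge) && is.null(pruned$root.edge) &&
      tree$root.edge > 0) pruned$root.edge <- tree$root.edge
  pruned
}

#' Resolve polytomies into zero-length caterpillars
#'
#' Replaces every multifurcation by a caterpillar of zero-length internal
#' edges among its children, ordered lexicographically by each subtree's
#' smallest tip label.  The rule is deterministic and leaves every tip depth
#' and every pairwise MRCA depth -- hence the Brownian covariance structure
#' -- exactly unchanged; binarizing a k-way node adds k - 2 zero-length
#' edges.
#'
#' @param tree a `"phylo"` object.
#' @return A strictly bifurcating `"phylo"` object.
#' @examples
#' tr <- parse_newick("((A:1,B:1,C:1):1,D:2);")
#' write_newick(resolve_polytomies(tr))
#' @export
resolve_polytomies <- function(tree) {
  validate_timetree(tree)
  ntip <- ape::Ntip(tree)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  elen <- tree$edge.length
  build <- function(node) {
    rows <- kids[[as.character(node)]]
    if (is.null(rows))
      return(list(str = tree$tip.label[node], min = tree$tip.label[node]))
    parts <- lapply(rows, function(i) {
      ch <- build(tree$edge[i, 2L])
      list(str = paste0(ch$str, ":", .fmt_exact(elen[i])), min = ch$min)
    })
    parts <- parts[order(vapply(parts, `[[`, "", "min"))]
    if (length(parts) == 1L)
      return(list(str = paste0("(", parts[[1L]]$str, ")"),
                  min = parts[[1L]]$min))
    cur <- paste0("(", parts[[1L]]$str, ",", parts[[2L]]$str, ")")
    if (length(parts) > 2L)
      for (j in 3:length(parts))
        cur <- paste0("(", cur, ":0,", parts[[j]]$str, ")")
    list(str = cur, min = parts[[1L]]$min)
  }
  if (ape::Nnode(tree) < ntip - 1L)
    message("resolving polytomies with deterministic zero-length caterpillars")
  out <- ape::read.tree(text = paste0(build(ntip + 1L)$str, ";"))
  out$root.edge <- tree$root.edge
  validate_timetree(out)
  out
}

#' Shared root-to-MRCA path lengths
#'
#' The tip-by-tip matrix whose `(i, j)` entry is the path length from the
#' root to the most recent common ancestor of tips `i` and `j`; diagonal
#' entries are root-to-tip depths.  Multiplied by a rate `sigma2`, this is
#' the tip covariance implied by Brownian motion on the tree.  A `root.edge`
#' is added to every entry (it is shared ancestry of all tips).
#'
#' @param tree a `"phylo"` object.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @examples
#' shared_paths(parse_newick("((A:1,B:1):1,C:2);"))
#' @export
shared_paths <- function(tree) {
  validate_timetree(tree)
  m <- ape::vcv.phylo(tree)
  if (!is.null(tree$root.edge)) m <- m + tree$root.edge
  m
}

#' Is the tree ultrametric (time-calibrated to the present)?
#'
#' `TRUE` iff the spread of root-to-tip depths is at most `rel_tol` times
#' the maximum depth.  The analysis engine warns about, but does not
#' require, ultrametricity: the Brownian null is well defined on any clock
#' tree.
#'
#' @param tree a `"phylo"` object.
#' @param rel_tol relative tolerance (fraction of the maximum depth).
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  d <- tip_depths(tree)
  if (length(d) == 1L) return(TRUE)
  (max(d) - min(d)) <= rel_tol * max(d)
}

#' Write a tree to Newick
#'
#' Branch lengths are emitted with 6 significant digits.
#'
#' @param tree a `"phylo"` object.
#' @param file optional output path; when `NULL` the string is returned.
#' @param digits significant digits for branch lengths.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 6) {
  validate_timetree(tree)
  if (is.null(file)) return(ape::write.tree(tree, digits = digits))
  ape::write.tree(tree, file = file, digits = digits)
  invisible(ape::write.tree(tree, digits = digits))
}
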