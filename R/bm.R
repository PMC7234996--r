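#' Simulate replicate traits under Brownian motion on a tree
#'
#' The engine of the empirical null.  Each replicate draws one set of tip
#' values by a preorder traversal that adds an independent mean-zero normal
#' increment of variance `sigma2 * branch_length` along every edge (plus the
#' `root.edge` stem, if present, as ancestry shared by all tips).  Tip
#' vectors therefore have mean `root_state` and covariance
#' `sigma2 * shared_paths(tree)`.
#'
#' Replicate `r` uses a deterministic RNG substream derived from
#' `(seed, r)` via [substream_seed()], so replicate `r` is identical no
#' matter how many replicates are requested.  Increments are generated as
#' standard normal draws scaled by `sqrt(sigma2 * branch_length)` and
#' shifted by `root_state`; consequently the within-replicate rank ordering
#' of tip values is exactly invariant to `sigma2` and `root_state`, which
#' guarantees that the downstream Kruskal-Wallis null distribution does not
#' depend on either.
#'
#' @param tree a `"phylo"` object (binary or polytomous, `>= 2` tips).
#' @param n_reps number of replicates (columns), `>= 1`.
#' @param sigma2 Brownian rate: trait variance accrued per unit branch
#'   length.  Must be `> 0`.
#' @param root_state trait value at the root.
#' @param seed integer master seed.
#' @return A tips-by-replicates numeric matrix of class `"trait_matrix"`
#'   with row names in tip order and a `"config"` attribute recording
#'   `sigma2`, `root_state`, `n_reps`, `seed` and a tree summary.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' x <- simulate_bm(tr, n_reps = 5, seed = 1)
#' dim(x)
#' @export
simulate_bm <- function(tree, n_reps = 1000L, sigma2 = 1, root_state = 0,
                        seed = 1L) {
  validate_timetree(tree)
  ntip <- ape::Ntip(tree)
  if (ntip < 2L) .fail("tree must have at least 2 tips")
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
      sigma2 <= 0)
    .fail("'sigma2' must be a single positive number")
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) .fail("'n_reps' must be >= 1")

  tr <- stats::reorder(tree, "cladewise")   # parents before children
  edge <- tr$edge
  sl <- sqrt(tr$edge.length)
  nedge <- nrow(edge)
  stem <- if (!is.null(tr$root.edge) && tr$root.edge > 0)
    sqrt(tr$root.edge) else 0
  ndraw <- nedge + (stem > 0)

  z <- matrix(0, ndraw, n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(substream_seed(seed, paste0("bm-rep:", r)))
    z[, r] <- rnorm(ndraw)
  }

  v <- matrix(0, ntip + ape::Nnode(tr), n_reps)
  row0 <- 0L
  if (stem > 0) {
    v[ntip + 1L, ] <- stem * z[1L, ]
    row0 <- 1L
  }
  for (i in seq_len(nedge))
    v[edge[i, 2L], ] <- v[edge[i, 1L], ] + sl[i] * z[i + row0, ]

  out <- root_state + sqrt(sigma2) * v[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tr$tip.label
  attr(out, "config") <- list(
    sigma2 = sigma2, root_state = root_state, n_reps = n_reps, seed = seed,
    tree = list(n_tips = ntip,
                total_branch_length = sum(tr$edge.length) +
                  (if (stem > 0) tr$root.edge else 0)))
  class(out) <- c("trait_matrix", class(out))
  out
}

#' Write a trait matrix as TSV with a JSON sidecar
#'
#' Tips are rows and replicates columns; the sidecar
#' (`<prefix>.config.json`) records the simulation configuration so the
#' matrix can be regenerated.
#'
#' @param x a `"trait_matrix"` from [simulate_bm()].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.config.json`.
#' @return Invisibly, the two file paths.
#' @export
write_trait_matrix <- function(x, prefix) {
  if (!inherits(x, "trait_matrix")) .fail("'x' must be a trait_matrix")
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".config.json")
  df <- data.frame(species = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  colnames(df) <- c("species", paste0("rep", seq_len(ncol(x))))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(attr(x, "config"), js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv, js))
}
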