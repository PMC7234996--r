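#' Generate an ultrametric pure-birth tree
#'
#' Simulates a pure-birth (Yule) topology and rescales all branch lengths
#' so every tip sits at exactly `depth` time units from the root: a
#' stand-in for a fossil-calibrated, ultrametric phylogeny.  Deterministic
#' for a given seed; tips are labelled `sp001`, `sp002`, ...
#'
#' @param n_tips number of tips, `>= 2`.
#' @param depth root-to-tip depth in time units (default 100, the order of
#'   the avian crown age in Myr).
#' @param seed integer master seed.
#' @return A `"phylo"` object, ultrametric by construction.
#' @examples
#' is_ultrametric(generate_tree(10, seed = 1), rel_tol = 1e-9)
#' @export
generate_tree <- function(n_tips, depth = 100, seed = 1L) {
  n_tips <- as.integer(n_tips)
  if (is.na(n_tips) || n_tips < 2L) .fail("'n_tips' must be >= 2")
  if (!is.numeric(depth) || depth <= 0) .fail("'depth' must be > 0")
  set.seed(substream_seed(seed, "yule-tree"))
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  d <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (depth / d)
  tree$root.edge <- NULL
  validate_timetree(tree)
  tree
}

#' Label a monophyletic clade as factor level 0
#'
#' Emulates the real confound -- the KEAP1-non-functional species (Neoaves)
#' form a single clade -- by selecting the internal node whose descendant
#' tip count is closest to `clade_fraction * n_tips` (ties broken towards
#' the node whose descendant set contains the lexicographically smallest
#' tip label).  Descendants of that node get label 0, all other tips label
#' 1.  The selection is deterministic.
#'
#' @param tree a binary `"phylo"` object.
#' @param clade_fraction target share of tips labelled 0, in `(0, 1)`.
#' @return list with `labels` (named 0/1 integer vector over tips),
#'   `clade_node` (internal node number) and `clade_tips`.
#' @export
label_clade <- function(tree, clade_fraction = 0.87) {
  validate_timetree(tree)
  if (!is.numeric(clade_fraction) || clade_fraction <= 0 ||
      clade_fraction >= 1)
    .fail("'clade_fraction' must lie strictly between 0 and 1")
  ntip <- ape::Ntip(tree)
  target <- clade_fraction * ntip
  parts <- ape::prop.part(tree)            # tip sets per internal node
  sizes <- lengths(parts)
  cand <- which(sizes >= 1L & sizes <= ntip - 1L)   # both levels non-empty
  if (!length(cand))
    .fail("no internal node splits the tips into two non-empty levels")
  best <- cand[abs(sizes[cand] - target) == min(abs(sizes[cand] - target))]
  if (length(best) > 1L) {
    key <- vapply(best, function(i) min(tree$tip.label[parts[[i]]]), "")
    best <- best[order(key)][1L]
  }
  clade_tips <- tree$tip.label[parts[[best]]]
  labels <- setNames(rep(1L, ntip), tree$tip.label)
  labels[clade_tips] <- 0L
  list(labels = labels, clade_node = ntip + best, clade_tips = clade_tips)
}

#' Generate a synthetic species trait table with known ground truth
#'
#' Each trait's latent value is one Brownian replicate on the tree
#' (rate `sigma2`, root 0) plus `clade_shift` (in latent units) for tips
#' labelled 0.  Emitted traits are `exp(latent)` scaled to realistic
#' centres (mass-specific BMR around 4, lifespan around 15 years) --
#' positive and right-skewed like the real quantities; rank-based
#' downstream statistics are unaffected by the monotone transform.  With
#' `transform = "identity"` the latent values are emitted directly (useful
#' in operating-characteristic studies).  Body mass is a random power of
#' two and BMR is `ms_bmr * body_mass`, so the stored ratio reproduces the
#' trait exactly in floating point.  Quality labels are drawn
#' acceptable/high/questionable at 57/40/3%.
#'
#' @param tree a `"phylo"` object.
#' @param labels named 0/1 vector over tips (see [label_clade()]).
#' @param sigma2 Brownian rate for the latent traits; default `1 / depth`
#'   so the latent tip standard deviation is 1.
#' @param clade_shift added to the response latent trait (`ms_bmr`) for
#'   label-0 tips, in latent units (= root-to-tip BM standard deviations
#'   under the default `sigma2`).
#' @param lifespan_clade_shift same for the lifespan latent trait.
#' @param transform `"exponential"` (default) or `"identity"`.
#' @param seed integer master seed.
#' @return A `"species_traits"` data.frame; attribute `"truth"` records the
#'   latent values, shifts, `sigma2` and labels.
#' @export
generate_traits <- function(tree, labels, sigma2 = NULL, clade_shift = 0,
                            lifespan_clade_shift = 0,
                            transform = c("exponential", "identity"),
                            seed = 1L) {
  transform <- match.arg(transform)
  validate_timetree(tree)
  tips <- tree$tip.label
  if (!all(tips %in% names(labels)))
    .fail("'labels' must cover all tips")
  labels <- labels[tips]
  depth <- max(tip_depths(tree))
  if (is.null(sigma2)) sigma2 <- 1 / depth
  lat_bmr <- simulate_bm(tree, 1L, sigma2, 0,
                         substream_seed(seed, "trait:ms_bmr"))[, 1L]
  lat_ls <- simulate_bm(tree, 1L, sigma2, 0,
                        substream_seed(seed, "trait:lifespan"))[, 1L]
  lat_bmr <- lat_bmr + clade_shift * (labels == 0L)
  lat_ls <- lat_ls + lifespan_clade_shift * (labels == 0L)

  if (transform == "exponential") {
    ms_bmr <- 4 * exp(lat_bmr)
    lifespan <- 15 * exp(lat_ls)
  } else {
    ms_bmr <- lat_bmr
    lifespan <- lat_ls
  }

  set.seed(substream_seed(seed, "trait:mass-quality"))
  body_mass <- 2^sample(4:12, length(tips), replace = TRUE)   # grams
  quality <- sample(c("acceptable", "high", "questionable"),
                    length(tips), replace = TRUE,
                    prob = c(0.57, 0.40, 0.03))
  out <- data.frame(species = tips, body_mass = body_mass,
                    bmr = ms_bmr * body_mass, ms_bmr = ms_bmr,
                    max_lifespan = lifespan, lifespan_quality = quality,
                    keap1_functional = as.integer(labels),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "truth") <- list(latent_ms_bmr = lat_bmr,
                             latent_lifespan = lat_ls,
                             sigma2 = sigma2, clade_shift = clade_shift,
                             lifespan_clade_shift = lifespan_clade_shift,
                             transform = transform, labels = labels)
  class(out) <- c("species_traits", "data.frame")
  out
}

#' Generate promoter sequences with planted ARE motifs
#'
#' Emits i.i.d. background sequences with the given GC fraction, plants a
#' known number of non-overlapping consensus-expansion instances (random
#' strand) in the upstream window of each locus, and returns the full
#' ground truth.  Each sequence carries one gene locus (strands alternate)
#' whose `window`-bp upstream region contains the plants, so a scan of that
#' window must recover every planted position.
#'
#' @param n_seqs number of promoter sequences.
#' @param planted_counts integer vector (recycled to `n_seqs`) of plants
#'   per sequence.
#' @param window upstream window length in bp (default 1000).
#' @param gene_length length of the gene locus placed next to the window.
#' @param gc background GC fraction (default 0.42, avian-like).
#' @param pattern compiled `"iupac_pattern"` to plant (default ARE
#'   consensus).
#' @param seed integer master seed.
#' @return list with `sequences` (named character), `loci` (BED-style
#'   data.frame), `truth` (data.frame `sequence_id`, `start`, `strand`,
#'   `instance`; forward-strand 0-based starts) and `pattern`.
#' @export
generate_promoters <- function(n_seqs = 6L, planted_counts = 2L,
                               window = 1000L, gene_length = 500L,
                               gc = 0.42, pattern = are_consensus(),
                               seed = 1L) {
  n_seqs <- as.integer(n_seqs)
  planted_counts <- rep_len(as.integer(planted_counts), n_seqs)
  m <- pattern$length
  if (any(planted_counts < 0L)) .fail("'planted_counts' must be >= 0")
  if (window < 10L * max(planted_counts, 1L))
    .fail("window too small to pack ", max(planted_counts),
          " non-overlapping plants")
  L <- as.integer(window + gene_length)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  seqs <- character(n_seqs)
  loci <- vector("list", n_seqs)
  truth <- vector("list", n_seqs)
  for (i in seq_len(n_seqs)) {
    set.seed(substream_seed(seed, paste0("promoter:", i)))
    chars <- sample(names(base_p), L, replace = TRUE, prob = base_p)
    gene_strand <- if (i %% 2L == 1L) "+" else "-"
    if (gene_strand == "+") {
      gs <- window; ge <- L; win0 <- 0L
    } else {
      gs <- 0L; ge <- gene_length; win0 <- gene_length
    }
    k <- planted_counts[i]
    plants <- NULL
    if (k > 0L) {
      block <- window %/% k
      starts <- win0 + (seq_len(k) - 1L) * block +
        sample.int(block - m + 1L, k, replace = TRUE) - 1L
      inst <- vapply(seq_len(k), function(j)
        paste(vapply(pattern$sets, function(s)
          s[sample.int(length(s), 1L)], ""), collapse = ""), "")
      strand <- sample(c("+", "-"), k, replace = TRUE)
      for (j in seq_len(k)) {
        text <- if (strand[j] == "+") inst[j] else reverse_complement(inst[j])
        chars[(starts[j] + 1L):(starts[j] + m)] <-
          strsplit(text, "", fixed = TRUE)[[1L]]
      }
      plants <- data.frame(sequence_id = sprintf("prom%02d", i),
                           start = starts, strand = strand,
                           instance = inst, stringsAsFactors = FALSE)
    }
    seqs[i] <- paste(chars, collapse = "")
    loci[[i]] <- data.frame(sequence_id = sprintf("prom%02d", i),
                            start = gs, end = ge,
                            locus_id = sprintf("gene%02d", i),
                            strand = gene_strand, stringsAsFactors = FALSE)
    truth[[i]] <- plants
  }
  names(seqs) <- sprintf("prom%02d", seq_len(n_seqs))
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(sequence_id = character(), start = integer(),
                        strand = character(), instance = character(),
                        stringsAsFactors = FALSE)
  list(sequences = seqs, loci = do.call(rbind, loci), truth = truth,
       pattern = pattern)
}

#' Generate a complete synthetic comparative dataset
#'
#' Bundles [generate_tree()], [label_clade()] and [generate_traits()] into
#' the full input set the PI-KW pipeline expects, with ground truth
#' retained.  Defaults mirror the scale of the real study: 206 species, an
#' 87% monophyletic label-0 clade, a 100-unit-deep ultrametric tree, and
#' no clade effect (`clade_shift = 0`, the null).
#'
#' @param n_tips number of species.
#' @param depth tree depth in time units.
#' @param clade_fraction target share of label-0 (clade) tips.
#' @param clade_shift response-trait clade effect in latent SD units.
#' @param lifespan_clade_shift lifespan-trait clade effect.
#' @param transform trait transform (see [generate_traits()]).
#' @param seed integer master seed.
#' @return list with `tree`, `labels`, `clade`, `table` (and the truth
#'   attribute on `table`).
#' @export
synth_comparative <- function(n_tips = 206L, depth = 100,
                              clade_fraction = 0.87, clade_shift = 0,
                              lifespan_clade_shift = 0,
                              transform = "exponential", seed = 1L) {
  tree <- generate_tree(n_tips, depth, seed = seed)
  clade <- label_clade(tree, clade_fraction)
  table <- generate_traits(tree, clade$labels, clade_shift = clade_shift,
                           lifespan_clade_shift = lifespan_clade_shift,
                           transform = transform, seed = seed)
  list(tree = tree, labels = clade$labels, clade = clade, table = table)
}

#' Write a synthetic dataset to disk
#'
#' Emits `tree.nwk`, `traits.tsv` and -- when promoters are supplied --
#' `promoters.fa`, `loci.bed` and `truth.json`.  Output is deterministic:
#' identical inputs produce byte-identical files.
#'
#' @param comparative result of [synth_comparative()] (or `NULL`).
#' @param promoters result of [generate_promoters()] (or `NULL`).
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
synth_write <- function(comparative = NULL, promoters = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  if (!is.null(comparative)) {
    write_newick(comparative$tree, file.path(dir, "tree.nwk"))
    write.table(comparative$table, file.path(dir, "traits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, file.path(dir, c("tree.nwk", "traits.tsv")))
  }
  if (!is.null(promoters)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(promoters$sequences),
      file.path(dir, "promoters.fa"))
    bed <- promoters$loci
    bed_df <- data.frame(bed$sequence_id, bed$start, bed$end, bed$locus_id,
                         0L, bed$strand)
    write.table(bed_df, file.path(dir, "loci.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(promoters$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written,
                 file.path(dir, c("promoters.fa", "loci.bed", "truth.json")))
  }
  invisible(written)
}
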