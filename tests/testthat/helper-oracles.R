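# Independent oracles, deliberately implemented by different routes than the
# package code they check.

# Shared root-to-MRCA path lengths by explicit root-path enumeration over the
# edge matrix (the package uses ape::vcv.phylo).
oracle_shared_paths <- function(tree) {
  nt <- ape::Ntip(tree)
  nmax <- max(tree$edge)
  parent <- integer(nmax)
  plen <- numeric(nmax)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  root_path <- function(i) {       # nodes whose parent edge lies on root->i
    nodes <- integer()
    while (i != root) {
      nodes <- c(nodes, i)
      i <- parent[i]
    }
    nodes
  }
  paths <- lapply(seq_len(nt), root_path)
  m <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt))
    for (j in i:nt)
      m[i, j] <- m[j, i] <- sum(plen[intersect(paths[[i]], paths[[j]])])
  if (!is.null(tree$root.edge)) m <- m + tree$root.edge
  m
}

# Exact two-sided Mann-Whitney p by full enumeration of the C(n, n1) rank
# configurations.
oracle_mw_p <- function(a, b) {
  n1 <- length(a)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(length(r), n1), 2,
              function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Brute-force degenerate-motif scan: test every offset of every strand
# against every exact expansion of the pattern.
.oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp <- function(x)
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")

oracle_scan <- function(seq, pattern_text = "TGASWMAKCN") {
  sets <- .oracle_iupac[strsplit(toupper(pattern_text), "")[[1]]]
  expansions <- Reduce(function(acc, s)
    as.vector(outer(acc, s, paste0)), sets, "")
  s <- toupper(seq)
  m <- nchar(pattern_text)
  L <- nchar(s)
  out <- list()
  if (L >= m) {
    for (p in 0:(L - m)) {
      sub <- substring(s, p + 1, p + m)
      if (sub %in% expansions)
        out[[length(out) + 1]] <- data.frame(start = p, strand = "+",
                                             stringsAsFactors = FALSE)
      if (oracle_revcomp(sub) %in% expansions)
        out[[length(out) + 1]] <- data.frame(start = p, strand = "-",
                                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

random_dna <- function(n, seed, letters = c("A", "C", "G", "T")) {
  set.seed(seed)
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Small trait-table builder used across cohort/pikw tests.
make_table <- function(species, ms_bmr, lifespan, keap1) {
  data.frame(species = species, body_mass = 1, bmr = ms_bmr,
             ms_bmr = ms_bmr, max_lifespan = lifespan,
             lifespan_quality = "acceptable",
             keap1_functional = as.integer(keap1),
             stringsAsFactors = FALSE)
}
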