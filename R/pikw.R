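#' Conventional Kruskal-Wallis screening per stratum
#'
#' Within each bin of the assignment, runs the tie-corrected Kruskal-Wallis
#' test of the response by `keap1_functional` (0/1); a stratum is screened
#' (selected for the phylogenetically independent analysis) iff its
#' chi-square p-value is below `alpha`.  Strata missing a factor level are
#' skipped with a log entry (their statistics are `NA`).
#'
#' @param table a `"species_traits"` data.frame.
#' @param assignment a `"stratum_assignment"` from [assign_strata()].
#' @param response `"ms_bmr"` or `"max_lifespan"`.
#' @param alpha screening level (default 0.05).
#' @return data.frame with one row per bin: `stratum`, `n0`, `n1`, `H`,
#'   `chisq_p`, `screened`.
#' @export
conventional_screen <- function(table, assignment,
                                response = c("ms_bmr", "max_lifespan"),
                                alpha = 0.05) {
  response <- match.arg(response)
  idx <- match(assignment$bins$species, table$species)
  resp <- table[[response]][idx]
  fac <- table$keap1_functional[idx]
  res <- lapply(assignment$bin_labels, function(bl) {
    in_bin <- assignment$bins$bin == bl
    y <- resp[in_bin]; f <- fac[in_bin]
    n0 <- sum(f == 0L); n1 <- sum(f == 1L)
    if (n0 == 0L || n1 == 0L || (n0 + n1) < 3L) {
      message("stratum ", bl, " skipped in screening (n0 = ", n0,
              ", n1 = ", n1, ")")
      return(data.frame(stratum = bl, n0 = n0, n1 = n1, H = NA_real_,
                        chisq_p = NA_real_, screened = NA,
                        stringsAsFactors = FALSE))
    }
    kw <- kruskal_wallis(y, f)
    data.frame(stratum = bl, n0 = n0, n1 = n1, H = kw$H,
               chisq_p = kw$chisq_p, screened = kw$chisq_p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Empirical null distribution of the Kruskal-Wallis H statistic
#'
#' Simulates `n_sims` Brownian-motion trait replicates on the tree and
#' computes the tie-corrected H of each simulated trait against the fixed
#' group labels: the factor is held fixed and only the trait is simulated,
#' so the null embodies "no trait-factor association given the phylogeny".
#' Because increments are standard draws rescaled by
#' `sqrt(sigma2 * branch)` and shifted by `root_state` (see
#' [simulate_bm()]), the returned H vector is exactly identical for any
#' `sigma2 > 0` and any `root_state` at a fixed seed.
#'
#' @param tree a `"phylo"` object whose tips carry the groups.
#' @param groups vector of group labels in `tree$tip.label` order.
#' @param n_sims number of replicates.
#' @param seed integer seed (used directly; see [run_pi_kw()] for the
#'   per-stratum stream derivation).
#' @param sigma2,root_state Brownian parameters (the null does not depend
#'   on them; exposed to make that property checkable).
#' @return Numeric vector of `n_sims` simulated H values.
#' @export
empirical_null_h <- function(tree, groups, n_sims = 1000L, seed = 1L,
                             sigma2 = 1, root_state = 0) {
  if (length(groups) != ape::Ntip(tree))
    .fail("'groups' must have one label per tip")
  sims <- simulate_bm(tree, n_reps = n_sims, sigma2 = sigma2,
                      root_state = root_state, seed = seed)
  .kw_h_columns(sims, groups)
}

#' Phylogenetically independent Kruskal-Wallis test for one stratum
#'
#' The core correction for phylogenetic non-independence.  The tree is
#' pruned to exactly the stratum's species (so simulated characters
#' originate from the same phylogenetic position as the species analysed),
#' `n_sims` Brownian-motion trait replicates are simulated on the pruned
#' tree, and for each replicate the Kruskal-Wallis H is computed with the
#' real factor labels and the simulated trait as response.  The observed H
#' is compared with the 95th nearest-rank percentile of this empirical
#' null: the stratum is called significant iff it was conventionally
#' screened (chi-square p < `alpha`) and `observed_H > threshold` (strict
#' inequality; ties are conservatively not significant).  Both the add-one
#' and the raw empirical p-value are reported.
#'
#' The null H values are exactly invariant to the Brownian rate and root
#' state (see [simulate_bm()]), so the defaults `sigma2 = 1`,
#' `root_state = 0` are not assumptions.  The stratum's RNG stream is
#' derived from `(seed, stratum_id)`, so adding strata never perturbs the
#' nulls of existing ones.
#'
#' @param tree a `"phylo"` time tree containing all stratum species as tips.
#' @param table a `"species_traits"` data.frame.
#' @param assignment optional `"stratum_assignment"`; when `NULL` the whole
#'   table is analysed as a single stratum.
#' @param stratum_id bin label to analyse (one of
#'   `assignment$bin_labels`), or an arbitrary identifier when
#'   `assignment` is `NULL`.
#' @param response `"ms_bmr"` or `"max_lifespan"`.
#' @param n_sims number of Brownian replicates, `>= 100` (the paper-scale
#'   default is 1000); fewer make the 95th percentile too coarse.
#' @param seed integer master seed.
#' @param alpha screening level used for the `screened` flag.
#' @param sigma2,root_state Brownian parameters for the null simulation
#'   (defaults 1 and 0).  The null H values are provably independent of
#'   both, so these are not modelling choices; they are exposed only so
#'   that invariance can be verified.
#' @return An object of class `"pikw_result"`: list with `stratum_id`,
#'   `response`, `n_per_level`, `observed_H`, `chisq_p`, `screened`,
#'   `null` (list: `h_values`, `n_sims`, `seed`, `stratum_id`),
#'   `threshold_95`, `empirical_p_add_one`, `empirical_p_raw`,
#'   `significant`.
#' @export
run_pi_kw <- function(tree, table, assignment = NULL, stratum_id = "all",
                      response = c("ms_bmr", "max_lifespan"),
                      n_sims = 1000L, seed = 1L, alpha = 0.05,
                      sigma2 = 1, root_state = 0) {
  response <- match.arg(response)
  n_sims <- as.integer(n_sims)
  if (is.na(n_sims) || n_sims < 100L)
    .fail("'n_sims' must be >= 100: the 95th percentile of a coarser ",
          "null is unstable")
  if (is.null(assignment)) {
    species <- table$species
  } else {
    if (!stratum_id %in% assignment$bin_labels)
      .fail("unknown stratum '", stratum_id, "'")
    species <- assignment$bins$species[assignment$bins$bin == stratum_id]
  }
  missing <- setdiff(species, tree$tip.label)
  if (length(missing))
    .fail("stratum species missing from tree: ",
          paste(missing, collapse = ", "))
  idx <- match(species, table$species)
  y <- table[[response]][idx]
  f <- table$keap1_functional[idx]
  n0 <- sum(f == 0L); n1 <- sum(f == 1L)
  if (n0 == 0L || n1 == 0L)
    .fail("both factor levels must be present in stratum '", stratum_id, "'")

  pruned <- prune_to(tree, species)
  if (!is_ultrametric(pruned, rel_tol = 1e-3))
    warning("pruned tree is not ultrametric; proceeding (the null is ",
            "well defined on any clock tree)")
  ord <- match(pruned$tip.label, species)
  y <- y[ord]; f <- f[ord]

  kw <- kruskal_wallis(y, f)
  h_null <- empirical_null_h(pruned, f, n_sims = n_sims,
                             seed = substream_seed(seed, paste0("stratum:",
                                                                stratum_id)),
                             sigma2 = sigma2, root_state = root_state)
  thr <- empirical_percentile(h_null, 95)
  screened <- kw$chisq_p < alpha
  out <- list(
    stratum_id = stratum_id, response = response,
    n_per_level = c(`0` = n0, `1` = n1),
    observed_H = kw$H, chisq_p = kw$chisq_p, screened = screened,
    null = list(h_values = h_null, n_sims = n_sims, seed = seed,
                stratum_id = stratum_id),
    threshold_95 = thr,
    empirical_p_add_one = empirical_p(h_null, kw$H, "add-one"),
    empirical_p_raw = empirical_p(h_null, kw$H, "raw"),
    significant = screened && kw$H > thr)
  class(out) <- "pikw_result"
  out
}

#' @export
print.pikw_result <- function(x, ...) {
  cat("PI Kruskal-Wallis, stratum '", x$stratum_id, "' (", x$response,
      ")\n", sep = "")
  cat("  n(level 0/1) =", paste(x$n_per_level, collapse = "/"),
      "\n  observed H =", format(x$observed_H, digits = 4),
      "  conventional chi-square p =", format(x$chisq_p, digits = 4),
      "\n  null: ", x$null$n_sims, "Brownian sims; 95th-percentile",
      "threshold =", format(x$threshold_95, digits = 4),
      "\n  empirical p =", format(x$empirical_p_add_one, digits = 4),
      "(add-one),", format(x$empirical_p_raw, digits = 4), "(raw)",
      "\n  significant:", x$significant, "\n")
  invisible(x)
}

#' Run the full stratified PI-KW pipeline
#'
#' Stratifies the trait table, checks per-bin Mann-Whitney balance, screens
#' every testable stratum with the conventional Kruskal-Wallis test, and
#' runs the phylogenetically independent test on the screened strata (or on
#' all testable strata with `pi_on = "all"`, useful for operating
#' -characteristic studies).  Optionally writes a summary TSV and one JSON
#' record per analysed stratum (including the full null vector); identical
#' inputs and seed produce byte-identical files.
#'
#' @param tree a `"phylo"` time tree.
#' @param table a `"species_traits"` data.frame.
#' @param response trait tested between factor levels.
#' @param stratify_by stratifying variable (the other trait).
#' @param bin_edges ascending bin edges for the stratifying variable.
#' @param n_sims Brownian replicates per stratum (default 1000).
#' @param seed integer master seed.
#' @param alpha screening / significance level.
#' @param balance_alpha level for the Mann-Whitney balance check.
#' @param pi_on `"screened"` (default: strata with conventional p < alpha)
#'   or `"all"` testable strata.
#' @param out_dir optional output directory for `summary.tsv` and
#'   `stratum-<i>.json`.
#' @return An object of class `"pikw_pipeline"`: list with `assignment`,
#'   `balance`, `screen`, `results` (named list of `"pikw_result"`),
#'   `summary` (data.frame), `config`.
#' @export
pikw_pipeline <- function(tree, table,
                          response = c("ms_bmr", "max_lifespan"),
                          stratify_by = c("max_lifespan", "ms_bmr"),
                          bin_edges = c(10, 20, 30, 40, 50),
                          n_sims = 1000L, seed = 1L, alpha = 0.05,
                          balance_alpha = 0.05,
                          pi_on = c("screened", "all"), out_dir = NULL) {
  response <- match.arg(response)
  stratify_by <- match.arg(stratify_by)
  pi_on <- match.arg(pi_on)
  if (response == stratify_by)
    .fail("'response' and 'stratify_by' must differ")

  in_tree <- table$species %in% tree$tip.label
  if (any(!in_tree))
    message("excluding ", sum(!in_tree), " species absent from the tree: ",
            paste(head(table$species[!in_tree], 5), collapse = ", "),
            if (sum(!in_tree) > 5) ", ...")
  table <- table[in_tree, , drop = FALSE]

  assignment <- assign_strata(table, stratify_by, bin_edges)
  balance <- check_balance(assignment, table, alpha = balance_alpha)
  screen <- conventional_screen(table, assignment, response, alpha = alpha)

  run_these <- if (pi_on == "screened")
    screen$stratum[!is.na(screen$screened) & screen$screened]
  else screen$stratum[!is.na(screen$screened)]
  results <- lapply(run_these, function(bl)
    run_pi_kw(tree, table, assignment, bl, response,
              n_sims = n_sims, seed = seed, alpha = alpha))
  names(results) <- run_these

  summary <- merge(screen,
                   balance[, c("bin", "p", "status")],
                   by.x = "stratum", by.y = "bin", sort = FALSE)
  names(summary)[names(summary) == "p"] <- "balance_p"
  names(summary)[names(summary) == "status"] <- "balance"
  summary$threshold_95 <- NA_real_
  summary$empirical_p <- NA_real_
  summary$empirical_p_raw <- NA_real_
  summary$significant <- NA
  for (r in results) {
    i <- match(r$stratum_id, summary$stratum)
    summary$threshold_95[i] <- r$threshold_95
    summary$empirical_p[i] <- r$empirical_p_add_one
    summary$empirical_p_raw[i] <- r$empirical_p_raw
    summary$significant[i] <- r$significant
  }

  out <- list(assignment = assignment, balance = balance, screen = screen,
              results = results, summary = summary,
              config = list(response = response, stratify_by = stratify_by,
                            bin_edges = bin_edges, n_sims = n_sims,
                            seed = seed, alpha = alpha,
                            balance_alpha = balance_alpha, pi_on = pi_on))
  class(out) <- "pikw_pipeline"
  if (!is.null(out_dir)) .write_pipeline(out, out_dir)
  out
}

.write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(x$summary, file.path(out_dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (i in seq_along(x$results)) {
    r <- x$results[[i]]
    rec <- r[c("stratum_id", "response", "n_per_level", "observed_H",
               "chisq_p", "screened", "threshold_95",
               "empirical_p_add_one", "empirical_p_raw", "significant")]
    rec$n_per_level <- as.list(r$n_per_level)
    rec$null <- list(n_sims = r$null$n_sims, seed = r$null$seed,
                     h_values = r$null$h_values)
    jsonlite::write_json(rec, file.path(out_dir,
                                        sprintf("stratum-%02d.json", i)),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(x$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pikw_pipeline <- function(x, ...) {
  cat("PI Kruskal-Wallis pipeline:", x$config$response, "by KEAP1 factor,",
      "stratified by", x$config$stratify_by, "\n")
  print(x$summary, digits = 4)
  invisible(x)
}
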