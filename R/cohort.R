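#' Normalize species names for joining
#'
#' Case-folds, converts underscores to spaces, trims and collapses
#' whitespace, so `"gallus_gallus"` and `"Gallus gallus"` match.
#'
#' @param x character vector of binomial names.
#' @return Normalized character vector.
#' @export
normalize_species <- function(x)
  gsub(" +", " ", trimws(tolower(gsub("_", " ", as.character(x)))))

#' Merge BMR, lifespan and factor sources into a species trait table
#'
#' Inner join on normalized species names of (1) a body-mass/basal-metabolic
#' -rate table, (2) a maximum-lifespan table with AnAge-style data-quality
#' labels, and (3) the binary KEAP1-functionality factor (1 = functional,
#' basal Aves; 0 = non-functional, Neoaves).  Mass-specific BMR is computed
#' as the raw ratio `bmr / body_mass` with no unit conversion: all
#' downstream statistics are rank-based, hence unit-invariant.  Rows with
#' non-positive mass or BMR are rejected (and counted); duplicate species
#' within one source are an error.  A merge report (attribute
#' `"merge_report"`) records, per source, rows in, retained and dropped,
#' plus the unmatched names.
#'
#' @param bmr_table data.frame with species, mass and BMR columns.
#' @param lifespan_table data.frame with species, lifespan and quality
#'   columns (labels among `acceptable`, `high`, `questionable`).
#' @param factor_table data.frame with species and 0/1 factor columns.
#' @param cols named list mapping the roles `species`, `mass`, `bmr`,
#'   `lifespan`, `quality`, `keap1` to the column names used in the inputs.
#' @return A data.frame of class `"species_traits"` with columns `species`,
#'   `body_mass`, `bmr`, `ms_bmr`, `max_lifespan`, `lifespan_quality`,
#'   `keap1_functional`, and attribute `"merge_report"`.
#' @examples
#' bmr <- data.frame(species = "Gallus gallus", body_mass = 2000, bmr = 20)
#' ls <- data.frame(species = "gallus_gallus", max_lifespan = 30,
#'                  lifespan_quality = "high")
#' fc <- data.frame(species = "Gallus gallus", keap1_functional = 1)
#' merge_sources(bmr, ls, fc)$ms_bmr   # 0.01
#' @export
merge_sources <- function(bmr_table, lifespan_table, factor_table,
                          cols = list(species = "species",
                                      mass = "body_mass", bmr = "bmr",
                                      lifespan = "max_lifespan",
                                      quality = "lifespan_quality",
                                      keap1 = "keap1_functional")) {
  pick <- function(tab, roles, src) {
    need <- unlist(cols[roles], use.names = FALSE)
    miss <- setdiff(need, names(tab))
    if (length(miss))
      .fail(src, " source lacks column(s): ", paste(miss, collapse = ", "))
    out <- tab[, need, drop = FALSE]
    names(out) <- roles
    out$.key <- normalize_species(out$species)
    dup <- unique(out$.key[duplicated(out$.key)])
    if (length(dup))
      .fail("duplicate species in ", src, " source: ",
            paste(dup, collapse = ", "))
    out
  }
  b <- pick(bmr_table, c("species", "mass", "bmr"), "BMR")
  l <- pick(lifespan_table, c("species", "lifespan", "quality"), "lifespan")
  f <- pick(factor_table, c("species", "keap1"), "factor")

  bad <- !is.finite(b$mass) | !is.finite(b$bmr) | b$mass <= 0 | b$bmr <= 0
  n_rejected <- sum(bad)
  if (n_rejected) {
    message("rejected ", n_rejected,
            " BMR row(s) with non-positive or missing mass/BMR: ",
            paste(b$species[bad], collapse = ", "))
    b <- b[!bad, , drop = FALSE]
  }

  keys <- Reduce(intersect, list(b$.key, l$.key, f$.key))
  out <- data.frame(
    species = b$species[match(keys, b$.key)],
    body_mass = b$mass[match(keys, b$.key)],
    bmr = b$bmr[match(keys, b$.key)],
    max_lifespan = l$lifespan[match(keys, l$.key)],
    lifespan_quality = as.character(l$quality[match(keys, l$.key)]),
    keap1_functional = as.integer(f$keap1[match(keys, f$.key)]),
    stringsAsFactors = FALSE)
  out$ms_bmr <- out$bmr / out$body_mass
  out <- out[, c("species", "body_mass", "bmr", "ms_bmr", "max_lifespan",
                 "lifespan_quality", "keap1_functional")]
  if (any(!out$keap1_functional %in% c(0L, 1L)))
    .fail("keap1_functional must be 0 or 1")
  bad_q <- setdiff(unique(out$lifespan_quality),
                   c("acceptable", "high", "questionable"))
  if (length(bad_q))
    .fail("unknown lifespan quality label(s): ", paste(bad_q, collapse = ", "))

  report <- list(
    n_merged = nrow(out),
    sources = list(
      bmr = list(n_in = nrow(bmr_table), n_rejected = n_rejected,
                 n_retained = sum(b$.key %in% keys),
                 unmatched = b$species[!b$.key %in% keys]),
      lifespan = list(n_in = nrow(lifespan_table),
                      n_retained = sum(l$.key %in% keys),
                      unmatched = l$species[!l$.key %in% keys]),
      factor = list(n_in = nrow(factor_table),
                    n_retained = sum(f$.key %in% keys),
                    unmatched = f$species[!f$.key %in% keys])))
  attr(out, "merge_report") <- report
  class(out) <- c("species_traits", "data.frame")
  out
}

#' Filter by lifespan data-quality label
#'
#' By default all three AnAge-style labels are kept, questionable records
#' included: in the source data these are conservative underestimates of
#' lifespan, so retaining them only biases against detecting lifespan
#' differences.  With `include_questionable = FALSE` they are dropped.  The
#' retained fraction by label is attached as attribute `"quality_report"`.
#'
#' @param table a `"species_traits"` data.frame.
#' @param include_questionable keep `questionable` records?
#' @return The filtered table (class preserved).
#' @export
filter_quality <- function(table, include_questionable = TRUE) {
  if (!.is_flag(include_questionable))
    .fail("'include_questionable' must be TRUE or FALSE")
  lv <- c("acceptable", "high", "questionable")
  bad <- setdiff(unique(table$lifespan_quality), lv)
  if (length(bad))
    .fail("unknown lifespan quality label(s): ", paste(bad, collapse = ", "))
  keep_lv <- if (include_questionable) lv else c("acceptable", "high")
  keep <- table$lifespan_quality %in% keep_lv
  out <- table[keep, , drop = FALSE]
  counts_in <- table(factor(table$lifespan_quality, lv))
  counts_out <- table(factor(out$lifespan_quality, lv))
  attr(out, "quality_report") <- list(
    n_in = nrow(table), n_retained = nrow(out),
    retained_by_label = as.list(counts_out),
    retained_fraction_by_label =
      as.list(ifelse(counts_in > 0, counts_out / counts_in, NA_real_)))
  class(out) <- c("species_traits", "data.frame")
  out
}

#' Stratify species into trait intervals
#'
#' Assigns every species with a finite value of the stratifying variable to
#' exactly one bin.  Bins are left-closed right-open on the given ascending
#' edges, with a leading open bin below the first edge (`"<e1"`) and a
#' trailing open bin at and above the last (`">=ek"`) -- matching interval
#' groupings such as "<10 years", "10-19.9 years", ">50 years" for lifespan
#' and "2-2.9", ">8" for MS-BMR.  Species missing the variable are excluded
#' and counted.
#'
#' @param table a `"species_traits"` data.frame.
#' @param variable `"max_lifespan"` or `"ms_bmr"`.
#' @param bin_edges strictly increasing numeric vector (at least one edge).
#' @return An object of class `"stratum_assignment"`: list with `variable`,
#'   `edges`, `bin_labels`, `bins` (data.frame species/value/bin),
#'   `n_excluded`, `excluded_species`.
#' @examples
#' tab <- data.frame(species = letters[1:3], ms_bmr = c(1, 2.95, 9),
#'                   max_lifespan = c(5, 15, 55))
#' assign_strata(tab, "max_lifespan", c(10, 20, 30, 40, 50))
#' @export
assign_strata <- function(table, variable = c("max_lifespan", "ms_bmr"),
                          bin_edges) {
  variable <- match.arg(variable)
  if (!length(bin_edges) || any(diff(bin_edges) <= 0))
    .fail("'bin_edges' must be strictly increasing with at least one edge")
  v <- table[[variable]]
  if (is.null(v)) .fail("table lacks column '", variable, "'")
  ok <- is.finite(v)
  lab <- .bin_labels(bin_edges)
  idx <- findInterval(v[ok], bin_edges) + 1L   # 1 = below first edge
  out <- list(
    variable = variable, edges = bin_edges, bin_labels = lab,
    bins = data.frame(species = table$species[ok], value = v[ok],
                      bin = factor(lab[idx], levels = lab),
                      stringsAsFactors = FALSE),
    n_excluded = sum(!ok), excluded_species = table$species[!ok])
  class(out) <- "stratum_assignment"
  out
}

.bin_labels <- function(edges) {
  k <- length(edges)
  e <- format(edges, trim = TRUE)
  inner <- if (k >= 2)
    paste0("[", e[-k], ",", e[-1], ")") else character()
  c(paste0("<", e[1]), inner, paste0(">=", e[k]))
}

#' @export
print.stratum_assignment <- function(x, ...) {
  cat("Stratification of", nrow(x$bins), "species by", x$variable,
      "\n  edges:", paste(x$edges, collapse = ", "),
      "\n  excluded (missing value):", x$n_excluded, "\n")
  print(table(x$bins$bin))
  invisible(x)
}

#' Mann-Whitney balance check within strata
#'
#' Within each bin, tests whether the stratifying variable is statistically
#' indistinguishable between the two factor levels (Mann-Whitney, two
#' sided): a bin passes iff `p >= alpha`.  Bins missing a factor level are
#' flagged `"untestable"` rather than failed.  Note the logical weakness of
#' accept-the-null balance criteria: a pass means no detectable imbalance at
#' the given sample size, not demonstrated equality.
#'
#' @param assignment a `"stratum_assignment"`.
#' @param table the `"species_traits"` table carrying `keap1_functional`.
#' @param alpha balance significance level (default 0.05).
#' @return data.frame with one row per bin: `bin`, `n0`, `n1`, `U`, `p`,
#'   `status` (`pass`/`fail`/`untestable`).
#' @export
check_balance <- function(assignment, table, alpha = 0.05) {
  if (!inherits(assignment, "stratum_assignment"))
    .fail("'assignment' must come from assign_strata()")
  fac <- table$keap1_functional[match(assignment$bins$species, table$species)]
  res <- lapply(assignment$bin_labels, function(bl) {
    in_bin <- assignment$bins$bin == bl
    v <- assignment$bins$value[in_bin]
    f <- fac[in_bin]
    n0 <- sum(f == 0L); n1 <- sum(f == 1L)
    if (n0 == 0L || n1 == 0L)
      return(data.frame(bin = bl, n0 = n0, n1 = n1, U = NA_real_,
                        p = NA_real_, status = "untestable",
                        stringsAsFactors = FALSE))
    mw <- mann_whitney(v[f == 0L], v[f == 1L])
    data.frame(bin = bl, n0 = n0, n1 = n1, U = mw$U, p = mw$p_two_sided,
               status = if (mw$p_two_sided >= alpha) "pass" else "fail",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
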