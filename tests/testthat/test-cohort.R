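bmr_src <- data.frame(
  species = c("Gallus gallus", "Struthio camelus", "Corvus corax",
              "Apteryx rowi"),
  body_mass = c(2000, 100000, 1200, 2500),
  bmr = c(20, 300, 18, 15))
ls_src <- data.frame(
  species = c("gallus_gallus", "Corvus corax", "Taeniopygia guttata",
              "Apteryx rowi"),
  max_lifespan = c(30, 69, 12, 35),
  lifespan_quality = c("high", "acceptable", "questionable", "acceptable"))
fac_src <- data.frame(
  species = c("Gallus gallus", "Corvus corax", "Apteryx rowi",
              "Struthio camelus"),
  keap1_functional = c(1, 0, 1, 1))

test_that("merge_sources inner-joins on normalized names and derives MS-BMR", {
  tab <- merge_sources(bmr_src, ls_src, fac_src)
  expect_s3_class(tab, "species_traits")
  expect_setequal(tab$species, c("Gallus gallus", "Corvus corax",
                                 "Apteryx rowi"))
  gg <- tab[tab$species == "Gallus gallus", ]
  expect_equal(gg$ms_bmr, 0.01)
  expect_equal(gg$max_lifespan, 30)          # matched via "gallus_gallus"
  expect_equal(gg$keap1_functional, 1L)

  rep <- attr(tab, "merge_report")
  expect_equal(rep$n_merged, 3)
  # retained + dropped = rows in, per source
  expect_equal(rep$sources$bmr$n_retained +
                 length(rep$sources$bmr$unmatched) +
                 rep$sources$bmr$n_rejected, nrow(bmr_src))
  expect_true("Struthio camelus" %in% rep$sources$bmr$unmatched)
  expect_true("Taeniopygia guttata" %in% rep$sources$lifespan$unmatched)
})

test_that("merge_sources is symmetric in source row order", {
  tab1 <- merge_sources(bmr_src, ls_src, fac_src)
  shuffled <- merge_sources(bmr_src[c(3, 1, 4, 2), ],
                            ls_src[c(4, 2, 3, 1), ], fac_src)
  ord <- order(tab1$species)
  expect_equal(tab1[ord, ], shuffled[order(shuffled$species), ],
               ignore_attr = TRUE)
})

test_that("merge_sources rejects bad rows and duplicate species", {
  b2 <- bmr_src
  b2$bmr[2] <- -1
  expect_message(tab <- merge_sources(b2, ls_src, fac_src), "rejected 1")
  expect_false("Struthio camelus" %in% tab$species)

  dup <- rbind(bmr_src, bmr_src[1, ])
  expect_error(merge_sources(dup, ls_src, fac_src), "duplicate species")
})

test_that("ms_bmr always reproduces bmr / body_mass exactly", {
  tab <- merge_sources(bmr_src, ls_src, fac_src)
  expect_identical(tab$ms_bmr, tab$bmr / tab$body_mass)
  synth <- synth_comparative(n_tips = 30, seed = 42)$table
  expect_identical(synth$ms_bmr, synth$bmr / synth$body_mass)
})

test_that("filter_quality keeps everything by default, drops questionable on request", {
  tab <- make_table(sprintf("s%02d", 1:100), runif(100, 2, 8),
                    runif(100, 5, 60), rep(0:1, 50))
  tab$lifespan_quality <- rep(c("acceptable", "high", "questionable"),
                              c(57, 40, 3))
  expect_equal(nrow(filter_quality(tab)), 100)
  strict <- filter_quality(tab, include_questionable = FALSE)
  expect_equal(nrow(strict), 97)
  expect_equal(attr(strict, "quality_report")$retained_by_label$questionable,
               0L, ignore_attr = TRUE)

  empty <- filter_quality(tab[0, ])
  expect_equal(nrow(empty), 0)

  bad <- tab
  bad$lifespan_quality[1] <- "excellent"
  expect_error(filter_quality(bad), "unknown lifespan quality")
})

test_that("assign_strata uses left-closed right-open bins with open ends", {
  tab <- make_table(c("a", "b", "c", "d", "e"), c(1, 2.95, 8.4, 5, 3),
                    c(9.9, 10, 55, 20, NA), c(0, 1, 0, 1, 0))
  ls_bins <- assign_strata(tab, "max_lifespan", c(10, 20, 30, 40, 50))
  got <- setNames(as.character(ls_bins$bins$bin), ls_bins$bins$species)
  expect_equal(got[["a"]], "<10")
  expect_equal(got[["b"]], "[10,20)")
  expect_equal(got[["c"]], ">=50")
  expect_equal(got[["d"]], "[20,30)")
  expect_equal(ls_bins$n_excluded, 1L)
  expect_equal(ls_bins$excluded_species, "e")

  mb <- assign_strata(tab, "ms_bmr", 2:8)
  gm <- setNames(as.character(mb$bins$bin), mb$bins$species)
  expect_equal(gm[["b"]], "[2,3)")     # 2.95 falls in the "2-2.9" group
  expect_equal(gm[["c"]], ">=8")       # 8.4 falls in the ">8" group
  expect_equal(gm[["a"]], "<2")

  # partition property: every stratified species in exactly one bin
  expect_equal(nrow(mb$bins), 5L)
  expect_equal(sum(table(mb$bins$bin)), 5L)
  expect_error(assign_strata(tab, "ms_bmr", c(3, 2)), "increasing")
})

test_that("check_balance runs Mann-Whitney per bin and flags untestable bins", {
  tab <- make_table(sprintf("s%02d", 1:24),
                    ms_bmr = c(1:10, 11:20, 3, 4, 5, 6),
                    lifespan = c(rep(5, 20), rep(15, 4)),
                    keap1 = c(rep(0, 10), rep(1, 10), rep(0, 4)))
  asg <- assign_strata(tab, "max_lifespan", 10)
  bal <- check_balance(asg, tab)
  expect_equal(bal$status[bal$bin == ">=10"], "untestable")   # only level 0

  # in the "<10" bin the lifespans are identical across levels -> p = 1, pass
  expect_equal(bal$p[bal$bin == "<10"], 1)
  expect_equal(bal$status[bal$bin == "<10"], "pass")

  # clearly separated stratifying values fail the balance check
  tab2 <- make_table(sprintf("t%02d", 1:20), runif(20, 2, 8),
                     lifespan = c(1:10, 11:20),
                     keap1 = rep(0:1, each = 10))
  asg2 <- assign_strata(tab2, "max_lifespan", 1000)
  bal2 <- check_balance(asg2, tab2)
  expect_equal(bal2$status[bal2$bin == "<1000"], "fail")
})
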