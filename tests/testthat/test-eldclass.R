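# Independent semantic oracle for the decision table: derive each label from
# the meaning of the sign triple rather than from a lookup.
semanticCategory <- function(ha, hb, ab) {
  if (ha == 0 && hb == 0 && ab == 0) return("NO_CHANGE")
  if (ha == 0 && hb != 0 && ab == hb)          # hybrid = maternal
    return(if (hb > 0) "I" else "II")
  if (hb == 0 && ha != 0 && ab == -ha)         # hybrid = paternal
    return(if (ha > 0) "III" else "IV")
  if (ha != 0 && hb == -ha && ab == hb)        # strictly between parents
    return(if (ha < 0) "V" else "VI")
  if (ha == 1 && hb == 1)                      # above both parents
    return(c(`1` = "VII", `0` = "VIII", `-1` = "IX")[as.character(ab)])
  if (ha == -1 && hb == -1)                    # below both parents
    return(c(`1` = "X", `0` = "XI", `-1` = "XII")[as.character(ab)])
  "AMBIGUOUS"
}

test_that("the decision table partitions all 27 sign triples", {
  grid <- expand.grid(ha = -1:1, hb = -1:1, ab = -1:1)
  got <- classifyCategory(grid$ha, grid$hb, grid$ab)
  want <- mapply(semanticCategory, grid$ha, grid$hb, grid$ab)
  expect_identical(got$category, unname(want))
  expect_equal(sum(got$category == "AMBIGUOUS"), 14)
  expect_equal(length(unique(got$category[got$category != "AMBIGUOUS"])), 13)
  # group labels follow the category blocks
  expect_setequal(got$group_label[got$category %in% c("I", "II")], "BSB_ELD")
  expect_setequal(got$group_label[got$category %in% c("III", "IV")], "YB_ELD")
  expect_setequal(got$group_label[got$category %in% c("V", "VI")], "ADDITIVITY")
  expect_setequal(got$group_label[got$category %in% c("VII", "VIII", "IX")], "UP")
  expect_setequal(got$group_label[got$category %in% c("X", "XI", "XII")], "DOWN")
})

test_that("named examples classify as expected", {
  expect_equal(classifyCategory(0, 0, 0)$category, "NO_CHANGE")
  one <- classifyCategory(0, 1, 1)
  expect_equal(one$category, "I")
  expect_equal(one$group_label, "BSB_ELD")
  expect_error(classifyCategory(2, 0, 0), "-1, 0 or")
})

test_that("swapping the parents' roles permutes categories symmetrically", {
  # with roles swapped the triple (d_HA, d_HB, d_AB) becomes
  # (d_HB, d_HA, -d_AB); maternal and paternal blocks must exchange
  swapMap <- c(I = "III", II = "IV", III = "I", IV = "II",
               V = "VI", VI = "V", VII = "IX", VIII = "VIII", IX = "VII",
               X = "XII", XI = "XI", XII = "X",
               NO_CHANGE = "NO_CHANGE", AMBIGUOUS = "AMBIGUOUS")
  grid <- expand.grid(ha = -1:1, hb = -1:1, ab = -1:1)
  orig <- classifyCategory(grid$ha, grid$hb, grid$ab)
  swap <- classifyCategory(grid$hb, grid$ha, -grid$ab)
  expect_identical(swap$category, unname(swapMap[orig$category]))
  lab <- orig$group_label
  expect_identical(swap$group_label,
                   ifelse(lab == "BSB_ELD", "YB_ELD",
                          ifelse(lab == "YB_ELD", "BSB_ELD", lab)))
})

test_that("classifyTrios rejects mismatched gene sets and sums its groups", {
  mk <- function(ids, signs) data.frame(gene_id = ids, sign = signs)
  expect_error(classifyTrios(mk(c("a", "b"), c(0, 1)),
                             mk(c("a", "c"), c(0, 1)),
                             mk(c("a", "b"), c(0, 1))),
               "offenders")
  trio <- classifyTrios(mk(letters[1:4], c(0, 0, 1, 0)),
                        mk(letters[1:4], c(1, -1, 1, 0)),
                        mk(letters[1:4], c(1, -1, 1, 0)))
  expect_equal(sum(trio$summary$count), 4)
  parental <- sum(trio$summary$count[trio$summary$group_label %in%
                                       c("BSB_ELD", "YB_ELD")])
  expect_equal(parental,
               sum(trio$assignments$category %in% c("I", "II", "III", "IV")))
})

test_that("simulated category-I genes are recovered and nulls stay unchanged", {
  sim <- simulateCounts(simConfig(500, seed = 3, effect_log2fc = 3,
                                  nb_dispersion = 0.05,
                                  category_probs = c(I = 0.2, NO_CHANGE = 0.8)))
  he <- suppressMessages(filterCoexpressed(computeFpkm(sim$experiment)))
  truth <- sim$truth[match(rownames(he), sim$truth$gene_id), ]
  trio <- classifyTrios(
    nbExactTest(he, "2nBY", "BSB", fdrCutoff = 0.005),
    nbExactTest(he, "2nBY", "YB", fdrCutoff = 0.005),
    nbExactTest(he, "BSB", "YB", fdrCutoff = 0.005))
  isI <- truth$category == "I"
  expect_gte(mean(trio$assignments$category[isI] == "I"), 0.9)
  expect_gte(mean(trio$assignments$category[!isI] == "NO_CHANGE"), 0.95)
})

test_that("category recovery is monotone in the true effect size", {
  recovery <- sapply(c(1.5, 2, 3), function(f) {
    sim <- simulateCounts(simConfig(300, seed = 8, effect_log2fc = f,
                                    nb_dispersion = 0.05,
                                    category_probs = c(I = 0.4, II = 0.3,
                                                       NO_CHANGE = 0.3)))
    trio <- classifyTrios(
      nbExactTest(sim$experiment, "2nBY", "BSB", fdrCutoff = 0.005),
      nbExactTest(sim$experiment, "2nBY", "YB", fdrCutoff = 0.005),
      nbExactTest(sim$experiment, "BSB", "YB", fdrCutoff = 0.005))
    mean(trio$assignments$category == sim$truth$category)
  })
  expect_true(all(diff(recovery) >= 0))
})

test_that("asymmetry tests delegate to Fisher's exact test", {
  s1 <- data.frame(group_label = c("BSB_ELD", "YB_ELD", "UP", "DOWN"),
                   count = c(1866, 587, 184, 110))
  s2 <- data.frame(group_label = c("BSB_ELD", "YB_ELD", "UP", "DOWN"),
                   count = c(2710, 201, 55, 463))
  res <- eldAsymmetryTest(s1, s2, labels = c("2nBY", "3nBY"))
  expect_lt(res$updown$p, 0.05)
  expect_equal(res$updown$p, fisherExact2x2(rbind(c(184, 110), c(55, 463))))
  expect_equal(res$eld$p, fisherExact2x2(rbind(c(1866, 587), c(2710, 201))))
  sym <- data.frame(group_label = c("BSB_ELD", "YB_ELD", "UP", "DOWN"),
                    count = c(10, 10, 5, 5))
  expect_equal(eldAsymmetryTest(sym, sym)$eld$p, 1.0)
})

test_that("inheritance overlap counts shared and discordant parental ELD", {
  mk <- function(labels) data.frame(gene_id = paste0("g", seq_along(labels)),
                                    group_label = labels)
  a <- mk(c("BSB_ELD", "BSB_ELD", "YB_ELD", "NO_CHANGE", "BSB_ELD"))
  expect_equal(unname(eldInheritanceOverlap(a, a)["discordant"]), 0L)
  b <- mk(c("NO_CHANGE", "NO_CHANGE", "NO_CHANGE", "BSB_ELD", "YB_ELD"))
  ov <- eldInheritanceOverlap(a, b)
  expect_equal(unname(ov["bsb_eld_both"]), 0L)
  expect_equal(unname(ov["yb_eld_both"]), 0L)
  expect_equal(unname(ov["discordant"]), 1L)   # g5 BSB in a, YB in b
  expect_equal(unname(ov["eld_one_only"]), 4L)
})

test_that("shared truth labels give highly heritable parental ELD", {
  sim <- simulateCounts(simConfig(400, seed = 13, effect_log2fc = 3,
                                  nb_dispersion = 0.05,
                                  category_probs = c(I = 0.25, III = 0.25,
                                                     NO_CHANGE = 0.5)))
  he <- sim$experiment
  trios <- lapply(c("2nBY", "3nBY"), function(h)
    classifyTrios(nbExactTest(he, h, "BSB", fdrCutoff = 0.005),
                  nbExactTest(he, h, "YB", fdrCutoff = 0.005),
                  nbExactTest(he, "BSB", "YB", fdrCutoff = 0.005)))
  ov <- eldInheritanceOverlap(trios[[1]]$assignments, trios[[2]]$assignments)
  shared <- ov["bsb_eld_both"] + ov["yb_eld_both"]
  anyEld <- shared + ov["discordant"] + ov["eld_one_only"]
  expect_gte(unname(shared / anyEld), 0.8)
})
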