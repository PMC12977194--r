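# Reference ROI-group counts (k of n sites per hemisphere) used for the
# hemispheric asymmetry checks: stimulus / intermediate / behavior patterns.
roi_group_counts <- function() {
  d <- rbind(
    c(97, 100, 77, 78,  1, 100,  1, 78,   0, 100,  0, 78),
    c(96, 165, 82, 138, 10, 165, 12, 138,  1, 165,  0, 138),
    c(157, 295, 138, 228, 32, 295, 14, 228, 1, 295,  2, 228),
    c(66, 574, 89, 593, 15, 574, 19, 593, 15, 574,  5, 593),
    c(28, 264, 48, 254,  6, 264,  8, 254,  7, 264,  4, 254),
    c(3, 211,  1, 214,  3, 211,  2, 214, 10, 211,  9, 214),
    c(26, 765, 25, 675,  6, 765, 12, 675, 60, 765, 24, 675),
    c(32, 332, 49, 257, 18, 332,  5, 257, 13, 332,  5, 257))
  groups <- c("Auditory core", "STP", "STG", "Ventral", "Dorsal", "Limbic",
              "Prefrontal", "Sensorimotor")
  dimnames(d) <- list(groups,
                      c("stim_kL", "stim_nL", "stim_kR", "stim_nR",
                        "int_kL", "int_nL", "int_kR", "int_nR",
                        "beh_kL", "beh_nL", "beh_kR", "beh_nR"))
  d
}

test_that("prevalence tabulation counts patterns per scope cell", {
  meta <- data.frame(site_id = sprintf("s%d", 1:8),
                     participant_id = rep(c("P01", "P02"), 4),
                     hemisphere = rep(c("L", "R"), each = 4),
                     roi = rep(c("HGPM", "MFG"), 4),
                     roi_group = rep(c("Auditory core", "Prefrontal"), 4),
                     x = 0, y = 0, z = 0)
  cls <- data.frame(site_id = meta$site_id,
                    pattern = c("stimulus", "behavior", "stimulus", "none",
                                "stimulus", "none", "intermediate", "none"))
  whole <- tabulate_prevalence(cls, meta, "whole")
  L <- whole[whole$hemisphere == "L", ]
  expect_equal(L$n_total, 4)
  expect_equal(L$n_stim, 2)
  expect_equal(L$prev_stim_pct, 50)
  grp <- tabulate_prevalence(cls, meta, "roi_group")
  hg_l <- grp[grp$scope == "Auditory core" & grp$hemisphere == "L", ]
  expect_equal(hg_l$n_total, 2)
  expect_equal(hg_l$n_stim, 2)
  expect_equal(hg_l$prev_stim_pct, 100)

  cls_bad <- rbind(cls, data.frame(site_id = "s99", pattern = "none"))
  expect_error(tabulate_prevalence(cls_bad, meta, "whole"), "metadata")
})

test_that("whole-brain asymmetries reproduce the reference odds ratios", {
  stim <- hemispheric_fisher(c(571, 3643), c(551, 3101))
  expect_equal(round(stim$odds_ratio, 3), 0.860)
  expect_equal(round(stim$p_raw, 4), 0.0217)
  beh <- hemispheric_fisher(c(143, 3643), c(55, 3101))
  expect_equal(round(beh$odds_ratio, 2), 2.26)
  expect_lt(beh$p_raw, 1e-4)
  int <- hemispheric_fisher(c(102, 3643), c(82, 3101))
  expect_equal(round(int$odds_ratio, 2), 1.06)
  expect_equal(round(int$p_raw, 3), 0.708)
  sm <- hemispheric_fisher(c(32, 332), c(49, 257))
  expect_equal(round(sm$odds_ratio, 4), 0.4528)
})

test_that("degenerate and balanced Fisher tables behave sensibly", {
  same <- hemispheric_fisher(c(10, 100), c(10, 100))
  expect_equal(same$odds_ratio, 1)
  expect_equal(same$p_raw, 1)
  zero <- hemispheric_fisher(c(0, 50), c(0, 40))
  expect_true(is.na(zero$odds_ratio))
  expect_equal(zero$p_raw, 1)
})

test_that("Fisher p equals hypergeometric enumeration on random small tables", {
  set.seed(8)
  for (i in 1:200) {
    tot <- sample(4:40, 1)
    a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
    c_ <- sample(0:(tot - a - b), 1); d <- tot - a - b - c_
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    got <- hemispheric_fisher(c(a, a + b), c(c_, c_ + d))$p_raw
    expect_equal(got, fisher_enum(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the hand step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(bh_fdr(p), bh_hand(p), tolerance = 1e-12)
  }
})

test_that("BH adjustment is monotone in sorted p and permutation-invariant", {
  set.seed(10)
  p <- runif(25)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  perm <- sample(25)
  expect_equal(bh_fdr(p[perm]), adj[perm])
})

test_that("group-level asymmetry FDR reproduces the reference adjusted p-values", {
  d <- roi_group_counts()
  prev <- do.call(rbind, lapply(rownames(d), function(g) {
    data.frame(scope = g, hemisphere = c("L", "R"),
               n_total = c(d[g, "stim_nL"], d[g, "stim_nR"]),
               n_stim = c(d[g, "stim_kL"], d[g, "stim_kR"]),
               n_intermediate = c(d[g, "int_kL"], d[g, "int_kR"]),
               n_behav = c(d[g, "beh_kL"], d[g, "beh_kR"]))
  }))
  asym <- asymmetry_table(prev, fdr_family = "all")
  expect_equal(nrow(asym), 24)
  ref <- rbind(
    c("Auditory core", 0.893, 1, 1),
    c("STP", 1, 0.771, 1),
    c("STG", 0.292, 0.253, 0.893),
    c("Ventral", 0.290, 0.893, 0.140),
    c("Dorsal", 0.0715, 0.893, 0.893),
    c("Limbic", 0.771, 0.912, 0.982),
    c("Prefrontal", 0.981, 0.292, 0.0133),
    c("Sensorimotor", 0.0133, 0.158, 0.548))
  for (i in 1:8) for (j in 1:3) {
    got <- asym$p_fdr[asym$scope == ref[i, 1] &
                        asym$pattern == c("stim", "intermediate", "behav")[j]]
    expect_equal(signif(got, 3), as.numeric(ref[i, j + 1]),
                 tolerance = 1e-3)
  }
  # the sensorimotor stimulus-related asymmetry survives FDR
  sm <- asym[asym$scope == "Sensorimotor" & asym$pattern == "stim", ]
  expect_lt(sm$p_fdr, 0.05)
  expect_equal(round(sm$odds_ratio, 4), 0.4528)
})

test_that("SB index follows its closed form and symmetries", {
  expect_equal(round(sb_index(6, 22), 3), 0.571)
  expect_equal(round(sb_index(111, 1), 3), -0.982)
  expect_equal(sb_index(7, 7), 0)
  expect_true(is.na(sb_index(0, 0)))
  set.seed(11)
  for (i in 1:50) {
    a <- sample(0:40, 1); b <- sample(0:40, 1)
    if (a + b == 0) next
    expect_equal(sb_index(a, b), -sb_index(b, a))
    expect_lte(abs(sb_index(a, b)), 1)
  }
})

test_that("SB eligibility needs 5 responsive sites across 2 participants", {
  pat5 <- c("stimulus", "stimulus", "behavior", "stimulus", "behavior")
  expect_true(sb_eligibility(pat5, c("P1", "P1", "P1", "P2", "P2")))
  expect_false(sb_eligibility(pat5, rep("P1", 5)))
  expect_false(sb_eligibility(pat5[1:4], c("P1", "P2", "P3", "P1")))
  # none/intermediate sites do not count toward the five
  expect_false(sb_eligibility(c(pat5[1:4], "intermediate", "none"),
                              c("P1", "P2", "P3", "P1", "P2", "P3")))
})

test_that("coordinate asymmetry test matches the pooled-variance oracle", {
  res <- coord_asymmetry_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$p, 0.021312, tolerance = 1e-4)
  expect_equal(res$df, 4)
  same <- coord_asymmetry_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(coord_asymmetry_test(1, c(2, 3)), "at least 2")
})
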