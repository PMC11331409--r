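test_that("filter cascade records the first failing reason in fixed order", {
  ok <- pileup_3v3(45, 5, 50, 0)
  lowcov <- pileup_3v3(3, 1, 50, 0)
  lowq <- pileup_3v3(45, 5, 50, 0, mean_baseq = 15)
  flagged <- pileup_3v3(45, 5, 50, 0, flags = "homopolymer")
  # low coverage takes precedence over the flag
  both <- pileup_3v3(3, 1, 50, 0, flags = "near_splice", mean_baseq = 10)
  ct <- make_pileup(c(
    stats::setNames(rep(list(c(0, 45, 0, 5)), 3), paste0("wt_", 1:3)),
    stats::setNames(rep(list(c(0, 50, 0, 0)), 3), paste0("ko_", 1:3))),
    ref_base = "C")
  pu <- rbind(ok, lowcov, lowq, flagged, both, ct)
  fl <- filter_sites(pu)
  expect_equal(fl$status,
               c("kept", "filtered:low_coverage", "filtered:low_quality",
                 "filtered:artifact_flag", "filtered:low_coverage",
                 "filtered:non_AG"))
  # exactly five reads everywhere passes the coverage filter
  five <- make_pileup(c(
    stats::setNames(rep(list(c(4, 0, 1, 0)), 3), paste0("wt_", 1:3)),
    stats::setNames(rep(list(c(5, 0, 0, 0)), 3), paste0("ko_", 1:3))))
  expect_equal(filter_sites(five)$status, "kept")
  # ref A but T-dominated mismatches is not an A-to-G site
  tdom <- make_pileup(c(
    stats::setNames(rep(list(c(40, 0, 1, 9)), 3), paste0("wt_", 1:3)),
    stats::setNames(rep(list(c(50, 0, 0, 0)), 3), paste0("ko_", 1:3))))
  expect_equal(filter_sites(tdom)$status, "filtered:non_AG")
  expect_error(filter_sites(transform(ok, ref_base = "N")), "ref_base")
})

test_that("bookkeeping conserves sites across statuses", {
  gm <- gen_gene_models(20, seed = 1)
  sc <- sim_config()
  spec <- plant_edit_sites(gm, n_null = 300, n_wt_only = 40, n_ct = 15,
                           seed = 2)
  pu <- gen_pileups(gm, sc, spec, seed = 3)
  calls <- call_differential_editing(pu$pileup, groups_3v3)
  s <- attr(calls, "summary")
  expect_equal(s$n_pass + s$n_fail + s$n_filtered, s$n_sites)
  expect_equal(sum(unlist(s$by_status)), nrow(pu$pileup))
  # planted C-to-T sites are never called
  ct_pos <- pu$truth$sites$pos[pu$truth$sites$group == "ct"]
  expect_true(all(calls$status[calls$pos %in% ct_pos] != "pass"))
})

test_that("the beta-binomial LRT behaves like a calibrated score", {
  # identical compositions in every replicate: nested models coincide
  s0 <- dm_score(rep(45, 6), rep(5, 6), rep(c("wt", "ko"), each = 3))
  expect_equal(as.numeric(s0), 0, tolerance = 1e-6)
  # a 20% vs 0% difference at coverage 50 clears the 2.00 threshold
  s1 <- dm_score(c(40, 40, 40, 50, 50, 50), c(10, 10, 10, 0, 0, 0),
                 rep(c("wt", "ko"), each = 3))
  expect_gt(as.numeric(s1), 2)
  # symmetric in group order and invariant to replicate relabelling
  s1b <- dm_score(c(50, 50, 50, 40, 40, 40), c(0, 0, 0, 10, 10, 10),
                  rep(c("ko", "wt"), each = 3))
  expect_equal(as.numeric(s1), as.numeric(s1b), tolerance = 1e-6)
  a <- c(38, 41, 44, 50, 48, 47); g <- c(12, 9, 6, 0, 2, 3)
  s2 <- dm_score(a, g, rep(c("wt", "ko"), each = 3))
  perm <- c(3, 1, 2, 6, 5, 4)
  s2b <- dm_score(a[perm], g[perm], rep(c("wt", "ko"), each = 3))
  expect_equal(as.numeric(s2), as.numeric(s2b), tolerance = 1e-8)
  # group frequencies are pooled counts
  expect_equal(unname(attr(s1, "p_hat")["wt"]), 30 / 150)
  # error conditions
  expect_error(dm_score(c(0, 0, 0, 50, 50, 50), c(0, 0, 0, 0, 0, 0),
                        rep(c("wt", "ko"), each = 3)), "zero total coverage")
  expect_error(dm_score(c(5, 5), c(1, 0), c("wt", "ko")), "two replicates")
})

test_that("score exceedances are rare under the null and common under signal", {
  gm <- gen_gene_models(20, seed = 5)
  sc <- sim_config(flag_rate = 0, lowq_rate = 0)
  spec <- plant_edit_sites(gm, n_null = 800, n_wt_only = 120, seed = 6)
  pu <- gen_pileups(gm, sc, spec, seed = 7)
  calls <- call_differential_editing(pu$pileup, groups_3v3)
  m <- merge(calls, pu$truth$sites[, c("pos", "group")], by = "pos")
  null_pass <- mean(m$status[m$group == "none"] == "pass")
  sig_pass <- mean(m$status[m$group == "wt_only"] == "pass")
  expect_lte(null_pass, 0.05)
  expect_gte(sig_pass, 0.9)
  # infinite threshold passes nothing
  none <- call_differential_editing(pu$pileup, groups_3v3, threshold = Inf)
  expect_equal(attr(none, "summary")$n_pass, 0)
})

test_that("wt-only selection is directional", {
  pu <- rbind(
    pileup_3v3(40, 10, 50, 0),    # wt-only: retained
    pileup_3v3(40, 10, 42, 8),    # edited in both: removed
    pileup_3v3(50, 0, 40, 10))    # ko-only: removed
  calls <- call_differential_editing(pu, groups_3v3, threshold = 0)
  calls$status <- "pass"  # isolate the frequency logic from the score
  kept <- wt_only_filter(calls)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$wt_freq, 0.2)
  expect_error(wt_only_filter(calls[, setdiff(names(calls), "ko_freq")]),
               "group frequency")
})

test_that("the Alu editing index is the coverage-weighted pooled frequency", {
  alu <- data.frame(start = c(90L, 190L), end = c(110L, 210L),
                    class = c("SINE", "SINE"))
  # two positions, coverages 100 and 300, frequencies 0.2 and 0
  pu <- rbind(
    make_pileup(list(s1 = c(80, 0, 20, 0)), pos = 100),
    make_pileup(list(s1 = c(300, 0, 0, 0)), pos = 200))
  expect_equal(compute_aei(pu, alu, samples = "s1"), 20 / 400,
               tolerance = 1e-12)
  # uniform 10% editing at equal coverage
  pu2 <- rbind(
    make_pileup(list(s1 = c(90, 0, 10, 0)), pos = 100),
    make_pileup(list(s1 = c(90, 0, 10, 0)), pos = 200))
  expect_equal(compute_aei(pu2, alu, samples = "s1"), 0.1, tolerance = 1e-12)
  # no editing at all
  pu3 <- make_pileup(list(s1 = c(100, 0, 0, 0)), pos = 100)
  expect_equal(compute_aei(pu3, alu, samples = "s1"), 0)
  # empty intersection errors
  expect_error(compute_aei(make_pileup(list(s1 = c(9, 0, 1, 0)), pos = 500),
                           alu, samples = "s1"), "overlap")
})
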