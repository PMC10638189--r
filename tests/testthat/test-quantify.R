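test_that("relative abundances normalize to 100% within each class", {
  q <- make_quants(list("GlcAGalNAc4S", 42),
                   list("dUAGalNAc4S", 30), list("dUAGalNAc6S", 70))
  nre <- relative_abundance(q, "NRE")
  expect_equal(unname(nre["GlcAGalNAc4S"]), 100)
  int <- relative_abundance(q, "internal")
  expect_equal(unname(int[c("dUAGalNAc4S", "dUAGalNAc6S")]), c(30, 70))
  expect_equal(sum(int), 100, tolerance = 1e-9)
  set.seed(3)
  q2 <- make_quants(list("GlcAGalNAc4S", runif(1, 1, 9)),
                    list("GalNAc4S", runif(1, 1, 9)),
                    list("UAGlcNS", runif(1, 1, 9)))
  expect_equal(sum(relative_abundance(q2, "NRE")), 100, tolerance = 1e-9)
  expect_length(relative_abundance(q2, "internal"), 0L)
  q_bad <- q; q_bad$intensity[1] <- -1
  expect_error(relative_abundance(q_bad, "NRE"), "negative")
})

test_that("unlabeled QC species are excluded from class denominators", {
  q <- make_quants(list("dUAGalNAc4S", 60), list("dUA2SGalNAc4S", 40),
                   list("dUA2SGalNAc4S(unlabeled)", 1000))
  int <- relative_abundance(q, "internal")
  expect_equal(unname(int["dUAGalNAc4S"]), 60)
  expect_false("dUA2SGalNAc4S(unlabeled)" %in% names(int))
})

test_that("NRE/dp2S1 ratios use the combined internal references and scale-invariance holds", {
  q <- make_quants(list("IdoAGalNAc4S", 10),
                   list("dUAGalNAc4S", 40), list("dUAGalNAc6S", 60))
  r <- nre_to_dp2s1_ratio(q)
  expect_equal(unname(r["IdoAGalNAc4S"]), 10)
  qk <- q; qk$intensity <- qk$intensity * 7.3
  expect_equal(nre_to_dp2s1_ratio(qk), r)
  # missing references -> undefined flag, not zero or infinity
  q0 <- make_quants(list("IdoAGalNAc4S", 10))
  r0 <- nre_to_dp2s1_ratio(q0)
  expect_true(all(is.na(r0)))
  expect_match(attr(r0, "reason"), "reference")
})

test_that("GalNAc6S/GalNAc4S ratio reproduces the reported arithmetic and undefined case", {
  expect_equal(galnac6s_4s_ratio(make_quants(list("GalNAc6S", 154),
                                             list("GalNAc4S", 100))), 1.54)
  expect_equal(galnac6s_4s_ratio(make_quants(list("GalNAc6S", 45),
                                             list("GalNAc4S", 100))), 0.45)
  und <- galnac6s_4s_ratio(make_quants(list("GalNAc6S", 45)))
  expect_true(is.na(und))
  expect_match(attr(und, "reason"), "GalNAc4S")
})

test_that("labeling yield follows the labeled fraction of the dp2S2 QC pair", {
  q <- make_quants(list("dUA2SGalNAc4S", 91), list("dUA2SGalNAc4S(unlabeled)", 9))
  expect_equal(labeling_yield(q), 91)
  expect_equal(labeling_yield(make_quants(list("dUA2SGalNAc4S", 50))), 100)
  fail <- labeling_yield(make_quants(list("dUA2SGalNAc4S(unlabeled)", 50)))
  expect_equal(as.numeric(fail), 0)
  expect_true(attr(fail, "qc_fail"))
  expect_true(is.na(labeling_yield(make_quants(list("GalNAc4S", 5)))))
})

test_that("profiles assemble per sample and report the NRE fraction", {
  q <- make_quants(list("GlcAGalNAc4S", 5), list("GalNAc4S", 5),
                   list("dUAGalNAc4S", 50), list("dUAGalNAc6S", 40))
  p <- nre_profile(q)
  expect_s3_class(p, "nre_profile")
  expect_equal(p$nre_fraction_total, 10)
  expect_equal(sum(p$nre_rel), 100, tolerance = 1e-9)
  expect_equal(unname(p$nre_over_dp2s1["GalNAc4S"]), 100 * 5 / 90)
  # statistics invariant under global intensity scaling
  qk <- q; qk$intensity <- qk$intensity * 1e3
  pk <- nre_profile(qk)
  expect_equal(pk$nre_rel, p$nre_rel)
  expect_equal(pk$nre_fraction_total, p$nre_fraction_total)
  expect_equal(pk$nre_over_dp2s1, p$nre_over_dp2s1)
})

test_that("replicate summaries give mean and sample SD, single replicate has no SD", {
  mk <- function(v) nre_profile(make_quants(list("GlcAGalNAc4S", v),
                                            list("dUAGalNAc4S", 100)))
  profs <- lapply(c(10, 11, 12), mk)
  s <- replicate_summary(profs)
  expect_equal(unname(s$nre_over_dp2s1["GlcAGalNAc4S"]), 11)
  expect_equal(unname(s$sd$nre_over_dp2s1["GlcAGalNAc4S"]), 1)
  expect_equal(s$n_replicates, 3L)
  single <- replicate_summary(profs[1])
  expect_null(single$sd)
  # a composition missing from one replicate counts as zero, with a warning
  p_miss <- nre_profile(make_quants(list("GalNAc4S", 8),
                                    list("dUAGalNAc4S", 100)))
  suppressWarnings(
    expect_warning(replicate_summary(list(profs[[1]], p_miss)), "missing"))
  s2 <- suppressWarnings(replicate_summary(list(profs[[1]], p_miss)))
  expect_equal(unname(s2$nre_over_dp2s1["GalNAc4S"]), 4)
})

test_that("labeling-yield estimation recovers the configured efficiency", {
  set.seed(77)
  pairs <- simulate_dp2s2_pairs(400, efficiency = 0.91)
  pooled <- 100 * sum(pairs$labeled) / sum(pairs$labeled + pairs$unlabeled)
  expect_equal(pooled, 91, tolerance = 0.02)
  # per-pair yields through the quantification path agree on average
  yields <- 100 * pairs$labeled / (pairs$labeled + pairs$unlabeled)
  expect_lt(abs(mean(yields) - 91), 1)
})
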