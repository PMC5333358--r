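# Independent Weir-Cockerham oracle, written from the variance-components
# definitions (mean squares within/among populations for haploid samples)
# before the vectorized implementation; shares no code with wc_fst().
wc_oracle <- function(a1, n1, a2, n2) {
  p <- c(a1 / n1, a2 / n2)
  n <- c(n1, n2)
  r <- 2
  pbar <- sum(n * p) / sum(n)
  msp <- sum(n * (p - pbar)^2) / (r - 1)
  msg <- sum(n * p * (1 - p)) / sum(n - 1)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  num <- msp - msg
  den <- msp + (nc - 1) * msg
  if (den == 0) return(NA_real_)
  num / den
}

test_that("wc_fst matches the variance-components oracle to 1e-12", {
  set.seed(101)
  for (i in 1:25) {
    n1 <- sample(10:100, 1); n2 <- sample(10:100, 1)
    a1 <- rbinom(1, n1, runif(1, 0.1, 0.9))
    a2 <- rbinom(1, n2, runif(1, 0.1, 0.9))
    if ((a1 + a2) %in% c(0, n1 + n2)) next  # monomorphic pooled site
    expect_equal(wc_fst(a1, n1, a2, n2), wc_oracle(a1, n1, a2, n2),
                 tolerance = 1e-12)
  }
})

test_that("wc_fst hits the analytic edge cases", {
  # fixed difference with equal sample sizes: theta = 1 exactly
  expect_identical(wc_fst(50, 50, 0, 50), 1)
  expect_identical(wc_fst(0, 30, 30, 30), 1)
  # identical counts: no among-population variance, estimator <= 0
  expect_lte(wc_fst(20, 50, 20, 50), 0)
  # monomorphic pooled site is undefined
  expect_true(is.na(wc_fst(0, 40, 0, 60)))
  expect_true(is.na(wc_fst(40, 40, 60, 60)))
  # symmetric in the two sectors; invariant to swapping ref/alt labels
  set.seed(7)
  for (i in 1:10) {
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    a1 <- sample(0:n1, 1); a2 <- sample(0:n2, 1)
    expect_equal(wc_fst(a1, n1, a2, n2), wc_fst(a2, n2, a1, n1))
    expect_equal(wc_fst(a1, n1, a2, n2), wc_fst(n1 - a1, n1, n2 - a2, n2))
  }
})

test_that("theta grows with allele-frequency divergence at fixed pooled frequency", {
  n <- 100
  deltas <- seq(0.05, 0.45, by = 0.05)
  th <- vapply(deltas, function(d)
    wc_fst((0.5 + d) * n, n, (0.5 - d) * n, n), 0)
  expect_true(all(diff(th) > 0))
})

test_that("purity recalibration follows f_adj = min(f/purity, 1) in expectation", {
  v <- data.frame(chrom = "c", pos = 1:3, ref = "A", alt = "T")
  depth <- 200L
  mt <- mutation_table(v,
                       ref_count = cbind(S1 = c(120L, 140L, 40L)),
                       alt_count = cbind(S1 = c(80L, 60L, 160L)))
  # purity 1, target depth = observed depth: frequencies preserved in
  # expectation (binomial mean over replicates)
  reps <- vapply(1:300, function(i)
    purity_recalibrate(mt, c(S1 = 1), target_depth = depth,
                       seed = i)$alt_count[, 1], integer(3))
  f_obs <- c(0.4, 0.3, 0.8)
  expect_equal(unname(rowMeans(reps)) / depth, f_obs, tolerance = 0.02)

  # purity 0.6: f_adj = f/0.6; purity 0.5 caps 0.8 -> 1
  reps6 <- vapply(1:300, function(i)
    purity_recalibrate(mt, c(S1 = 0.6), target_depth = depth,
                       seed = i)$alt_count[, 1], integer(3))
  expect_equal(unname(rowMeans(reps6)[2]) / depth, 0.5, tolerance = 0.02)
  reps5 <- purity_recalibrate(mt, c(S1 = 0.5), target_depth = depth, seed = 1)
  expect_identical(reps5$alt_count[3, 1], depth)  # capped at 1 -> all alt

  expect_error(purity_recalibrate(mt, c(S1 = 0)), "purities")
  # default target depth is the minimum positive observed depth
  rc <- purity_recalibrate(mt, c(S1 = 1), seed = 2)
  expect_true(all(total_depth(rc) == 200L))
})

test_that("pairwise sector distances are Euclidean", {
  meta <- sector_metadata(c("A", "B", "C"),
                          rbind(c(0, 0, 0), c(10, 0, 0), c(3, 4, 0)),
                          c(0.7, 0.7, 0.7))
  d <- pairwise_distances(meta)
  expect_equal(d["A", "B"], 10)
  expect_equal(d["A", "C"], 5)  # 3-4-5 triangle
  expect_equal(d["A", "A"], 0)
})

test_that("fst_records pools per-site pairs and excludes undefined sites", {
  mt <- random_table(40, 4, seed = 21)
  meta <- sector_metadata(mt$sectors,
                          cbind((0:3) * 10, 0, 0), rep(0.8, 4))
  rec <- fst_records(mt, meta)
  expect_true(all(rec$fst <= 1))
  expect_true(all(rec$distance_mm %in% c(10, 20, 30)))
  # spot-check one record against wc_fst directly
  r1 <- rec[1L, ]
  i <- match(r1$mutation_id, mt$variants$mutation_id)
  dth <- total_depth(mt)
  expect_equal(r1$fst, wc_fst(mt$alt_count[i, r1$sector1], dth[i, r1$sector1],
                              mt$alt_count[i, r1$sector2], dth[i, r1$sector2]))
  # monomorphic sites are excluded, with a count
  mono <- mutation_table(data.frame(chrom = "c", pos = 1:2, ref = "A", alt = "T"),
                         ref_count = cbind(S1 = c(10L, 5L), S2 = c(10L, 6L)),
                         alt_count = cbind(S1 = c(0L, 5L), S2 = c(0L, 4L)))
  meta2 <- sector_metadata(c("S1", "S2"), rbind(c(0, 0, 0), c(5, 0, 0)),
                           c(1, 1))
  rec2 <- fst_records(mono, meta2)
  expect_equal(nrow(rec2), 1L)
  expect_equal(attr(rec2, "n_excluded"), 1L)
})

test_that("IBD regression recovers a known generative slope and handles edge cases", {
  set.seed(33)
  n <- 500
  dist_mm <- sample(seq(5, 50, by = 5), n, replace = TRUE)
  fst <- 0.002 * dist_mm + rnorm(n, 0, 0.01)
  rec <- data.frame(mutation_id = paste0("m", 1:n), sector1 = "A",
                    sector2 = "B", fst = fst, distance_mm = dist_mm)
  fit <- ibd_regression(rec)
  se <- summary(fit$lm)$coefficients["distance_mm", "Std. Error"]
  expect_lt(abs(fit$slope - 0.002), 3 * se)
  expect_lt(fit$p_value, 1e-6)
  expect_equal(fit$n_points, n)
  expect_equal(unname(coef(fit)["slope"]), fit$slope)

  # constant response: slope exactly 0
  rec0 <- rec; rec0$fst <- 0.3
  expect_equal(suppressWarnings(ibd_regression(rec0))$slope, 0)
  # all distances equal: unidentifiable
  rec1 <- rec; rec1$distance_mm <- 10
  expect_error(ibd_regression(rec1), "distances")
  # per-pair mean pooling averages within pairs first
  fit2 <- ibd_regression(rec, pool = "pair_mean")
  expect_equal(fit2$n_points, length(unique(dist_mm)))
})

test_that("distance boxplots follow the stated whisker formulas", {
  rec <- data.frame(mutation_id = "m", sector1 = "A", sector2 = "B",
                    fst = c(1, 2, 3, 4, 100), distance_mm = 10)
  bx <- distance_boxplots(rec)
  expect_equal(bx$Q1, 2)
  expect_equal(bx$Q3, 4)
  expect_equal(bx$upper_whisker, min(100, 4 + 1.5 * 2))  # = 7
  expect_equal(bx$lower_whisker, max(1, 2 - 1.5 * 2))    # = 1
  expect_equal(bx$outliers[[1]], 100)
  expect_equal(bx$median, 3)

  # single value: every summary field equals it
  one <- data.frame(fst = 0.42, distance_mm = 5)
  b1 <- distance_boxplots(one)
  expect_true(all(unlist(b1[c("lower_whisker", "Q1", "median", "Q3",
                              "upper_whisker")]) == 0.42))
  expect_length(b1$outliers[[1]], 0)

  # ordering invariant and grouping by distance
  rec2 <- rbind(rec, data.frame(mutation_id = "m", sector1 = "A",
                                sector2 = "C", fst = c(0.1, 0.2),
                                distance_mm = 20))
  bx2 <- distance_boxplots(rec2)
  expect_equal(bx2$distance_mm, c(10, 20))
  expect_true(all(bx2$lower_whisker <= bx2$Q1 & bx2$Q1 <= bx2$median &
                  bx2$median <= bx2$Q3 & bx2$Q3 <= bx2$upper_whisker))
})

test_that("two-clade synthetic tumours show higher cross-clade than within-clade Fst", {
  tum <- generate_tumour(6, n_truncal = 40, n_clade = 40, n_private = 10,
                         mean_depth = 120, seed = 5)
  tab <- purity_recalibrate(tum$table,
                            setNames(tum$truth$purity, tum$meta$sector_id),
                            seed = 5)
  rec <- fst_records(tab, tum$meta)
  cl <- tum$truth$clade_assignment
  cross <- cl[rec$sector1] != cl[rec$sector2]
  expect_gt(median(rec$fst[cross]), median(rec$fst[!cross]))
})
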