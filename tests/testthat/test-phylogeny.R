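test_that("presence matrix applies the alt-read threshold elementwise", {
  mt <- tiny_table()
  pm <- suppressWarnings(presence_matrix(mt, min_alt = 3L))
  # m2 is detected nowhere and must be dropped
  expect_identical(colnames(pm), c("m1", "m3"))
  expect_equal(unname(unclass(pm)), rbind(c(1L, 1L), c(1L, 1L)))
  expect_warning(presence_matrix(mt, min_alt = 3L), "dropped")

  # alt [5, 30] at min_alt 10 -> [0, 1]; min_alt 1 calls any positive alt
  pm10 <- suppressWarnings(presence_matrix(mt, min_alt = 10L))
  expect_equal(unname(unclass(pm10)[, "m1"]), c(0L, 1L))
  expect_equal(unname(unclass(suppressWarnings(presence_matrix(mt, 1L)))),
               rbind(c(1L, 1L), c(1L, 1L)))

  # random table: matches direct per-entry comparison
  rt <- random_table(20, 4, seed = 11)
  pm2 <- presence_matrix(rt, min_alt = 3L)
  direct <- t(rt$alt_count >= 3L) * 1L
  direct <- direct[, colSums(direct) > 0, drop = FALSE]
  expect_equal(unname(unclass(pm2)), unname(direct))
})

test_that("Hamming distances equal brute-force pairwise XOR sums", {
  pm <- two_clade_pm()
  d <- hamming_distances(pm)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_equal(d["S1", "S2"], 0)      # identical clade profiles
  expect_equal(d["S1", "S3"], 6)      # 3 + 3 differing clade mutations

  # rows [1,1,0] vs [1,0,1] differ in 2 coordinates
  m <- rbind(A = c(1L, 1L, 0L), B = c(1L, 0L, 1L), C = c(1L, 1L, 1L))
  expect_equal(hamming_distances(m)["A", "B"], 2)

  set.seed(5)
  m6 <- matrix(rbinom(6 * 50, 1, 0.4), 6,
               dimnames = list(paste0("S", 1:6), NULL))
  m6[, colSums(m6) == 0] <- 1L  # keep presence_matrix from dropping columns
  d6 <- hamming_distances(presence_matrix(m6))
  brute <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) brute[i, j] <- sum(m6[i, ] != m6[j, ])
  expect_equal(unname(d6), brute)
})

test_that("neighbour joining solves the 3-taxon system and is consistent on additive input", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  pend <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                   tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(pend[c("A", "B", "C")], c(A = 1, B = 2, C = 3))

  # additive distances from random trees are recovered exactly
  set.seed(9)
  for (n in c(5, 8, 12)) {
    gen <- ape::rtree(n)
    dm2 <- cophenetic(gen)
    rec <- nj_tree(dm2)
    expect_identical(tree_splits(rec), tree_splits(gen))
    expect_equal(cophenetic(rec)[rownames(dm2), colnames(dm2)], dm2,
                 tolerance = 1e-8)
  }

  # equidistant taxa: internal branches collapse to length 0
  star <- matrix(2, 5, 5, dimnames = list(paste0("S", 1:5), paste0("S", 1:5)))
  diag(star) <- 0
  ts <- nj_tree(star)
  internal <- ts$edge.length[ts$edge[, 2] > length(ts$tip.label)]
  expect_true(all(abs(internal) < 1e-12))

  expect_error(nj_tree(matrix(0, 1, 1)), "2 taxa")
  expect_warning(t2 <- nj_tree(matrix(c(0, 4, 4, 0), 2,
    dimnames = list(c("A", "B"), c("A", "B")))), "2 taxa")
  expect_equal(sum(t2$edge.length), 4)
})

test_that("negative NJ branch lengths are clamped and recorded", {
  # non-metric distances that force a negative branch estimate
  dm <- matrix(c(0, 10, 1, 1,
                 10, 0, 1, 1,
                 1, 1, 0, 1,
                 1, 1, 1, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(dm)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "clamped"), 1L)
})

test_that("exhaustive bootstrap supports match full resample enumeration", {
  # 4 sectors x 3 mutations: all 3^3 = 27 column resamples enumerated by an
  # independent oracle (rebuilding hamming+NJ per resample from scratch)
  m <- rbind(S1 = c(1L, 1L, 0L), S2 = c(1L, 1L, 0L),
             S3 = c(0L, 0L, 1L), S4 = c(0L, 1L, 1L))
  colnames(m) <- paste0("m", 1:3)
  pm <- presence_matrix(m)
  boot <- bootstrap_consensus(pm, method = "exhaustive")
  expect_identical(boot$method, "exhaustive")
  expect_equal(boot$n_replicates, 27L)

  oracle <- new.env()
  idx <- expand.grid(1:3, 1:3, 1:3)
  for (r in seq_len(nrow(idx))) {
    sub <- m[, as.integer(idx[r, ]), drop = FALSE]
    d <- matrix(0, 4, 4, dimnames = list(rownames(m), rownames(m)))
    for (i in 1:4) for (j in 1:4) d[i, j] <- sum(sub[i, ] != sub[j, ])
    tr <- if (all(d == 0)) NULL else ape::nj(as.dist(d))
    if (is.null(tr)) next
    for (key in tree_splits(tr))
      assign(key, (if (exists(key, oracle)) get(key, oracle) else 0) + 1,
             oracle)
  }
  for (key in ls(oracle)) {
    expect_equal(split_support(boot, strsplit(key, "|", fixed = TRUE)[[1L]]),
                 get(key, oracle) / 27, tolerance = 1e-12)
  }
  # splits never produced by the oracle have support 0
  expect_equal(split_support(boot, c("S1", "S3")),
               if (exists("S1|S3", oracle)) get("S1|S3", oracle) / 27 else 0)
})

test_that("co-segregating clade signal yields full support; one replicate gives 0/1", {
  pm <- two_clade_pm(n_per_clade = 2, n_clade_mut = 3, n_truncal = 2)
  boot <- bootstrap_consensus(pm, n_replicates = 50, seed = 3,
                              method = "resample")
  expect_equal(split_support(boot, c("S1", "S2")), 1.0)
  b1 <- bootstrap_consensus(pm, n_replicates = 1, seed = 3,
                            method = "resample")
  expect_true(all(b1$supports$support %in% c(0, 1)))
})

test_that("bootstrap supports are valid, order-invariant, and consensus splits compatible", {
  pm <- two_clade_pm(n_per_clade = 2, n_clade_mut = 2, n_truncal = 1)
  boot <- bootstrap_consensus(pm, method = "exhaustive")  # all 5^5 resamples
  expect_true(all(boot$supports$support >= 0 & boot$supports$support <= 1))

  set.seed(17)
  perm <- sample(ncol(pm))
  pm2 <- presence_matrix(unclass(pm)[, perm])
  boot2 <- bootstrap_consensus(pm2, method = "exhaustive")
  expect_equal(boot$supports[order(boot$supports$split), ],
               boot2$supports[order(boot2$supports$split), ],
               ignore_attr = TRUE)

  # consensus splits are pairwise compatible (nested or disjoint)
  splits <- strsplit(tree_splits(boot$consensus), "|", fixed = TRUE)
  tips <- boot$consensus$tip.label
  for (a in splits) for (b in splits) {
    sides_a <- list(a, setdiff(tips, a))
    sides_b <- list(b, setdiff(tips, b))
    ok <- any(vapply(sides_a, function(x) any(vapply(sides_b, function(y)
      length(intersect(x, y)) == 0, TRUE)), TRUE))
    expect_true(ok)
  }
})
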