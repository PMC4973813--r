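sim_f2_pair <- function(r, n, seed) {
  set.seed(seed)
  # draw gametes explicitly: allele pairs with recombination r
  gam <- function() {
    a <- rbinom(n, 1, 0.5)
    b <- ifelse(runif(n) < r, 1 - a, a)
    cbind(a, b)
  }
  m <- gam() + gam()   # columns: marker1, marker2 dosages 0/1/2
  lv <- c("AA", "AB", "BB")
  list(a = lv[m[, 1] + 1], b = lv[m[, 2] + 1])
}

test_that("estimate_rf: complete linkage and independence", {
  p <- sim_f2_pair(0, 50, seed = 51)
  fit <- estimate_rf(p$a, p$b, "f2_codominant")
  expect_equal(fit$r_hat, 0, tolerance = 1e-6)
  expect_gt(fit$lod, 5)

  q <- sim_f2_pair(0.5, 200, seed = 52)
  fit2 <- estimate_rf(q$a, q$b, "f2_codominant")
  expect_gt(fit2$r_hat, 0.4)
  expect_lt(fit2$lod, 1)

  expect_error(estimate_rf(p$a[1:5], p$b[1:5], "f2_codominant"),
               "fewer than 10")
})

test_that("EM r-hat matches grid-search ML within 1e-3 on random tables", {
  set.seed(53)
  for (rep in 1:20) {
    r_true <- runif(1, 0.02, 0.45)
    p <- sim_f2_pair(r_true, 120, seed = 530 + rep)
    fit <- estimate_rf(p$a, p$b, "f2_codominant")
    counts <- table(factor(p$a, c("AA", "AB", "BB")),
                    factor(p$b, c("AA", "AB", "BB")))
    expect_lt(abs(fit$r_hat - oracle_grid_rf(unclass(counts))), 1e-3)
  }
})

test_that("r-hat is symmetric and LOD at r = 0.5 is zero", {
  p <- sim_f2_pair(0.2, 100, seed = 54)
  f1 <- estimate_rf(p$a, p$b, "f2_codominant")
  f2 <- estimate_rf(p$b, p$a, "f2_codominant")
  expect_equal(f1$r_hat, f2$r_hat)
  expect_equal(f1$lod, f2$lod)
})

test_that("inbred design applies the RIL selfing correction", {
  # R = 2r/(1+2r): with r = 0.1, R = 1/6
  set.seed(55)
  n <- 3000
  R <- 2 * 0.1 / (1 + 2 * 0.1)
  a <- sample(c("AA", "BB"), n, TRUE)
  b <- ifelse(runif(n) < R, ifelse(a == "AA", "BB", "AA"), a)
  fit <- estimate_rf(a, b, "inbred")
  expect_lt(abs(fit$r_hat - 0.1), 0.02)
  expect_gt(fit$lod, 10)
})

test_that("dominant-trait EM recovers linkage in both phases", {
  set.seed(56)
  for (r_true in c(0.05, 0.2)) {
    p <- sim_f2_pair(r_true, 400, seed = round(1000 * r_true))
    trait <- ifelse(p$a %in% c("AB", "BB"), "A_", "aa")   # repulsion-ish
    fit <- estimate_rf(trait, p$b, "f2_dominant_pair")
    expect_lt(abs(fit$r_hat - r_true), 0.08)
    trait2 <- ifelse(p$a %in% c("AA", "AB"), "A_", "aa")  # coupling
    fit2 <- estimate_rf(trait2, p$b, "f2_dominant_pair")
    expect_lt(abs(fit2$r_hat - r_true), 0.08)
  }
})

test_that("group_markers: thresholds, boundaries, singletons", {
  lk <- data.frame(marker_a = c("a", "a", "c"),
                   marker_b = c("b", "c", "d"),
                   r_hat = c(0.1, 0.5, 0.05),
                   lod = c(8, 0.1, 5.0),
                   n_informative = 100, stringsAsFactors = FALSE)
  g <- group_markers(lk, c("a", "b", "c", "d", "e"))
  # lod exactly 5 is included (>= semantics); e is a singleton
  expect_equal(g[[1]], c("a", "b"))
  expect_equal(g[[2]], c("c", "d"))
  expect_true(any(vapply(g, identical, TRUE, "e")))

  none <- group_markers(lk[0, ], c("x", "y"))
  expect_equal(length(none), 2L)
})

test_that("two simulated chromosomes separate into two groups", {
  pop <- simulate_population(toy_map(2, 6, 10), "f2", n = 150,
                             error_rate = 0, missing_rate = 0, seed = 57)
  lk <- pairwise_linkage(pop$gm, "f2")
  g <- group_markers(lk, colnames(pop$gm))
  expect_equal(length(g), 2L)
  expect_equal(sort(g[[1]]), sprintf("G1M%02d", 1:6))
  expect_equal(sort(g[[2]]), sprintf("G2M%02d", 1:6))
})

test_that("ordering achieves the brute-force SARF minimum for <= 6 loci", {
  set.seed(58)
  for (rep in 1:8) {
    n <- sample(4:6, 1)
    mk <- paste0("m", 1:n)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(sum(upper.tri(d)), 0.01, 0.45)
    d <- d + t(d)
    idx <- which(upper.tri(d), arr.ind = TRUE)
    lk <- data.frame(marker_a = mk[idx[, 1]], marker_b = mk[idx[, 2]],
                     r_hat = d[idx], lod = 10, n_informative = 100,
                     stringsAsFactors = FALSE)
    ord <- order_markers(mk, lk)
    expect_equal(sum(ord$adjacent_r),
                 oracle_sarf_min(d), tolerance = 1e-12,
                 info = sprintf("replicate %d", rep))
  }
})

test_that("true order is recovered from clean simulated data", {
  tm <- toy_map(1, 8, 8)
  pop <- simulate_population(tm, "f2", n = 200, error_rate = 0,
                             missing_rate = 0, seed = 59)
  lk <- pairwise_linkage(pop$gm, "f2")
  ord <- order_markers(colnames(pop$gm), lk)
  est <- vapply(ord$bins, `[`, "", 1L)
  tau <- abs(kendall_tau_orders(tm$marker, est))
  expect_equal(tau, 1)
})

test_that("map functions match closed forms and are ordered", {
  expect_equal(kosambi(0), 0)
  expect_equal(haldane(0), 0)
  expect_equal(kosambi(0.2), 21.18, tolerance = 1e-3)
  expect_equal(haldane(0.2), 25.54, tolerance = 1e-3)
  r <- seq(0.01, 0.49, by = 0.01)
  expect_true(all(diff(kosambi(r)) > 0))
  expect_true(all(diff(haldane(r)) > 0))
  # agreement to first order at small r
  expect_lt(abs(kosambi(0.001) - haldane(0.001)) / kosambi(0.001), 0.01)
  expect_equal(haldane_inv(haldane(0.3)), 0.3)
})

test_that("space_markers accumulates positions from adjacent fractions", {
  ord <- list(bins = list("a", "b", "c"), adjacent_r = c(0, 0.2))
  sp <- space_markers(ord, "kosambi")
  expect_equal(sp$position_cM, c(0, 0, kosambi(0.2)))
  sph <- space_markers(ord, "haldane")
  expect_equal(sph$position_cM[3], haldane(0.2))
  # r at the 0.5 ceiling gets the configured ceiling distance
  ord2 <- list(bins = list("a", "b"), adjacent_r = 0.5)
  expect_equal(space_markers(ord2, "kosambi",
                             ceiling_cm = 40)$position_cM[2], 40)
})

test_that("build_map reports unplaced singletons and ordered groups", {
  tm <- toy_map(2, 5, 10)
  pop <- simulate_population(tm, "f2", n = 150, error_rate = 0.01,
                             missing_rate = 0.03, seed = 60)
  map <- build_map(pop$gm, "f2")
  expect_s3_class(map, "genetic_map")
  expect_true(all(map$table$position_cM >= 0))
  for (g in unique(map$table$group)) {
    pos <- map$table$position_cM[map$table$group == g]
    expect_true(!is.unsorted(pos))
  }
  expect_setequal(c(map$table$marker, map$unplaced), colnames(pop$gm))
})

test_that("parameter recovery: order tau >= 0.95 with error and missing data", {
  taus <- vapply(1:5, function(s) {
    tm <- toy_map(1, 10, 5)
    pop <- simulate_population(tm, "f2", n = 150, error_rate = 0.01,
                               missing_rate = 0.05, seed = 600 + s)
    map <- build_map(pop$gm, "f2")
    grp <- map$table[map$table$group == "G1", ]
    est <- grp$marker[order(grp$position_cM)]
    abs(kendall_tau_orders(tm$marker, est))
  }, 0)
  expect_gte(median(taus), 0.95)
})

test_that("a trait locus is placed between its true flanking markers", {
  tm <- toy_map(1, 9, 10)
  pop <- simulate_population(tm, "f2", n = 200, error_rate = 0,
                             missing_rate = 0, seed = 61)
  map <- build_map(pop$gm, "f2")
  # trait driven by marker 5's true genotype, dominant coding
  g5 <- unclass(pop$true_genotypes)[, "G1M05"]
  trait <- ifelse(g5 %in% c("AA", "AB"), "A_", "aa")
  res <- map_trait_locus(trait, pop$gm, map)
  expect_equal(res$interval_cM, 0)
  expect_equal(res$flank_left, "G1M05")
  expect_gt(res$segregation$p_value, 0.05)

  # perturbed trait: no longer identical to any marker, still brackets M05
  set.seed(62)
  flip <- runif(length(trait)) < 0.05
  trait2 <- ifelse(flip, ifelse(trait == "A_", "aa", "A_"), trait)
  res2 <- map_trait_locus(trait2, pop$gm, map)
  pos5 <- map$table$position_cM[map$table$marker == "G1M05"]
  expect_true(!is.na(res2$flank_left) && !is.na(res2$flank_right))
  lo <- map$table$position_cM[map$table$marker == res2$flank_left]
  hi <- map$table$position_cM[map$table$marker == res2$flank_right]
  expect_true(lo <= pos5 && hi >= pos5)

  expect_error(map_trait_locus(rep("A_", 200), pop$gm, map), "monomorphic")
})
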