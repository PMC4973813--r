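test_that("classify_quality separates clean, noisy and merged assays", {
  set.seed(41)
  tight <- data.frame(
    x = c(rnorm(20, 0.9, 0.01), rnorm(20, 0.5, 0.01), rnorm(20, 0.1, 0.01)),
    y = c(rnorm(20, 0.1, 0.01), rnorm(20, 0.5, 0.01), rnorm(20, 0.9, 0.01)),
    call = rep(c("AA", "AB", "BB"), each = 20))
  expect_equal(classify_quality(tight, "m1")$quality_class, "I")

  merged <- data.frame(x = rnorm(60, 0.5, 0.2), y = rnorm(60, 0.5, 0.2),
                       call = rep(c("AA", "AB", "BB"), each = 20))
  expect_equal(classify_quality(merged, "m2")$quality_class, "IV")

  mono <- data.frame(x = rnorm(10, 0.9, 0.01), y = rnorm(10, 0.1, 0.01),
                     call = rep("AA", 10))
  expect_equal(classify_quality(mono, "m3")$quality_class, "IV")

  expect_error(classify_quality(tight[1:5, ]), "at least 6")
})

test_that("archetype II fluorescence classifies as class II in >=90% of draws", {
  set.seed(42)
  calls <- sample(c("AA", "AB", "BB"), 60, TRUE, prob = c(.25, .5, .25))
  cls <- vapply(1:100, function(s) {
    classify_quality(simulate_fluorescence(calls, "II", seed = s),
                     "m")$quality_class
  }, "")
  expect_gte(mean(cls == "II"), 0.9)
})

test_that("iterative no-call filter removes the worst offender until clean", {
  gm <- random_gm(20, 20, nc_rate = 0, seed = 2)
  res <- iterative_no_call_filter(gm)
  expect_equal(dim(res$matrix), dim(gm))
  expect_equal(nrow(res$removed), 0L)

  # one line pushed to 10% NC (markers only reach 5%)
  calls <- unclass(gm)
  calls["L03", 1:2] <- "NC"
  res2 <- iterative_no_call_filter(genotype_matrix(calls))
  expect_equal(res2$removed$what, "line")
  expect_equal(res2$removed$id, "L03")
  expect_false("L03" %in% rownames(res2$matrix))

  expect_error(iterative_no_call_filter(
    genotype_matrix(matrix("NC", 2, 2,
                           dimnames = list(c("a", "b"), c("x", "y"))))),
    "exhausted")
})

test_that("no-call filter is idempotent and leaves no offender", {
  gm <- random_gm(20, 50, nc_rate = 0.06, seed = 3)
  res <- iterative_no_call_filter(gm)
  nc <- unclass(res$matrix) == "NC"
  expect_true(all(rowMeans(nc) <= 0.06))
  expect_true(all(colMeans(nc) <= 0.06))
  again <- iterative_no_call_filter(res$matrix)
  expect_equal(unclass(again$matrix), unclass(res$matrix))
  expect_equal(nrow(again$removed), 0L)
})

test_that("allele_stats matches closed forms", {
  calls <- matrix(c("AA", "AB", "BB", "AB",   # p = 0.5
                    "AA", "AA", "AA", "AA",   # monomorphic
                    "AA", "AB", "BB", "NC"),  # NC excluded, p = 0.5
                  nrow = 4,
                  dimnames = list(paste0("l", 1:4), c("m1", "m2", "m3")))
  gm <- genotype_matrix(calls)
  s1 <- allele_stats(gm, "m1")
  expect_equal(s1$p, 0.5)
  expect_equal(s1$gene_diversity, 0.5)
  expect_equal(s1$pic, 0.375)

  s2 <- allele_stats(gm, "m2")
  expect_equal(s2$gene_diversity, 0)
  expect_equal(s2$pic, 0)

  # p = 0.25 example: 2pq = 0.375
  calls4 <- matrix(c("BB", "BB", "AB", "BB"), nrow = 4,
                   dimnames = list(paste0("l", 1:4), "m"))
  expect_equal(allele_stats(genotype_matrix(calls4), "m")$gene_diversity,
               2 * 0.125 * 0.875)

  expect_error(allele_stats(genotype_matrix(
    matrix("NC", 2, 1, dimnames = list(c("a", "b"), "m"))), "m"), "no-call")
})

test_that("gene diversity is symmetric in p and maximal at 0.5, pic below it", {
  gd <- function(p) 2 * p * (1 - p)
  for (seed in 1:5) {
    gm <- random_gm(30, 10, nc_rate = 0.02, p = runif(1, 0.1, 0.9),
                    seed = seed)
    st <- allele_stats(gm, "M001")
    expect_equal(st$gene_diversity, gd(st$q))
    expect_lte(st$gene_diversity, 0.5)
    expect_lte(st$pic, st$gene_diversity)
  }
})

test_that("private-allele detection keys on the discovery lines", {
  calls <- matrix("AA", nrow = 4, ncol = 1,
                  dimnames = list(c("disc1", "disc2", "x", "y"), "m"))
  calls["disc2", 1] <- "BB"
  gm <- genotype_matrix(calls)
  expect_equal(allele_stats(gm, "m", c("disc1", "disc2"))$private_to,
               "disc2")
  calls["x", 1] <- "AB"
  expect_true(is.na(allele_stats(genotype_matrix(calls), "m",
                                 c("disc1", "disc2"))$private_to))
})

test_that("line heterozygosity and homozygosity are complementary", {
  calls <- matrix("AA", nrow = 2, ncol = 100,
                  dimnames = list(c("a", "b"), sprintf("m%03d", 1:100)))
  calls["b", 1] <- "AB"
  gm <- genotype_matrix(calls)
  lh <- line_heterozygosity(gm)
  expect_equal(lh$pct_het, c(0, 1))
  gm2 <- random_gm(15, 60, nc_rate = 0.1, seed = 5)
  lh2 <- line_heterozygosity(gm2)
  expect_equal(lh2$pct_het + lh2$pct_hom, rep(100, 15))
})

test_that("concordance audit counts matches and excludes discovery no-calls", {
  calls <- matrix(c("AA", "BB",
                    "AA", "AA",
                    "NC", "BB"), nrow = 2,
                  dimnames = list(c("d1", "d2"), c("m1", "m2", "m3")))
  gm <- genotype_matrix(calls)
  pred <- data.frame(marker = c("m1", "m2", "m3"),
                     line_a_call = c("AA", "AA", "AA"),
                     line_b_call = c("BB", "BB", "BB"),
                     stringsAsFactors = FALSE)
  res <- concordance_audit(gm, pred, c("d1", "d2"))
  expect_equal(res$excluded, "m3")
  expect_equal(res$per_marker$match, c(TRUE, FALSE))
  expect_equal(res$fraction, 0.5)
})

test_that("distortion filter applies design-specific ratio bands", {
  f2_ok <- distortion_filter(rep(c("AA", "AB", "BB"), c(30, 60, 30)), "f2")
  expect_equal(f2_ok$ratio, 1)
  expect_equal(f2_ok$verdict, "keep")

  f2_skew <- distortion_filter(rep(c("AA", "AB", "BB"), c(35, 30, 35)), "f2")
  expect_equal(f2_skew$ratio, 70 / 30, tolerance = 1e-12)
  expect_equal(f2_skew$reason, "skew")

  # inbred: 9% heterozygotes -> ratio ~0.099, inside (0.045, 0.25)
  inb <- distortion_filter(rep(c("AA", "AB", "BB"), c(46, 9, 45)), "inbred")
  expect_equal(inb$ratio, 9 / 91, tolerance = 1e-12)
  expect_equal(inb$verdict, "keep")

  miss <- distortion_filter(rep(c("AA", "AB"), c(50, 50)), "f2")
  expect_equal(miss$reason, "missing_parental_allele")

  nohet <- distortion_filter(rep(c("AA", "BB"), c(50, 50)), "f2")
  expect_equal(nohet$ratio, Inf)
  expect_equal(nohet$reason, "skew")
})

test_that("UPGMA: duplicate lines give a zero-length cherry", {
  calls <- matrix(c("AA", "AA", "BB",
                    "AB", "AB", "AA",
                    "BB", "BB", "AB",
                    "AA", "AA", "BB"), nrow = 3,
                  dimnames = list(c("dupA", "dupB", "other"),
                                  paste0("m", 1:4)))
  res <- distance_and_upgma(genotype_matrix(calls))
  expect_equal(res$distance["dupA", "dupB"], 0)
  expect_match(res$newick, "\\(dupA:0,dupB:0\\)")
})

test_that("UPGMA matches a hand-computed 3-taxon case and is ultrametric", {
  d <- matrix(c(0, 0.1, 0.4,
                0.1, 0, 0.4,
                0.4, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nw <- fabmap:::upgma_newick(d)
  expect_equal(nw, "((A:0.05,B:0.05):0.15,C:0.2);")

  skip_if_not_installed("ape")
  gm <- random_gm(12, 80, nc_rate = 0.05, seed = 9)
  res <- distance_and_upgma(gm)
  tr <- ape::read.tree(text = res$newick)
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_lt(diff(range(depths)), 1e-8)
})

test_that("zero co-called markers is an error", {
  calls <- matrix(c("AA", "NC", "NC", "BB"), nrow = 2,
                  dimnames = list(c("a", "b"), c("m1", "m2")))
  expect_error(distance_and_upgma(genotype_matrix(calls)), "co-called")
})
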