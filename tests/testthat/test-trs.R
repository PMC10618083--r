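makePanel <- function(df, tissue = "t") TwasPanel(tissue, df)

test_that("per-panel Bonferroni threshold is alpha over genes tested", {
  one <- makePanel(data.frame(gene_id = "A", zscore = 1, pvalue = 0.5,
                              chrom = "chr1", tss = 1))
  expect_equal(bonferroniThreshold(one, 0.05), 0.05)
  big <- makePanel(randomPanelDf(200, 1))
  expect_equal(bonferroniThreshold(big, 0.05), 0.05 / 200)
  expect_error(bonferroniThreshold(big, 1.5), "outside the allowed range")
})

test_that("gene selection matches the direct p-value filter", {
  df <- data.frame(gene_id = c("g1", "g2", "g3"),
                   zscore = c(5.3, 2.6, 1.3),
                   pvalue = c(1e-7, 0.01, 0.2),
                   chrom = "chr1", tss = c(1, 2, 3) * 1e6)
  pan <- makePanel(df)
  # BF threshold 0.05/3 = 0.0167 keeps the first two
  sel <- selectGenes(pan, "BF")
  expect_equal(selectedGenes(sel), c("g1", "g2"))
  expect_equal(unname(scoreWeights(sel)), c(5.3, 2.6))
  # vacuous threshold keeps everything
  expect_length(selectGenes(pan, "1"), 3L)
  expect_error(selectGenes(pan, "0.07"), "must be one of")

  # random panels against the brute-force filter, across the ladder
  for (seed in 1:5) {
    rp <- makePanel(randomPanelDf(60, seed))
    for (lab in trsThresholdLadder()) {
      thr <- if (lab == "BF") bonferroniThreshold(rp) else as.numeric(lab)
      got <- suppressMessages(selectGenes(rp, lab))
      expect_identical(sort(selectedGenes(got)),
                       bruteSelect(as.data.frame(twasResults(rp)), thr))
    }
  }
})

test_that("threshold ladder selections are nested", {
  pan <- makePanel(randomPanelDf(120, 42))
  labs <- trsThresholdLadder()
  sels <- lapply(labs, function(l) suppressMessages(selectGenes(pan, l)))
  thr <- vapply(sels, thresholdValue, numeric(1))
  o <- order(thr)
  for (k in seq_len(length(o) - 1)) {
    expect_true(all(selectedGenes(sels[[o[k]]]) %in%
                    selectedGenes(sels[[o[k + 1]]])))
  }
})

test_that("standardization hits exact moments and is idempotent", {
  m <- cbind(g1 = c(1, 2, 3), g2 = c(10, 10, 16))
  rownames(m) <- paste0("s", 1:3)
  s <- standardizeExpression(m)
  expect_equal(unname(s[, "g1"]), c(-1, 0, 1))
  expect_equal(standardizeExpression(s), s, tolerance = 1e-8)

  set.seed(6)
  r <- matrix(rnorm(1000, 5, 3), 50, 20,
              dimnames = list(NULL, paste0("g", 1:20)))
  rs <- standardizeExpression(r)
  expect_lt(max(abs(colMeans(rs))), 1e-10)
  expect_lt(max(abs(apply(rs, 2, sd) - 1)), 1e-10)

  flat <- cbind(g1 = c(1, 1, 1), g2 = c(1, 2, 3))
  expect_error(standardizeExpression(flat), "zero-variance gene\\(s\\): g1")
})

test_that("TRS equals the weighted sum, checked against a double loop", {
  # antisymmetry and single-gene identity
  m <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("s1", c("a", "b")))
  attr(m, "standardized") <- TRUE
  selAB <- new("GeneSelection", tissue = "t", thresholdLabel = "1",
               thresholdValue = 1, geneIds = c("a", "b"),
               weights = c(1, -1))
  expect_equal(unname(computeTrs(m, selAB))[1], 0)
  selA <- new("GeneSelection", tissue = "t", thresholdLabel = "1",
              thresholdValue = 1, geneIds = "a", weights = 2.5)
  expect_equal(unname(computeTrs(m, selA))[1], 2.5 * 0.5)

  # random instance vs brute force
  set.seed(20)
  std <- standardizeExpression(
    matrix(rnorm(300), 30, 10, dimnames = list(paste0("s", 1:30),
                                               paste0("g", 1:10))))
  ids <- sample(colnames(std), 6)
  w <- rnorm(6)
  sel <- new("GeneSelection", tissue = "t", thresholdLabel = "0.5",
             thresholdValue = 0.5, geneIds = ids, weights = w)
  expect_equal(as.numeric(computeTrs(std, sel)), bruteTrs(std, ids, w),
               tolerance = 1e-12)

  # unstandardized input is refused
  raw <- matrix(rnorm(300), 30, 10,
                dimnames = list(NULL, paste0("g", 1:10)))
  expect_error(computeTrs(raw, sel), "standardized")

  # genes missing from expression are dropped with a logged count
  selMiss <- new("GeneSelection", tissue = "t", thresholdLabel = "0.5",
                 thresholdValue = 0.5, geneIds = c(ids, "absent"),
                 weights = c(w, 3))
  expect_message(trs2 <- computeTrs(std, selMiss), "1 of 7")
  expect_equal(as.numeric(trs2), bruteTrs(std, ids, w), tolerance = 1e-12)
  expect_equal(attr(trs2, "n_genes"), 6L)
})

test_that("TRS is additive over disjoint gene selections", {
  set.seed(21)
  std <- standardizeExpression(
    matrix(rnorm(800), 40, 20, dimnames = list(NULL, paste0("g", 1:20))))
  mk <- function(ids, w) new("GeneSelection", tissue = "t",
                             thresholdLabel = "1", thresholdValue = 1,
                             geneIds = ids, weights = w)
  wAll <- rnorm(20)
  a <- mk(paste0("g", 1:8), wAll[1:8])
  b <- mk(paste0("g", 9:20), wAll[9:20])
  ab <- mk(paste0("g", 1:20), wAll)
  expect_equal(as.numeric(computeTrs(std, ab)),
               as.numeric(computeTrs(std, a)) + as.numeric(computeTrs(std, b)),
               tolerance = 1e-12)
})

test_that("locus chaining follows the 500 kb single-linkage rule", {
  # 400 kb and 600 kb gaps: first two chain, third stands alone
  cl <- clusterLoci(c("g1", "g2", "g3"), rep("chr1", 3),
                    c(1000000, 1400000, 2000000))
  expect_equal(length(unique(cl$locus)), 2L)
  expect_equal(cl$locus[1], cl$locus[2])
  # chaining: consecutive 450 kb steps give one locus of three
  cl2 <- clusterLoci(c("g1", "g2", "g3"), rep("chr1", 3),
                     c(1000000, 1450000, 1900000))
  expect_equal(length(unique(cl2$locus)), 1L)
  # exactly 500 kb merges (inclusive) and is logged
  expect_message(cl3 <- clusterLoci(c("a", "b"), c("chr1", "chr1"),
                                    c(1e6, 1e6 + 500000)),
                 "exactly 500000")
  expect_equal(cl3$locus[1], cl3$locus[2])
  expect_error(clusterLoci(c("a", "b"), c("chr1", NA), c(1, 2)),
               "missing position")

  # random instances vs the all-pairs connected-components oracle
  for (seed in 1:8) {
    set.seed(seed)
    n <- 30
    chrom <- paste0("chr", sample(1:2, n, replace = TRUE))
    tss <- sample.int(4e6, n)
    got <- suppressMessages(
      clusterLoci(sprintf("g%02d", 1:n), chrom, tss))$locus
    want <- bruteComponents(chrom, tss, 500000)
    # identical partitions: same co-membership for every pair
    expect_identical(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("lead-gene pruning keeps the per-locus p-value minimum", {
  df <- data.frame(gene_id = c("A", "B", "C"),
                   zscore = c(5.7, 3.9, 2.1),
                   pvalue = c(1e-8, 1e-4, 0.03),
                   chrom = "chr1", tss = c(1000000, 1200000, 5000000))
  pan <- makePanel(df)
  sel <- selectGenes(pan, "0.05")
  loci <- clusterLoci(df$gene_id, df$chrom, df$tss)
  pruned <- pruneToLead(sel, loci, pan)
  expect_setequal(selectedGenes(pruned), c("A", "C"))

  # all-singleton loci: pruning is the identity
  far <- clusterLoci(df$gene_id, df$chrom, c(1e6, 3e6, 5e6))
  expect_equal(selectedGenes(pruneToLead(sel, far, pan)),
               selectedGenes(sel))

  # random instances vs the per-cluster argmin oracle, and fixed-point
  for (seed in 11:16) {
    df2 <- randomPanelDf(40, seed)
    pan2 <- makePanel(df2)
    sel2 <- suppressMessages(selectGenes(pan2, "1"))
    loci2 <- suppressMessages(clusterLoci(df2$gene_id, df2$chrom, df2$tss))
    pruned2 <- pruneToLead(sel2, loci2, pan2)
    comp <- loci2$locus[match(df2$gene_id, loci2$gene_id)]
    want <- bruteLead(df2$gene_id, df2$pvalue, df2$tss, comp)
    expect_setequal(selectedGenes(pruned2), want)
    expect_length(pruned2, length(unique(comp)))  # one lead per locus
    again <- pruneToLead(pruned2, loci2, pan2)
    expect_identical(selectedGenes(again), selectedGenes(pruned2))
  }
})

test_that("colocalization restriction keeps GLCP >= cutoff inclusively", {
  df <- data.frame(gene_id = c("a", "b", "c"), zscore = c(2, 3, 4),
                   pvalue = c(0.01, 0.02, 0.03), chrom = "chr1",
                   tss = c(1, 2, 3) * 1e6)
  sel <- selectGenes(makePanel(df, "cortex"), "0.05")
  coloc <- data.frame(gene_id = c("a", "b", "c"), tissue = "cortex",
                      glcp = c(0.3, 0.5, 0.9))
  kept <- restrictColocalized(sel, coloc)
  # the boundary value 0.5 is retained
  expect_setequal(selectedGenes(kept), c("b", "c"))

  none <- data.frame(gene_id = c("a", "b", "c"), tissue = "cortex",
                     glcp = 0)
  expect_message(empty <- restrictColocalized(sel, none), "removed every")
  expect_length(empty, 0L)

  # genes with no record in the matching tissue are dropped
  other <- data.frame(gene_id = c("a", "b", "c"), tissue = "amygdala",
                      glcp = 1)
  expect_length(suppressMessages(restrictColocalized(sel, other)), 0L)
})
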