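test_that("Simpson and Pielou reproduce closed-form values", {
  expect_equal(simpsonIndex(c(1)), 0)
  expect_equal(simpsonIndex(c(50, 50)), 0.5)
  expect_equal(simpsonIndex(rep(10, 10)), 0.9)
  expect_error(simpsonIndex(c(0, 0)), "all zero")
  expect_equal(pielouEvenness(rep(5, 7)), 1)
  expect_equal(pielouEvenness(c(0.9, 0.1)),
               -(0.9 * log(0.9) + 0.1 * log(0.1)) / log(2))
  expect_true(is.na(pielouEvenness(c(3, 0, 0))))
  # zero taxa do not perturb the value; percent and proportion agree
  expect_equal(pielouEvenness(c(0.9, 0.1, 0)), pielouEvenness(c(90, 10)))
  expect_equal(simpsonIndex(c(30, 70)), simpsonIndex(c(0.3, 0.7)))
  p <- c(5, 2, 9, 1)
  expect_equal(simpsonIndex(p), simpsonIndex(rev(p)))
})

test_that("diversity agrees with the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(5)
  m <- matrix(runif(60), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
  expect_equal(apply(m, 1, simpsonIndex),
               vegan::diversity(m, index = "simpson"))
  je <- vegan::diversity(m, "shannon") / log(vegan::specnumber(m))
  expect_equal(apply(m, 1, pielouEvenness), je)
})

test_that("Bray-Curtis satisfies its identities and matches vegdist", {
  expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(brayCurtis(c(5, 0, 0), c(0, 2, 3)), 1)
  expect_equal(brayCurtis(c(2, 0, 1), c(0, 2, 1)), 4 / 6)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all zero")
  set.seed(6)
  x <- runif(8); y <- runif(8)
  expect_equal(brayCurtis(x, y), brayCurtis(y, x))
  skip_if_not_installed("vegan")
  m <- matrix(runif(40), 5, 8,
              dimnames = list(paste0("s", 1:5), paste0("t", 1:8)))
  expect_equal(brayCurtisMatrix(m),
               as.matrix(vegan::vegdist(m, "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

clusteredTable <- function(seed = 8, nPerGroup = 4, shift = 30) {
  set.seed(seed)
  base <- matrix(runif(2 * nPerGroup * 6, 1, 10), 2 * nPerGroup, 6)
  base[seq_len(nPerGroup), 1] <- base[seq_len(nPerGroup), 1] + shift
  rownames(base) <- paste0("s", seq_len(2 * nPerGroup))
  colnames(base) <- paste0("t", 1:6)
  list(m = base, groups = rep(c("A", "B"), each = nPerGroup))
}

test_that("PERMANOVA pseudo-F matches vegan::adonis2", {
  skip_if_not_installed("vegan")
  ct <- clusteredTable()
  d <- brayCurtisMatrix(ct$m)
  mine <- permanova(d, ct$groups, nPermutations = 99, seed = 2)
  van <- vegan::adonis2(as.dist(d) ~ g,
                        data = data.frame(g = ct$groups),
                        permutations = 99)
  expect_equal(mine$pseudoF, van$F[1], tolerance = 1e-10)
})

test_that("well-separated clusters saturate the permutation p-value", {
  ct <- clusteredTable(shift = 500, nPerGroup = 8)
  d <- brayCurtisMatrix(ct$m)
  r <- permanova(d, ct$groups, nPermutations = 199, seed = 3)
  expect_equal(r$pValue, 1 / 200)
  # identical samples are a flagged degenerate case
  m <- matrix(rep(c(1, 2, 3), each = 4), 4, 3,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  r0 <- permanova(brayCurtisMatrix(m), c("A", "A", "B", "B"),
                  nPermutations = 19, seed = 1)
  expect_true(is.na(r0$pseudoF))
  expect_error(permanova(brayCurtisMatrix(m), c("A", "B", "C", "D"),
                         19, 1), "degrees of freedom")
})

test_that("pairwise PERMANOVA covers all pairs consistently", {
  set.seed(12)
  m <- matrix(runif(9 * 5, 1, 10), 9, 5,
              dimnames = list(paste0("s", 1:9), paste0("t", 1:5)))
  groups <- rep(c("A", "B", "C"), each = 3)
  d <- brayCurtisMatrix(m)
  pw <- pairwisePermanova(d, groups, nPermutations = 49, seed = 4)
  expect_equal(nrow(pw), 3L)
  # standalone sub-analysis reproduces the pairwise F
  idx <- groups %in% c("A", "B")
  solo <- permanova(d[idx, idx], groups[idx], nPermutations = 49, seed = 4)
  expect_equal(pw$pseudoF[pw$group1 == "A" & pw$group2 == "B"],
               solo$pseudoF)
  # BH adjustment never rejects more than raw p-values
  pwBH <- pairwisePermanova(d, groups, nPermutations = 49, seed = 4,
                            adjust = "BH")
  expect_true(all(pwBH$pAdjusted >= pwBH$pValue - 1e-12))
})

test_that("SIMPER contributions decompose the mean Bray-Curtis exactly", {
  # one differing taxon carries 100% of the dissimilarity
  m <- rbind(s1 = c(5, 3, 2), s2 = c(5, 3, 2), s3 = c(9, 3, 2),
             s4 = c(9, 3, 2))
  colnames(m) <- c("t1", "t2", "t3")
  sp <- simperAnalysis(m, c("A", "A", "B", "B"))[["A vs B"]]
  expect_equal(sp$contribution_pct[sp$taxon == "t1"], 100)
  # symmetric swap: the two taxa tie
  m2 <- rbind(s1 = c(5, 1, 2), s2 = c(1, 5, 2))
  colnames(m2) <- c("t1", "t2", "t3")
  sp2 <- simperAnalysis(m2, c("A", "B"))[[1]]
  expect_equal(sp2$contribution[sp2$taxon == "t1"],
               sp2$contribution[sp2$taxon == "t2"])
  # conservation on random tables
  set.seed(13)
  m3 <- matrix(runif(8 * 7, 0, 12), 8, 7,
               dimnames = list(paste0("s", 1:8), paste0("t", 1:7)))
  g <- rep(c("A", "B"), each = 4)
  sp3 <- simperAnalysis(m3, g)[[1]]
  meanBC <- mean(vapply(1:4, function(i) vapply(5:8, function(j)
    brayCurtis(m3[i, ], m3[j, ]), numeric(1)), numeric(4)))
  expect_equal(sum(sp3$contribution), meanBC, tolerance = 1e-9)
  expect_equal(attr(sp3, "meanDissimilarity"), meanBC, tolerance = 1e-12)
})

test_that("SIMPER ranking agrees with the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(14)
  m <- matrix(runif(10 * 6, 0, 10), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:6)))
  g <- rep(c("A", "B"), each = 5)
  mine <- simperAnalysis(m, g)[[1]]
  van <- summary(vegan::simper(m, g, permutations = 0))[[1]]
  expect_equal(mine$contribution[match(rownames(van), mine$taxon)],
               van$average, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("PCA filters taxa, reconstructs the table, and separates clusters", {
  ct <- clusteredTable(shift = 40)
  m <- ct$m
  m <- cbind(m, low = rep(0.3, nrow(m)))  # stays under the 0.9% filter
  ord <- pcaOrdination(m, minAbundance = 0.9)
  expect_false("low" %in% ord$taxa)
  recon <- ord$scores %*% t(ord$loadings) +
    matrix(ord$centers, nrow(m), length(ord$centers), byrow = TRUE)
  expect_equal(recon, m[, ord$taxa], tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(ord$varianceExplained) <= 1e-12))
  expect_gt(ord$varianceExplained[1], 0.5)
  # PC1 separates the two planted clusters
  pc1 <- ord$scores[, 1]
  expect_true(max(pc1[ct$groups == "B"]) < min(pc1[ct$groups == "A"]) ||
                max(pc1[ct$groups == "A"]) < min(pc1[ct$groups == "B"]))
  # duplicated samples: zero variance is flagged, not crashed
  dup <- matrix(rep(c(5, 3, 2), each = 4), 4, 3,
                dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  expect_true(pcaOrdination(dup, minAbundance = 0.9)$degenerate)
  expect_error(pcaOrdination(m[, 1, drop = FALSE]), "fewer than two")
})

test_that("AbundanceTable validity guards ranges and row sums", {
  m <- matrix(c(60, 30, 20, 10), 2, 2,
              dimnames = list(c("s1", "s2"), c("t1", "t2")))
  tab <- abundanceTable(m, rank = "genus")
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(taxonRank(tab), "genus")
  expect_error(abundanceTable(m * 2), "row sums")
  expect_error(abundanceTable(-m), "non-negative")
  expect_equal(diversityTable(tab)$`Simpson (D)`[1],
               simpsonIndex(c(60, 20)))
})
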