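rec <- function(qseqid, genome, pident, bitscore, qlen = 100,
                alnLen = qlen, sstart = 1) {
  data.frame(qseqid = qseqid, sseqid = paste0(genome, "|1"),
             pident = pident, length = alnLen, mismatch = 0L,
             gapopen = 0L, qstart = 1L, qend = alnLen, sstart = sstart,
             send = sstart + alnLen - 1, evalue = 0, bitscore = bitscore,
             qlen = qlen, stringsAsFactors = FALSE)
}

test_that("best hit filters and breaks ties deterministically", {
  expect_equal(nrow(bestHit(rec("r1", "gA", 59, 100))), 0L)
  b <- bestHit(rbind(rec("r1", "gA", 95, 180), rec("r1", "gB", 99, 150)))
  expect_equal(b$genome_id, "gA")
  # equal bit score: higher identity wins
  b2 <- bestHit(rbind(rec("r1", "gA", 92, 180), rec("r1", "gB", 97, 180)))
  expect_equal(b2$genome_id, "gB")
  # equal bit score and identity: smallest genome id
  b3 <- bestHit(rbind(rec("r1", "gB", 97, 180), rec("r1", "gA", 97, 180)))
  expect_equal(b3$genome_id, "gA")
})

test_that("best hit matches a pairwise-comparison oracle on random tables", {
  set.seed(21)
  for (i in 1:200) {
    k <- sample(1:6, 1)
    tab <- do.call(rbind, lapply(seq_len(k), function(j)
      rec("r1", sample(c("gA", "gB", "gC"), 1),
          pident = sample(c(55, 61, 80, 97), 1),
          bitscore = sample(c(120, 150, 180), 1),
          alnLen = sample(c(50, 70, 100), 1))))
    got <- bestHit(tab)
    tab$genome_id <- sub("\\|.*$", "", tab$sseqid)
    want <- oracleBestHit(tab)
    if (is.null(want)) expect_equal(nrow(got), 0L)
    else expect_equal(got[, c("genome_id", "pident", "bitscore")],
                      want[, c("genome_id", "pident", "bitscore")],
                      ignore_attr = TRUE)
  }
})

test_that("section assignment uses subject-interval midpoints", {
  expect_equal(sectionCounts(1000, c(50, 950)),
               c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L))
  expect_error(sectionCounts(5, 1), ">= 10")
  expect_error(sectionCounts(1000, 1000), "within")
  # multinomial 99.9% band for uniform recruitment, checked by simulation
  set.seed(9)
  mids <- runif(5000, 0, 10000)
  sc <- sectionCounts(10000, mids)
  expect_equal(sum(sc), 5000L)
  lim <- qbinom(c(5e-5, 1 - 5e-5), 5000, 0.1)
  expect_true(all(sc >= lim[1] & sc <= lim[2]))
})

test_that("RSD equals sd/mean with the n-1 denominator", {
  expect_equal(computeRSD(rep(100, 10)), 0)
  expect_equal(computeRSD(c(10, rep(0, 9))), sqrt(10))
  expect_true(is.na(computeRSD(rep(0, 10))))
  # direct two-pass oracle on 10,000 random count vectors
  set.seed(33)
  for (i in 1:10000) {
    x <- rpois(10, lambda = sample(1:50, 1))
    if (sum(x) == 0) next
    m <- sum(x) / 10
    s <- sqrt(sum((x - m)^2) / 9)
    expect_equal(computeRSD(x), s / m, tolerance = 1e-12)
  }
  # population-sd mode is a single switch
  x <- c(4, 6, 5, 5, 5, 5, 5, 5, 5, 5)
  expect_equal(computeRSD(x, "population"),
               sqrt(sum((x - 5)^2) / 10) / 5)
})

test_that("ANI is the unweighted mean identity, permutation-invariant", {
  expect_equal(computeANI(c(90, 100)), 95)
  expect_equal(computeANI(rep(100, 7)), 100)
  expect_true(is.na(computeANI(numeric(0))))
  set.seed(2)
  x <- runif(50, 60, 100)
  expect_equal(computeANI(x), computeANI(sample(x)))
})

histFrom <- function(identities) frpkit:::identityHistogramOf(identities)

test_that("cloud detection flags planted bimodality only", {
  set.seed(17)
  len <- 200
  uni <- 100 * (1 - rbinom(3000, len, 0.03) / len)
  one <- detectClouds(histFrom(uni))
  expect_false(one$twoClouds)
  lo <- 100 * (1 - rbinom(1500, len, 0.12) / len)
  hi <- 100 * (1 - rbinom(1500, len, 0.02) / len)
  two <- detectClouds(histFrom(c(lo, hi)))
  expect_true(two$twoClouds)
  hiCloud <- two$clouds[two$clouds$cloud == "high", ]
  expect_equal(hiCloud$mean_identity, 98, tolerance = 1 / 98)
  expect_equal(sum(two$clouds$n_reads), 3000)
  # tiny read sets never report two clouds (peak-mass floor)
  few <- detectClouds(histFrom(c(70, 70, 71, 97, 98, 98, 99, 99, 98, 97)))
  expect_false(few$twoClouds || sum(histFrom(numeric(0))) > 0)
  empty <- detectClouds(histFrom(numeric(0)))
  expect_false(empty$twoClouds)
  expect_equal(nrow(empty$clouds), 0L)
})

test_that("presence rule enforces the read-count and RSD thresholds", {
  ok <- callPresence(makeProfile(1500, 0.5, 96.2))
  expect_true(isPresent(ok))
  expect_equal(aniBand(ok), "95-100")
  few <- callPresence(makeProfile(999, 0.1, 99))
  expect_false(isPresent(few))
  expect_equal(failReasons(few), "too_few_reads")
  rough <- callPresence(makeProfile(5000, 0.80, 95))
  expect_false(isPresent(rough))
  expect_equal(failReasons(rough), "rsd_too_high")
  # boundary: n = 1000 with rsd just below 0.8 is present
  expect_true(isPresent(callPresence(makeProfile(1000, 0.79))))
  # band from the high cloud when two clouds and high mean > 90
  clouds <- data.frame(cloud = c("low", "high"), n_reads = c(500, 1500),
                       mean_identity = c(75, 96.5))
  p <- makeProfile(2000, 0.3, aniVal = 85, twoClouds = TRUE,
                   clouds = clouds)
  call <- callPresence(p)
  expect_equal(aniBand(call), "95-100")
  expect_true(twoClouds(call))
})

test_that("relative abundance recovers the planted fraction", {
  expect_equal(relativeAbundance(500, 100000), 0.5)
  expect_equal(relativeAbundance(makeProfile(2000, 0.1), 2000), 100)
  expect_error(relativeAbundance(10, 0), "positive")
  genomes <- generateGenomes(list(genomeSpec("gA",
                                             contigLengths = 50000L,
                                             seed = 1L)))
  d <- communityDesign("S", data.frame(
    genome_id = "gA", read_fraction = 0.404, divergence = 0,
    coverage_mode = "uniform"), unclassifiedFraction = 0.596,
    nReads = 100000L, seed = 3L)
  sim <- simulateReads(d, genomes)
  aln <- simulateAlignments(sim$truth, genomes)
  man <- manifestFromSpecs(list(genomeSpec("gA", contigLengths = 50000L,
                                           seed = 1L)))
  prof <- recruitReads(aln, man, contigTable(genomes))[["gA"]]
  got <- relativeAbundance(prof, 100000)
  # binomial 99.9% interval at the simulated depth
  lim <- 100 * qbinom(c(5e-4, 1 - 5e-4), 100000, 0.404) / 100000
  expect_gte(got, lim[1]); expect_lte(got, lim[2])
})

test_that("profiles are internally consistent on a simulated community", {
  st <- recoveryStudy(seed = 4L, nReads = 10000L)
  profs <- recruitReads(st$aln, st$manifest, st$contigs)
  for (p in profs) {
    expect_equal(sum(sections(p)), nReads(p))
    expect_equal(sum(identityHistogram(p)), nReads(p))
    if (nReads(p) > 0) {
      ids <- st$aln$pident[st$aln$qseqid %in%
        bestHit(st$aln, contigMap = st$contigs)$qseqid]
      expect_gte(ani(p), 60); expect_lte(ani(p), 100)
    }
  }
  # single-region artifact genome: reads pile into one section
  art <- profs[["g8"]]
  expect_gt(nReads(art), 0L)
  expect_equal(sum(sections(art) > 0), 1L)
  expect_gte(rsd(art), 0.8)
})

test_that("rollups aggregate species abundances by sample and group", {
  calls <- data.frame(
    sample_id = c("s1", "s1", "s1", "s2"),
    species = c("a", "b", "c", "a"),
    group = c("G1", "G1", "G2", "G1"),
    percent = c(1.5, 2.5, 3, 4), stringsAsFactors = FALSE)
  ru <- rollupAbundance(calls)
  expect_equal(ru$sampleTotals$total, c(7, 4))
  expect_equal(ru$sampleTotals$n_species, c(3, 1))
  expect_equal(ru$groupTotals$total[ru$groupTotals$sample_id == "s1" &
                                      ru$groupTotals$group == "G1"], 4)
})
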