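test_that("genome generation conserves lengths and is seed-deterministic", {
  g1 <- generateGenome(genomeSpec("g1", contigLengths = 1000L, seed = 1L))
  expect_length(g1, 1L)
  expect_equal(sum(Biostrings::width(g1)), 1000L)
  g1b <- generateGenome(genomeSpec("g1", contigLengths = 1000L, seed = 1L))
  expect_identical(as.character(g1), as.character(g1b))
  g2 <- generateGenome(genomeSpec("g2", contigLengths = c(600L, 400L),
                                  seed = 3L))
  expect_length(g2, 2L)
  expect_equal(sum(Biostrings::width(g2)), 1000L)
  expect_error(genomeSpec("bad", contigLengths = c(100L, 0L)),
               "positive")
})

test_that("contig table lays contigs on a concatenated axis", {
  g <- generateGenomes(list(
    genomeSpec("a", contigLengths = c(300L, 200L), seed = 1L),
    genomeSpec("b", contigLengths = 500L, seed = 2L)))
  ct <- contigTable(g)
  expect_equal(ct$genome_id, c("a", "a", "b"))
  expect_equal(ct$offset, c(0, 300, 0))
})

simpleDesign <- function(frac = 0.5, div = 0, n = 2000L, seed = 7L,
                         mode = "uniform", host = 0, uncl = 1 - frac - host) {
  communityDesign("S", data.frame(
    genome_id = "gA", read_fraction = frac, divergence = div,
    coverage_mode = mode), hostFraction = host,
    unclassifiedFraction = uncl, nReads = n, seed = seed)
}

test_that("read simulation respects design fractions and determinism", {
  genomes <- generateGenomes(list(
    genomeSpec("gA", contigLengths = 50000L, seed = 1L),
    genomeSpec("hostX", contigLengths = 50000L, seed = 2L)))
  d <- simpleDesign(frac = 0.5, n = 10000L)
  sim <- simulateReads(d, genomes)
  # binomial 99.9% interval for n=10000, p=0.5 (derived below via qbinom)
  lim <- stats::qbinom(c(5e-4, 1 - 5e-4), 10000, 0.5)
  expect_gte(sum(sim$truth$origin == "gA"), lim[1])
  expect_lte(sum(sim$truth$origin == "gA"), lim[2])
  # truth covers every read exactly once
  expect_identical(sort(sim$truth$read_id), sort(names(sim$reads)))
  sim2 <- simulateReads(d, genomes)
  expect_identical(as.character(sim$reads), as.character(sim2$reads))
  expect_identical(sim$truth, sim2$truth)
  # fraction sum != 1 is rejected
  expect_error(simpleDesign(frac = 0.5, uncl = 0.6), "sum to 1")
})

test_that("zero divergence yields exact source substrings", {
  genomes <- generateGenomes(list(genomeSpec("gA", contigLengths = 20000L,
                                             seed = 1L)))
  sim <- simulateReads(simpleDesign(frac = 1, uncl = 0, n = 200L), genomes)
  contig <- as.character(genomes)[["gA|1"]]
  tt <- sim$truth
  expect_true(all(tt$n_substitutions == 0))
  got <- as.character(sim$reads)[tt$read_id]
  expected <- substring(contig, tt$source_start + 1,
                        tt$source_start + tt$read_length)
  expect_identical(unname(got), unname(expected))
})

test_that("single-region coverage confines reads to one genome tenth", {
  genomes <- generateGenomes(list(genomeSpec("gA", contigLengths = 50000L,
                                             seed = 1L)))
  sim <- simulateReads(simpleDesign(frac = 1, uncl = 0, n = 500L,
                                    mode = "single-region"), genomes)
  w <- 50000 %/% 10
  expect_true(all(sim$truth$source_start >= 0))
  expect_true(all(sim$truth$source_start + sim$truth$read_length <= w))
})

test_that("simulated alignments encode identity from planted substitutions", {
  genomes <- generateGenomes(list(genomeSpec("gA", contigLengths = 50000L,
                                             seed = 1L)))
  d <- communityDesign("S", data.frame(
    genome_id = "gA", read_fraction = 0.8, divergence = 0.05,
    coverage_mode = "uniform"), unclassifiedFraction = 0.2,
    nReads = 4000L, readLengthMean = 200, readLengthSd = 0, seed = 11L)
  sim <- simulateReads(d, genomes)
  aln <- simulateAlignments(sim$truth, genomes)
  # random-origin reads produce no records
  expect_false(any(aln$qseqid %in%
                     sim$truth$read_id[sim$truth$origin == "random"]))
  # identity consistency: recompute from truth to 0.01
  tt <- sim$truth[match(aln$qseqid, sim$truth$read_id), ]
  expect_equal(aln$pident,
               round(100 * (tt$read_length - tt$n_substitutions) /
                       tt$read_length, 3),
               tolerance = 1e-4)
  # binomial expectation: mean identity ~ 95 +- 0.5 at divergence 0.05
  expect_equal(mean(aln$pident), 95, tolerance = 0.5 / 95)
  # subject interval equals the planted interval
  expect_equal(aln$sstart, tt$source_start + 1)
  expect_equal(aln$send, tt$source_start + tt$read_length)
})

test_that("zero-divergence reads align at identity 100", {
  genomes <- generateGenomes(list(genomeSpec("gA", contigLengths = 10000L,
                                             seed = 1L)))
  sim <- simulateReads(simpleDesign(frac = 1, uncl = 0, n = 50L), genomes)
  aln <- simulateAlignments(sim$truth, genomes)
  expect_true(all(aln$pident == 100))
})

test_that("decoy hits rank below the true source and land on the sister", {
  genomes <- generateGenomes(list(
    genomeSpec("gA", contigLengths = 30000L, seed = 1L),
    genomeSpec("gSis", contigLengths = 30000L, seed = 2L)))
  sim <- simulateReads(simpleDesign(frac = 1, uncl = 0, n = 100L,
                                    div = 0.02), genomes)
  aln <- simulateAlignments(sim$truth, genomes, decoyMap = c(gA = "gSis"),
                            decoyExtraDivergence = 0.05)
  expect_equal(nrow(aln), 200L)
  prim <- aln[grepl("^gA", aln$sseqid), ]
  dec <- aln[grepl("^gSis", aln$sseqid), ]
  m <- match(prim$qseqid, dec$qseqid)
  expect_true(all(prim$bitscore > dec$bitscore[m]))
  expect_true(all(prim$pident > dec$pident[m]))
})

test_that("byte-identical outputs for identical seeds", {
  genomes <- generateGenomes(list(genomeSpec("gA", contigLengths = 5000L,
                                             seed = 1L)))
  d <- simpleDesign(frac = 1, uncl = 0, n = 100L, div = 0.03)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  writeFastq(simulateReads(d, genomes)$reads, f1)
  writeFastq(simulateReads(d, genomes)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})
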