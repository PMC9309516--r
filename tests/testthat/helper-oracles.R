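# Independent reference implementations used as oracles.

# Naive loop version of the trimming rule: window scan by explicit loops,
# no cumulative sums; one pass of the rule, iterated to a fixpoint.
oracleTrimPass <- function(q, lo, hi, window, step, minMeanQ, minEndQ,
                           minLen) {
  end <- hi
  pos <- lo
  while (pos <= hi) {
    w <- q[pos:min(pos + window - 1, hi)]
    if (sum(w) / length(w) < minMeanQ) {
      end <- pos - 1
      break
    }
    pos <- pos + step
  }
  if (end < lo) return(NULL)
  s <- lo
  while (s <= end && q[s] < minEndQ) s <- s + 1
  e <- end
  while (e >= s && q[e] < minEndQ) e <- e - 1
  if (e - s + 1 < minLen) NULL else c(as.integer(s), as.integer(e))
}

oracleTrim <- function(q, window = 10, step = 4, minMeanQ = 20,
                       minEndQ = 20, minLen = 50) {
  rng <- c(1L, length(q))
  repeat {
    new <- oracleTrimPass(q, rng[1], rng[2], window, step, minMeanQ,
                          minEndQ, minLen)
    if (is.null(new)) return(NULL)
    if (identical(new, rng)) return(rng)
    rng <- new
  }
}

# Pairwise-comparison best hit: filters then picks the winner by comparing
# every pair of surviving records explicitly.
oracleBestHit <- function(recs, minIdentity = 60, minCoverage = 60) {
  cov <- 100 * recs$length / recs$qlen
  recs <- recs[recs$pident >= minIdentity & cov >= minCoverage, ,
               drop = FALSE]
  if (nrow(recs) == 0) return(NULL)
  beats <- function(a, b) {
    if (a$bitscore != b$bitscore) return(a$bitscore > b$bitscore)
    if (a$pident != b$pident) return(a$pident > b$pident)
    a$genome_id < b$genome_id
  }
  best <- recs[1, , drop = FALSE]
  for (i in seq_len(nrow(recs))[-1])
    if (beats(recs[i, , drop = FALSE], best)) best <- recs[i, , drop = FALSE]
  best
}

# quality-scaled read set from explicit base/quality vectors
makeReads <- function(seqs, quals) {
  qs <- vapply(quals, function(q) rawToChar(as.raw(q + 33L)), character(1))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(qs))
  names(x) <- sprintf("read%03d", seq_along(seqs))
  x
}

# minimal RecruitmentProfile with consistent slots
makeProfile <- function(n, rsdVal, aniVal = 96, genome = "g1",
                        twoClouds = FALSE, clouds = NULL) {
  secs <- as.integer(rep(n %/% 10, 10))
  secs[10] <- as.integer(secs[10] + n - sum(secs))
  hist <- stats::setNames(numeric(41), 60:100)
  hist[as.character(min(100, max(60, floor(aniVal))))] <- n
  if (is.null(clouds))
    clouds <- data.frame(cloud = "all", n_reads = n, mean_identity = aniVal)
  new("RecruitmentProfile", genomeId = genome, nReads = as.integer(n),
      ani = if (n > 0) aniVal else NA_real_, sectionCounts = secs,
      rsd = if (n > 0) rsdVal else NA_real_, identityHistogram = hist,
      twoClouds = twoClouds, cloudSummaries = clouds)
}

# the parameter-recovery community: 5 true members, 2 decoy genomes that
# receive only cross-mapped secondary hits, 1 single-region artifact genome
recoveryStudy <- function(seed = 1L, nReads = 20000L) {
  mk <- function(id, cls) genomeSpec(id, paste("Species", id), id, cls,
                                     contigLengths = 40000L,
                                     seed = seed + match(id, sprintf("g%d", 1:8)))
  specs <- lapply(sprintf("g%d", 1:8), mk, cls = "ClassA")
  members <- data.frame(
    genome_id = sprintf("g%d", 1:5),
    read_fraction = rep(0.12, 5),
    divergence = c(0.01, 0.02, 0.03, 0.04, 0.05),
    coverage_mode = "uniform", stringsAsFactors = FALSE)
  artifact <- data.frame(genome_id = "g8", read_fraction = 0.10,
                         divergence = 0.02,
                         coverage_mode = "single-region",
                         stringsAsFactors = FALSE)
  design <- communityDesign("S1", rbind(members, artifact),
                            hostFraction = 0, unclassifiedFraction = 0.30,
                            nReads = nReads, seed = seed)
  genomes <- generateGenomes(specs)
  sim <- simulateReads(design, genomes)
  aln <- simulateAlignments(sim$truth, genomes,
                            decoyMap = c(g1 = "g6", g2 = "g7"),
                            decoyExtraDivergence = 0.2)
  list(specs = specs, design = design, genomes = genomes, sim = sim,
       aln = aln, manifest = manifestFromSpecs(specs),
       contigs = contigTable(genomes))
}
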