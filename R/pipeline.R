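#' Pipeline configuration
#'
#' Assembles and validates the single configuration object holding every
#' numeric threshold of the pipeline, the seed, the output directory and
#' the reporting modes. Defaults are the study-condition values: trimming
#' window 10 with step 4 and minimum mean quality 20, end quality 20,
#' minimum length 50; host depletion and recruitment at 60 percent identity
#' and 60 percent query coverage; presence at >= 1000 reads and RSD < 0.8;
#' database genus selection at >= 0.1 percent; minority folding below 0.9
#' percent; PCA filter at >= 0.9 percent.
#'
#' @param ... named overrides of the defaults (see
#'   \code{pipelineConfig()} for names).
#' @return validated named list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    trimWindow = 10L, trimStep = 4L, trimMinMeanQ = 20, trimMinEndQ = 20,
    trimMinLen = 50L,
    hostMinIdentity = 60, hostMinCoverage = 60,
    recruitMinIdentity = 60, recruitMinCoverage = 60,
    presenceMinReads = 1000L, presenceMaxRsd = 0.8,
    dbMinAbundance = 0.1, minorityThreshold = 0.9, pcaMinAbundance = 0.9,
    nPermutations = 999L,
    seed = 1L,
    denominator = "trimmed",   # or "depleted"
    sdMode = "sample",         # or "population"
    outdir = "frpkit_run"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validatePipelineConfig(cfg)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param cfg a configuration list.
#' @export
validatePipelineConfig <- function(cfg) {
  chk <- function(key, lo, hi) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < lo || v > hi)
      stop("configuration key '", key, "' must lie in [", lo, ", ", hi,
           "] (got ", deparse(v), ")")
  }
  chk("trimWindow", 1, 1e6); chk("trimStep", 1, 1e6)
  chk("trimMinMeanQ", 0, 93); chk("trimMinEndQ", 0, 93)
  chk("trimMinLen", 1, 1e6)
  chk("hostMinIdentity", 0, 100); chk("hostMinCoverage", 0, 100)
  chk("recruitMinIdentity", 0, 100); chk("recruitMinCoverage", 0, 100)
  chk("presenceMinReads", 1, 1e9); chk("presenceMaxRsd", 0, sqrt(10))
  chk("dbMinAbundance", 0, 100); chk("minorityThreshold", 0, 100)
  chk("pcaMinAbundance", 0, 100)
  chk("nPermutations", 1, 1e7); chk("seed", -2^31, 2^31)
  if (!cfg$denominator %in% c("trimmed", "depleted"))
    stop("configuration key 'denominator' must be 'trimmed' or 'depleted'")
  if (!cfg$sdMode %in% c("sample", "population"))
    stop("configuration key 'sdMode' must be 'sample' or 'population'")
  invisible(TRUE)
}

#' @rdname pipelineConfig
#' @param path YAML file of overrides (keys as in \code{pipelineConfig}).
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Built-in demonstration study
#'
#' A small two-group synthetic study used by [runPipeline()]: six microbial
#' genomes (two genera x species pairs plus two low-abundance species) and
#' one host-plant genome; four samples, two per sample group, with
#' group-distinct dominant members, host contamination and an unplaceable
#' read fraction.
#'
#' @param seed integer master seed.
#' @param nReads reads per sample.
#' @return list with \code{specs}, \code{hostSpec}, \code{designs} (list of
#'   [CommunityDesign-class]) and \code{groups} (named by sample).
#' @export
demoStudy <- function(seed = 1L, nReads = 20000L) {
  specs <- list(
    genomeSpec("ent_rogg", "Enterobacter roggenkampii", "Enterobacter",
               "Gammaproteobacteria", c(30000L, 20000L), seed + 11L),
    genomeSpec("pan_vaga", "Pantoea vagans", "Pantoea",
               "Gammaproteobacteria", 50000L, seed + 12L),
    genomeSpec("leu_pseu", "Leuconostoc pseudomesenteroides", "Leuconostoc",
               "Bacilli", 40000L, seed + 13L),
    genomeSpec("mam_sciu", "Mammaliicoccus sciuri", "Mammaliicoccus",
               "Bacilli", 40000L, seed + 14L),
    genomeSpec("chr_arto", "Chryseobacterium artocarpi", "Chryseobacterium",
               "Flavobacteriia", 45000L, seed + 15L),
    genomeSpec("met_reuk", "Metschnikowia reukaufii", "Metschnikowia",
               "Ascomycota", 55000L, seed + 16L))
  hostSpec <- genomeSpec("host_plant", "Carica papaya", "Carica",
                         "host", c(70000L, 50000L), seed + 99L)
  member <- function(gid, frac, div) data.frame(
    genome_id = gid, read_fraction = frac, divergence = div,
    coverage_mode = "uniform", stringsAsFactors = FALSE)
  mk <- function(sid, fr, sseed) communityDesign(
    sid, do.call(rbind, Map(member, names(fr), unname(fr),
                            c(0.02, 0.03, 0.02, 0.03, 0.02, 0.03))),
    hostFraction = 0.10, unclassifiedFraction = 0.10, nReads = nReads,
    readLengthMean = 200, readLengthSd = 20, seed = sseed)
  designs <- list(
    mk("A1", c(ent_rogg = 0.40, pan_vaga = 0.20, leu_pseu = 0.12,
               mam_sciu = 0.03, chr_arto = 0.03, met_reuk = 0.02),
       seed + 1L),
    mk("A2", c(ent_rogg = 0.36, pan_vaga = 0.24, leu_pseu = 0.10,
               mam_sciu = 0.04, chr_arto = 0.04, met_reuk = 0.02),
       seed + 2L),
    mk("B1", c(ent_rogg = 0.04, pan_vaga = 0.06, leu_pseu = 0.03,
               mam_sciu = 0.30, chr_arto = 0.27, met_reuk = 0.10),
       seed + 3L),
    mk("B2", c(ent_rogg = 0.03, pan_vaga = 0.05, leu_pseu = 0.04,
               mam_sciu = 0.33, chr_arto = 0.24, met_reuk = 0.11),
       seed + 4L))
  groups <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  list(specs = specs, hostSpec = hostSpec, designs = designs,
       groups = groups)
}

stageOrder <- c("simulate", "trim", "deplete", "build-db", "recruit",
                "call", "diversity", "ordinate", "report")

requireStageFile <- function(path, stage, neededBy) {
  if (!file.exists(path))
    stop("stage '", neededBy, "' requires '", basename(path),
         "' produced by stage '", stage, "'; run that stage first")
  path
}

writeProvenance <- function(outdir, stage, inputs, outputs, cfg) {
  cfgFile <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg[order(names(cfg))], cfgFile)
  rec <- data.frame(
    stage = stage,
    version = as.character(utils::packageVersion("frpkit")),
    config_md5 = unname(tools::md5sum(cfgFile)),
    input_md5 = paste(unname(tools::md5sum(inputs[file.exists(inputs)])),
                      collapse = ","),
    outputs = paste(basename(outputs), collapse = ","),
    stringsAsFactors = FALSE)
  pf <- file.path(outdir, "provenance.tsv")
  utils::write.table(rec, pf, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !file.exists(pf), append = file.exists(pf))
  unlink(cfgFile)
}

#' Run the pipeline on the built-in synthetic study
#'
#' Orchestrates the stages in dependency order (simulate, trim, deplete,
#' build-db, recruit, call, diversity, ordinate, report) on the
#' demonstration study, exchanging data between stages through plain-text
#' files under \code{config$outdir}. Each stage appends a provenance record
#' (package version, configuration hash, input hashes) and reruns with an
#' identical configuration are byte-identical for the deterministic stages.
#'
#' @param config a [pipelineConfig()] object.
#' @param stages character vector of stages to run (default all, in order).
#' @param study a [demoStudy()]-shaped list; defaults to
#'   \code{demoStudy(config$seed)}.
#' @return invisibly, a named list of the output files written.
#' @export
runPipeline <- function(config = pipelineConfig(), stages = stageOrder,
                        study = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  bad <- setdiff(stages, stageOrder)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- stageOrder[stageOrder %in% stages]
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (is.null(study)) study <- demoStudy(config$seed)
  sids <- vapply(study$designs, function(d) d@sampleId, character(1))
  files <- list()
  p <- function(...) file.path(out, paste0(...))

  if ("simulate" %in% stages) {
    genomes <- generateGenomes(c(study$specs, list(study$hostSpec)))
    Biostrings::writeXStringSet(genomes, p("genomes.fasta"))
    utils::write.table(contigTable(genomes), p("contigs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    man <- manifestFromSpecs(study$specs)
    utils::write.table(man, p("representatives.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    reports <- list()
    for (i in seq_along(study$designs)) {
      d <- study$designs[[i]]
      sim <- simulateReads(d, genomes, hostId = genomeId(study$hostSpec))
      writeFastq(sim$reads, p(sids[i], ".fastq"))
      utils::write.table(sim$truth, p(sids[i], "_truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      aln <- simulateAlignments(sim$truth, genomes)
      hostContigs <- paste0(genomeId(study$hostSpec), "|",
                            seq_along(study$hostSpec@contigLengths))
      writeBlastTab(aln[aln$sseqid %in% hostContigs, , drop = FALSE],
                    p(sids[i], "_host_alignments.tsv"))
      writeBlastTab(aln[!aln$sseqid %in% hostContigs, , drop = FALSE],
                    p(sids[i], "_alignments.tsv"))
      # pseudo classifier reports: four methods with seeded jitter
      fr <- d@members
      gn <- man$genus[match(fr$genome_id, man$genome_id)]
      withr_seed(d@seed + 1000L, {
        rep4 <- do.call(rbind, lapply(paste0("method", 1:4), function(mth)
          data.frame(method = mth, sample_id = d@sampleId, genus = gn,
                     relative_abundance = pmax(0, 100 * fr$read_fraction *
                       stats::runif(length(gn), 0.8, 1.2)),
                     stringsAsFactors = FALSE)))
      })
      reports[[i]] <- rep4
    }
    utils::write.table(do.call(rbind, reports), p("classifier_reports.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeProvenance(out, "simulate", character(),
                    c("genomes.fasta", "contigs.tsv"), config)
  }

  if ("trim" %in% stages) {
    stats <- lapply(sids, function(s) {
      requireStageFile(p(s, ".fastq"), "simulate", "trim")
      trimFastq(p(s, ".fastq"), p(s, "_trimmed.fastq"),
                window = config$trimWindow, step = config$trimStep,
                minMeanQ = config$trimMinMeanQ,
                minEndQ = config$trimMinEndQ, minLen = config$trimMinLen)
    })
    st <- cbind(sample_id = sids, do.call(rbind, stats))
    utils::write.table(st, p("trim_stats.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeProvenance(out, "trim", p(sids, ".fastq"), "trim_stats.tsv",
                    config)
  }

  if ("deplete" %in% stages) {
    counts <- lapply(sids, function(s) {
      reads <- readFastq(requireStageFile(p(s, "_trimmed.fastq"), "trim",
                                          "deplete"))
      aln <- readBlastTab(requireStageFile(p(s, "_host_alignments.tsv"),
                                           "simulate", "deplete"))
      # reads dropped by trimming legitimately no longer exist
      aln <- aln[aln$qseqid %in% names(reads), , drop = FALSE]
      dep <- depleteHost(reads, aln, config$hostMinIdentity,
                         config$hostMinCoverage)
      writeFastq(dep$kept, p(s, "_depleted.fastq"))
      data.frame(sample_id = s, n_in = length(reads),
                 n_removed = dep$nRemoved, n_kept = length(dep$kept))
    })
    utils::write.table(do.call(rbind, counts), p("host_removal.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeProvenance(out, "deplete", p(sids, "_trimmed.fastq"),
                    "host_removal.tsv", config)
  }

  if ("build-db" %in% stages) {
    reports <- utils::read.delim(requireStageFile(
      p("classifier_reports.tsv"), "simulate", "build-db"))
    reps <- utils::read.delim(requireStageFile(
      p("representatives.tsv"), "simulate", "build-db"))
    genera <- selectGenera(reports, config$dbMinAbundance)
    man <- buildManifest(genera, reps)
    utils::write.table(man, p("db_manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeProvenance(out, "build-db", p("classifier_reports.tsv"),
                    "db_manifest.tsv", config)
  }

  if ("recruit" %in% stages || "call" %in% stages) {
    man <- utils::read.delim(requireStageFile(p("db_manifest.tsv"),
                                              "build-db", "recruit"))
    contigs <- utils::read.delim(requireStageFile(p("contigs.tsv"),
                                                  "simulate", "recruit"))
    trimStats <- utils::read.delim(requireStageFile(p("trim_stats.tsv"),
                                                    "trim", "recruit"))
    allCalls <- list()
    for (s in sids) {
      kept <- readFastq(requireStageFile(p(s, "_depleted.fastq"),
                                         "deplete", "recruit"))
      aln <- readBlastTab(requireStageFile(p(s, "_alignments.tsv"),
                                           "simulate", "recruit"))
      aln <- aln[aln$qseqid %in% names(kept), , drop = FALSE]
      profs <- recruitReads(aln, man, contigs,
                            config$recruitMinIdentity,
                            config$recruitMinCoverage, config$sdMode)
      denom <- if (config$denominator == "trimmed")
        trimStats$n_reads_out[trimStats$sample_id == s] else length(kept)
      tab <- presenceTable(profs, man, denom, config$presenceMinReads,
                           config$presenceMaxRsd)
      tab <- cbind(sample_id = s, tab)
      utils::write.table(tab, p(s, "_presence.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      allCalls[[s]] <- tab
    }
    calls <- do.call(rbind, allCalls)
    utils::write.table(calls, p("presence_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    # genus-level abundance table of recruited mass
    gn <- man$genus[match(calls$genome_id, man$genome_id)]
    wide <- tapply(calls$relative_abundance,
                   list(calls$sample_id, gn), sum, default = 0)
    utils::write.table(cbind(sample_id = rownames(wide), as.data.frame(wide)),
                       p("abundance_genus.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = sids, group = unname(study$groups[sids])),
      p("samples.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    writeProvenance(out, "recruit",
                    c(p("db_manifest.tsv"), p(sids, "_depleted.fastq")),
                    c("presence_calls.tsv", "abundance_genus.tsv"), config)
  }

  readAbundance <- function(neededBy) {
    f <- requireStageFile(p("abundance_genus.tsv"), "recruit/call",
                          neededBy)
    x <- utils::read.delim(f, check.names = FALSE)
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- x$sample_id
    abundanceTable(m, rank = "genus")
  }

  if ("diversity" %in% stages) {
    tab <- readAbundance("diversity")
    grp <- utils::read.delim(requireStageFile(p("samples.tsv"),
                                              "recruit/call", "diversity"))
    div <- diversityTable(tab)
    utils::write.table(div, p("diversity.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    d <- brayCurtisMatrix(tab)
    pv <- permanova(d, grp$group[match(rownames(d), grp$sample_id)],
                    config$nPermutations, config$seed)
    utils::write.table(
      data.frame(pseudo_F = pv$pseudoF, p_value = pv$pValue,
                 n_permutations = pv$nPermutations, seed = pv$seed),
      p("permanova.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    sim <- simperAnalysis(tab, grp$group[match(rownames(d),
                                               grp$sample_id)])
    simDf <- do.call(rbind, Map(function(nm, df)
      cbind(pair = nm, df), names(sim), sim))
    utils::write.table(simDf, p("simper.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeProvenance(out, "diversity", p("abundance_genus.tsv"),
                    c("diversity.tsv", "permanova.tsv", "simper.tsv"),
                    config)
  }

  if ("ordinate" %in% stages) {
    tab <- readAbundance("ordinate")
    ord <- pcaOrdination(tab, config$pcaMinAbundance)
    if (!ord$degenerate) {
      utils::write.table(
        cbind(sample_id = rownames(ord$scores),
              as.data.frame(ord$scores)),
        p("pca_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        cbind(taxon = rownames(ord$loadings),
              as.data.frame(ord$loadings),
              variance_explained = c(ord$varianceExplained,
                rep(NA, nrow(ord$loadings) -
                      length(ord$varianceExplained)))[
                        seq_len(nrow(ord$loadings))]),
        p("pca_loadings.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    writeProvenance(out, "ordinate", p("abundance_genus.tsv"),
                    c("pca_scores.tsv", "pca_loadings.tsv"), config)
  }

  if ("report" %in% stages) {
    man <- utils::read.delim(requireStageFile(p("db_manifest.tsv"),
                                              "build-db", "report"))
    contigs <- utils::read.delim(requireStageFile(p("contigs.tsv"),
                                                  "simulate", "report"))
    s <- sids[1]
    kept <- readFastq(requireStageFile(p(s, "_depleted.fastq"), "deplete",
                                       "report"))
    aln <- readBlastTab(requireStageFile(p(s, "_alignments.tsv"),
                                         "simulate", "report"))
    aln <- aln[aln$qseqid %in% names(kept), , drop = FALSE]
    best <- bestHit(aln, config$recruitMinIdentity,
                    config$recruitMinCoverage,
                    contigMap = contigs[, c("contig", "genome_id")])
    profs <- recruitReads(aln, man, contigs, config$recruitMinIdentity,
                          config$recruitMinCoverage, config$sdMode)
    top <- which.max(vapply(profs, nReads, integer(1)))
    renderFrp(profs[[top]], best, contigs,
              man$total_length[match(names(profs)[top], man$genome_id)],
              p(s, "_frp_", names(profs)[top], ".png"))
    reports <- utils::read.delim(requireStageFile(
      p("classifier_reports.tsv"), "simulate", "report"))
    rs <- reports[reports$sample_id == s, , drop = FALSE]
    assign4 <- data.frame(method = rs$method, label = rs$genus,
                          n_reads = round(rs$relative_abundance * 100))
    comp <- categorizeReport(assign4, 10000,
                             config$minorityThreshold)
    renderComposition(comp, p(s, "_composition.png"),
                      counts = tapply(assign4$n_reads, assign4$method,
                                      sum))
    writeProvenance(out, "report", p("presence_calls.tsv"),
                    c(paste0(s, "_frp.png"),
                      paste0(s, "_composition.png")), config)
  }
  invisible(list(outdir = out))
}
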