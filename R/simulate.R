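# Synthetic bacterial genomes with planted, annotated genes. Each organism
# draws its own codon-usage profile from a Dirichlet around a shared skewed
# base profile, so coding frames carry a learnable compositional signal that
# varies between organisms (held-out-organism evaluation stays nontrivial).
# True starts are marked by a Shine-Dalgarno-like hexamer at a fixed upstream
# offset; decoy in-frame start codons are planted upstream and downstream of
# true starts to create ambiguous TIS candidates.

allCodons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

senseCodons <- function() setdiff(allCodons(), STOP_CODONS)

# Fixed skewed base codon profile shared by all organisms (drawn once from a
# gamma prior under a constant internal seed; heavy skew emulates biased
# codon usage).
baseCodonProfile <- function() {
  w <- withSeed(104729L, rgamma(length(senseCodons()), shape = 0.6) + 1e-4)
  w / sum(w)
}

#' Simulation configuration
#'
#' @param nOrganisms number of organisms in the corpus.
#' @param genesPerGenome planted genes per genome.
#' @param genomeLen genome length in bp; must be at least
#'   \code{genesPerGenome * 300}.
#' @param gcContent GC fraction of the intergenic background.
#' @param codonBias Dirichlet concentration of the per-organism codon profile
#'   around the shared base profile; larger = less organism-to-organism
#'   variation.
#' @param nDecoyStarts expected planted in-frame alternative starts per gene
#'   (one in-body downstream decoy, plus an upstream decoy chain with
#'   probability \code{nDecoyStarts - 1}).
#' @param minGeneCodons,maxGeneCodons gene body length range in codons
#'   (excluding start and stop).
#' @param motif upstream hexamer planted before every true start.
#' @param motifOffset offset of the motif's 3' end relative to the start codon
#'   (default -8: an 8-nt gap, Shine-Dalgarno-like spacing).
#' @param seed base RNG seed for the corpus.
#' @return named configuration list.
#' @export
simConfig <- function(nOrganisms = 30L, genesPerGenome = 12L,
                      genomeLen = 12000L, gcContent = 0.5, codonBias = 30,
                      nDecoyStarts = 2, minGeneCodons = 100L,
                      maxGeneCodons = 250L, motif = "AGGAGG",
                      motifOffset = -8L, seed = 1L) {
  stopifnot(gcContent > 0, gcContent < 1,
            genomeLen >= genesPerGenome * 300L, nchar(motif) == 6L)
  list(n_organisms = as.integer(nOrganisms),
       genes_per_genome = as.integer(genesPerGenome),
       genome_len = as.integer(genomeLen), gc_content = gcContent,
       codon_bias = codonBias, n_decoy_starts = nDecoyStarts,
       min_gene_codons = as.integer(minGeneCodons),
       max_gene_codons = as.integer(maxGeneCodons), motif = motif,
       motif_offset = as.integer(motifOffset), seed = as.integer(seed))
}

#' @rdname simConfig
#' @param path YAML file whose keys match the [simConfig()] arguments.
#' @export
simConfigFromYaml <- function(path) {
  do.call(simConfig, yaml::read_yaml(path))
}

randomBackground <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

sampleStartCodon <- function() {
  sample(c("ATG", "GTG", "TTG"), 1L, prob = c(0.80, 0.15, 0.05))
}

# One oriented gene cassette: a 30-nt upstream flank (background, optional
# upstream decoy-start chain, then the motif overwrite) followed by the gene
# (start codon, biased sense-codon body with an optional planted in-body
# decoy start, stop codon). Returns the cassette string and the gene's
# 0-based interval within it.
geneCassette <- function(cfg, profile) {
  u <- 30L
  nCod <- sample(cfg$min_gene_codons:cfg$max_gene_codons, 1L)
  body <- sample(senseCodons(), nCod, replace = TRUE, prob = profile)
  if (cfg$n_decoy_starts >= 1)
    body[sample(3:10, 1L)] <- sampleStartCodon()   # downstream in-frame decoy
  gene <- paste0(sampleStartCodon(), paste(body, collapse = ""),
                 sample(STOP_CODONS, 1L))
  up <- strsplit(randomBackground(u, cfg$gc_content), "")[[1]]
  pUpDecoy <- min(1, max(0, cfg$n_decoy_starts - 1))
  if (runif(1) < pUpDecoy) {
    m <- sample(6:8, 1L)                           # chain length in codons
    chain <- c(sampleStartCodon(),
               sample(senseCodons(), m - 1L, replace = TRUE, prob = profile))
    up[(u - 3L * m + 1L):u] <- strsplit(paste(chain, collapse = ""), "")[[1]]
  }
  # motif 3' end sits |motifOffset| nt upstream of the start codon
  mEnd <- u + cfg$motif_offset
  up[(mEnd - 5L):mEnd] <- strsplit(cfg$motif, "")[[1]]
  list(cassette = paste0(paste(up, collapse = ""), gene),
       geneStart = u, geneEnd = u + nchar(gene))
}

#' Simulate one genome with planted, annotated genes
#'
#' Genes are placed sequentially on random strands with intergenic gaps of at
#' least 40 nt (so every true-TIS window fits inside the contig), separated by
#' i.i.d. background at the configured GC content. Returns the genome and its
#' ground-truth CDS annotations in the package-internal coordinate convention.
#'
#' @param cfg a [simConfig()] list.
#' @param organismId identifier recorded as the seqid.
#' @param seed RNG seed for this genome (defaults to \code{cfg$seed}).
#' @return list with \code{id}, \code{seq} and \code{cds} (data.frame:
#'   \code{seqid}, \code{start}, \code{end}, \code{strand}).
#' @export
simulateGenome <- function(cfg, organismId = "org01", seed = cfg$seed) {
  withSeed(seed, {
    alpha <- cfg$codon_bias * baseCodonProfile()
    profile <- rgamma(length(alpha), shape = alpha + 1e-9)
    profile <- profile / sum(profile)
    nGenes <- cfg$genes_per_genome
    cassettes <- replicate(nGenes, geneCassette(cfg, profile),
                           simplify = FALSE)
    strands <- sample(c("+", "-"), nGenes, replace = TRUE)
    clens <- vapply(cassettes, function(x) nchar(x$cassette), integer(1))
    minGap <- 40L
    free <- cfg$genome_len - sum(clens) - minGap * (nGenes + 1L)
    if (free < 0L)
      stop("simulateGenome: placement failed; increase genome_len")
    w <- runif(nGenes + 1L)
    extra <- floor(free * w / sum(w))
    extra[nGenes + 1L] <- extra[nGenes + 1L] + (free - sum(extra))
    gaps <- as.integer(minGap + extra)
    pieces <- character(2L * nGenes + 1L)
    cds <- vector("list", nGenes)
    pos <- 0L
    for (i in seq_len(nGenes)) {
      pieces[2L * i - 1L] <- randomBackground(gaps[i], cfg$gc_content)
      pos <- pos + gaps[i]
      cs <- cassettes[[i]]
      if (strands[i] == "+") {
        pieces[2L * i] <- cs$cassette
        gs <- pos + cs$geneStart; ge <- pos + cs$geneEnd
      } else {
        pieces[2L * i] <- revcompChr(cs$cassette)
        cl <- nchar(cs$cassette)
        gs <- pos + cl - cs$geneEnd; ge <- pos + cl - cs$geneStart
      }
      cds[[i]] <- data.frame(seqid = organismId, start = as.integer(gs),
                             end = as.integer(ge), strand = strands[i],
                             stringsAsFactors = FALSE)
      pos <- pos + nchar(cs$cassette)
    }
    pieces[2L * nGenes + 1L] <- randomBackground(gaps[nGenes + 1L],
                                                 cfg$gc_content)
    list(id = organismId, seq = paste(pieces, collapse = ""),
         cds = do.call(rbind, cds))
  })
}

# GFF3 lines for ground-truth CDS annotations.
simGffLines <- function(cds) {
  g <- internalToGff(cds$start, cds$end)
  sprintf("%s\tbactgene_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=gene%d",
          cds$seqid, g$start, g$end, cds$strand, seq_len(nrow(cds)))
}

#' Simulate a corpus of organisms
#'
#' One genome per organism; each organism draws a distinct codon-bias profile
#' so that held-out-organism generalization is nontrivial. Optionally writes
#' one FASTA and one GFF3 file per organism.
#'
#' @param cfg a [simConfig()] list.
#' @param outDir optional directory for \code{<org>.fna} / \code{<org>.gff}
#'   file pairs.
#' @return named list of [simulateGenome()] results, one per organism.
#' @export
simulateCorpus <- function(cfg, outDir = NULL) {
  stopifnot(cfg$n_organisms >= 3L)
  genomes <- lapply(seq_len(cfg$n_organisms), function(i)
    simulateGenome(cfg, sprintf("org%03d", i), seed = childSeed(cfg$seed, i)))
  names(genomes) <- vapply(genomes, `[[`, character(1), "id")
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (g in genomes) {
      dna <- Biostrings::DNAStringSet(g$seq)
      names(dna) <- g$id
      Biostrings::writeXStringSet(dna, file.path(outDir,
                                                 paste0(g$id, ".fna")))
      writeLines(c("##gff-version 3", simGffLines(g$cds)),
                 file.path(outDir, paste0(g$id, ".gff")))
    }
  }
  genomes
}

#' Build the two-stage training datasets from a simulated corpus
#'
#' Runs the full dataset-construction pipeline over every organism: ORF
#' extraction, stop-codon grouping, CDS labeling with length-matched negative
#' downsampling, TIS window construction with random undersampling, and
#' organism-held-out splitting.
#'
#' @param genomes list from [simulateCorpus()].
#' @param minLen minimum ORF length in bp.
#' @param flank TIS window flank in nt.
#' @param binWidth length-balancing bin width in bp.
#' @param fractions train/test/eval organism fractions.
#' @param seed RNG seed for balancing and splitting.
#' @return list with \code{cds} and \code{tis}, each a list with
#'   \code{train}, \code{test}, \code{eval} data.frames.
#' @export
buildCorpusDatasets <- function(genomes, minLen = 90L, flank = 30L,
                                binWidth = 50L, fractions = c(0.6, 0.2, 0.2),
                                seed = 1L) {
  cdsAll <- list(); tisAll <- list()
  for (g in genomes) {
    orfs <- extractOrfs(g$seq, g$id, minLen)
    groups <- groupOrfs(orfs)
    cdsAll[[g$id]] <- labelCds(groups, g$cds, organismId = g$id)
    tisAll[[g$id]] <- buildTisWindows(groups, g$cds, g$seq, flank,
                                      organismId = g$id)
  }
  cdsEx <- do.call(rbind, cdsAll)
  tisEx <- do.call(rbind, tisAll)
  cdsBal <- lengthBalance(cdsEx[cdsEx$label == 1L, , drop = FALSE],
                          cdsEx[cdsEx$label == 0L, , drop = FALSE],
                          binWidth, seed = childSeed(seed, 1L))
  tisBal <- undersample(tisEx, seed = childSeed(seed, 2L))
  list(cds = splitByOrganism(cdsBal, fractions, seed = childSeed(seed, 3L)),
       tis = splitByOrganism(tisBal, fractions, seed = childSeed(seed, 3L)))
}
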