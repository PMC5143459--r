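## Synthetic tRNA gene record sets with full ground-truth bookkeeping.
## The generator emulates the statistical structure the analysis assumes:
## per-genome gene sets with base-paired acceptor stems, class-dependent
## 1:72 motifs (initiators mismatched, mostly C1-A72; elongators almost
## always Watson-Crick/wobble), class-dependent probabilities of
## templating CCA at 74-76, trailer sequences, genomic context windows
## and taxonomy labels.

#' Configuration for the synthetic genome generator
#'
#' Defaults are the study conditions the analysis targets: initiator
#' genes carry a 1:72 mismatch dominated by C1-A72 (probability 0.775)
#' with a rare U1:A72 Watson-Crick match (0.015); elongator genes carry
#' a Watson-Crick or wobble 1:72 pair with probability 0.995; initiator
#' genes template CCA at probability 0.741 and elongators at 0.662.
#' Gene bodies are random with fixed length 55 (no introns or split
#' genes).
#'
#' @param genomes data.frame with `genome_id`, `taxon_id`, `genome_size`;
#'   by default 8 genomes of 2-8 Mbp spread over 4 genera in 2 phyla
#'   (with a matching `lineage`).
#' @param lineage lineage data.frame covering the genome taxa (see
#'   [readLineageTable()] for the columns).
#' @param geneCounts named integer vector of genes per class emitted in
#'   every genome, or a matrix with one row per genome (rownames =
#'   genome ids).
#' @param pCCA named per-class probabilities of templating CCA; classes
#'   not named fall back to `pCCAElongDefault`.
#' @param pCCAElongDefault default elongator templating probability.
#' @param iniC1A72,iniU1A72 initiator 1:72 motif probabilities (C1-A72
#'   mismatch and U1:A72 match; the remainder is spread uniformly over
#'   the other mismatches).
#' @param elongWCWobble probability that an elongator 1:72 pair is
#'   Watson-Crick or wobble.
#' @param bodyLength gene body length between the acceptor strands.
#' @param pTrailerCCA probability that the 74-76 triplet sits in the
#'   trailer rather than inside the annotated gene end.
#' @param pAcc3Missing probability that a record omits its 3'
#'   acceptor-strand annotation (`acc3_pos = "."`), disabling the
#'   annotation bonus for that record.
#' @return a `syntheticConfig` list.
#' @seealso [simulateGenomes()], [simulateTrainingAlignment()]
#' @export
syntheticConfig <- function(genomes = NULL, lineage = NULL,
                            geneCounts = c(Ini = 2L, Met = 6L, kIle = 2L,
                                           Tyr = 8L, Asp = 8L, Glu = 8L),
                            pCCA = c(Ini = 0.741),
                            pCCAElongDefault = 0.662,
                            iniC1A72 = 0.775, iniU1A72 = 0.015,
                            elongWCWobble = 0.995,
                            bodyLength = 55L,
                            pTrailerCCA = 0.1,
                            pAcc3Missing = 0) {
  if (is.null(genomes)) {
    def <- .defaultTaxonomy(8L)
    genomes <- def$genomes
    if (is.null(lineage)) lineage <- def$lineage
  }
  stopifnot(all(c("genome_id", "taxon_id", "genome_size") %in%
                names(genomes)))
  probs <- c(iniC1A72, iniU1A72, elongWCWobble, pTrailerCCA, pAcc3Missing,
             pCCA, pCCAElongDefault)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (iniC1A72 + iniU1A72 > 1)
    stop("initiator 1:72 motif probabilities exceed 1")
  if (is.matrix(geneCounts)) {
    stopifnot(!is.null(rownames(geneCounts)),
              all(genomes$genome_id %in% rownames(geneCounts)))
  } else stopifnot(!is.null(names(geneCounts)))
  if (any(geneCounts < 0)) stop("gene counts must be >= 0")
  structure(list(genomes = genomes, lineage = lineage,
                 geneCounts = geneCounts, pCCA = pCCA,
                 pCCAElongDefault = pCCAElongDefault,
                 iniC1A72 = iniC1A72, iniU1A72 = iniU1A72,
                 elongWCWobble = elongWCWobble,
                 bodyLength = as.integer(bodyLength),
                 pTrailerCCA = pTrailerCCA,
                 pAcc3Missing = pAcc3Missing),
            class = "syntheticConfig")
}

.defaultTaxonomy <- function(nGenomes, nPhyla = 2L, generaPerPhylum = 2L) {
  phyla <- data.frame(taxon_id = 10L + seq_len(nPhyla) - 1L,
                      rank = "phylum",
                      name = paste0("Phylum", seq_len(nPhyla)),
                      parent_taxon_id = 1L)
  nGen <- nPhyla * generaPerPhylum
  genera <- data.frame(taxon_id = 100L + seq_len(nGen) - 1L,
                       rank = "genus",
                       name = paste0("Genus", seq_len(nGen)),
                       parent_taxon_id = rep(phyla$taxon_id,
                                             each = generaPerPhylum))
  gidx <- rep_len(seq_len(nGen), nGenomes)
  species <- data.frame(taxon_id = 1000L + seq_len(nGenomes) - 1L,
                        rank = "species",
                        name = paste0("Species", seq_len(nGenomes)),
                        parent_taxon_id = genera$taxon_id[gidx])
  lineage <- rbind(
    data.frame(taxon_id = 1L, rank = "no rank", name = "root",
               parent_taxon_id = 1L),
    phyla, genera, species)
  genomes <- data.frame(
    genome_id = sprintf("GENOME%02d", seq_len(nGenomes)),
    taxon_id = species$taxon_id,
    genome_size = round(seq(2e6, 8e6, length.out = nGenomes)))
  list(genomes = genomes, lineage = lineage)
}

.classPCCA <- function(config, cl) {
  if (cl %in% names(config$pCCA)) unname(config$pCCA[cl])
  else config$pCCAElongDefault
}

.draw172 <- function(config, isIni) {
  if (isIni) {
    u <- stats::runif(1)
    if (u < config$iniC1A72) return(c("C", "A"))
    if (u < config$iniC1A72 + config$iniU1A72) return(c("U", "A"))
    other <- .MISMATCH_COMBOS[!(.MISMATCH_COMBOS$b1 == "C" &
                                .MISMATCH_COMBOS$b2 == "A"), ]
    k <- sample.int(nrow(other), 1L)
    c(other$b1[k], other$b2[k])
  } else {
    if (stats::runif(1) < config$elongWCWobble) {
      k <- sample.int(nrow(.PAIRING_SET), 1L)
      .PAIRING_SET[k, ]
    } else {
      k <- sample.int(nrow(.MISMATCH_COMBOS), 1L)
      c(.MISMATCH_COMBOS$b1[k], .MISMATCH_COMBOS$b2[k])
    }
  }
}

.randomBases <- function(n) paste(sample(.RNA_BASES, n, replace = TRUE),
                                  collapse = "")

.randomNonCCA <- function() {
  repeat {
    t3 <- .randomBases(3L)
    if (t3 != "CCA") return(t3)
  }
}

#' Generate the tRNA gene records of one genome
#'
#' Each emitted gene carries a 7-bp complementary acceptor stem whose
#' 1:72 pair is drawn from the class motif distribution, a random body,
#' the 3' acceptor strand, a discriminator, then CCA with the class
#' templating probability (else a random non-CCA triplet) placed either
#' inside the gene end or at the start of the trailer, plus 10-base
#' genomic contexts. All ground truths are recorded.
#'
#' @param config a [syntheticConfig()].
#' @param genomeIndex row of `config$genomes` to generate.
#' @param seed integer master seed; the genome's substream is derived
#'   from it and a hash of the genome id, so genome order is irrelevant.
#' @return list with `records` (gene-record data.frame in the
#'   [readGeneRecords()] dialect) and `truth` (per-record true class,
#'   templating flag, 1:72 pair and 66-76 placement).
#' @export
simulateGenome <- function(config, genomeIndex, seed) {
  gm <- config$genomes[genomeIndex, ]
  set.seed((as.integer(seed) + .stringHash(gm$genome_id)) %% 2147483647L)
  cnts <- if (is.matrix(config$geneCounts))
    config$geneCounts[gm$genome_id, ] else config$geneCounts
  classes <- rep(names(cnts), times = cnts)
  if (!length(classes)) {
    warning("genome ", gm$genome_id, " has zero genes")
    return(list(records = NULL, truth = NULL))
  }
  recs <- vector("list", length(classes))
  truths <- vector("list", length(classes))
  bl <- config$bodyLength
  for (g in seq_along(classes)) {
    cl <- classes[g]
    isIni <- cl == "Ini"
    m <- .draw172(config, isIni)
    stem5 <- c(m[1L], .splitBases(.randomBases(6L)))
    ## 3' strand 5'->3' is Sprinzl 66..72 = partners of stem 7..1
    stem3 <- c(.wcComplement(stem5[7:2]), m[2L])
    body <- .randomBases(bl)
    disc <- .randomBases(1L)
    templ <- stats::runif(1) < .classPCCA(config, cl)
    triplet <- if (templ) "CCA" else .randomNonCCA()
    inTrailer <- stats::runif(1) < config$pTrailerCCA
    core <- paste0(paste(stem5, collapse = ""), body,
                   paste(stem3, collapse = ""), disc)
    if (inTrailer) {
      gene <- core
      downstream <- paste0(triplet, .randomBases(7L))
    } else {
      gene <- paste0(core, triplet)
      downstream <- .randomBases(10L)
    }
    acc3start <- 7L + bl + 1L
    acc3 <- if (stats::runif(1) < config$pAcc3Missing) "." else
      paste(acc3start:(acc3start + 6L), collapse = ",")
    rid <- sprintf("%s_t%03d", gm$genome_id, g)
    recs[[g]] <- data.frame(
      record_id = rid,
      genome_id = gm$genome_id,
      taxon_id = gm$taxon_id,
      gene_seq = gene,
      upstream = .randomBases(10L),
      downstream = downstream,
      anticodon = if (cl %in% c("Ini", "Met", "kIle")) "CAU" else
        .randomBases(3L),
      prior_class = cl,
      acc5_pos = paste(1:7, collapse = ","),
      acc3_pos = acc3
    )
    truths[[g]] <- data.frame(
      record_id = rid,
      genome_id = gm$genome_id,
      class = cl,
      templates_cca = templ,
      b1 = m[1L], b72 = m[2L],
      pair_1_72 = pairCategory(m[1L], m[2L]),
      pos66 = acc3start, pos72 = acc3start + 6L, pos73 = acc3start + 7L,
      source74_76 = if (inTrailer) "trailer" else "gene",
      pos74 = if (inTrailer) 1L else acc3start + 8L
    )
  }
  list(records = do.call(rbind, recs), truth = do.call(rbind, truths))
}

#' Generate a full synthetic dataset of genomes
#'
#' Runs [simulateGenome()] over every configured genome. Identical seed
#' and configuration give byte-identical output, and per-genome RNG
#' substreams are derived from the genome id, so the genome order in the
#' configuration does not affect any genome's genes.
#'
#' @param config a [syntheticConfig()].
#' @param seed integer master seed.
#' @return list with `records`, `truth`, `lineage`, `genomeSizes`.
#' @examples
#' sim <- simulateGenomes(syntheticConfig(), seed = 1)
#' head(sim$records[, c("record_id", "prior_class", "anticodon")])
#' @export
simulateGenomes <- function(config, seed) {
  stopifnot(inherits(config, "syntheticConfig"))
  per <- lapply(seq_len(nrow(config$genomes)),
                function(i) simulateGenome(config, i, seed))
  records <- do.call(rbind, lapply(per, `[[`, "records"))
  truth <- do.call(rbind, lapply(per, `[[`, "truth"))
  rownames(records) <- rownames(truth) <- NULL
  list(records = records, truth = truth,
       lineage = config$lineage,
       genomeSizes = data.frame(genome_id = config$genomes$genome_id,
                                size_bp = config$genomes$genome_size))
}

## Class consensus over the Sprinzl frame for the three CAU classes.
## Discriminative columns: 1:72 motif, 11:24 D-stem pair, 29-31/39-41
## anticodon stem; anticodon 34-36 is CAU for all three; the shared
## acceptor stem is complementary; 74-76 reads CCA in the frame.
.classConsensus <- function(cl) {
  spec <- switch(cl,
    Ini = list(b1 = "C", b72 = "A", d = c("A", "U"),
               ac = c("G", "G", "G"), ac2 = c("C", "C", "C")),
    Met = list(b1 = "G", b72 = "U", d = c("C", "G"),
               ac = c("U", "C", "A"), ac2 = c("U", "G", "A")),
    kIle = list(b1 = "G", b72 = "C", d = c("C", "G"),
                ac = c("C", "G", "A"), ac2 = c("U", "C", "G")),
    stop("no built-in consensus for class ", cl))
  stem5 <- c(spec$b1, "G", "C", "G", "G", "A", "U")
  stem3 <- c(.wcComplement(stem5[7:2]), spec$b72)
  cons <- c(stem5,                  # 1-7
            spec$d,                 # 11, 24
            spec$ac,                # 29-31
            c("C", "A", "U"),       # 34-36 anticodon
            spec$ac2,               # 39-41
            stem3,                  # 66-72
            "A",                    # 73 discriminator
            c("C", "C", "A"))       # 74-76
  names(cons) <- sprinzlColumns()
  cons
}

#' Generate labelled aligned training/test sequences
#'
#' Emits fixed-length sequences over the [sprinzlColumns()] frame with a
#' class-specific consensus (distinct at the 1:72, 11:24 and
#' anticodon-stem motif columns) and independent per-column noise: with
#' probability `noise` a column is replaced by a uniformly random base.
#'
#' @param nPerClass sequences per class (at least 5 for training use).
#' @param noise per-column substitution probability (default 0.05).
#' @param seed integer seed.
#' @param classes class labels (default the three CAU classes).
#' @param consensus optional named list of consensus vectors (length 29)
#'   overriding the built-ins, e.g. to give two classes identical
#'   consensus.
#' @return data.frame with `record_id`, `class`, `seq`.
#' @examples
#' tr <- simulateTrainingAlignment(nPerClass = 10, noise = 0.05, seed = 1)
#' table(tr$class)
#' @export
simulateTrainingAlignment <- function(nPerClass, noise = 0.05, seed = 1,
                                      classes = c("Ini", "Met", "kIle"),
                                      consensus = NULL) {
  stopifnot(nPerClass >= 1L, noise >= 0, noise <= 1)
  set.seed(as.integer(seed))
  width <- length(sprinzlColumns())
  out <- lapply(classes, function(cl) {
    cons <- if (!is.null(consensus)) consensus[[cl]] else .classConsensus(cl)
    stopifnot(length(cons) == width)
    seqs <- vapply(seq_len(nPerClass), function(k) {
      b <- cons
      hit <- stats::runif(width) < noise
      if (any(hit)) b[hit] <- sample(.RNA_BASES, sum(hit), replace = TRUE)
      paste(b, collapse = "")
    }, character(1))
    data.frame(record_id = sprintf("%s_%04d", cl, seq_len(nPerClass)),
               class = cl, seq = seqs)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
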