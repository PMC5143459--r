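## Aggregation of per-gene CCA-templating calls to genomes and clades,
## and the four phyletic patterns (all/none/initiator-/elongator-
## predominant templating).

#' Summarise CCA-templating per genome and functional class
#'
#' @param genes data.frame with one row per gene: `genome_id`,
#'   `taxon_id`, `class`, `templates_cca` (logical). All multi-copy genes
#'   count individually.
#' @param genomeSizes data.frame with `genome_id`, `size_bp` (as from
#'   [readGenomeSizes()]).
#' @param missingInitiator optional named logical vector per genome (e.g.
#'   from [detectMissingInitiator()] run on classifier output); by default
#'   a genome is flagged when it has no gene of class `Ini`.
#' @return data.frame with one row per genome x class: `genome_id`,
#'   `taxon_id`, `genome_size`, `class`, `n_genes`, `n_templating`,
#'   `missing_initiator`.
#' @export
summarizeGenomes <- function(genes, genomeSizes, missingInitiator = NULL) {
  stopifnot(all(c("genome_id", "taxon_id", "class", "templates_cca") %in%
                names(genes)))
  agg <- stats::aggregate(
    cbind(n_genes = rep(1L, nrow(genes)),
          n_templating = as.integer(genes$templates_cca)),
    by = list(genome_id = genes$genome_id, taxon_id = genes$taxon_id,
              class = genes$class),
    FUN = sum)
  agg$genome_size <-
    genomeSizes$size_bp[match(agg$genome_id, genomeSizes$genome_id)]
  if (is.null(missingInitiator)) {
    hasIni <- tapply(genes$class == "Ini", genes$genome_id, any)
    missingInitiator <- !hasIni
  }
  agg$missing_initiator <-
    as.logical(missingInitiator[as.character(agg$genome_id)])
  agg <- agg[order(agg$genome_id, agg$class),
             c("genome_id", "taxon_id", "genome_size", "class",
               "n_genes", "n_templating", "missing_initiator")]
  rownames(agg) <- NULL
  agg
}

#' Ancestor of a taxon at a given rank
#'
#' Walks the lineage table from `taxonId` to the root and returns the
#' first ancestor (including the taxon itself) whose rank matches.
#'
#' @param lineage lineage data.frame (see [readLineageTable()]).
#' @param taxonId integer taxon id(s).
#' @param rank target rank (e.g. "genus", "phylum").
#' @return integer vector of ancestor taxon ids (NA when unresolvable).
#' @export
ancestorAtRank <- function(lineage, taxonId, rank) {
  vapply(taxonId, function(tid) {
    seen <- integer(0)
    while (!is.na(tid) && !(tid %in% seen)) {
      row <- match(tid, lineage$taxon_id)
      if (is.na(row)) return(NA_integer_)
      if (identical(lineage$rank[row], rank)) return(tid)
      seen <- c(seen, tid)
      tid <- lineage$parent_taxon_id[row]
    }
    NA_integer_
  }, integer(1))
}

#' Roll genome summaries up to clades at a taxonomic rank
#'
#' Groups genomes by their ancestor at `rank` and reports, per clade and
#' class, the pooled (gene-weighted) CCA-templating frequency
#' `sum(templating)/sum(genes)` and, optionally, the unweighted mean of
#' per-genome frequencies; genome size is averaged unweighted over member
#' genomes. Classes are ordered by decreasing pooled frequency over the
#' whole input. Genomes whose taxon does not resolve at `rank` are
#' excluded with a warning.
#'
#' @param summaries genome summaries from [summarizeGenomes()].
#' @param lineage lineage data.frame.
#' @param rank taxonomic rank to aggregate at.
#' @param freq `"pooled"` (gene-weighted, default) or `"genome_mean"`
#'   (unweighted mean of per-genome frequencies).
#' @return data.frame with one row per clade x class: `clade`, `rank`,
#'   `clade_taxon_id`, `n_genomes`, `mean_genome_size`, `class`,
#'   `n_genes`, `n_templating`, `freq`.
#' @export
rollupClades <- function(summaries, lineage, rank, freq = c("pooled",
                                                            "genome_mean")) {
  freq <- match.arg(freq)
  anc <- ancestorAtRank(lineage, summaries$taxon_id, rank)
  if (any(is.na(anc))) {
    bad <- unique(summaries$genome_id[is.na(anc)])
    warning("excluding ", length(bad),
            " genome(s) with taxa unresolvable at rank ", rank)
  }
  keep <- !is.na(anc)
  s <- summaries[keep, , drop = FALSE]
  s$clade_taxon_id <- anc[keep]
  if (!nrow(s)) stop("no genome resolves at rank ", rank)
  perGenome <- unique(s[, c("clade_taxon_id", "genome_id", "genome_size")])
  gStats <- stats::aggregate(
    cbind(n_genomes = rep(1L, nrow(perGenome)),
          sum_size = perGenome$genome_size),
    by = list(clade_taxon_id = perGenome$clade_taxon_id), FUN = sum)
  s$gfreq <- ifelse(s$n_genes > 0, s$n_templating / s$n_genes, NA_real_)
  agg <- stats::aggregate(
    cbind(n_genes = s$n_genes, n_templating = s$n_templating,
          sum_gfreq = s$gfreq, n_gfreq = as.integer(!is.na(s$gfreq))),
    by = list(clade_taxon_id = s$clade_taxon_id, class = s$class),
    FUN = sum, na.rm = TRUE)
  agg$freq <- if (freq == "pooled") agg$n_templating / agg$n_genes
  else agg$sum_gfreq / agg$n_gfreq
  gi <- match(agg$clade_taxon_id, gStats$clade_taxon_id)
  agg$n_genomes <- gStats$n_genomes[gi]
  agg$mean_genome_size <- gStats$sum_size[gi] / gStats$n_genomes[gi]
  li <- match(agg$clade_taxon_id, lineage$taxon_id)
  agg$clade <- lineage$name[li]
  agg$rank <- rank
  ## order classes by decreasing overall pooled frequency
  overall <- stats::aggregate(
    cbind(t = agg$n_templating, n = agg$n_genes),
    by = list(class = agg$class), FUN = sum)
  overall <- overall[order(-(overall$t / overall$n)), ]
  agg$class <- factor(agg$class, levels = overall$class)
  agg <- agg[order(agg$clade, agg$class),
             c("clade", "rank", "clade_taxon_id", "n_genomes",
               "mean_genome_size", "class", "n_genes", "n_templating",
               "freq")]
  agg$class <- as.character(agg$class)
  rownames(agg) <- NULL
  agg
}

#' Call the phyletic CCA-templating pattern of a clade
#'
#' Classifies a clade into one of four patterns from its pooled
#' initiator and elongator CCA-templating frequencies: `all_template`
#' (both at least `high`), `none_template` (both below `low`),
#' `initiator_predominant` (initiator at least `high` and elongator less
#' than half the initiator frequency), `elongator_predominant`
#' (elongator at least `high` and initiator below `low`). Rules are
#' tried in that order; when none matches exactly, the rule with the
#' smallest total threshold violation wins.
#'
#' @param iniFreq pooled initiator CCA-templating frequency in `[0, 1]`.
#' @param elongFreq pooled elongator frequency in `[0, 1]`.
#' @param high,low fraction thresholds (defaults 0.5 and 0.10; the low
#'   threshold separates "intermediate" from background frequencies).
#' @return character(1) pattern label.
#' @examples
#' callPattern(0.917, 0.034)  # initiator_predominant
#' callPattern(0.0, 0.60)     # elongator_predominant
#' @export
callPattern <- function(iniFreq, elongFreq, high = 0.5, low = 0.10) {
  stopifnot(length(iniFreq) == 1L, length(elongFreq) == 1L,
            is.finite(iniFreq), is.finite(elongFreq))
  if (iniFreq >= high && elongFreq >= high) return("all_template")
  if (iniFreq < low && elongFreq < low) return("none_template")
  if (iniFreq >= high && elongFreq < iniFreq / 2)
    return("initiator_predominant")
  if (elongFreq >= high && iniFreq < low) return("elongator_predominant")
  ## nearest rule: smallest total violation, ties to the listed order
  viol <- c(
    all_template = max(0, high - iniFreq) + max(0, high - elongFreq),
    none_template = max(0, iniFreq - low) + max(0, elongFreq - low),
    initiator_predominant = max(0, high - iniFreq) +
      max(0, elongFreq - iniFreq / 2),
    elongator_predominant = max(0, high - elongFreq) +
      max(0, iniFreq - low))
  names(viol)[which.min(viol)]
}

#' Pattern calls for a clade rollup table
#'
#' Computes, per clade, the pooled initiator frequency and the pooled
#' frequency over all non-initiator (elongator) classes, then applies
#' [callPattern()]. Clades with no initiator genes are called from the
#' elongator side alone (initiator frequency taken as 0) and flagged.
#'
#' @param rollup data.frame from [rollupClades()].
#' @param high,low thresholds passed to [callPattern()].
#' @return data.frame with one row per clade: `clade`, `ini_freq`,
#'   `elong_freq`, `pattern`, `no_initiator_flag`.
#' @export
cladePatterns <- function(rollup, high = 0.5, low = 0.10) {
  clades <- unique(rollup$clade)
  out <- lapply(clades, function(cl) {
    sub <- rollup[rollup$clade == cl, , drop = FALSE]
    ini <- sub[sub$class == "Ini", , drop = FALSE]
    elo <- sub[sub$class != "Ini", , drop = FALSE]
    noIni <- !nrow(ini) || sum(ini$n_genes) == 0
    iniFreq <- if (noIni) 0 else sum(ini$n_templating) / sum(ini$n_genes)
    elongFreq <- if (sum(elo$n_genes) > 0)
      sum(elo$n_templating) / sum(elo$n_genes) else 0
    data.frame(clade = cl, ini_freq = iniFreq, elong_freq = elongFreq,
               pattern = callPattern(iniFreq, elongFreq, high, low),
               no_initiator_flag = noIni)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
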