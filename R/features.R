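## Structural feature extraction over the Sprinzl alignment frame and
## class-by-feature contingency tables (1:72 acceptor pair, 11:24 D-stem
## pair, 29-31/39-41 anticodon-stem triplets).

#' Category of a juxtaposed base pair
#'
#' Watson-Crick for A:U/U:A/C:G/G:C, wobble for G:U/U:G, absent when
#' either side is a gap, mismatch otherwise (ambiguity codes count as
#' mismatches). The three residue categories partition all 16 base
#' combinations: 4 Watson-Crick, 2 wobble, 10 mismatches.
#'
#' @param b1,b2 single characters (base or "-").
#' @return one of "WatsonCrick", "wobble", "mismatch", "absent".
#' @examples
#' pairCategory("C", "A")  # mismatch (the classic initiator C1-A72)
#' pairCategory("U", "A")  # WatsonCrick
#' pairCategory("G", "U")  # wobble
#' @export
pairCategory <- function(b1, b2) {
  b1 <- normalizeRNA(b1); b2 <- normalizeRNA(b2)
  if (b1 == "-" || b2 == "-") return("absent")
  if (any(b1 == .WC_SET[, 1L] & b2 == .WC_SET[, 2L])) return("WatsonCrick")
  if (any(b1 == .WOBBLE_SET[, 1L] & b2 == .WOBBLE_SET[, 2L])) return("wobble")
  "mismatch"
}

## position of a Sprinzl coordinate label in the alignment frame
.frameIndex <- function(coord, columns = sprinzlColumns()) {
  idx <- match(as.character(coord), columns)
  if (any(is.na(idx)))
    stop("coordinate(s) not in the alignment frame: ",
         paste(coord[is.na(idx)], collapse = ", "))
  idx
}

#' Extract a coordinate-pair feature from one aligned sequence
#'
#' @param seq character(1), aligned sequence over the
#'   [sprinzlColumns()] frame.
#' @param leftCoord,rightCoord Sprinzl coordinates of the two partners
#'   (e.g. 1 and 72, or 11 and 24).
#' @return list with `label` (e.g. `"1:72"`), `bases` (the two residues),
#'   and `category` (see [pairCategory()]).
#' @examples
#' tr <- simulateTrainingAlignment(nPerClass = 5, noise = 0, seed = 1)
#' extractPair(tr$seq[tr$class == "Ini"][1], 1, 72)
#' @export
extractPair <- function(seq, leftCoord, rightCoord) {
  b <- .splitBases(normalizeRNA(seq))
  idx <- .frameIndex(c(leftCoord, rightCoord))
  bases <- b[idx]
  list(label = paste(leftCoord, rightCoord, sep = ":"),
       bases = bases,
       category = pairCategory(bases[1L], bases[2L]))
}

## feature value string of one sequence for a feature spec
.featureValue <- function(bases, spec) {
  if (spec$type == "pair") {
    idx <- .frameIndex(c(spec$left, spec$right))
    paste(bases[idx], collapse = ":")
  } else {
    li <- .frameIndex(spec$left)
    ri <- .frameIndex(spec$right)
    paste(paste(bases[li], collapse = ""),
          paste(bases[ri], collapse = ""), sep = ",")
  }
}

#' Feature specifications for tabulation
#'
#' `pairFeature()` describes a single base pair (e.g. 1:72 or 11:24);
#' `stemFeature()` a pair of coordinate runs read as juxtaposed strands
#' (e.g. 29-31 with 39-41).
#'
#' @param left,right Sprinzl coordinate (scalar for `pairFeature`,
#'   vector for `stemFeature`).
#' @return a feature spec list for [tabulateFeatures()].
#' @export
pairFeature <- function(left, right) {
  list(type = "pair", left = left, right = right,
       label = paste(left, right, sep = ":"))
}

#' @rdname pairFeature
#' @export
stemFeature <- function(left, right) {
  list(type = "stem", left = left, right = right,
       label = paste(paste(range(left), collapse = "-"),
                     paste(range(right), collapse = "-"), sep = ","))
}

#' Tabulate a structural feature against functional classes
#'
#' Counts each observed feature value (rows) per class label (columns).
#' Gapped coordinates yield feature values containing "-" and are counted
#' in their own rows. Tabulation is permutation-invariant and additive
#' over disjoint sequence sets.
#'
#' @param aligned data.frame with `class` and `seq` columns (uniform
#'   alignment frame).
#' @param feature a spec from [pairFeature()] or [stemFeature()].
#' @return a [ContingencyTable-class], rows ordered by decreasing total.
#' @examples
#' tr <- simulateTrainingAlignment(nPerClass = 10, noise = 0, seed = 1)
#' tabulateFeatures(tr, pairFeature(1, 72))
#' @export
tabulateFeatures <- function(aligned, feature) {
  stopifnot(all(c("class", "seq") %in% names(aligned)))
  mat <- .alignedMatrix(aligned)
  vals <- apply(mat, 1L, .featureValue, spec = feature)
  tab <- table(value = vals, class = aligned$class)
  m <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m <- m[order(-rowSums(m)), , drop = FALSE]
  ContingencyTable(m)
}

#' Derived percentage from a contingency table
#'
#' 100 x (sum of numerator-row cells) / (sum of denominator-row cells)
#' over the given column(s), rounded half-up to one decimal, as used for
#' statements like "the C1-A72 share of 1:72-mismatched initiators".
#'
#' @param table a [ContingencyTable-class].
#' @param numeratorRows,denominatorRows character vectors of row labels
#'   (subsets of the table rows).
#' @param cols character vector of column labels (default all columns).
#' @return numeric(1) percentage with one decimal.
#' @examples
#' t2 <- readCountTable(system.file("extdata", "table2_pair_1_72.tsv",
#'                                  package = "trnacca"))
#' mism <- setdiff(rownames(counts(t2)), "U:A")
#' derivedFraction(t2, "C:A", mism, "Ini")
#' @export
derivedFraction <- function(table, numeratorRows, denominatorRows,
                            cols = colnames(counts(table))) {
  m <- counts(table)
  missRow <- setdiff(c(numeratorRows, denominatorRows), rownames(m))
  if (length(missRow))
    stop("row label(s) not in table: ", paste(missRow, collapse = ", "))
  missCol <- setdiff(cols, colnames(m))
  if (length(missCol))
    stop("column label(s) not in table: ", paste(missCol, collapse = ", "))
  num <- sum(m[numeratorRows, cols, drop = FALSE])
  den <- sum(m[denominatorRows, cols, drop = FALSE])
  if (den == 0) stop("zero denominator")
  roundHalfUp(100 * num / den, 1L)
}
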