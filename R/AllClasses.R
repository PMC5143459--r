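#' @import methods
NULL

#' Scoring scheme for the acceptor 3'-end aligner
#'
#' Parameters of the semi-global dynamic program that pairs the reversed
#' 5' acceptor-stem heptamer against the annotated 3' end plus trailer.
#' A Watson-Crick or wobble (G-U/U-G) juxtaposition scores `matchScore`,
#' any other juxtaposition `mismatchScore`, and a gap extends linearly at
#' `gapPenalty` per residue. `annotationBonus` is added on top of the pair
#' score whenever the juxtaposed residues were annotated as a stem pair in
#' the source record (see the `bonusMask` of [buildAlignmentMatrix()]).
#'
#' @slot matchScore integer, score of a paired juxtaposition (default 4).
#' @slot mismatchScore integer, score of any other juxtaposition (default 1).
#' @slot gapPenalty integer, linear gap penalty (default -5).
#' @slot annotationBonus integer, bonus for database-annotated pairs
#'   (default 1; set 0 to disable).
#'
#' @examples
#' ScoringScheme()
#' ScoringScheme(annotationBonus = 0)
#' @export
setClass("ScoringScheme",
  representation(
    matchScore = "integer",
    mismatchScore = "integer",
    gapPenalty = "integer",
    annotationBonus = "integer"
  ),
  prototype(
    matchScore = 4L,
    mismatchScore = 1L,
    gapPenalty = -5L,
    annotationBonus = 1L
  )
)

setValidity("ScoringScheme", function(object) {
  msg <- character()
  if (!(object@matchScore > object@mismatchScore))
    msg <- c(msg, "matchScore must exceed mismatchScore")
  if (!(object@mismatchScore > object@gapPenalty))
    msg <- c(msg, "mismatchScore must exceed gapPenalty")
  if (object@annotationBonus < 0L)
    msg <- c(msg, "annotationBonus must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn ScoringScheme-class Constructor.
#' @param matchScore,mismatchScore,gapPenalty,annotationBonus see slots.
#' @return A `ScoringScheme` object.
#' @export
ScoringScheme <- function(matchScore = 4L, mismatchScore = 1L,
                          gapPenalty = -5L, annotationBonus = 1L) {
  new("ScoringScheme",
    matchScore = as.integer(matchScore),
    mismatchScore = as.integer(mismatchScore),
    gapPenalty = as.integer(gapPenalty),
    annotationBonus = as.integer(annotationBonus))
}

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme: pair =", object@matchScore,
      "/ other =", object@mismatchScore,
      "/ gap =", object@gapPenalty,
      "/ annotation bonus =", object@annotationBonus, "\n")
})

#' Sprinzl 3'-end annotation of one tRNA gene record
#'
#' Result of [assignSprinzl3prime()]: the mapping of 3'-region residues to
#' Sprinzl coordinates 66-76, the aligned acceptor-stem pairs, and the
#' optimal alignment score. Coordinates 66-72 come from the stem pairing
#' (a gapped stem position leaves its coordinate "absent"); 73 is the
#' discriminator and 74-76 the (potential) CCA template, taken as the up
#' to four residues following the alignment end. Each assigned residue is
#' tagged by whether it lies inside the annotated gene span or in the
#' 3' trailer.
#'
#' @slot recordId character(1).
#' @slot coords data.frame with columns `sprinzl` (66:76), `base`
#'   (residue or "-" when absent), `source` ("gene", "trailer" or
#'   "absent"), `yIndex` (index into the aligned 3'-region string y, NA
#'   when absent).
#' @slot pairs integer matrix with columns `i` (index into the reversed
#'   stem heptamer x) and `j` (index into y); one row per diagonally
#'   aligned pair.
#' @slot score numeric(1), optimal alignment score.
#' @slot usedBonus logical(1), whether any annotation bonus was applied.
#' @slot status character(1), one of "ok", "truncated", "unannotatable".
#' @export
setClass("SprinzlAnnotation",
  representation(
    recordId = "character",
    coords = "data.frame",
    pairs = "matrix",
    score = "numeric",
    usedBonus = "logical",
    status = "character"
  )
)

setValidity("SprinzlAnnotation", function(object) {
  msg <- character()
  cd <- object@coords
  if (!identical(cd$sprinzl, 66:76))
    msg <- c(msg, "coords must have one row per Sprinzl coordinate 66:76")
  if (!all(cd$source %in% c("gene", "trailer", "absent")))
    msg <- c(msg, "coords$source must be gene/trailer/absent")
  if (!object@status %in% c("ok", "truncated", "unannotatable"))
    msg <- c(msg, "status must be ok/truncated/unannotatable")
  yi <- cd$yIndex[!is.na(cd$yIndex)]
  if (is.unsorted(yi, strictly = TRUE))
    msg <- c(msg, "assigned y indices must be strictly increasing in Sprinzl order")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SprinzlAnnotation", function(object) {
  cat("SprinzlAnnotation for record", object@recordId,
      "(", object@status, ")\n")
  cat("  score:", object@score,
      if (object@usedBonus) "(with annotation bonus)" else "", "\n")
  b <- sprinzlCoords(object)
  cat("  66-72:", paste(b$base[b$sprinzl <= 72], collapse = ""), "\n")
  cat("  73-76:", paste(b$base[b$sprinzl >= 73], collapse = ""),
      " templates CCA:", templatesCCA(object), "\n")
})

#' Labelled contingency table with margins
#'
#' A matrix of non-negative integer counts with row and column labels,
#' as used for the reannotation confusion matrix and the structural
#' feature tables. Margins are computed, not stored.
#'
#' @slot counts integer matrix with dimnames.
#' @export
setClass("ContingencyTable", representation(counts = "matrix"))

setValidity("ContingencyTable", function(object) {
  cts <- object@counts
  msg <- character()
  if (!is.numeric(cts))
    msg <- c(msg, "counts must be numeric")
  else {
    if (any(is.na(cts)) || any(cts < 0) || any(cts != round(cts)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (is.null(rownames(cts)) || is.null(colnames(cts)))
    msg <- c(msg, "counts must have row and column labels")
  if (length(msg)) msg else TRUE
})

#' @describeIn ContingencyTable-class Constructor from a labelled matrix.
#' @param counts labelled matrix of non-negative integer counts.
#' @return A `ContingencyTable`.
#' @export
ContingencyTable <- function(counts) {
  storage.mode(counts) <- "double"
  new("ContingencyTable", counts = counts)
}

setMethod("show", "ContingencyTable", function(object) {
  m <- object@counts
  out <- rbind(cbind(m, Sum = rowSums(m)),
               Sum = c(colSums(m), sum(m)))
  cat("ContingencyTable:", nrow(m), "x", ncol(m), "\n")
  print(out)
})

#' Per-class position-specific log-odds profile models
#'
#' One log-odds matrix per functional class (rows = symbols A,C,G,U and
#' the gap "-", columns = alignment frame columns), trained by
#' [trainProfiles()], with the pooled background composition and the
#' training-set size per class.
#'
#' @slot logOdds named list, one `symbols x columns` matrix (bits) per class.
#' @slot background named numeric, smoothed pooled symbol composition.
#' @slot trainingSizes named integer, sequences per class.
#' @slot pseudocount numeric(1).
#' @slot columns character, alignment frame column labels.
#' @export
setClass("ProfileModelSet",
  representation(
    logOdds = "list",
    background = "numeric",
    trainingSizes = "integer",
    pseudocount = "numeric",
    columns = "character"
  )
)

setValidity("ProfileModelSet", function(object) {
  msg <- character()
  if (is.null(names(object@logOdds)) || anyDuplicated(names(object@logOdds)))
    msg <- c(msg, "logOdds must be a uniquely named list of class matrices")
  nc <- length(object@columns)
  ok <- vapply(object@logOdds, function(m)
    is.matrix(m) && nrow(m) == 5L && ncol(m) == nc && all(is.finite(m)),
    logical(1))
  if (!all(ok))
    msg <- c(msg, "each class matrix must be finite with 5 symbol rows and one column per frame column")
  if (object@pseudocount <= 0)
    msg <- c(msg, "pseudocount must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProfileModelSet", function(object) {
  cat("ProfileModelSet:", paste(names(object@logOdds), collapse = ", "), "\n")
  cat("  frame columns:", length(object@columns),
      "| pseudocount:", object@pseudocount, "\n")
  cat("  training sizes:",
      paste(names(object@trainingSizes), object@trainingSizes,
            sep = "=", collapse = ", "), "\n")
})
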