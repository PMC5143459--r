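## Semi-global dynamic programming over the 3' acceptor region.
##
## x = reversed 5'-most acceptor-stem heptamer (m = 7), y = last 12
## annotated gene bases followed by the first 5 trailer bases (n = 17).
## Boundary row and column of H are zero; interior cells take
## max(D, U, L) with D = H[i-1, j-1] + s(x_i, y_j) + a(i, j),
## U = H[i-1, j] + g, L = H[i, j-1] + g, with no floor at zero. The
## traceback starts at the maximum of the final row (smallest column on
## ties), so all of x is consumed while y may extend 3'-ward into the
## discriminator, 74-76 and trailer.

#' Base-pair score of two juxtaposed residues
#'
#' Watson-Crick pairs and the G-U/U-G wobble pairs score
#' `matchScore` (default 4); every other juxtaposition scores
#' `mismatchScore` (default 1).
#'
#' @param b1,b2 single RNA bases (A, C, G or U; T accepted as U).
#' @param scheme a [ScoringScheme-class].
#' @return integer score.
#' @examples
#' pairScore("G", "C")  # 4
#' pairScore("G", "U")  # wobble, 4
#' pairScore("A", "C")  # 1
#' @export
pairScore <- function(b1, b2, scheme = ScoringScheme()) {
  b1 <- normalizeRNA(b1); b2 <- normalizeRNA(b2)
  if (!all(c(b1, b2) %in% .RNA_BASES))
    stop("pairScore: bases must be one of A, C, G, U")
  if (any(b1 == .PAIRING_SET[, 1L] & b2 == .PAIRING_SET[, 2L]))
    scheme@matchScore else scheme@mismatchScore
}

## Vectorised, tolerant variant: ambiguity codes (N etc.) score as
## mismatches, never as pairs.
.pairScoreVec <- function(b1, b2, scheme) {
  paired <- paste(b1, b2) %in% paste(.PAIRING_SET[, 1L], .PAIRING_SET[, 2L])
  ifelse(paired, scheme@matchScore, scheme@mismatchScore)
}

#' Fill the alignment matrix of the 3'-end dynamic program
#'
#' @param x character(1) or character vector: the reversed acceptor-stem
#'   heptamer (so `x[1]` is stem position 7 and `x[m]` stem position 1).
#' @param y character(1) or character vector: the 3'-end region, 5' to 3'.
#' @param scheme a [ScoringScheme-class].
#' @param bonusMask optional `length(x) x length(y)` logical matrix; TRUE
#'   where the database annotated the juxtaposed gene positions as a stem
#'   pair, adding `annotationBonus` to the diagonal move. NULL = no bonus.
#' @return an object of class `AlignmentMatrix`: a list with the
#'   `(m+1) x (n+1)` score matrix `H` (zero boundary in row/column 0),
#'   the traceback pointer matrix `ptr` (0 boundary, 1 diagonal, 2 up,
#'   3 left), and the inputs.
#' @seealso [bestAlignment()]
#' @export
buildAlignmentMatrix <- function(x, y, scheme = ScoringScheme(),
                                 bonusMask = NULL) {
  x <- normalizeRNA(if (length(x) == 1L) .splitBases(x) else x)
  y <- normalizeRNA(if (length(y) == 1L) .splitBases(y) else y)
  m <- length(x); n <- length(y)
  if (!m || !n) stop("x and y must be non-empty")
  if (!all(x %in% .RNA_BASES))
    stop("x must contain only A, C, G, U")
  if (is.null(bonusMask)) bonusMask <- matrix(FALSE, m, n)
  stopifnot(identical(dim(bonusMask), c(m, n)))
  g <- scheme@gapPenalty
  a <- scheme@annotationBonus
  H <- matrix(0, m + 1L, n + 1L)
  ptr <- matrix(0L, m + 1L, n + 1L)
  for (i in seq_len(m)) {
    s_row <- .pairScoreVec(rep(x[i], n), y, scheme) +
      ifelse(bonusMask[i, ], a, 0L)
    for (j in seq_len(n)) {
      D <- H[i, j] + s_row[j]
      U <- H[i, j + 1L] + g
      L <- H[i + 1L, j] + g
      best <- max(D, U, L)
      H[i + 1L, j + 1L] <- best
      ## preference at ties: diagonal, then up, then left
      ptr[i + 1L, j + 1L] <- if (D == best) 1L else if (U == best) 2L else 3L
    }
  }
  structure(list(H = H, ptr = ptr, x = x, y = y, scheme = scheme,
                 bonusMask = bonusMask),
            class = "AlignmentMatrix")
}

#' @export
print.AlignmentMatrix <- function(x, ...) {
  cat("AlignmentMatrix:", length(x$x), "x", length(x$y),
      "| last-row optimum:", max(x$H[nrow(x$H), ]), "\n")
  invisible(x)
}

#' Trace back the optimal semi-global alignment
#'
#' Starts at the maximum cell of the final row (all stem bases consumed;
#' ties broken toward the smallest column) and walks pointers preferring
#' diagonal, then up, then left at equal-score steps.
#'
#' @param mat an `AlignmentMatrix` from [buildAlignmentMatrix()].
#' @return list with `score` (numeric), `pairs` (integer matrix, columns
#'   `i`/`j`, the diagonally aligned index pairs) and `jEnd` (the final-row
#'   column at which the traceback started; 0 when the empty alignment is
#'   optimal).
#' @export
bestAlignment <- function(mat) {
  H <- mat$H; ptr <- mat$ptr
  m <- nrow(H) - 1L; n <- ncol(H) - 1L
  lastRow <- H[m + 1L, ]
  jEnd <- which.max(lastRow) - 1L   # which.max returns the first (smallest j)
  score <- lastRow[jEnd + 1L]
  i <- m; j <- jEnd
  pairs <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j")))
  while (i > 0L && j > 0L) {
    p <- ptr[i + 1L, j + 1L]
    if (p == 1L) {
      pairs <- rbind(c(i = i, j = j), pairs)
      i <- i - 1L; j <- j - 1L
    } else if (p == 2L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(score = score, pairs = pairs, jEnd = jEnd)
}

## Assemble x, y and bookkeeping for one record row.
.alignmentProblem <- function(record) {
  gene <- normalizeRNA(record$gene_seq)
  glen <- nchar(gene)
  a5 <- .parsePosList(record$acc5_pos)
  stopifnot(length(a5) == 7L)
  stem5 <- substring(gene, a5, a5)
  x <- rev(stem5)                       # x[7] is stem position 1
  nGene <- min(12L, glen)
  genePos <- seq.int(glen - nGene + 1L, glen)
  down <- normalizeRNA(record$downstream)
  trailer <- .splitBases(substr(down, 1L, 5L))
  y <- c(.splitBases(substr(gene, genePos[1L], glen)), trailer)
  ySource <- c(rep("gene", nGene), rep("trailer", length(trailer)))
  yGenePos <- c(genePos, rep(NA_integer_, length(trailer)))
  a3 <- .parsePosList(record$acc3_pos)
  bonusMask <- matrix(FALSE, 7L, length(y))
  if (length(a3) == 7L) {
    ## a3 is ordered 5'->3' along the gene, i.e. Sprinzl 66..72, the
    ## partners of stem positions 7..1 = x[1]..x[7]
    for (i in 1:7) bonusMask[i, ] <- !is.na(yGenePos) & yGenePos == a3[i]
  }
  list(x = x, y = y, bonusMask = bonusMask, ySource = ySource,
       yGenePos = yGenePos, truncated = glen < 12L)
}

#' Assign Sprinzl coordinates 66-76 to the 3' end of a gene record
#'
#' Pairs the reversed 5' acceptor-stem heptamer against the last 12
#' annotated gene bases plus the first 5 trailer bases. The partner of
#' stem position 1 receives Sprinzl coordinate 72 (and so on down to 66
#' for stem position 7); the four residues following the alignment end
#' receive 73 (discriminator) and 74-76, each tagged `gene` or `trailer`
#' by whether it falls inside the annotated gene span. The acceptor stem
#' itself is never re-annotated; only 3'-end coordinates are assigned.
#'
#' @param record one gene-record row (as from [readGeneRecords()]).
#' @param scheme a [ScoringScheme-class].
#' @param useBonus logical(1); apply the annotation bonus where the record
#'   carries a 3' acceptor-strand annotation (`acc3_pos`). With no such
#'   annotation the bonus mask is empty and results equal a no-bonus run.
#' @return a [SprinzlAnnotation-class].
#' @examples
#' recs <- simulateGenomes(syntheticConfig(), seed = 1)$records
#' ann <- assignSprinzl3prime(recs[1, ])
#' sprinzlCoords(ann)
#' templatesCCA(ann)
#' @export
assignSprinzl3prime <- function(record, scheme = ScoringScheme(),
                                useBonus = TRUE) {
  prob <- .alignmentProblem(record)
  mask <- if (useBonus) prob$bonusMask else
    matrix(FALSE, 7L, length(prob$y))
  mat <- buildAlignmentMatrix(prob$x, prob$y, scheme, mask)
  aln <- bestAlignment(mat)
  coords <- data.frame(
    sprinzl = 66:76,
    base = "-",
    source = "absent",
    yIndex = NA_integer_
  )
  status <- if (prob$truncated) "truncated" else "ok"
  if (aln$jEnd == 0L || nrow(aln$pairs) == 0L) {
    status <- "unannotatable"
  } else {
    ## x index i corresponds to stem position 8 - i, partner Sprinzl 65 + i
    for (r in seq_len(nrow(aln$pairs))) {
      i <- aln$pairs[r, "i"]; j <- aln$pairs[r, "j"]
      row <- match(65L + i, coords$sprinzl)
      coords$base[row] <- prob$y[j]
      coords$source[row] <- prob$ySource[j]
      coords$yIndex[row] <- j
    }
    ## 73-76: the up-to-four residues after the traceback start column
    after <- aln$jEnd + 1:4
    ok <- after <= length(prob$y)
    rows <- match(73:76, coords$sprinzl)
    coords$base[rows[ok]] <- prob$y[after[ok]]
    coords$source[rows[ok]] <- prob$ySource[after[ok]]
    coords$yIndex[rows[ok]] <- after[ok]
  }
  new("SprinzlAnnotation",
      recordId = as.character(record$record_id),
      coords = coords,
      pairs = aln$pairs,
      score = as.numeric(aln$score),
      usedBonus = any(mask) && scheme@annotationBonus > 0L,
      status = status)
}

#' Annotate a set of gene records and call CCA-templating
#'
#' Runs [assignSprinzl3prime()] over every record and collects the
#' 73-76 residues, their sources, the alignment score and the
#' CCA-templating call into one table.
#'
#' @param records data.frame of gene records.
#' @param scheme a [ScoringScheme-class].
#' @param useBonus logical(1), see [assignSprinzl3prime()].
#' @return data.frame with one row per record: `record_id`, `genome_id`,
#'   `taxon_id`, `prior_class`, `score`, `base73`-`base76`,
#'   `source74_76` ("gene", "trailer", "mixed" or "absent"),
#'   `templates_cca`, `status`.
#' @export
annotateRecords <- function(records, scheme = ScoringScheme(),
                            useBonus = TRUE) {
  n <- NROW(records)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    ann <- assignSprinzl3prime(records[k, ], scheme, useBonus)
    cd <- ann@coords
    b <- cd$base[match(73:76, cd$sprinzl)]
    src <- cd$source[match(74:76, cd$sprinzl)]
    src74_76 <- if (all(src == "absent")) "absent"
      else if (all(src[src != "absent"] == "gene")) "gene"
      else if (all(src[src != "absent"] == "trailer")) "trailer"
      else "mixed"
    out[[k]] <- data.frame(
      record_id = records$record_id[k],
      genome_id = records$genome_id[k],
      taxon_id = records$taxon_id[k],
      prior_class = records$prior_class[k],
      score = ann@score,
      base73 = b[1L], base74 = b[2L], base75 = b[3L], base76 = b[4L],
      source74_76 = src74_76,
      templates_cca = templatesCCA(ann),
      status = ann@status
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
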