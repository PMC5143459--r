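## Profile log-odds classification of CAU-anticodon tRNA genes into
## initiator (Ini), elongator methionine (Met) and lysidinylated
## isoleucine (kIle), the stage that a profile-based tRNA functional
## classifier performs on structurally aligned sequences. Gaps are a
## fifth symbol with their own pseudocount.

.PROFILE_SYMBOLS <- c("A", "C", "G", "U", "-")

#' Sprinzl alignment frame used by the classifier and feature tables
#'
#' The fixed column frame of aligned sequences: acceptor-stem 5' strand
#' (1-7), D-stem pair partners 11 and 24, anticodon-stem strands 29-31
#' and 39-41, the anticodon 34-36, and the 3' region 66-76.
#'
#' @return character vector of 29 Sprinzl coordinate labels.
#' @export
sprinzlColumns <- function() {
  as.character(c(1:7, 11, 24, 29:31, 34:36, 39:41, 66:76))
}

## character matrix (sequences x columns) from an aligned set
.alignedMatrix <- function(aligned) {
  stopifnot(all(c("record_id", "seq") %in% names(aligned)))
  lens <- nchar(aligned$seq)
  if (length(unique(lens)) > 1L)
    stop("aligned sequences must all have the same length")
  m <- do.call(rbind, strsplit(normalizeRNA(aligned$seq), "", fixed = TRUE))
  rownames(m) <- aligned$record_id
  m
}

.frameColumns <- function(width) {
  if (width == length(sprinzlColumns())) sprinzlColumns()
  else paste0("col", seq_len(width))
}

#' Train per-class position-specific log-odds profiles
#'
#' For each class and alignment column, the symbol probability is the
#' pseudocount-smoothed within-class frequency; the log-odds (bits) are
#' taken against the pooled, equally smoothed symbol composition of the
#' whole training set. Gap ("-") is a fifth symbol.
#'
#' @param training data.frame with columns `record_id`, `class`, `seq`
#'   (aligned strings over A/C/G/U/-, all the same length); at least two
#'   classes with at least 5 sequences each.
#' @param pseudocount positive smoothing count per symbol per column
#'   (default 1).
#' @return a [ProfileModelSet-class].
#' @examples
#' tr <- simulateTrainingAlignment(nPerClass = 20, noise = 0.05, seed = 1)
#' models <- trainProfiles(tr)
#' modelClasses(models)
#' @export
trainProfiles <- function(training, pseudocount = 1) {
  stopifnot(all(c("record_id", "class", "seq") %in% names(training)))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  mat <- .alignedMatrix(training)
  classes <- sort(unique(training$class))
  if (length(classes) < 2L)
    stop("training set must contain at least two classes")
  sizes <- table(training$class)
  small <- names(sizes)[sizes < 5L]
  if (length(small))
    stop("class with fewer than 5 training sequences: ",
         paste(small, collapse = ", "))
  nSym <- length(.PROFILE_SYMBOLS)
  bgCount <- vapply(.PROFILE_SYMBOLS, function(s) sum(mat == s), numeric(1))
  if (sum(bgCount) != length(mat))
    stop("aligned sequences may contain only A, C, G, U and '-'")
  ## per-class smoothed probability matrices
  probs <- lapply(classes, function(cl) {
    sub <- mat[training$class == cl, , drop = FALSE]
    cnt <- vapply(seq_len(ncol(sub)), function(j)
      vapply(.PROFILE_SYMBOLS, function(s) sum(sub[, j] == s), numeric(1)),
      numeric(nSym))
    (cnt + pseudocount) / (nrow(sub) + nSym * pseudocount)
  })
  names(probs) <- classes
  ## background: pooled training composition under the same smoothing,
  ## i.e. the class-size-weighted mean of the smoothed model columns, so
  ## a symbol absent from every column scores log-odds ~ 0, not a bonus
  w <- as.numeric(sizes[classes]) / sum(sizes[classes])
  background <- Reduce(`+`, Map(function(p, wc) wc * rowMeans(p), probs, w))
  names(background) <- .PROFILE_SYMBOLS
  lo <- lapply(probs, function(p) {
    m <- log2(p / background)
    dimnames(m) <- list(.PROFILE_SYMBOLS, .frameColumns(ncol(p)))
    m
  })
  new("ProfileModelSet",
      logOdds = lo,
      background = background,
      trainingSizes = stats::setNames(as.integer(sizes[classes]), classes),
      pseudocount = as.numeric(pseudocount),
      columns = .frameColumns(ncol(mat)))
}

## score a character matrix under one class matrix; unknown symbols
## (ambiguity codes) contribute 0 bits
.scoreMatrix <- function(mat, lo) {
  idx <- match(mat, rownames(lo))
  contrib <- matrix(0, nrow(mat), ncol(mat))
  colIdx <- matrix(rep(seq_len(ncol(mat)), each = nrow(mat)), nrow(mat))
  known <- !is.na(idx)
  contrib[known] <- lo[cbind(idx[known], colIdx[known])]
  rowSums(contrib)
}

#' Score aligned sequences under every class profile
#'
#' The score of a sequence under a class is the sum over alignment
#' columns of that class's log-odds for the observed symbol (bits).
#'
#' @param models a [ProfileModelSet-class].
#' @param aligned data.frame with `record_id`, `seq` (lengths must match
#'   the model frame).
#' @return numeric matrix, one row per sequence, one column per class.
#' @export
scoreSequences <- function(models, aligned) {
  mat <- .alignedMatrix(aligned)
  if (ncol(mat) != length(models@columns))
    stop("sequence length does not match the model frame (",
         length(models@columns), " columns)")
  res <- vapply(models@logOdds, function(lo) .scoreMatrix(mat, lo),
                numeric(nrow(mat)))
  res <- matrix(res, nrow = nrow(mat),
                dimnames = list(rownames(mat), names(models@logOdds)))
  res
}

#' Per-class background score distributions from shuffled sequences
#'
#' Shuffles the residues within each scored sequence `nShuffle` times
#' (seed-fixed) and scores the shuffles under every class model, giving
#' a null distribution of scores per class against which observed scores
#' can be standardised.
#'
#' @param models a [ProfileModelSet-class].
#' @param aligned data.frame of the sequences being scored.
#' @param nShuffle shuffles of the sequence set (default 1000).
#' @param seed integer seed for the shuffles.
#' @return data.frame with one row per class: `class`, `mean`, `sd`.
#' @export
backgroundDistribution <- function(models, aligned, nShuffle = 1000,
                                   seed = 1) {
  mat <- .alignedMatrix(aligned)
  if (ncol(mat) != length(models@columns))
    stop("sequence length does not match the model frame")
  classes <- names(models@logOdds)
  sums <- stats::setNames(numeric(length(classes)), classes)
  sqs <- sums
  nTot <- 0L
  set.seed(seed)
  for (b in seq_len(nShuffle)) {
    shuf <- t(apply(mat, 1L, sample))
    for (cl in classes) {
      sc <- .scoreMatrix(shuf, models@logOdds[[cl]])
      sums[cl] <- sums[cl] + sum(sc)
      sqs[cl] <- sqs[cl] + sum(sc^2)
    }
    nTot <- nTot + nrow(mat)
  }
  mu <- sums / nTot
  sdv <- sqrt(pmax(sqs / nTot - mu^2, 0)) * sqrt(nTot / (nTot - 1))
  data.frame(class = classes, mean = unname(mu), sd = unname(sdv))
}

#' Classify aligned CAU-anticodon sequences
#'
#' Assigns each sequence the class with the maximal profile score;
#' results whose margin over the runner-up falls below `marginMin` are
#' flagged ambiguous (the best class is retained). When
#' `backgroundShuffles > 0`, a shuffle-based background distribution is
#' estimated per class and each call is standardised against the
#' background of its best class (`background_z`).
#'
#' @param models a [ProfileModelSet-class].
#' @param aligned data.frame with `record_id`, `seq` (and optionally
#'   `class`, carried through as `prior_class`).
#' @param marginMin bits; ambiguity threshold (default 1).
#' @param backgroundShuffles shuffles for the background distribution
#'   (default 1000; 0 skips it and `background_z` is NA).
#' @param seed integer seed for the background shuffles.
#' @return data.frame with `record_id`, per-class score columns
#'   (`score_<class>`), `best_class`, `margin`, `ambiguous`,
#'   `background_z`.
#' @examples
#' tr <- simulateTrainingAlignment(nPerClass = 20, noise = 0.05, seed = 1)
#' models <- trainProfiles(tr)
#' te <- simulateTrainingAlignment(nPerClass = 5, noise = 0.05, seed = 2)
#' head(classifySequences(models, te, backgroundShuffles = 50))
#' @export
classifySequences <- function(models, aligned, marginMin = 1,
                              backgroundShuffles = 1000, seed = 1) {
  sc <- scoreSequences(models, aligned)
  ord <- t(apply(sc, 1L, sort, decreasing = TRUE))
  bestIdx <- apply(sc, 1L, which.max)
  best <- colnames(sc)[bestIdx]
  margin <- if (ncol(sc) > 1L) ord[, 1L] - ord[, 2L] else rep(Inf, nrow(sc))
  z <- rep(NA_real_, nrow(sc))
  if (backgroundShuffles > 0L) {
    bg <- backgroundDistribution(models, aligned, backgroundShuffles, seed)
    bi <- match(best, bg$class)
    z <- (sc[cbind(seq_len(nrow(sc)), bestIdx)] - bg$mean[bi]) / bg$sd[bi]
  }
  res <- data.frame(record_id = aligned$record_id,
                    best_class = best,
                    margin = as.numeric(margin),
                    ambiguous = margin < marginMin,
                    background_z = z)
  scdf <- as.data.frame(sc)
  names(scdf) <- paste0("score_", colnames(sc))
  rownames(scdf) <- NULL
  if ("class" %in% names(aligned)) res$prior_class <- aligned$class
  cbind(res, scdf)
}

#' Reconcile new CAU-anticodon calls with prior annotations
#'
#' Only CAU-anticodon classes (Ini, Met, kIle) are ever revised;
#' canonical elongator, Sec and Pyl labels pass through untouched. A
#' previously annotated initiator whose new call disagrees raises a
#' warning (initiator labels are expected to be stable).
#'
#' @param priorClass character vector of prior labels.
#' @param newClass character vector of classifier calls (same length).
#' @return character vector of reconciled labels.
#' @export
reconcileAnnotations <- function(priorClass, newClass) {
  stopifnot(length(priorClass) == length(newClass))
  cau <- c("Ini", "Met", "kIle", "Unspecified")
  out <- priorClass
  revise <- priorClass %in% cau
  if (any(priorClass == "Ini" & newClass != "Ini" & revise))
    warning("previously annotated initiator gene(s) reassigned by the classifier")
  out[revise] <- newClass[revise]
  out
}

#' Does a genome lack a viable initiator-tRNA gene candidate?
#'
#' TRUE when no gene in the genome is called initiator (`Ini`) with a
#' background z-score of at least `zMin`, i.e. every putative initiator
#' scores inside the shuffle background distribution of the initiator
#' model.
#'
#' @param results classification results for one genome (data.frame from
#'   [classifySequences()], with `background_z`).
#' @param zMin minimal standardised score for a viable candidate
#'   (default 5).
#' @return logical(1).
#' @export
detectMissingInitiator <- function(results, zMin = 5) {
  if (!NROW(results)) {
    warning("empty gene list: treating genome as missing its initiator")
    return(TRUE)
  }
  viable <- results$best_class == "Ini" &
    !is.na(results$background_z) & results$background_z >= zMin
  !any(viable)
}
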