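## Reannotation confusion-matrix summaries, class-level CCA-templating
## frequencies, and the G-test of independence.

#' Summarise a reannotation confusion matrix
#'
#' Rows are prior labels (including `Unspecified`, alias `???`), columns
#' the classifier's labels. Revised genes are the off-diagonal counts
#' over previously annotated rows; newly annotated genes are the whole
#' `Unspecified` row.
#'
#' @param confusion a [ContingencyTable-class] whose rows include the
#'   column labels plus `Unspecified` (or `???`).
#' @return list with `n_previously_annotated`, `n_revised`,
#'   `revised_fraction` (percent), `n_newly_annotated`,
#'   `newly_annotated_fraction` (percent of the grand total),
#'   `grand_total`.
#' @examples
#' t1 <- readCountTable(system.file("extdata", "table1_reannotation.tsv",
#'                                  package = "trnacca"))
#' reannotationStats(t1)
#' @export
reannotationStats <- function(confusion) {
  m <- counts(confusion)
  rn <- rownames(m)
  rn[rn == "???"] <- "Unspecified"
  rownames(m) <- rn
  if (!"Unspecified" %in% rn)
    stop("confusion matrix must contain an Unspecified (or ???) row")
  if (!all(colnames(m) %in% rn))
    stop("every column label must appear among the prior-label rows")
  annotated <- setdiff(rn, "Unspecified")
  nPrev <- sum(m[annotated, , drop = FALSE])
  offDiag <- 0
  for (r in annotated) for (cc in colnames(m))
    if (r != cc) offDiag <- offDiag + m[r, cc]
  nNew <- sum(m["Unspecified", ])
  total <- sum(m)
  list(
    n_previously_annotated = nPrev,
    n_revised = offDiag,
    revised_fraction = 100 * offDiag / nPrev,
    n_newly_annotated = nNew,
    newly_annotated_fraction = 100 * nNew / total,
    grand_total = total
  )
}

#' G-test of independence on a contingency table
#'
#' Likelihood-ratio statistic `G = 2 * sum(O * ln(O / E))` with expected
#' counts from the margins; zero observed cells contribute zero. The
#' p-value comes from the chi-square distribution with
#' `(rows - 1) * (cols - 1)` degrees of freedom. No continuity
#' correction; Williams' correction is available but off by default.
#'
#' @param table numeric matrix of non-negative counts (typically 2x2) or
#'   a [ContingencyTable-class].
#' @param williams logical(1), divide G by Williams' correction factor.
#' @return list with `G`, `df`, `p`.
#' @examples
#' gTest2x2(matrix(c(10, 90, 90, 10), 2))
#' @export
gTest2x2 <- function(table, williams = FALSE) {
  m <- if (is(table, "ContingencyTable")) counts(table) else as.matrix(table)
  if (any(m < 0) || any(is.na(m))) stop("cells must be non-negative counts")
  rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in contingency table")
  E <- outer(rs, cs) / N
  terms <- ifelse(m > 0, m * log(m / E), 0)
  G <- 2 * sum(terms)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  if (williams) {
    q <- 1 + ((N * sum(1 / rs) - 1) * (N * sum(1 / cs) - 1)) / (6 * N * df)
    G <- G / q
  }
  list(G = G, df = df, p = stats::pchisq(G, df, lower.tail = FALSE))
}

#' Pooled CCA-templating frequency per functional class
#'
#' Pools gene and templating counts over genomes per class and reports
#' frequencies in decreasing order, with an `All` row pooled over the
#' included classes (the count-weighted mean of the class rows).
#'
#' @param summaries genome summaries from [summarizeGenomes()].
#' @param classes optional class filter (default: all classes present).
#' @return data.frame with `class`, `n_templating`, `n_genes`, `freq`,
#'   sorted by decreasing `freq`, with a final `All` row.
#' @export
classFrequencies <- function(summaries, classes = NULL) {
  if (!NROW(summaries)) stop("empty summary set")
  s <- summaries
  if (!is.null(classes)) s <- s[s$class %in% classes, , drop = FALSE]
  if (!nrow(s)) stop("no genes left after class filtering")
  agg <- stats::aggregate(
    cbind(n_templating = s$n_templating, n_genes = s$n_genes),
    by = list(class = s$class), FUN = sum)
  agg$freq <- agg$n_templating / agg$n_genes
  agg <- agg[order(-agg$freq), ]
  all <- data.frame(class = "All",
                    n_templating = sum(agg$n_templating),
                    n_genes = sum(agg$n_genes),
                    freq = sum(agg$n_templating) / sum(agg$n_genes))
  res <- rbind(agg, all)
  rownames(res) <- NULL
  res
}
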