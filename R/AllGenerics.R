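#' Accessors for ContingencyTable margins
#'
#' @param x a [ContingencyTable-class].
#' @return `rowTotals`/`colTotals` return named numeric margin sums;
#'   `grandTotal` the total count; `counts` the labelled count matrix.
#' @examples
#' ct <- ContingencyTable(matrix(1:4, 2, dimnames = list(c("a", "b"), c("x", "y"))))
#' grandTotal(ct)
#' @name ContingencyTable-accessors
NULL

#' @rdname ContingencyTable-accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname ContingencyTable-accessors
#' @export
setGeneric("rowTotals", function(x) standardGeneric("rowTotals"))

#' @rdname ContingencyTable-accessors
#' @export
setGeneric("colTotals", function(x) standardGeneric("colTotals"))

#' @rdname ContingencyTable-accessors
#' @export
setGeneric("grandTotal", function(x) standardGeneric("grandTotal"))

#' @rdname ContingencyTable-accessors
#' @export
setMethod("counts", "ContingencyTable", function(x) x@counts)

#' @rdname ContingencyTable-accessors
#' @export
setMethod("rowTotals", "ContingencyTable", function(x) rowSums(x@counts))

#' @rdname ContingencyTable-accessors
#' @export
setMethod("colTotals", "ContingencyTable", function(x) colSums(x@counts))

#' @rdname ContingencyTable-accessors
#' @export
setMethod("grandTotal", "ContingencyTable", function(x) sum(x@counts))

#' Accessors for SprinzlAnnotation objects
#'
#' @param x a [SprinzlAnnotation-class].
#' @return `sprinzlCoords` returns the coordinate data.frame (Sprinzl
#'   66-76, base, source, y index); `alignedPairs` the aligned stem pairs;
#'   `alignmentScore` the optimal score; `annotationStatus` the status flag.
#' @name SprinzlAnnotation-accessors
NULL

#' @rdname SprinzlAnnotation-accessors
#' @export
setGeneric("sprinzlCoords", function(x) standardGeneric("sprinzlCoords"))

#' @rdname SprinzlAnnotation-accessors
#' @export
setGeneric("alignedPairs", function(x) standardGeneric("alignedPairs"))

#' @rdname SprinzlAnnotation-accessors
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @rdname SprinzlAnnotation-accessors
#' @export
setGeneric("annotationStatus", function(x) standardGeneric("annotationStatus"))

#' @rdname SprinzlAnnotation-accessors
#' @export
setMethod("sprinzlCoords", "SprinzlAnnotation", function(x) x@coords)

#' @rdname SprinzlAnnotation-accessors
#' @export
setMethod("alignedPairs", "SprinzlAnnotation", function(x) x@pairs)

#' @rdname SprinzlAnnotation-accessors
#' @export
setMethod("alignmentScore", "SprinzlAnnotation", function(x) x@score)

#' @rdname SprinzlAnnotation-accessors
#' @export
setMethod("annotationStatus", "SprinzlAnnotation", function(x) x@status)

#' Does an annotated gene template the 3' CCA end?
#'
#' A gene is called CCA-templating when the residues assigned Sprinzl
#' coordinates 74, 75 and 76 read C, C, A (case-insensitive, T and U
#' interchangeable). Records whose 74-76 coordinates could not all be
#' assigned (truncated 3' ends) are called non-templating.
#'
#' @param x a [SprinzlAnnotation-class].
#' @return logical(1).
#' @export
setGeneric("templatesCCA", function(x) standardGeneric("templatesCCA"))

#' @rdname templatesCCA
#' @export
setMethod("templatesCCA", "SprinzlAnnotation", function(x) {
  cd <- x@coords
  b <- cd$base[cd$sprinzl %in% 74:76]
  if (any(b == "-") || length(b) < 3L) return(FALSE)
  identical(paste(normalizeRNA(b), collapse = ""), "CCA")
})

#' Accessors for ProfileModelSet objects
#'
#' @param x a [ProfileModelSet-class].
#' @return `modelClasses` returns the class labels; `logOdds` the named
#'   list of per-class log-odds matrices (bits); `backgroundComposition`
#'   the smoothed pooled symbol frequencies.
#' @name ProfileModelSet-accessors
NULL

#' @rdname ProfileModelSet-accessors
#' @export
setGeneric("modelClasses", function(x) standardGeneric("modelClasses"))

#' @rdname ProfileModelSet-accessors
#' @export
setGeneric("logOdds", function(x) standardGeneric("logOdds"))

#' @rdname ProfileModelSet-accessors
#' @export
setGeneric("backgroundComposition",
           function(x) standardGeneric("backgroundComposition"))

#' @rdname ProfileModelSet-accessors
#' @export
setMethod("modelClasses", "ProfileModelSet", function(x) names(x@logOdds))

#' @rdname ProfileModelSet-accessors
#' @export
setMethod("logOdds", "ProfileModelSet", function(x) x@logOdds)

#' @rdname ProfileModelSet-accessors
#' @export
setMethod("backgroundComposition", "ProfileModelSet", function(x) x@background)
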