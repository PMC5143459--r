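## Flat-record I/O. The record dialect is a single-line TSV with a fixed
## header; it stands in for the defunct tRNAdb-CE dump format (coordinates
## 1-based inclusive, contexts exactly 10 bases, "." marks an absent
## 3' acceptor-strand annotation).

.RECORD_FIELDS <- c("record_id", "genome_id", "taxon_id", "gene_seq",
                    "upstream", "downstream", "anticodon", "prior_class",
                    "acc5_pos", "acc3_pos")

.CANONICAL_ELONGATORS <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu",
                           "Gly", "His", "Ile", "Leu", "Lys", "Met", "Phe",
                           "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")

#' Valid functional class labels for gene records
#'
#' The twenty canonical elongator labels plus initiator (`Ini`),
#' lysidinylated isoleucine (`kIle`), selenocysteine (`Sec`),
#' pyrrolysine (`Pyl`) and `Unspecified`.
#'
#' @return character vector of admissible `prior_class` values.
#' @export
priorClassLabels <- function() {
  c(.CANONICAL_ELONGATORS, "Ini", "kIle", "Sec", "Pyl", "Unspecified")
}

.parsePosList <- function(s) {
  if (is.na(s) || s == "." || s == "") return(integer(0))
  as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
}

.validateRecord <- function(rec) {
  if (nchar(rec$upstream) != 10L)
    return("upstream context must have exactly 10 bases")
  if (nchar(rec$downstream) != 10L)
    return("downstream context must have exactly 10 bases")
  if (nchar(rec$gene_seq) < 50L)
    return("gene_seq shorter than 50 bases")
  if (nchar(rec$anticodon) != 3L)
    return("anticodon must have exactly 3 bases")
  a5 <- .parsePosList(rec$acc5_pos)
  if (length(a5) != 7L)
    return("acc5_pos must list exactly 7 positions")
  if (any(a5 < 1L | a5 > nchar(rec$gene_seq)))
    return("acc5_pos outside gene_seq")
  a3 <- .parsePosList(rec$acc3_pos)
  if (length(a3) && length(a3) != 7L)
    return("acc3_pos must list exactly 7 positions or be absent ('.')")
  if (any(a3 < 1L | a3 > nchar(rec$gene_seq)))
    return("acc3_pos outside gene_seq")
  if (is.na(suppressWarnings(as.integer(rec$taxon_id))))
    return("taxon_id must be an integer")
  NULL
}

#' Read tRNA gene records from the flat TSV dialect
#'
#' One record per line; tab-separated fields `record_id`, `genome_id`,
#' `taxon_id`, `gene_seq`, `upstream`, `downstream`, `anticodon`,
#' `prior_class`, `acc5_pos`, `acc3_pos` (a header line naming them is
#' required). `acc5_pos`/`acc3_pos` are comma-separated 1-based positions
#' in `gene_seq` of the 5' and 3' acceptor-stem strands; `acc3_pos` may be
#' `"."` when the database provided no 3'-strand annotation. Sequence case
#' and T/U are preserved as read (normalisation to uppercase RNA happens
#' inside the analysis functions), so parse-write round-trips are exact.
#'
#' Malformed lines are skipped with a record-level warning naming the line
#' and the offending field; parsing continues. The skipped lines are
#' available in the `"errors"` attribute of the result.
#'
#' @param path file path (or connection) to read.
#' @return data.frame of gene records, one row per well-formed line, in
#'   input order, with attribute `"errors"` (data.frame of `line`,
#'   `reason` for rejected lines).
#' @seealso [writeGeneRecords()], [writeGeneFasta()]
#' @export
readGeneRecords <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty record file")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, .RECORD_FIELDS))
    stop("record file header must name the fields: ",
         paste(.RECORD_FIELDS, collapse = ", "))
  body <- lines[-1L]
  rows <- vector("list", length(body))
  errors <- list()
  for (k in seq_along(body)) {
    fields <- strsplit(body[[k]], "\t", fixed = TRUE)[[1L]]
    lineno <- k + 1L
    if (length(fields) != length(.RECORD_FIELDS)) {
      errors[[length(errors) + 1L]] <-
        data.frame(line = lineno,
                   reason = sprintf("expected %d fields, found %d",
                                    length(.RECORD_FIELDS), length(fields)))
      next
    }
    rec <- as.list(fields)
    names(rec) <- .RECORD_FIELDS
    bad <- .validateRecord(rec)
    if (!is.null(bad)) {
      errors[[length(errors) + 1L]] <- data.frame(line = lineno, reason = bad)
      next
    }
    rows[[k]] <- as.data.frame(rec)
  }
  errors <- if (length(errors)) do.call(rbind, errors) else
    data.frame(line = integer(0), reason = character(0))
  if (nrow(errors))
    warning(sprintf("%d malformed record line(s) skipped (first: line %d: %s)",
                    nrow(errors), errors$line[1L], errors$reason[1L]))
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(records)) {
    records <- as.data.frame(
      setNames(rep(list(character(0)), length(.RECORD_FIELDS)),
               .RECORD_FIELDS))
  }
  records$taxon_id <- as.integer(records$taxon_id)
  rownames(records) <- NULL
  attr(records, "errors") <- errors
  records
}

#' Write tRNA gene records in the flat TSV dialect
#'
#' Inverse of [readGeneRecords()]; sequences are written exactly as held,
#' so read-write round-trips are identity.
#'
#' @param records data.frame of gene records.
#' @param path output file path (or connection).
#' @return invisibly, `path`.
#' @export
writeGeneRecords <- function(records, path) {
  stopifnot(all(.RECORD_FIELDS %in% names(records)))
  out <- records[, .RECORD_FIELDS, drop = FALSE]
  lines <- c(paste(.RECORD_FIELDS, collapse = "\t"),
             do.call(paste, c(unname(as.list(out)), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Export gene records as FASTA
#'
#' Headers read `record_id|genome_id|prior_class`. With
#' `includeContext = TRUE` the emitted sequence is
#' upstream context + gene + downstream context.
#'
#' @param records data.frame of gene records (non-empty).
#' @param path output FASTA path.
#' @param includeContext logical(1), prepend/append the 10-base contexts.
#' @return invisibly, `path`.
#' @export
writeGeneFasta <- function(records, path, includeContext = FALSE) {
  if (!NROW(records)) stop("empty record set")
  seqs <- if (includeContext)
    paste0(records$upstream, records$gene_seq, records$downstream)
  else records$gene_seq
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- paste(records$record_id, records$genome_id,
                     records$prior_class, sep = "|")
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Read an NCBI-Taxonomy-style lineage table
#'
#' TSV with columns `taxon_id`, `rank`, `name`, `parent_taxon_id`. The
#' root is marked by a parent equal to its own id (or NA). Every other
#' parent must resolve within the table.
#'
#' @param path file path.
#' @return data.frame with integer ids.
#' @export
readLineageTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon_id", "rank", "name", "parent_taxon_id")
  if (!all(need %in% names(tab)))
    stop("lineage table must have columns: ", paste(need, collapse = ", "))
  tab$taxon_id <- as.integer(tab$taxon_id)
  tab$parent_taxon_id <- as.integer(tab$parent_taxon_id)
  root <- is.na(tab$parent_taxon_id) | tab$parent_taxon_id == tab$taxon_id
  if (!all(root | tab$parent_taxon_id %in% tab$taxon_id))
    stop("every parent_taxon_id must resolve in the table or be the root")
  tab
}

#' Read a genome-size table
#'
#' TSV with columns `genome_id`, `size_bp` (positive base-pair counts).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readGenomeSizes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "size_bp") %in% names(tab)))
    stop("genome size table must have columns genome_id, size_bp")
  tab$size_bp <- as.numeric(tab$size_bp)
  if (any(is.na(tab$size_bp) | tab$size_bp <= 0))
    stop("genome sizes must be positive")
  tab
}

#' Read a labelled count table into a ContingencyTable
#'
#' TSV whose first column holds row labels and whose header names the
#' column labels; cells must be non-negative integers. Margins are not
#' stored in the file; they are recomputed by the accessors.
#'
#' @param path file path.
#' @return a [ContingencyTable-class].
#' @examples
#' t1 <- readCountTable(system.file("extdata", "table1_reannotation.tsv",
#'                                  package = "trnacca"))
#' grandTotal(t1)
#' @export
readCountTable <- function(path) {
  if (file.exists(path) && file.size(path) == 0)
    stop("empty count table file")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!nrow(tab) || ncol(tab) < 2L)
    stop("count table must have row labels and at least one count column")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("count table cells must be non-negative integers")
  ContingencyTable(m)
}
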