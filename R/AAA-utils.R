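## Internal helpers shared across modules.

.RNA_BASES <- c("A", "C", "G", "U")

## Watson-Crick plus wobble pairs, as unordered-by-name ordered tuples.
.PAIRING_SET <- matrix(c(
  "A", "U",
  "U", "A",
  "C", "G",
  "G", "C",
  "G", "U",
  "U", "G"), ncol = 2, byrow = TRUE)

.WC_SET <- .PAIRING_SET[1:4, , drop = FALSE]
.WOBBLE_SET <- .PAIRING_SET[5:6, , drop = FALSE]

## Uppercase and DNA->RNA (T->U). Accepts vectors.
normalizeRNA <- function(x) {
  chartr("T", "U", toupper(x))
}

## Watson-Crick complement of RNA bases (vectorized over single characters).
.wcComplement <- function(b) {
  map <- c(A = "U", U = "A", C = "G", G = "C")
  unname(map[b])
}

.splitBases <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

## Round half-up to `digits` decimals (base round() is round-half-even).
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## Deterministic 31-ary string hash modulo 2^31 - 1, used to derive
## per-genome RNG substreams so that genome order is irrelevant.
.stringHash <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

.isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == round(x)

## The 10 non-pairing base combinations (16 minus 4 Watson-Crick minus
## 2 wobble), used by the generator's 1:72 motif draws.
.MISMATCH_COMBOS <- local({
  all16 <- expand.grid(b1 = .RNA_BASES, b2 = .RNA_BASES,
                       stringsAsFactors = FALSE)
  pairing <- paste(.PAIRING_SET[, 1L], .PAIRING_SET[, 2L])
  all16[!(paste(all16$b1, all16$b2) %in% pairing), ]
})
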