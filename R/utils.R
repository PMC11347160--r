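## Shared low-level sequence helpers. Sequences are plain uppercase character
## strings internally; Biostrings handles file I/O and translation.

BASES <- c("A", "C", "G", "T")

#' Reverse-complement a nucleotide string
#'
#' @param x character vector of nucleotide strings (A/C/G/T/N and IUPAC codes).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTNRYSWKMBDHVacgtn", "TGCANYRSWMKVHDBtgcan", s)
    intToUtf8(rev(utf8ToInt(comp)))
  }, character(1), USE.NAMES = FALSE)
}

## complement without reversal
complement_base <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- map[x]
  out[is.na(out)] <- "N"
  unname(out)
}

## split a string into single characters
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## encode bases as integers: A=1 C=2 G=3 T=4, anything else (N etc.) = 5
base_ints <- function(x) {
  v <- utf8ToInt(x)
  out <- integer(length(v))
  out[v == 65L] <- 1L  # A
  out[v == 67L] <- 2L  # C
  out[v == 71L] <- 3L  # G
  out[v == 84L] <- 4L  # T
  out[out == 0L] <- 5L
  out
}

## IUPAC code -> set of concrete bases
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

## does concrete sequence `seq` match IUPAC pattern `pat` (equal lengths)?
iupac_match <- function(seq, pat) {
  if (nchar(seq) != nchar(pat)) return(FALSE)
  s <- str_chars(seq)
  p <- str_chars(pat)
  all(mapply(function(b, code) {
    set <- IUPAC_SETS[[code]]
    !is.null(set) && b %in% set
  }, s, p))
}

## logical vector over all k-length windows of chromosome integer vector `si`,
## TRUE where the window matches IUPAC pattern `pat`
iupac_window_match <- function(si, pat) {
  p <- str_chars(pat)
  k <- length(p)
  n <- length(si) - k + 1L
  if (n < 1L) return(logical(0))
  ok <- rep(TRUE, n)
  for (j in seq_len(k)) {
    allowed <- match(IUPAC_SETS[[p[j]]], BASES)
    ok <- ok & (si[j:(n + j - 1L)] %in% allowed)
  }
  ok
}

## GC percentage of a string (0-100)
gc_percent <- function(x) {
  v <- base_ints(x)
  100 * sum(v == 2L | v == 3L) / length(v)
}

## run a block with a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## translate a DNA string (length multiple of 3) to amino acids
translate_dna <- function(x) {
  if (nchar(x) == 0) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     if.fuzzy.codon = "X"))
}

## path to a package data file
pkg_extdata <- function(name) {
  path <- system.file("extdata", name, package = "knockinDesign")
  if (path == "") stop("missing package data file: ", name)
  path
}

read_table_csv <- function(name) {
  utils::read.csv(pkg_extdata(name), comment.char = "#",
                  stringsAsFactors = FALSE)
}
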