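## Genome + annotation model: FASTA index, transcript models built from
## Ensembl-dialect GFF3, positional queries (region class, frame, distance to
## splice junctions). All coordinates are 1-based inclusive, genome + strand,
## matching the Ensembl convention used by the input files.

#' Load a reference genome from FASTA
#'
#' Reads a (multi-record) FASTA file into an in-memory index. Sequences are
#' stored uppercase; record names are truncated at the first whitespace as is
#' conventional for chromosome names.
#'
#' @param fasta_path path to a FASTA file.
#' @return a `GenomeIndex` object: list with `sequences` (named character
#'   vector) and `lengths` (named integer vector).
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  set <- tryCatch(Biostrings::readDNAStringSet(fasta_path),
                  error = function(e) stop("malformed FASTA '", fasta_path,
                                           "': ", conditionMessage(e)))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  obj <- list(sequences = seqs,
              lengths = stats::setNames(nchar(seqs), names(seqs)))
  class(obj) <- "GenomeIndex"
  obj
}

#' @export
print.GenomeIndex <- function(x, ...) {
  cat("GenomeIndex:", length(x$sequences), "sequence(s),",
      sum(x$lengths), "bp total\n")
  invisible(x)
}

#' Extract a genomic subsequence
#'
#' @param genome a `GenomeIndex`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` (default) or `"-"`; minus returns the reverse
#'   complement.
#' @return uppercase nucleotide string.
#' @export
get_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome$sequences))
    stop("unknown chromosome: ", chrom)
  len <- genome$lengths[[chrom]]
  if (start < 1 || end > len || start > end)
    stop("window [", start, ",", end, "] out of bounds for ", chrom,
         " (length ", len, ")")
  s <- substr(genome$sequences[[chrom]], start, end)
  if (strand == "-") s <- revcomp(s)
  s
}

## intervals: data.frame(start, end) sorted in *transcript* order
sort_tx <- function(df, strand) {
  if (nrow(df) == 0) return(df)
  df <- df[order(df$start), , drop = FALSE]
  if (strand == "-") df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

interval_df <- function(gr) {
  data.frame(start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
}

## subtract interval set b from a (both data.frames), genomic order
interval_setdiff <- function(a, b) {
  if (nrow(a) == 0) return(a)
  ra <- IRanges::IRanges(a$start, a$end)
  rb <- if (nrow(b) == 0) IRanges::IRanges() else IRanges::IRanges(b$start, b$end)
  rd <- IRanges::setdiff(ra, rb)
  data.frame(start = IRanges::start(rd), end = IRanges::end(rd))
}

#' Build transcript models from an Ensembl-dialect GFF3
#'
#' Parses gene/mRNA/exon/CDS (and optional five_prime_UTR/three_prime_UTR)
#' features and assembles one model per mRNA: exon, CDS and UTR intervals
#' plus a per-position reading-frame map over all CDS bases. When explicit
#' UTR features are absent, UTRs are derived as exon minus CDS, split at the
#' CDS span into 5' and 3' parts. Minus-strand transcripts have frames
#' assigned 5'->3' in transcript orientation.
#'
#' @param gff3_path path to a GFF3 file.
#' @param genome a `GenomeIndex` (used for coordinate validation).
#' @return named list of `TranscriptModel` objects keyed by transcript ID.
#' @export
build_transcript_models <- function(gff3_path, genome) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  type <- as.character(gr$type)
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) gr$ID else
    rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(S4Vectors::mcols(gr))) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p[1]) else
      NA_character_, character(1))
  } else rep(NA_character_, length(gr))

  is_tx <- type %in% c("mRNA", "transcript")
  models <- list()
  for (i in which(is_tx)) {
    tid <- ids[i]
    if (is.na(tid)) next
    chrom <- as.character(GenomicRanges::seqnames(gr[i]))
    strand <- as.character(GenomicRanges::strand(gr[i]))
    if (!chrom %in% names(genome$sequences))
      stop("transcript ", tid, " on unknown chromosome ", chrom)
    child <- which(parents == tid)
    exons <- sort_tx(interval_df(gr[child[type[child] == "exon"]]), strand)
    cds   <- sort_tx(interval_df(gr[child[type[child] == "CDS"]]), strand)
    utr5  <- sort_tx(interval_df(gr[child[type[child] == "five_prime_UTR"]]), strand)
    utr3  <- sort_tx(interval_df(gr[child[type[child] == "three_prime_UTR"]]), strand)
    if (nrow(exons) && max(exons$end) > genome$lengths[[chrom]])
      stop("transcript ", tid, " has coordinates beyond end of ", chrom)

    ## derive UTRs when the file carries no explicit UTR features
    if (nrow(utr5) == 0 && nrow(utr3) == 0 && nrow(cds) > 0 && nrow(exons) > 0) {
      non_cds <- interval_setdiff(exons[order(exons$start), , drop = FALSE],
                                  cds)
      cds_lo <- min(cds$start); cds_hi <- max(cds$end)
      left  <- non_cds[non_cds$end < cds_lo, , drop = FALSE]
      right <- non_cds[non_cds$start > cds_hi, , drop = FALSE]
      if (strand == "+") { utr5 <- left; utr3 <- right }
      else { utr5 <- sort_tx(right, strand); utr3 <- sort_tx(left, strand) }
    }

    ## frame map over CDS positions, in transcript orientation
    frame_map <- integer(0)
    if (nrow(cds) > 0) {
      pos <- unlist(lapply(seq_len(nrow(cds)), function(k) {
        p <- seq(cds$start[k], cds$end[k])
        if (strand == "-") rev(p) else p
      }))
      frame_map <- stats::setNames((seq_along(pos) - 1L) %% 3L,
                                   as.character(pos))
    }
    cds_len <- sum(cds$end - cds$start + 1)
    model <- list(
      transcript_id = tid,
      gene_id = parents[i],
      chrom = chrom,
      strand = strand,
      exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
      frame_map = frame_map,
      cds_length = cds_len,
      cds_incomplete = (cds_len %% 3L) != 0L,
      tx_start = if (nrow(exons)) min(exons$start) else NA_integer_,
      tx_end = if (nrow(exons)) max(exons$end) else NA_integer_)
    class(model) <- "TranscriptModel"
    models[[tid]] <- model
  }

  ## CDS features whose parent is not an mRNA: warn and skip
  orphan <- which(type == "CDS" & !(parents %in% ids[is_tx]))
  if (length(orphan))
    warning(length(orphan), " CDS feature(s) without a parent mRNA skipped")
  models
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat("TranscriptModel", x$transcript_id, "(", x$strand, ")",
      nrow(x$exons), "exon(s), CDS", x$cds_length, "bp",
      if (x$cds_incomplete) "[incomplete]" else "", "\n")
  invisible(x)
}

#' Look up a transcript model, tolerating missing version suffixes
#'
#' Accepts both versioned (`TX1.2`) and unversioned (`TX1`) identifiers.
#' An unversioned query matches the single annotated version and errors if
#' several versions are annotated.
#'
#' @param models list returned by [build_transcript_models()].
#' @param id transcript identifier.
#' @return a `TranscriptModel`.
#' @export
find_transcript <- function(models, id) {
  if (id %in% names(models)) return(models[[id]])
  stripped <- sub("\\.\\d+$", "", names(models))
  hit <- which(stripped == id)
  if (length(hit) == 1) return(models[[hit]])
  if (length(hit) > 1)
    stop("transcript ID '", id, "' is ambiguous between: ",
         paste(names(models)[hit], collapse = ", "))
  stop("unknown transcript ID: ", id)
}

in_intervals <- function(pos, df) {
  nrow(df) > 0 && any(pos >= df$start & pos <= df$end)
}

## genomic coordinates of internal exon/intron junctions. Each junction is the
## boundary between exon base `e` and intron base `e+1`; we record `e` (the
## exon-side base of a donor-side junction) or `a` (the intron-side base of an
## acceptor-side junction) as (exon_edge, intron_edge) pairs.
junctions_of <- function(model) {
  ex <- model$exons[order(model$exons$start), , drop = FALSE]
  if (nrow(ex) < 2) return(data.frame(exon_edge = integer(0),
                                      intron_edge = integer(0)))
  jl <- data.frame(exon_edge = ex$end[-nrow(ex)],
                   intron_edge = ex$end[-nrow(ex)] + 1L)
  jr <- data.frame(exon_edge = ex$start[-1],
                   intron_edge = ex$start[-1] - 1L)
  rbind(jl, jr)
}

#' Classify a genomic position relative to a transcript model
#'
#' @param pos 1-based genomic coordinate.
#' @param model a `TranscriptModel`.
#' @return list with `class` (one of `"UTR5"`, `"UTR3"`, `"CDS"`,
#'   `"INTRON"`, `"INTERGENIC"`), `junction_distance` (bp count from the
#'   nearest exon/intron boundary, where the boundary-adjacent base on either
#'   side has distance 1; `NA` when the transcript has no internal junction
#'   or the position is intergenic) and `junction_side` (`"exon"` or
#'   `"intron"`).
#' @export
classify_position <- function(pos, model) {
  cls <- if (in_intervals(pos, model$cds)) "CDS"
  else if (in_intervals(pos, model$utr5)) "UTR5"
  else if (in_intervals(pos, model$utr3)) "UTR3"
  else if (in_intervals(pos, model$exons)) "UTR5"  # exon outside CDS, no UTR split
  else if (!is.na(model$tx_start) && pos >= model$tx_start &&
           pos <= model$tx_end) "INTRON"
  else "INTERGENIC"

  jd <- NA_integer_; side <- NA_character_
  if (cls != "INTERGENIC") {
    j <- junctions_of(model)
    if (nrow(j) > 0) {
      in_exon <- in_intervals(pos, model$exons)
      edge <- if (in_exon) j$exon_edge else j$intron_edge
      jd <- min(abs(pos - edge)) + 1L
      side <- if (in_exon) "exon" else "intron"
    }
  }
  list(class = cls, junction_distance = jd, junction_side = side)
}

#' Reading frame of a CDS position
#'
#' @param pos genomic coordinate.
#' @param model a `TranscriptModel`.
#' @return frame 0/1/2 in transcript orientation, or `NA` outside the CDS.
#' @export
frame_at <- function(pos, model) {
  f <- model$frame_map[as.character(pos)]
  if (is.na(f)) NA_integer_ else unname(f)
}

#' Spliced CDS sequence of a transcript
#'
#' @param model a `TranscriptModel`.
#' @param genome a `GenomeIndex`.
#' @return the CDS nucleotide string, 5'->3' in transcript orientation.
#' @export
cds_sequence <- function(model, genome) {
  if (nrow(model$cds) == 0) return("")
  paste0(vapply(seq_len(nrow(model$cds)), function(k)
    get_sequence(genome, model$chrom, model$cds$start[k], model$cds$end[k],
                 model$strand), character(1)), collapse = "")
}
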