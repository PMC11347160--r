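## GenBank flat-file output for annotated HDR donors, plus a minimal reader
## used to round-trip the writer's output.

gb_location <- function(start, end, strand = "+") {
  loc <- if (start == end) as.character(start) else paste0(start, "..", end)
  if (strand == "-") paste0("complement(", loc, ")") else loc
}

gb_feature <- function(type, location, qualifiers) {
  head <- sprintf("     %-16s%s", type, location)
  quals <- unlist(lapply(names(qualifiers), function(q)
    sprintf("                     /%s=\"%s\"", q, qualifiers[[q]])))
  c(head, quals)
}

#' Write an annotated donor as a GenBank flat file
#'
#' Features: homology arms, payload, each recoded base (`variation`), the
#' guide protospacer and PAM where they fall inside the donor, and exon/CDS
#' chunks of the transcript model with in-frame translations.
#'
#' @param donor a `DonorDesign`.
#' @param path output file path.
#' @param name locus name (defaults to the file stem).
#' @param guide optional guide row (protospacer interval + strand).
#' @param model optional `TranscriptModel` for exon/CDS features.
#' @return the path, invisibly.
#' @export
write_genbank <- function(donor, path, name = NULL, guide = NULL,
                          model = NULL) {
  seq <- donor$sequence
  L <- nchar(seq)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN %s",
            substr(name, 1, 16), L, format(Sys.Date(), "%d-%b-%Y")),
    sprintf("DEFINITION  HDR donor (%s, strand %s) at %s:%d.",
            donor$mode, donor$strand, donor$chrom, donor$insert_site),
    "FEATURES             Location/Qualifiers")
  add <- function(...) lines <<- c(lines, gb_feature(...))
  if (donor$arm5_len > 0)
    add("misc_feature", gb_location(1, donor$arm5_len),
        list(label = "5' homology arm"))
  if (donor$payload_len > 0)
    add("misc_feature", gb_location(donor$payload_start, donor$payload_end),
        list(label = "payload"))
  if (donor$arm3_len > 0)
    add("misc_feature", gb_location(donor$payload_end + 1, L),
        list(label = "3' homology arm"))
  if (!is.null(guide)) {
    offs <- genomic_to_donor_offset(donor, c(guide$start, guide$end))
    if (!anyNA(offs))
      add("misc_feature", gb_location(min(offs), max(offs), guide$strand),
          list(label = paste0("protospacer (", guide$protospacer, " PAM ",
                              guide$pam, ")")))
  }
  if (!is.null(donor$recoding) && nrow(donor$recoding$mutations)) {
    m <- donor$recoding$mutations
    for (i in seq_len(nrow(m)))
      add("variation", gb_location(m$offset[i], m$offset[i]),
          list(label = paste0("recoded ", m$class[i], " (", m$region[i], ")"),
               replace = tolower(m$alt[i]),
               note = paste0("reference ", m$ref[i])))
  }
  if (!is.null(model)) {
    for (k in seq_len(nrow(model$exons))) {
      offs <- genomic_to_donor_offset(
        donor, c(max(model$exons$start[k], donor$win_start),
                 min(model$exons$end[k], donor$win_end)))
      if (anyNA(offs) || model$exons$start[k] > donor$win_end ||
          model$exons$end[k] < donor$win_start) next
      add("exon", gb_location(min(offs), max(offs), model$strand),
          list(label = paste0(model$transcript_id, " exon ", k)))
    }
    for (k in seq_len(nrow(model$cds))) {
      lo <- max(model$cds$start[k], donor$win_start)
      hi <- min(model$cds$end[k], donor$win_end)
      if (lo > hi) next
      offs <- genomic_to_donor_offset(donor, c(lo, hi))
      if (anyNA(offs)) next
      ## translate the in-frame portion of this CDS chunk
      chunk <- substr(seq, min(offs), max(offs))
      if (model$strand == "-") chunk <- revcomp(chunk)
      f_first <- model$frame_map[as.character(if (model$strand == "+") lo else hi)]
      if (!is.na(f_first)) {
        skip <- (3 - f_first) %% 3
        inframe <- substr(chunk, skip + 1,
                          skip + 3 * ((nchar(chunk) - skip) %/% 3))
        tr <- if (nchar(inframe) >= 3) translate_dna(inframe) else ""
        add("CDS", gb_location(min(offs), max(offs), model$strand),
            list(label = paste0(model$transcript_id, " CDS"),
                 translation = tr))
      }
    }
  }
  lines <- c(lines, "ORIGIN")
  for (i in seq(1, L, by = 60)) {
    chunk <- substr(seq, i, min(i + 59, L))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", i,
                              tolower(paste(blocks, collapse = " "))))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Minimal GenBank flat-file reader
#'
#' Parses the LOCUS length, feature table (type, location, strand) and
#' ORIGIN sequence of a single-record GenBank file; sufficient to round-trip
#' [write_genbank()] output.
#'
#' @param path GenBank file.
#' @return list with `name`, `length`, `sequence` (uppercase), `features`
#'   (data.frame type, start, end, strand).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- lines[grepl("^LOCUS", lines)][1]
  name <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]
  len <- as.integer(sub(".*?(\\d+) bp.*", "\\1", locus))
  fstart <- which(grepl("^FEATURES", lines)) + 1
  fend <- which(grepl("^ORIGIN", lines)) - 1
  feats <- list()
  for (ln in lines[seq2(fstart, fend)]) {
    if (!grepl("^     \\S", ln)) next
    type <- sub("^\\s+(\\S+)\\s.*", "\\1", ln)
    loc <- sub("^\\s+\\S+\\s+(\\S+)\\s*$", "\\1", ln)
    strand <- if (grepl("complement", loc)) "-" else "+"
    loc <- gsub("complement\\(|\\)", "", loc)
    parts <- strsplit(loc, "\\.\\.")[[1]]
    feats[[length(feats) + 1]] <- data.frame(
      type = type, start = as.integer(parts[1]),
      end = as.integer(parts[length(parts)]), strand = strand)
  }
  ostart <- which(grepl("^ORIGIN", lines)) + 1
  oend <- which(grepl("^//", lines)) - 1
  seq <- toupper(gsub("[^a-zA-Z]", "", paste(lines[seq2(ostart, oend)],
                                             collapse = "")))
  list(name = name, length = len, sequence = seq,
       features = if (length(feats)) do.call(rbind, feats) else
         data.frame(type = character(0), start = integer(0),
                    end = integer(0), strand = character(0)))
}
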