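## HDR donor assembly and donor-type rules: dsDNA synthesis-feasibility
## flags and homology-arm trimming, ssODN length capping and strand-polarity
## selection. Donor sequences are assembled and recoded on the genome +
## strand; ssODN output is re-oriented to the chosen strand at the end.

#' Donor specification defaults
#'
#' @param mode `"dsDNA"` or `"ssODN"`.
#' @param arm5_len,arm3_len dsDNA homology arm lengths (default 500/500 bp).
#' @param ssodn_max_len ssODN total length cap (default 200 nt).
#' @param recoding_level `"none"`, `"prevent_recut"` or `"full"`.
#' @param strand_mode ssODN strand choice: `"auto"`, `"target"`,
#'   `"non_target"`, `"transcribed"`, `"non_transcribed"`.
#' @param trim_enabled enable dsDNA arm trimming.
#' @param min_arm_len minimum arm length retained by trimming (default 100).
#' @param forbidden_motifs character vector of motifs to avoid (also
#'   searched as reverse complements).
#' @return a `DonorSpec` list.
#' @export
donor_spec <- function(mode = c("dsDNA", "ssODN"),
                       arm5_len = 500, arm3_len = 500,
                       ssodn_max_len = 200,
                       recoding_level = c("full", "prevent_recut", "none"),
                       strand_mode = c("auto", "target", "non_target",
                                       "transcribed", "non_transcribed"),
                       trim_enabled = FALSE, min_arm_len = 100,
                       forbidden_motifs = character(0)) {
  spec <- list(mode = match.arg(mode), arm5_len = arm5_len,
               arm3_len = arm3_len, ssodn_max_len = ssodn_max_len,
               recoding_level = match.arg(recoding_level),
               strand_mode = match.arg(strand_mode),
               trim_enabled = trim_enabled, min_arm_len = min_arm_len,
               forbidden_motifs = forbidden_motifs)
  class(spec) <- "DonorSpec"
  spec
}

#' Assemble a donor: 5' arm + payload + 3' arm on the genome + strand
#'
#' The payload is inserted between genomic positions `insert_site` and
#' `insert_site + 1`. Arms are clipped (with a warning) at chromosome ends.
#'
#' @param genome a `GenomeIndex`.
#' @param chrom chromosome.
#' @param insert_site 1-based coordinate of the reference base immediately
#'   5' (+ strand) of the payload.
#' @param payload payload sequence, already oriented to the genome + strand.
#' @param arm5_len,arm3_len requested arm lengths in bp.
#' @param mode `"dsDNA"` or `"ssODN"`.
#' @return a `DonorDesign` object.
#' @export
assemble_donor <- function(genome, chrom, insert_site, payload,
                           arm5_len, arm3_len, mode = "dsDNA") {
  if (nchar(payload) > 0 && grepl("[^ACGT]", payload))
    stop("payload contains non-ACGT characters")
  L <- genome$lengths[[chrom]]
  if (is.null(L) || insert_site < 1 || insert_site > L)
    stop("insertion site ", insert_site, " outside chromosome ", chrom)
  a5_start <- insert_site - arm5_len + 1
  a3_end <- insert_site + arm3_len
  if (a5_start < 1 || a3_end > L) {
    warning("homology arms clipped at chromosome ends")
    a5_start <- max(1, a5_start)
    a3_end <- min(L, a3_end)
  }
  arm5 <- get_sequence(genome, chrom, a5_start, insert_site)
  arm3 <- if (a3_end > insert_site)
    get_sequence(genome, chrom, insert_site + 1, a3_end) else ""
  obj <- list(
    sequence = paste0(arm5, payload, arm3),
    mode = mode, strand = "+",
    chrom = chrom, insert_site = insert_site,
    win_start = a5_start, win_end = a3_end,
    arm5_len = nchar(arm5), arm3_len = nchar(arm3),
    payload = payload, payload_len = nchar(payload),
    payload_start = nchar(arm5) + 1L,
    payload_end = nchar(arm5) + nchar(payload),
    recoding = NULL, flags = NULL,
    effective_arm5_len = nchar(arm5), effective_arm3_len = nchar(arm3))
  class(obj) <- "DonorDesign"
  obj
}

#' @export
print.DonorDesign <- function(x, ...) {
  cat("DonorDesign (", x$mode, ", strand ", x$strand, "): ",
      nchar(x$sequence), " nt; arms ", x$arm5_len, "/", x$arm3_len,
      " bp; payload ", x$payload_len, " nt\n", sep = "")
  invisible(x)
}

#' Map a donor offset to its genomic coordinate
#'
#' @param donor a `DonorDesign`.
#' @param offset 1-based offset(s) into the donor sequence.
#' @return genomic coordinate(s); `NA` for payload positions.
#' @export
donor_offset_to_genomic <- function(donor, offset) {
  p <- donor$payload_len
  a5 <- donor$arm5_len
  g <- ifelse(offset <= a5, donor$win_start + offset - 1,
        ifelse(offset <= a5 + p, NA_integer_,
               donor$insert_site + (offset - a5 - p)))
  as.integer(g)
}

#' Map a genomic coordinate to its donor offset
#'
#' @param donor a `DonorDesign`.
#' @param pos genomic coordinate(s) within the donor window.
#' @return 1-based donor offset(s); `NA` outside the window.
#' @export
genomic_to_donor_offset <- function(donor, pos) {
  a5 <- donor$arm5_len; p <- donor$payload_len
  off <- ifelse(pos >= donor$win_start & pos <= donor$insert_site,
                pos - donor$win_start + 1,
         ifelse(pos > donor$insert_site & pos <= donor$win_end,
                a5 + p + (pos - donor$insert_site), NA_integer_))
  as.integer(off)
}

#' Flag motifs incompatible with commercial dsDNA synthesis
#'
#' Three flag families: homopolymeric runs (>= 10 A/T or >= 6 G/C), extreme
#' global GC content (> 65% or < 25%), and GC window skew (> 52% difference
#' between any two 50-bp windows, stride 1). Optionally also reports
#' user-defined forbidden motifs (searched on both strands).
#'
#' @param sequence donor nucleotide string.
#' @param forbidden_motifs character vector of motifs.
#' @return a `SynthesisFlags` list: `homopolymers` (data.frame offset, base,
#'   length), `gc_global` (list flagged, value), `gc_window_skew` (list
#'   flagged, value, evaluated), `forbidden_motif_hits` (data.frame motif,
#'   offset), `any` (logical).
#' @export
flag_synthesis_problems <- function(sequence, forbidden_motifs = character(0)) {
  stopifnot(nchar(sequence) > 0)
  ch <- str_chars(sequence)
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hp_at <- (r$values %in% c("A", "T") & r$lengths >= 10) |
           (r$values %in% c("G", "C") & r$lengths >= 6)
  homopolymers <- data.frame(offset = starts[hp_at], base = r$values[hp_at],
                             length = r$lengths[hp_at])
  gc <- gc_percent(sequence)
  gc_global <- list(flagged = gc > 65 || gc < 25, value = gc)
  n <- nchar(sequence)
  if (n >= 50) {
    isgc <- as.integer(ch %in% c("G", "C"))
    win <- (cumsum(isgc)[50:n] - c(0, cumsum(isgc))[1:(n - 49)]) * 2
    skew <- max(win) - min(win)
    gc_window_skew <- list(flagged = skew > 52, value = skew, evaluated = TRUE)
  } else {
    gc_window_skew <- list(flagged = FALSE, value = NA_real_, evaluated = FALSE)
  }
  hits <- list()
  for (m in forbidden_motifs) {
    for (q in unique(c(m, revcomp(m)))) {
      loc <- gregexpr(q, sequence, fixed = TRUE)[[1]]
      if (loc[1] != -1)
        hits[[length(hits) + 1]] <- data.frame(motif = m, offset = as.integer(loc))
    }
  }
  forbidden_motif_hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(motif = character(0), offset = integer(0))
  flags <- list(homopolymers = homopolymers, gc_global = gc_global,
                gc_window_skew = gc_window_skew,
                forbidden_motif_hits = forbidden_motif_hits)
  flags$any <- nrow(homopolymers) > 0 || gc_global$flagged ||
    gc_window_skew$flagged || nrow(forbidden_motif_hits) > 0
  class(flags) <- "SynthesisFlags"
  flags
}

## trimmable features (homopolymers + forbidden motifs) within one arm,
## as offsets relative to the arm's own sequence
arm_trim_features <- function(arm_seq, forbidden_motifs) {
  if (nchar(arm_seq) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  fl <- flag_synthesis_problems(arm_seq, forbidden_motifs)
  feats <- data.frame(start = integer(0), end = integer(0))
  if (nrow(fl$homopolymers))
    feats <- rbind(feats, data.frame(start = fl$homopolymers$offset,
                                     end = fl$homopolymers$offset +
                                       fl$homopolymers$length - 1))
  if (nrow(fl$forbidden_motif_hits)) {
    w <- nchar(fl$forbidden_motif_hits$motif)
    feats <- rbind(feats, data.frame(start = fl$forbidden_motif_hits$offset,
                                     end = fl$forbidden_motif_hits$offset + w - 1))
  }
  feats
}

#' Trim dsDNA homology arms to remove hard-to-synthesize features
#'
#' Each arm is shortened from its distal end inward, one flagged feature
#' (homopolymer or forbidden motif) at a time — the cut lands 1 nt past the
#' feature's payload-proximal edge — re-evaluating after every cut. Trimming
#' halts when the arm is feature-free or when removing the next feature
#' would take the arm below `min_arm_len`, in which case the arm is trimmed
#' to exactly `min_arm_len` and the surviving flags remain reported.
#'
#' @param donor a `DonorDesign` (dsDNA mode).
#' @param min_arm_len minimum arm length to retain.
#' @param forbidden_motifs motifs treated like homopolymers for trimming.
#' @return the trimmed `DonorDesign` with updated `flags`.
#' @export
trim_arms <- function(donor, min_arm_len = 100,
                      forbidden_motifs = character(0)) {
  stopifnot(donor$mode == "dsDNA")
  trim_one <- function(arm_seq, distal) {
    ## distal = "left" for the 5' arm, "right" for the 3' arm
    len <- nchar(arm_seq)
    if (len <= min_arm_len) return(arm_seq)
    repeat {
      len <- nchar(arm_seq)
      feats <- arm_trim_features(arm_seq, forbidden_motifs)
      if (!nrow(feats)) break
      if (distal == "left") {
        f <- feats[which.min(feats$start), ]        # most distal feature
        new_len <- len - f$end                      # keep 1 nt past its
        if (new_len < min_arm_len) new_len <- min_arm_len  # proximal edge
        if (new_len >= len) break
        arm_seq <- substr(arm_seq, len - new_len + 1, len)
      } else {
        f <- feats[which.max(feats$end), ]
        new_len <- f$start - 1
        if (new_len < min_arm_len) new_len <- min_arm_len
        if (new_len >= len) break
        arm_seq <- substr(arm_seq, 1, new_len)
      }
      if (new_len == min_arm_len) break
    }
    arm_seq
  }
  a5 <- substr(donor$sequence, 1, donor$arm5_len)
  a3 <- substr(donor$sequence, donor$payload_end + 1, nchar(donor$sequence))
  if (min_arm_len > donor$arm5_len || min_arm_len > donor$arm3_len) {
    warning("min_arm_len exceeds current arm length; no trimming performed")
    return(donor)
  }
  new5 <- trim_one(a5, "left")
  new3 <- trim_one(a3, "right")
  trim5 <- donor$arm5_len - nchar(new5)
  donor <- shrink_donor(donor, trim5, donor$arm3_len - nchar(new3))
  donor$flags <- flag_synthesis_problems(donor$sequence, forbidden_motifs)
  donor
}

## remove n5 bases from the donor's 5' (distal) end and n3 from the 3' end,
## keeping offsets/recoding bookkeeping consistent
shrink_donor <- function(donor, n5, n3) {
  if (n5 == 0 && n3 == 0) return(donor)
  L <- nchar(donor$sequence)
  donor$sequence <- substr(donor$sequence, n5 + 1, L - n3)
  donor$win_start <- donor$win_start + n5
  donor$win_end <- donor$win_end - n3
  donor$arm5_len <- donor$arm5_len - n5
  donor$arm3_len <- donor$arm3_len - n3
  donor$payload_start <- donor$payload_start - n5
  donor$payload_end <- donor$payload_end - n5
  if (!is.null(donor$recoding) && nrow(donor$recoding$mutations)) {
    m <- donor$recoding$mutations
    m$offset <- m$offset - n5
    keep <- m$offset >= 1 & m$offset <= nchar(donor$sequence)
    donor$recoding$mutations <- m[keep, , drop = FALSE]
  }
  donor$effective_arm5_len <- min(donor$effective_arm5_len, donor$arm5_len)
  donor$effective_arm3_len <- min(donor$effective_arm3_len, donor$arm3_len)
  donor
}

#' Select the ssODN strand polarity
#'
#' In `auto` mode the favored strand follows the strand-annealing polarity
#' rule: when the cut falls 5' of the insertion site on the + strand the
#' minus strand is favored; when the cut falls 3' of it the plus strand is
#' favored; when cut and insert coincide the guide's non-target strand is
#' used. `target`/`non_target` return the strand carrying / complementary
#' to the protospacer; `transcribed`/`non_transcribed` use the transcript's
#' template / sense strand and require transcript context.
#'
#' @param cut_site,insert_site genomic coordinates (left-base convention).
#' @param guide_strand strand carrying the protospacer (`"+"`/`"-"`).
#' @param transcript_strand transcript strand or `NA`.
#' @param mode one of the five strand modes.
#' @return `"+"` or `"-"`.
#' @export
select_ssodn_strand <- function(cut_site, insert_site, guide_strand,
                                transcript_strand = NA,
                                mode = c("auto", "target", "non_target",
                                         "transcribed", "non_transcribed")) {
  mode <- match.arg(mode)
  other <- function(s) if (s == "+") "-" else "+"
  switch(mode,
    auto = if (cut_site < insert_site) "-"
           else if (cut_site > insert_site) "+"
           else other(guide_strand),
    target = guide_strand,
    non_target = other(guide_strand),
    transcribed = {
      if (is.na(transcript_strand))
        stop("strand mode 'transcribed' requires transcript context")
      other(transcript_strand)
    },
    non_transcribed = {
      if (is.na(transcript_strand))
        stop("strand mode 'non_transcribed' requires transcript context")
      transcript_strand
    })
}

#' Cap an ssODN donor to a maximum total length
#'
#' Arms are shortened from their distal ends, longest-arm-first, until the
#' total length is within the cap. The payload is never truncated, and an
#' arm containing the cut site (the cut-to-insert region must survive in the
#' donor) is never shortened past it.
#'
#' @param donor a `DonorDesign` (ssODN mode).
#' @param max_len total length cap (default 200 nt).
#' @param cut_site genomic coordinate of the guide cut, or `NA`.
#' @return the capped `DonorDesign`.
#' @export
cap_ssodn <- function(donor, max_len = 200, cut_site = NA) {
  if (donor$payload_len > max_len)
    stop("payload (", donor$payload_len, " nt) alone exceeds the ssODN cap ",
         "of ", max_len, " nt; minimum required cap is ",
         donor$payload_len + 2)
  ## per-arm floors: keep the cut site (and 1 nt beyond it) inside the donor
  floor5 <- 1L; floor3 <- 1L
  if (!is.na(cut_site)) {
    if (cut_site <= donor$insert_site)
      floor5 <- max(floor5, donor$insert_site - cut_site + 2L)
    else
      floor3 <- max(floor3, cut_site - donor$insert_site + 1L)
  }
  a5 <- donor$arm5_len; a3 <- donor$arm3_len
  excess <- a5 + a3 + donor$payload_len - max_len
  while (excess > 0 && (a5 > floor5 || a3 > floor3)) {
    if (a5 >= a3 && a5 > floor5) a5 <- a5 - 1L
    else if (a3 > floor3) a3 <- a3 - 1L
    else a5 <- a5 - 1L
    excess <- excess - 1L
  }
  if (a5 + a3 + donor$payload_len > max_len)
    stop("cannot satisfy ssODN cap of ", max_len,
         " nt while keeping the cut site in the donor; minimum required cap is ",
         donor$payload_len + floor5 + floor3)
  shrink_donor(donor, donor$arm5_len - a5, donor$arm3_len - a3)
}

#' Re-orient an ssODN donor to its chosen strand
#'
#' @param donor a `DonorDesign`.
#' @param strand `"+"` or `"-"`; minus reverse-complements the reported
#'   sequence (bookkeeping offsets stay on the + strand).
#' @return the `DonorDesign` with `strand` and `sequence` updated.
#' @export
orient_ssodn <- function(donor, strand) {
  donor$strand <- strand
  if (strand == "-") donor$sequence_oriented <- revcomp(donor$sequence)
  else donor$sequence_oriented <- donor$sequence
  donor
}

#' Reconstruct the genomic reference from a donor
#'
#' Strips the payload and reverts all recoding mutations; used to audit that
#' donor assembly is faithful to the genome.
#'
#' @param donor a `DonorDesign` (with optional `recoding` plan attached).
#' @return the genomic reference window as a string.
#' @export
donor_reference_reconstruction <- function(donor) {
  s <- donor$sequence
  if (!is.null(donor$recoding) && nrow(donor$recoding$mutations)) {
    m <- donor$recoding$mutations
    for (i in seq_len(nrow(m)))
      substr(s, m$offset[i], m$offset[i]) <- m$ref[i]
  }
  if (donor$payload_len > 0)
    s <- paste0(substr(s, 1, donor$payload_start - 1),
                substr(s, donor$payload_end + 1, nchar(s)))
  s
}
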