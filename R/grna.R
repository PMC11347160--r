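## Guide RNA engine: protospacer enumeration for the three supported Cas
## enzymes, exhaustive k-mismatch off-target search, MIT/Hsu single-hit and
## aggregated specificity scoring, and the three-factor composite ranking.

#' Cas enzyme definitions
#'
#' Returns the geometry and PAM rules for one of the three supported
#' enzymes. `cut_site` conventions (blunt cut between spacer positions 17/18
#' for SpCas9/SpCas9-VQR, nominal cut after spacer position 18 for
#' enAsCas12a) are encoded in [enumerate_protospacers()].
#'
#' @param name `"SpCas9"`, `"SpCas9-VQR"` or `"enAsCas12a"`.
#' @return a `CasEnzyme` list: `name`, `pam` (IUPAC), `pam_side`,
#'   `spacer_length`, `offtarget_pams`, `cut_offset` (spacer position after
#'   which the cut falls, counted 5'->3' along the protospacer).
#' @export
cas_enzyme <- function(name = c("SpCas9", "SpCas9-VQR", "enAsCas12a")) {
  name <- match.arg(name)
  enz <- switch(name,
    "SpCas9" = list(name = name, pam = "NGG", pam_side = "3prime",
                    spacer_length = 20L, offtarget_pams = c("NGG", "NGA", "NAG"),
                    cut_offset = 17L),
    "SpCas9-VQR" = list(name = name, pam = "NGA", pam_side = "3prime",
                        spacer_length = 20L, offtarget_pams = c("NGA", "NGG"),
                        cut_offset = 17L),
    "enAsCas12a" = list(name = name, pam = "TTTV", pam_side = "5prime",
                        spacer_length = 20L, offtarget_pams = "TTTN",
                        cut_offset = 18L))
  class(enz) <- "CasEnzyme"
  enz
}

pam_length <- function(enzyme) nchar(enzyme$pam)

## genomic coordinate of the base immediately 5' (genome + strand) of the cut,
## given the protospacer's genomic interval and strand
cut_site_for <- function(enzyme, start, end, strand) {
  co <- enzyme$cut_offset
  if (strand == "+") start + co - 1L else end - co
}

#' Enumerate protospacers in a genomic window
#'
#' Scans both strands of `window` for spacer+PAM occurrences of the given
#' enzyme. Protospacers overlapping N are dropped. The protospacer and PAM
#' must lie entirely within the window.
#'
#' @param genome a `GenomeIndex`.
#' @param enzyme a `CasEnzyme`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive window.
#' @return data.frame of unscored guide candidates with columns
#'   `protospacer`, `pam`, `chrom`, `start`, `end` (protospacer interval),
#'   `strand`, `cut_site`.
#' @export
enumerate_protospacers <- function(genome, enzyme, chrom, start, end) {
  sl <- enzyme$spacer_length; pl <- pam_length(enzyme)
  empty <- data.frame(protospacer = character(0), pam = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      cut_site = integer(0))
  if (end - start + 1 < sl + pl) return(empty)
  seq_fwd <- get_sequence(genome, chrom, start, end)
  L <- nchar(seq_fwd)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_fwd else revcomp(seq_fwd)
    si <- base_ints(s)
    n_units <- L - (sl + pl) + 1L
    if (n_units < 1) next
    ## unit = spacer+PAM in scan orientation; PAM position depends on side
    if (enzyme$pam_side == "3prime") {
      pam_ok <- iupac_window_match(si, enzyme$pam)          # at offset sl
      unit_ok <- pam_ok[(sl + 1L):(sl + n_units)]
      sp_off <- 0L
    } else {
      pam_ok <- iupac_window_match(si, enzyme$pam)          # at offset 0
      unit_ok <- pam_ok[seq_len(n_units)]
      sp_off <- pl
    }
    idx <- which(unit_ok)
    for (i in idx) {
      sp_start_scan <- i + sp_off
      sp <- substr(s, sp_start_scan, sp_start_scan + sl - 1L)
      if (grepl("[^ACGT]", sp)) next
      pam_start_scan <- if (enzyme$pam_side == "3prime") sp_start_scan + sl
                        else i
      pam <- substr(s, pam_start_scan, pam_start_scan + pl - 1L)
      if (grepl("[^ACGT]", pam)) next
      ## map protospacer scan interval back to genome + coordinates
      if (strand == "+") {
        g_start <- start + sp_start_scan - 1L
        g_end <- g_start + sl - 1L
      } else {
        g_end <- end - (sp_start_scan - 1L)
        g_start <- g_end - sl + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        protospacer = sp, pam = pam, chrom = chrom,
        start = g_start, end = g_end, strand = strand,
        cut_site = cut_site_for(enzyme, g_start, g_end, strand))
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## All approximate matches of `pattern` (length k) in the genome within
## `max_mm` mismatches, on both strands. Returns data.frame
## (chrom, start, end, strand, mismatches). N counts as a mismatch.
## Vectorised shift-and-compare scan; the brute-force oracle lives in the
## test suite.
scan_mismatch_sites <- function(genome, pattern, max_mm) {
  k <- nchar(pattern)
  pi_ <- base_ints(pattern)
  res <- list()
  for (chrom in names(genome$sequences)) {
    L <- genome$lengths[[chrom]]
    if (L < k) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") genome$sequences[[chrom]] else
        revcomp(genome$sequences[[chrom]])
      si <- base_ints(s)
      n <- L - k + 1L
      mm <- integer(n)
      for (j in seq_len(k))
        mm <- mm + (si[j:(n + j - 1L)] != pi_[j])
      hit <- which(mm <= max_mm)
      if (!length(hit)) next
      if (strand == "+") {
        st <- hit
      } else {
        st <- L - (hit + k - 1L) + 1L
      }
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = st, end = st + k - 1L, strand = strand,
        mismatches = mm[hit])
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0)))
  do.call(rbind, res)
}

## spacer mismatch indices (PAM-distal = 1) between protospacer and site
## sequence, both given 5'->3' in protospacer orientation
mismatch_positions <- function(enzyme, protospacer, site_seq) {
  a <- str_chars(protospacer); b <- str_chars(site_seq)
  idx <- which(a != b)
  if (enzyme$pam_side == "3prime") idx else enzyme$spacer_length + 1L - idx
}

#' Find genomic off-target sites of a guide
#'
#' Exhaustively scans every FASTA record on both strands for sites within
#' `max_mismatches` of the protospacer that are flanked, on the enzyme's PAM
#' side, by one of the enzyme's off-target PAMs. The on-target site itself
#' is excluded.
#'
#' @param guide one row of the candidate table from
#'   [enumerate_protospacers()] (or a list with the same fields).
#' @param genome a `GenomeIndex`.
#' @param enzyme a `CasEnzyme`.
#' @param max_mismatches maximum spacer mismatches (default 4).
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `pam_seq`,
#'   `mismatches`, `mit_hit_score` and a list-column `mismatch_positions`
#'   (spacer indices, PAM-distal = 1).
#' @export
find_offtargets <- function(guide, genome, enzyme, max_mismatches = 4) {
  sl <- enzyme$spacer_length; pl <- pam_length(enzyme)
  sites <- scan_mismatch_sites(genome, guide$protospacer, max_mismatches)
  keep <- logical(nrow(sites))
  pam_seq <- character(nrow(sites))
  mmpos <- vector("list", nrow(sites))
  hitscore <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]; st <- sites$start[i]; en <- sites$end[i]
    strand <- sites$strand[i]
    ## on-target exclusion
    if (ch == guide$chrom && st == guide$start && strand == guide$strand) next
    L <- genome$lengths[[ch]]
    ## PAM interval on the genome for this site
    if (enzyme$pam_side == "3prime") {
      if (strand == "+") { ps <- en + 1L; pe <- en + pl }
      else { ps <- st - pl; pe <- st - 1L }
    } else {
      if (strand == "+") { ps <- st - pl; pe <- st - 1L }
      else { ps <- en + 1L; pe <- en + pl }
    }
    if (ps < 1L || pe > L) next
    pam <- get_sequence(genome, ch, ps, pe, strand)
    if (!any(vapply(enzyme$offtarget_pams, function(p) iupac_match(pam, p),
                    logical(1)))) next
    site_seq <- get_sequence(genome, ch, st, en, strand)
    mp <- mismatch_positions(enzyme, guide$protospacer, site_seq)
    keep[i] <- TRUE
    pam_seq[i] <- pam
    mmpos[[i]] <- mp
    hitscore[i] <- mit_hit_score(mp, enzyme$spacer_length)
  }
  out <- sites[keep, c("chrom", "start", "end", "strand", "mismatches"),
               drop = FALSE]
  out$pam_seq <- pam_seq[keep]
  out$mit_hit_score <- hitscore[keep]
  out$mismatch_positions <- mmpos[keep]
  rownames(out) <- NULL
  out
}

.mit_weights_env <- new.env(parent = emptyenv())

mit_weights <- function() {
  if (is.null(.mit_weights_env$w)) {
    tab <- read_table_csv("mit_position_weights.csv")
    .mit_weights_env$w <- tab$weight[order(tab$position)]
  }
  .mit_weights_env$w
}

#' MIT/Hsu single-hit off-target score
#'
#' The published single-hit formula: the product over mismatched positions of
#' `(1 - w[p])` with the 20 vendored position weights (position 1 =
#' PAM-distal), multiplied by a mean-pairwise-distance factor
#' `1 / (((19 - d)/19) * 4 + 1)` (d = mean distance between consecutive
#' mismatches) and `1 / n^2`, scaled to 0-100. Zero mismatches score 100.
#'
#' @param mismatch_positions integer vector of spacer indices (PAM-distal = 1).
#' @param spacer_length spacer length (default 20; the weight table is
#'   defined for 20-nt spacers).
#' @return score in `[0, 100]`.
#' @export
mit_hit_score <- function(mismatch_positions, spacer_length = 20L) {
  n <- length(mismatch_positions)
  if (n == 0) return(100)
  if (any(mismatch_positions < 1 | mismatch_positions > spacer_length))
    stop("mismatch position out of range [1, ", spacer_length, "]")
  w <- mit_weights()
  score <- prod(1 - w[mismatch_positions])
  if (n > 1) {
    p <- sort(mismatch_positions)
    d <- (max(p) - min(p)) / (n - 1)
    score <- score * (1 / (((19 - d) / 19) * 4 + 1)) * (1 / n^2)
  }
  100 * score
}

#' Aggregate off-target hits into a guide specificity score
#'
#' `100 * 100 / (100 + sum of single-hit MIT scores)`, i.e. the published
#' aggregation scaled to a 0-100 range so that the 45/65 weighting
#' thresholds apply directly. A guide with no off-targets scores 100.
#'
#' @param hits data.frame from [find_offtargets()] (only the
#'   `mit_hit_score` column is used), or a numeric vector of hit scores.
#' @return specificity score in `[0, 100]`.
#' @export
aggregate_specificity <- function(hits) {
  s <- if (is.data.frame(hits)) hits$mit_hit_score else hits
  100 * 100 / (100 + sum(s))
}

#' On-target specificity weight
#'
#' Piecewise linear in the aggregated specificity score: 0 below 45, 1 above
#' 65, linear interpolation between.
#'
#' @param score specificity score in `[0, 100]`.
#' @return weight in `[0, 1]`.
#' @export
specificity_weight <- function(score) {
  pmin(1, pmax(0, (score - 45) / 20))
}

#' Cut-to-insert distance weight
#'
#' Gaussian `exp(-d^2 / 110)` of the absolute distance (bp) between the cut
#' site and the insertion site.
#'
#' @param cut_to_insert non-negative distance in bp.
#' @return weight in `(0, 1]`.
#' @export
distance_weight <- function(cut_to_insert) {
  exp(-cut_to_insert^2 / 110)
}

#' Positional weight penalizing 5'UTR and splice-junction cuts
#'
#' Weight 1 for cuts in CDS, 3'UTR or deep-intronic positions; 0.4 for cuts
#' inside a 5'UTR; 0.1 within 2 bp (exon side) or 6 bp (intron side) of a
#' splice junction, ramping linearly back to 1 over the following 10 bp.
#' The 5'UTR and junction penalties combine by minimum. Without transcript
#' context, or when disabled, the weight is 1.
#'
#' @param cut_site genomic coordinate of the cut.
#' @param model a `TranscriptModel` or `NULL`.
#' @param enabled logical; `FALSE` disables the penalty.
#' @param utr5_weight,junction_weight,ramp_bp penalty configuration.
#' @return weight in `[0, 1]`.
#' @export
position_weight <- function(cut_site, model = NULL, enabled = TRUE,
                            utr5_weight = 0.4, junction_weight = 0.1,
                            ramp_bp = 10) {
  if (!enabled || is.null(model)) return(1)
  cl <- classify_position(cut_site, model)
  w_region <- if (cl$class == "UTR5") utr5_weight else 1
  w_junc <- 1
  if (!is.na(cl$junction_distance)) {
    core <- if (identical(cl$junction_side, "exon")) 2 else 6
    d <- cl$junction_distance
    if (d <= core) w_junc <- junction_weight
    else if (d <= core + ramp_bp)
      w_junc <- junction_weight + (1 - junction_weight) * (d - core) / ramp_bp
  }
  min(w_region, w_junc)
}

#' Score guide candidates
#'
#' Runs the off-target search and computes the three ranking weights and the
#' composite score for every candidate.
#'
#' @param candidates data.frame from [enumerate_protospacers()].
#' @param genome a `GenomeIndex`.
#' @param enzyme a `CasEnzyme`.
#' @param insert_site genomic coordinate of the payload insertion (the
#'   payload goes between `insert_site` and `insert_site + 1`).
#' @param model optional `TranscriptModel` supplying positional context.
#' @param position_weight_enabled logical.
#' @param max_mismatches off-target search depth (default 4).
#' @return the candidate data.frame with added columns `specificity_score`,
#'   `n_offtargets`, `distance_to_insert`, `w_spec`, `w_dist`, `w_pos`,
#'   `composite`.
#' @export
score_guides <- function(candidates, genome, enzyme, insert_site,
                         model = NULL, position_weight_enabled = TRUE,
                         max_mismatches = 4) {
  n <- nrow(candidates)
  spec <- numeric(n); noff <- integer(n); wpos <- numeric(n)
  for (i in seq_len(n)) {
    hits <- find_offtargets(candidates[i, ], genome, enzyme, max_mismatches)
    noff[i] <- nrow(hits)
    spec[i] <- aggregate_specificity(hits)
    wpos[i] <- position_weight(candidates$cut_site[i], model,
                               position_weight_enabled)
  }
  candidates$specificity_score <- spec
  candidates$n_offtargets <- noff
  candidates$distance_to_insert <- abs(candidates$cut_site - insert_site)
  candidates$w_spec <- specificity_weight(spec)
  candidates$w_dist <- distance_weight(candidates$distance_to_insert)
  candidates$w_pos <- wpos
  candidates$composite <- candidates$w_spec * candidates$w_dist *
    candidates$w_pos
  candidates
}

#' Rank scored guides and return the top k
#'
#' Stable deterministic ordering: composite descending, then cut-to-insert
#' distance ascending, then specificity score descending, then leftmost
#' genomic start, then strand.
#'
#' @param candidates scored candidate data.frame from [score_guides()].
#' @param k number of guides to return.
#' @return the top `k` rows with a `rank` column; zero rows (with a warning)
#'   when no candidates exist.
#' @export
rank_guides <- function(candidates, k = 1) {
  if (nrow(candidates) == 0) {
    warning("no guide candidates in the search window")
    candidates$rank <- integer(0)
    return(candidates)
  }
  ord <- order(-candidates$composite, candidates$distance_to_insert,
               -candidates$specificity_score, candidates$start,
               candidates$strand)
  out <- candidates[ord[seq_len(min(k, nrow(candidates)))], , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
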