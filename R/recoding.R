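## Mutational recoding of HDR donors: plan the fewest single-base mutations
## (silent in CDS, complement transversions in non-coding sequence) that
## bring the donor's maximal CFD re-cut potential below threshold, and/or
## recode the cut-to-insert "repair track". Splice junctions are protected;
## the payload is never recoded; protein sequence is always preserved.

.codon_env <- new.env(parent = emptyenv())

#' Codon usage table
#'
#' @param organism currently `"human"` (vendored standard frequencies).
#' @return named numeric vector of per-codon fractions (sums to 1 over 64).
#' @export
codon_usage <- function(organism = "human") {
  key <- paste0("usage_", organism)
  if (is.null(.codon_env[[key]])) {
    tab <- read_table_csv(paste0("codon_usage_", organism, ".csv"))
    .codon_env[[key]] <- stats::setNames(tab$fraction, tab$codon)
  }
  .codon_env[[key]]
}

GENETIC_CODE_VEC <- Biostrings::GENETIC_CODE

aa_of <- function(codon) unname(GENETIC_CODE_VEC[codon])

## synonyms of a codon (standard code; stop codons form their own group)
synonyms_of <- function(codon) {
  names(GENETIC_CODE_VEC)[GENETIC_CODE_VEC == aa_of(codon)]
}

## eligibility per the rare-codon rule: usage >= 7e-3 AND >= half the median
## usage of the synonym group
codon_eligible <- function(codon, usage) {
  grp <- synonyms_of(codon)
  med <- stats::median(usage[grp])
  usage[[codon]] >= 7e-3 && usage[[codon]] >= med / 2
}

#' Maximally divergent eligible synonymous codon
#'
#' Among synonyms passing the rare-codon rule (usage at least 7.0e-3 and at
#' least half the median usage of the synonym group), returns the codon with
#' the most base differences from the input; ties are broken by the highest
#' usage. Returns `NA` when no eligible synonym differs.
#'
#' @param codon 3-letter codon.
#' @param usage codon usage vector from [codon_usage()].
#' @return alternative codon string or `NA_character_`.
#' @export
synonymous_substitution <- function(codon, usage = codon_usage()) {
  syn <- setdiff(synonyms_of(codon), codon)
  syn <- syn[vapply(syn, codon_eligible, logical(1), usage = usage)]
  if (!length(syn)) return(NA_character_)
  diffs <- vapply(syn, function(s)
    sum(str_chars(s) != str_chars(codon)), integer(1))
  best <- syn[diffs == max(diffs)]
  best[which.max(usage[best])]
}

#' Splice-protection mask
#'
#' Genomic positions around every exon/intron junction of the model that must
#' not be recoded: `exonic` bases on the exon side and `intronic` bases on
#' the intron side of each junction (defaults 3 and 6, covering the
#' conserved GT/AG dinucleotides and branch-proximal motifs).
#'
#' @param model a `TranscriptModel`.
#' @param win_start,win_end genomic window to clip the mask to.
#' @param exonic,intronic window half-widths in bp.
#' @return integer vector of protected genomic positions.
#' @export
splice_protection_mask <- function(model, win_start, win_end,
                                   exonic = 3, intronic = 6) {
  j <- junctions_of(model)
  pos <- integer(0)
  for (i in seq_len(nrow(j))) {
    e <- j$exon_edge[i]; n <- j$intron_edge[i]
    dir_ex <- sign(e - n)                 # toward exon interior
    pos <- c(pos, e + dir_ex * (0:(exonic - 1)),
             n - dir_ex * (0:(intronic - 1)))
  }
  sort(unique(pos[pos >= win_start & pos <= win_end]))
}

## -- donor annotation ------------------------------------------------------

#' Annotate every donor position with region class, frame and protection
#'
#' @param donor a `DonorDesign`.
#' @param model a `TranscriptModel` or `NULL` (no transcript context: all
#'   arm positions are non-coding and unprotected).
#' @param exonic,intronic splice-protection half-widths.
#' @return a `DonorAnnotation`: data.frame with one row per donor offset
#'   (`offset`, `genomic`, `region` in cds/noncoding/payload, `protected`,
#'   `frame`), with the model attached as an attribute.
#' @export
annotate_donor <- function(donor, model = NULL, exonic = 3, intronic = 6) {
  L <- nchar(donor$sequence)
  off <- seq_len(L)
  gen <- donor_offset_to_genomic(donor, off)
  region <- ifelse(is.na(gen), "payload", "noncoding")
  protected <- is.na(gen)                 # payload is never recoded
  frame <- rep(NA_integer_, L)
  if (!is.null(model)) {
    mask <- splice_protection_mask(model, donor$win_start, donor$win_end,
                                   exonic, intronic)
    arm <- which(!is.na(gen))
    incds <- gen[arm] %in% as.numeric(names(model$frame_map))
    region[arm[incds]] <- "cds"
    frame[arm[incds]] <- unname(model$frame_map[as.character(gen[arm[incds]])])
    protected[arm] <- protected[arm] | (gen[arm] %in% mask)
  }
  ann <- data.frame(offset = off, genomic = gen, region = region,
                    protected = protected, frame = frame)
  attr(ann, "model") <- model
  class(ann) <- c("DonorAnnotation", class(ann))
  ann
}

## codon context of a CDS genomic position: genomic positions of the codon's
## three bases in transcript (reading) order, and the index of `g` within it
codon_context <- function(model, g) {
  idx <- match(as.character(g), names(model$frame_map))
  if (is.na(idx)) return(NULL)
  c0 <- ((idx - 1) %/% 3) * 3
  list(positions = as.integer(names(model$frame_map)[c0 + 1:3]),
       within = idx - c0)
}

## current codon (in reading orientation) for a CDS genomic position, taking
## already-mutated donor bases where the codon overlaps the donor
current_codon <- function(model, genome, donor, donor_seq, ctx) {
  base_at <- function(g) {
    off <- genomic_to_donor_offset(donor, g)
    b <- if (!is.na(off)) substr(donor_seq, off, off)
         else get_sequence(genome, model$chrom, g, g)
    if (model$strand == "-") complement_base(b) else b
  }
  paste0(vapply(ctx$positions, base_at, character(1)), collapse = "")
}

## single-base silent alternatives (donor-strand bases) at donor offset
## `off`; returns character vector of alternative donor bases
silent_alternatives <- function(off, ann, donor, donor_seq, genome, usage) {
  model <- attr(ann, "model")
  g <- ann$genomic[off]
  ctx <- codon_context(model, g)
  if (is.null(ctx)) return(character(0))
  cod <- current_codon(model, genome, donor, donor_seq, ctx)
  if (grepl("[^ACGT]", cod)) return(character(0))
  k <- ctx$within
  cur_read <- substr(cod, k, k)            # base in reading orientation
  alts <- character(0)
  for (b in setdiff(BASES, cur_read)) {
    newcod <- cod
    substr(newcod, k, k) <- b
    if (aa_of(newcod) != aa_of(cod)) next
    if (!codon_eligible(newcod, usage)) next
    alts <- c(alts, if (model$strand == "-") complement_base(b) else b)
  }
  alts
}

## complement transversion (A<->T, G<->C) of a base
transversion_of <- function(b) complement_base(b)

apply_mutation_str <- function(s, off, alt) {
  substr(s, off, off) <- alt
  s
}

empty_mutations <- function() {
  data.frame(offset = integer(0), genomic = integer(0),
             ref = character(0), alt = character(0),
             class = character(0), region = character(0))
}

new_recoding_plan <- function(mutations, residual, level, feasible = TRUE) {
  plan <- list(mutations = mutations, residual_max_cfd = residual,
               level = level, feasible = feasible)
  class(plan) <- "RecodingPlan"
  plan
}

#' @export
print.RecodingPlan <- function(x, ...) {
  cat("RecodingPlan (", x$level, "): ", nrow(x$mutations), " mutation(s), ",
      "residual max CFD ", signif(x$residual_max_cfd, 3),
      if (!x$feasible) "  [RESIDUAL ABOVE THRESHOLD]" else "", "\n", sep = "")
  invisible(x)
}

## candidate single-base mutations at the given donor offsets
recut_candidates <- function(offsets, ann, donor, donor_seq, genome, usage,
                             coding_only) {
  out <- list()
  for (p in offsets) {
    if (p < 1 || p > nrow(ann)) next
    if (ann$protected[p]) next
    reg <- ann$region[p]
    if (reg == "payload") next
    cur <- substr(donor_seq, p, p)
    if (reg == "cds") {
      for (alt in silent_alternatives(p, ann, donor, donor_seq, genome, usage))
        out[[length(out) + 1]] <- list(offset = p, ref = cur, alt = alt,
                                       class = "silent")
    } else if (!coding_only) {
      out[[length(out) + 1]] <- list(offset = p, ref = cur,
                                     alt = transversion_of(cur),
                                     class = "noncoding_transversion")
    }
  }
  out
}

## donor offsets covered by the worst-scoring window, and which of them are
## PAM positions (accounting for window strand)
window_offsets <- function(hit, enzyme) {
  wl <- enzyme$spacer_length + pam_length(enzyme)
  offs <- hit$offset:(hit$offset + wl - 1)
  pam_at_high <- (enzyme$pam_side == "3prime") == (hit$strand == "+")
  pam_offs <- if (pam_at_high) offs[(wl - pam_length(enzyme) + 1):wl]
              else offs[1:pam_length(enzyme)]
  list(all = offs, pam = pam_offs)
}

#' Plan re-cut-preventing mutations
#'
#' Greedy fewest-mutation search: every allowed single-base mutation inside
#' the current worst-scoring CFD window is scored by the donor-wide maximal
#' CFD it leaves behind; the best is applied and the donor re-scanned, until
#' the maximum drops below `threshold`. With `priority = "PAM_first"`
#' (default) PAM-disrupting candidates are preferred whenever one improves
#' the score. For plans of three or more mutations an exhaustive search over
#' smaller candidate subsets is run to restore minimality where the greedy
#' path overshot. If the threshold is unreachable under the constraints the
#' best-effort plan is returned flagged infeasible.
#'
#' @param donor a `DonorDesign`.
#' @param ann a `DonorAnnotation` for it.
#' @param protospacer guide protospacer whose re-cutting is to be prevented.
#' @param model_cfd a `CFDModel`.
#' @param genome the `GenomeIndex` (codon context can extend past the donor).
#' @param threshold residual CFD threshold (default 0.03).
#' @param priority `"PAM_first"` or `"protospacer_first"`.
#' @param coding_only restrict mutations to protein-coding positions.
#' @param usage codon usage vector.
#' @return a `RecodingPlan` (level `"prevent_recut"`).
#' @export
plan_recut_mutations <- function(donor, ann, protospacer, model_cfd, genome,
                                 threshold = 0.03,
                                 priority = c("PAM_first", "protospacer_first"),
                                 coding_only = FALSE,
                                 usage = codon_usage()) {
  priority <- match.arg(priority)
  enzyme <- model_cfd$enzyme
  seq_cur <- donor$sequence
  muts <- empty_mutations()
  pool <- list()
  hit <- max_cfd_in_donor(seq_cur, protospacer, model_cfd)
  for (iter in seq_len(12)) {
    if (hit$score < threshold) break
    wo <- window_offsets(hit, enzyme)
    cands <- recut_candidates(wo$all, ann, donor, seq_cur, genome, usage,
                              coding_only)
    if (!length(cands)) break
    scores <- vapply(cands, function(cd)
      max_cfd_in_donor(apply_mutation_str(seq_cur, cd$offset, cd$alt),
                       protospacer, model_cfd)$score, numeric(1))
    is_pam <- vapply(cands, function(cd) cd$offset %in% wo$pam, logical(1))
    pick_from <- if (priority == "PAM_first" && any(is_pam & scores < hit$score))
      which(is_pam) else seq_along(cands)
    pick_from <- pick_from[scores[pick_from] < hit$score]
    if (!length(pick_from)) break
    ord <- pick_from[order(scores[pick_from],
                           vapply(cands[pick_from], `[[`, 0L, "offset"))]
    best <- ord[1]
    cd <- cands[[best]]
    pool <- c(pool, cands)
    seq_cur <- apply_mutation_str(seq_cur, cd$offset, cd$alt)
    muts <- rbind(muts, data.frame(offset = cd$offset,
                                   genomic = ann$genomic[cd$offset],
                                   ref = cd$ref, alt = cd$alt,
                                   class = cd$class, region = "recut"))
    hit <- max_cfd_in_donor(seq_cur, protospacer, model_cfd)
  }
  ## minimality refinement: a greedy plan of k >= 3 may hide a smaller one
  if (nrow(muts) >= 3 && length(pool)) {
    keys <- vapply(pool, function(cd) paste(cd$offset, cd$alt), character(1))
    pool <- pool[!duplicated(keys)]
    n <- length(pool)
    found <- NULL
    if (n <= 80) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          a <- pool[[i]]; b <- pool[[j]]
          if (a$offset == b$offset) next
          s2 <- apply_mutation_str(apply_mutation_str(donor$sequence,
                 a$offset, a$alt), b$offset, b$alt)
          if (max_cfd_in_donor(s2, protospacer, model_cfd)$score < threshold) {
            found <- list(a, b); break
          }
        }
        if (!is.null(found)) break
      }
    }
    if (!is.null(found)) {
      seq_cur <- donor$sequence
      muts <- empty_mutations()
      for (cd in found) {
        seq_cur <- apply_mutation_str(seq_cur, cd$offset, cd$alt)
        muts <- rbind(muts, data.frame(offset = cd$offset,
                                       genomic = ann$genomic[cd$offset],
                                       ref = cd$ref, alt = cd$alt,
                                       class = cd$class, region = "recut"))
      }
      hit <- max_cfd_in_donor(seq_cur, protospacer, model_cfd)
    }
  }
  new_recoding_plan(muts, hit$score, "prevent_recut",
                    feasible = hit$score < threshold)
}

#' Plan repair-track mutations in the cut-to-insert region
#'
#' Every codon lying fully inside the cut-to-insert region (and free of
#' protected positions) receives its maximally divergent non-rare synonymous
#' substitution; non-coding stretches receive complement transversions at up
#' to one of every three bases (at least two unmutated bases between
#' consecutive mutations, scanning from the cut site toward the payload).
#'
#' @param donor a `DonorDesign`.
#' @param ann a `DonorAnnotation`.
#' @param cut_offset donor offset of the base 5' of the cut (left-base
#'   convention); the repair track runs from the cut to the payload junction.
#' @param genome a `GenomeIndex`.
#' @param usage codon usage vector.
#' @return a `RecodingPlan` (level `"repair_track"`).
#' @export
plan_repair_track_mutations <- function(donor, ann, cut_offset, genome,
                                        usage = codon_usage()) {
  p1 <- donor$payload_start; p2 <- donor$payload_end
  if (donor$payload_len == 0) { p1 <- donor$arm5_len + 1L; p2 <- donor$arm5_len }
  if (cut_offset <= donor$arm5_len) {
    region <- seq2(cut_offset + 1L, p1 - 1L)
    toward <- region                        # already cut -> payload order
  } else {
    region <- seq2(p2 + 1L, cut_offset)
    toward <- rev(region)                   # scan from cut toward payload
  }
  muts <- empty_mutations()
  if (!length(region))
    return(new_recoding_plan(muts, NA_real_, "repair_track"))
  seq_cur <- donor$sequence
  model <- attr(ann, "model")
  done_codons <- character(0)
  mutated_off <- integer(0)
  ## pass 1: whole-codon synonymous substitutions for codons fully inside
  if (!is.null(model)) {
    for (p in toward) {
      if (ann$region[p] != "cds" || ann$protected[p]) next
      ctx <- codon_context(model, ann$genomic[p])
      if (is.null(ctx)) next
      key <- paste(ctx$positions, collapse = ",")
      if (key %in% done_codons) next
      done_codons <- c(done_codons, key)
      offs <- genomic_to_donor_offset(donor, ctx$positions)
      if (anyNA(offs) || !all(offs %in% region)) next
      if (any(ann$protected[offs])) next
      cod <- current_codon(model, genome, donor, seq_cur, ctx)
      if (grepl("[^ACGT]", cod)) next
      alt <- synonymous_substitution(cod, usage)
      if (is.na(alt)) next
      for (k in 1:3) {
        if (substr(alt, k, k) == substr(cod, k, k)) next
        b <- substr(alt, k, k)
        if (model$strand == "-") b <- complement_base(b)
        muts <- rbind(muts, data.frame(offset = offs[k],
                                       genomic = ctx$positions[k],
                                       ref = substr(seq_cur, offs[k], offs[k]),
                                       alt = b, class = "silent",
                                       region = "repair_track"))
        seq_cur <- apply_mutation_str(seq_cur, offs[k], b)
        mutated_off <- c(mutated_off, offs[k])
      }
    }
  }
  ## pass 2: non-coding transversions at <= 1 of every 3 bases
  last_mut <- -Inf
  for (p in toward) {
    if (ann$region[p] != "noncoding" || ann$protected[p]) next
    if (any(abs(p - mutated_off) < 3)) next
    if (abs(p - last_mut) < 3) next
    cur <- substr(seq_cur, p, p)
    if (!cur %in% BASES) next
    alt <- transversion_of(cur)
    muts <- rbind(muts, data.frame(offset = p, genomic = ann$genomic[p],
                                   ref = cur, alt = alt,
                                   class = "noncoding_transversion",
                                   region = "repair_track"))
    seq_cur <- apply_mutation_str(seq_cur, p, alt)
    last_mut <- p
    mutated_off <- c(mutated_off, p)
  }
  new_recoding_plan(muts, NA_real_, "repair_track")
}

seq2 <- function(from, to) if (from > to) integer(0) else seq(from, to)

#' Apply a recoding plan to a donor
#'
#' Mutates the donor sequence, attaches (or merges) the plan, recomputes the
#' residual maximal CFD when a protospacer is supplied, and updates the
#' effective homology-arm lengths (recoded stretches do not count as
#' homology: the effective arm runs from the arm's distal end to the
#' payload-proximal-most recoded base).
#'
#' @param donor a `DonorDesign`.
#' @param plan a `RecodingPlan`.
#' @param protospacer,model_cfd optional; when given, `residual_max_cfd` is
#'   recomputed over the fully mutated donor.
#' @return the mutated `DonorDesign` with `recoding` attached.
#' @export
apply_recoding_plan <- function(donor, plan, protospacer = NULL,
                                model_cfd = NULL) {
  m <- plan$mutations
  s <- donor$sequence
  for (i in seq_len(nrow(m))) s <- apply_mutation_str(s, m$offset[i], m$alt[i])
  donor$sequence <- s
  if (!is.null(donor$recoding)) {
    prev <- donor$recoding$mutations
    m <- rbind(prev, m)
    level <- "full"
    feasible <- plan$feasible && donor$recoding$feasible
  } else {
    level <- plan$level
    feasible <- plan$feasible
  }
  residual <- plan$residual_max_cfd
  if (!is.null(protospacer) && !is.null(model_cfd))
    residual <- max_cfd_in_donor(s, protospacer, model_cfd)$score
  donor$recoding <- new_recoding_plan(m, residual, level, feasible)
  if (nrow(m)) {
    in5 <- m$offset[m$offset <= donor$arm5_len]
    in3 <- m$offset[m$offset > donor$payload_end]
    donor$effective_arm5_len <- if (length(in5)) min(in5) - 1L else donor$arm5_len
    donor$effective_arm3_len <- if (length(in3))
      nchar(donor$sequence) - max(in3) else donor$arm3_len
  }
  donor
}
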