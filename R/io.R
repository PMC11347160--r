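## Submission parsing, per-design orchestration (guides -> recoding ->
## donor -> primers) and CSV/GenBank output. One malformed design never
## aborts the batch; outputs are deterministic given inputs and config.

SUBMISSION_COLUMNS <- c("design_id", "target", "payload", "enzyme",
                        "num_guides", "donor_mode", "arm5_len", "arm3_len",
                        "ssodn_max_len", "recoding_level", "strand_mode",
                        "trim_enabled", "min_arm_len", "forbidden_motifs",
                        "primer_mode", "position_weight")

request_defaults <- function() {
  list(payload = "", enzyme = "SpCas9", num_guides = 1L,
       donor_mode = "dsDNA", arm5_len = 500L, arm3_len = 500L,
       ssodn_max_len = 200L, recoding_level = "full", strand_mode = "auto",
       trim_enabled = FALSE, min_arm_len = 100L, forbidden_motifs = "",
       primer_mode = "", position_weight = TRUE)
}

#' Parse a submission list
#'
#' Reads a CSV (or takes a data.frame) of design requests. Mandatory
#' columns: `design_id`, `target`; all others default per
#' `request_defaults`. Targets take one of three forms:
#' `"TRANSCRIPT,N"` / `"TRANSCRIPT,C"` (terminal insertion on an annotated
#' transcript), `"chrom:position"` (coordinate), or
#' `"TRANSCRIPT,chrom:position"` (coordinate with transcript context).
#'
#' @param x CSV path or data.frame.
#' @return list of `DesignRequest` lists.
#' @export
parse_submission <- function(x) {
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE,
                                             colClasses = "character")
        else as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(c("design_id", "target") %in% names(df)))
    stop("submission must have 'design_id' and 'target' columns")
  defs <- request_defaults()
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, , drop = FALSE])
    req <- defs
    req$design_id <- as.character(row$design_id)
    req$target <- as.character(row$target)
    for (nm in names(defs)) {
      if (!is.null(row[[nm]]) && !is.na(row[[nm]]) && row[[nm]] != "") {
        v <- row[[nm]]
        req[[nm]] <- switch(nm,
          num_guides = , arm5_len = , arm3_len = , ssodn_max_len = ,
          min_arm_len = as.integer(v),
          trim_enabled = , position_weight = as.logical(toupper(v) %in%
            c("TRUE", "T", "1", "YES")),
          as.character(v))
      }
    }
    class(req) <- "DesignRequest"
    req
  })
}

## resolve a target string into chrom / insert_site / transcript model
resolve_target <- function(target, models) {
  parts <- strsplit(target, ",", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  model <- NULL; terminus <- NULL; coord <- NULL
  for (p in parts) {
    if (grepl(":", p, fixed = TRUE)) coord <- p
    else if (toupper(p) %in% c("N", "C")) terminus <- toupper(p)
    else model <- find_transcript(models, p)
  }
  if (!is.null(coord)) {
    cp <- strsplit(coord, ":", fixed = TRUE)[[1]]
    if (length(cp) != 2 || is.na(suppressWarnings(as.integer(cp[2]))))
      stop("malformed coordinate target: ", coord)
    return(list(chrom = cp[1], insert_site = as.integer(cp[2]),
                model = model, terminus = NULL))
  }
  if (is.null(model) || is.null(terminus))
    stop("target must be 'TRANSCRIPT,N|C', 'chrom:pos' or ",
         "'TRANSCRIPT,chrom:pos': ", target)
  cds <- model$cds
  if (nrow(cds) == 0) stop("transcript ", model$transcript_id, " has no CDS")
  insert_site <- if (model$strand == "+") {
    if (terminus == "N") cds$start[1] + 2L else cds$end[nrow(cds)] - 3L
  } else {
    if (terminus == "N") cds$end[1] - 3L else cds$start[nrow(cds)] + 2L
  }
  list(chrom = model$chrom, insert_site = insert_site, model = model,
       terminus = terminus)
}

#' Pipeline configuration defaults
#'
#' @param guide_window_bp half-width of the guide search window around the
#'   insertion site (cut sites farther than this are not considered; the
#'   distance weight is negligible beyond 50 bp).
#' @param cfd_threshold re-cut recoding threshold.
#' @param recut_priority `"PAM_first"` or `"protospacer_first"`.
#' @param coding_only restrict recoding to protein-coding positions.
#' @param max_mismatches off-target search depth.
#' @return named list.
#' @export
design_config <- function(guide_window_bp = 50, cfd_threshold = 0.03,
                          recut_priority = "PAM_first", coding_only = FALSE,
                          max_mismatches = 4) {
  list(guide_window_bp = guide_window_bp, cfd_threshold = cfd_threshold,
       recut_priority = recut_priority, coding_only = coding_only,
       max_mismatches = max_mismatches)
}

## run one design request end to end
design_one <- function(req, genome, models, config = design_config()) {
  warnings <- character(0)
  wcollect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  tgt <- resolve_target(req$target, models)
  chrom <- tgt$chrom; insert_site <- tgt$insert_site; model <- tgt$model
  enzyme <- cas_enzyme(req$enzyme)
  payload <- toupper(req$payload)
  if (!is.null(tgt$terminus) && nchar(payload) %% 3 != 0 &&
      nchar(payload) > 0)
    warnings <- c(warnings, "payload length is not a multiple of 3 for an in-frame terminal insertion")
  ## payload is supplied in transcript sense; place it on the genome + strand
  payload_genomic <- if (!is.null(model) && model$strand == "-" &&
                         !is.null(tgt$terminus)) revcomp(payload) else payload

  ## -- guides --
  w <- config$guide_window_bp
  margin <- enzyme$spacer_length + pam_length(enzyme)
  win_lo <- max(1L, insert_site - w - margin)
  win_hi <- min(genome$lengths[[chrom]], insert_site + w + margin)
  cands <- enumerate_protospacers(genome, enzyme, chrom, win_lo, win_hi)
  cands <- cands[abs(cands$cut_site - insert_site) <= w, , drop = FALSE]
  cands <- wcollect(score_guides(cands, genome, enzyme, insert_site, model,
                                 isTRUE(req$position_weight),
                                 config$max_mismatches))
  guides <- wcollect(rank_guides(cands, req$num_guides))

  donor <- NULL; primer_report <- NULL
  if (nchar(payload) > 0 && nrow(guides) > 0) {
    top <- guides[1, ]
    mdl <- cfd_model(enzyme)
    if (req$donor_mode == "dsDNA") {
      donor <- wcollect(assemble_donor(genome, chrom, insert_site,
                                       payload_genomic,
                                       req$arm5_len, req$arm3_len, "dsDNA"))
    } else {
      donor <- wcollect(assemble_donor(genome, chrom, insert_site,
                                       payload_genomic,
                                       req$ssodn_max_len, req$ssodn_max_len,
                                       "ssODN"))
    }
    ann <- annotate_donor(donor, model)
    if (req$recoding_level %in% c("prevent_recut", "full")) {
      ## repair-track recoding runs first so the re-cut planner has the last
      ## word on the donor's final CFD (repair mutations may otherwise
      ## recreate guide similarity)
      if (req$recoding_level == "full") {
        cut_off <- genomic_to_donor_offset(donor, top$cut_site)
        if (!is.na(cut_off)) {
          plan2 <- plan_repair_track_mutations(donor, ann, cut_off, genome)
          donor <- apply_recoding_plan(donor, plan2, top$protospacer, mdl)
        }
      }
      plan <- plan_recut_mutations(donor, ann, top$protospacer, mdl, genome,
                                   threshold = config$cfd_threshold,
                                   priority = config$recut_priority,
                                   coding_only = config$coding_only)
      donor <- apply_recoding_plan(donor, plan, top$protospacer, mdl)
      if (!is.null(donor$recoding))
        donor$recoding$feasible <-
          donor$recoding$residual_max_cfd < config$cfd_threshold
    }
    if (req$donor_mode == "dsDNA") {
      motifs <- if (nzchar(req$forbidden_motifs))
        strsplit(req$forbidden_motifs, ";", fixed = TRUE)[[1]] else character(0)
      if (isTRUE(req$trim_enabled))
        donor <- wcollect(trim_arms(donor, req$min_arm_len, motifs))
      donor$flags <- flag_synthesis_problems(donor$sequence, motifs)
    } else {
      strand <- select_ssodn_strand(top$cut_site, insert_site, top$strand,
                                    if (is.null(model)) NA else model$strand,
                                    req$strand_mode)
      donor <- wcollect(cap_ssodn(donor, req$ssodn_max_len, top$cut_site))
      donor <- orient_ssodn(donor, strand)
      donor$flags <- flag_synthesis_problems(donor$sequence)
    }
  }
  if (nzchar(req$primer_mode))
    primer_report <- wcollect(design_genotyping_primers(genome, chrom,
                                                        insert_site,
                                                        req$primer_mode))
  res <- list(request = req, design_id = req$design_id, chrom = chrom,
              insert_site = insert_site,
              transcript = if (is.null(model)) NA_character_ else
                model$transcript_id,
              guides = guides, donor = donor, primer_report = primer_report,
              warnings = warnings, error = NULL)
  class(res) <- "DesignResult"
  res
}

#' Run a batch of design requests
#'
#' Each design runs in isolation: an error in one produces an error record
#' without aborting the others. Deterministic for fixed inputs and config.
#'
#' @param requests list from [parse_submission()].
#' @param genome a `GenomeIndex`.
#' @param models transcript models from [build_transcript_models()].
#' @param config list from [design_config()].
#' @return list of `DesignResult` objects (failed ones have `error` set).
#' @export
run_designs <- function(requests, genome, models, config = design_config()) {
  lapply(requests, function(req) {
    tryCatch(design_one(req, genome, models, config),
             error = function(e) {
               res <- list(request = req, design_id = req$design_id,
                           guides = NULL, donor = NULL, primer_report = NULL,
                           warnings = character(0),
                           error = conditionMessage(e))
               class(res) <- "DesignResult"
               res
             })
  })
}

flags_summary <- function(flags) {
  if (is.null(flags)) return("")
  parts <- character(0)
  if (nrow(flags$homopolymers))
    parts <- c(parts, paste0("homopolymer:",
      paste0(flags$homopolymers$base, flags$homopolymers$length,
             "@", flags$homopolymers$offset, collapse = "|")))
  if (flags$gc_global$flagged)
    parts <- c(parts, sprintf("gc_global:%.1f", flags$gc_global$value))
  if (flags$gc_window_skew$flagged)
    parts <- c(parts, sprintf("gc_skew:%.1f", flags$gc_window_skew$value))
  if (nrow(flags$forbidden_motif_hits))
    parts <- c(parts, paste0("motif:",
      paste0(flags$forbidden_motif_hits$motif, "@",
             flags$forbidden_motif_hits$offset, collapse = "|")))
  paste(parts, collapse = ";")
}

#' Write batch outputs
#'
#' Writes `results.csv` (one row per ranked guide, with donor, recoding and
#' top-primer columns on the rank-1 row), `primers.csv` (all returned
#' pairs), `submission_echo.csv` (the fully parameterised submission,
#' itself a valid submission reproducing the run), one GenBank file per
#' donor, and `log.txt`.
#'
#' @param results list from [run_designs()].
#' @param out_dir output directory.
#' @param models optional transcript models (for GenBank exon features).
#' @return invisible list of written paths.
#' @export
write_outputs <- function(results, out_dir, models = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); prows <- list(); log <- character(0)
  echo <- list()
  for (res in results) {
    req <- res$request
    echo[[length(echo) + 1]] <- data.frame(
      c(list(design_id = req$design_id, target = req$target),
        lapply(request_defaults(), function(x) x)[
          setdiff(SUBMISSION_COLUMNS, c("design_id", "target"))] |>
        utils::modifyList(req[setdiff(SUBMISSION_COLUMNS,
                                      c("design_id", "target"))])))
    if (!is.null(res$error)) {
      log <- c(log, paste0(res$design_id, "\tERROR\t", res$error))
      next
    }
    g <- res$guides
    for (i in seq_len(NROW(g))) {
      row <- data.frame(
        design_id = res$design_id, enzyme = req$enzyme,
        protospacer = g$protospacer[i], PAM = g$pam[i], chrom = g$chrom[i],
        cut_site = g$cut_site[i], strand = g$strand[i],
        distance_to_insert = g$distance_to_insert[i],
        specificity_score = g$specificity_score[i],
        w_spec = g$w_spec[i], w_dist = g$w_dist[i], w_pos = g$w_pos[i],
        composite = g$composite[i], rank = g$rank[i],
        donor_mode = NA, donor_strand = NA, donor_length = NA,
        arm5_len = NA, arm3_len = NA,
        effective_arm5_len = NA, effective_arm3_len = NA,
        recoding_level = NA, n_recoding_mutations = NA,
        residual_max_cfd = NA, recoding_flag = NA,
        synthesis_flags = NA, donor_sequence = NA,
        primer_fwd = NA, primer_rev = NA, primer_product_size = NA,
        primer_attempt = NA, primer_verdict = NA)
      if (i == 1 && !is.null(res$donor)) {
        d <- res$donor
        row$donor_mode <- d$mode
        row$donor_strand <- d$strand
        row$donor_length <- nchar(d$sequence)
        row$arm5_len <- d$arm5_len; row$arm3_len <- d$arm3_len
        row$effective_arm5_len <- d$effective_arm5_len
        row$effective_arm3_len <- d$effective_arm3_len
        row$recoding_level <- req$recoding_level
        if (!is.null(d$recoding)) {
          row$n_recoding_mutations <- nrow(d$recoding$mutations)
          row$residual_max_cfd <- d$recoding$residual_max_cfd
          row$recoding_flag <- if (d$recoding$feasible) "ok" else
            "residual above threshold"
        }
        row$synthesis_flags <- flags_summary(d$flags)
        row$donor_sequence <- if (d$strand == "-") d$sequence_oriented else
          d$sequence
      }
      if (i == 1 && !is.null(res$primer_report)) {
        pr <- res$primer_report
        if (!pr$failed) {
          row$primer_fwd <- pr$pairs$fwd_seq[1]
          row$primer_rev <- pr$pairs$rev_seq[1]
          row$primer_product_size <- pr$pairs$product_size[1]
          row$primer_attempt <- pr$pairs$attempt[1]
          row$primer_verdict <- "pass"
          for (k in seq_len(nrow(pr$pairs)))
            prows[[length(prows) + 1]] <- data.frame(
              design_id = res$design_id, pair_rank = k,
              mode = req$primer_mode,
              fwd_seq = pr$pairs$fwd_seq[k], rev_seq = pr$pairs$rev_seq[k],
              fwd_tm = pr$pairs$fwd_tm[k], rev_tm = pr$pairs$rev_tm[k],
              fwd_gc = pr$pairs$fwd_gc[k], rev_gc = pr$pairs$rev_gc[k],
              product_size = pr$pairs$product_size[k],
              annealing_temp_suggestion =
                pr$pairs$annealing_temp_suggestion[k],
              attempt = pr$pairs$attempt[k], verdict = "pass",
              failure_reason = "")
        } else {
          row$primer_verdict <- "fail"
          prows[[length(prows) + 1]] <- data.frame(
            design_id = res$design_id, pair_rank = NA,
            mode = req$primer_mode, fwd_seq = NA, rev_seq = NA,
            fwd_tm = NA, rev_tm = NA, fwd_gc = NA, rev_gc = NA,
            product_size = NA, annealing_temp_suggestion = NA,
            attempt = 6, verdict = "fail",
            failure_reason = pr$failure_reason)
        }
      }
      rows[[length(rows) + 1]] <- row
    }
    if (!is.null(res$donor)) {
      gb <- file.path(out_dir, paste0(res$design_id, ".gb"))
      mdl <- if (!is.null(models) && !is.na(res$transcript))
        models[[res$transcript]] else NULL
      write_genbank(res$donor, gb, name = res$design_id,
                    guide = res$guides[1, ], model = mdl)
    }
    log <- c(log, paste0(res$design_id, "\tOK\t",
                         NROW(res$guides), " guide(s)",
                         if (length(res$warnings))
                           paste0("\twarnings: ",
                                  paste(res$warnings, collapse = "; "))
                         else ""))
  }
  results_path <- file.path(out_dir, "results.csv")
  utils::write.csv(if (length(rows)) do.call(rbind, rows) else data.frame(),
                   results_path, row.names = FALSE)
  echo_path <- file.path(out_dir, "submission_echo.csv")
  utils::write.csv(do.call(rbind, echo), echo_path, row.names = FALSE)
  primers_path <- file.path(out_dir, "primers.csv")
  if (length(prows))
    utils::write.csv(do.call(rbind, prows), primers_path, row.names = FALSE)
  writeLines(log, file.path(out_dir, "log.txt"))
  invisible(list(results = results_path, echo = echo_path,
                 primers = if (length(prows)) primers_path else NULL))
}
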