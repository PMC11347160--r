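## Genotyping primer design for short- or long-read amplicon sequencing:
## locus extraction centered on the edit site, thermodynamic + positional +
## product-size filtering of candidate primer pairs, genome-wide
## annealing-site search with a 3'-anchor rule, unintended-product (in
## silico PCR) rejection, and a six-attempt constraint-relaxation ladder.

#' Primer design mode parameters
#'
#' @param name `"short"` or `"long"`.
#' @return a `PrimerMode` list: `extract_len`, `min_edit_distance`,
#'   `product_range`, `relax_size_step`, `relax_extend`.
#' @export
primer_mode <- function(name = c("short", "long")) {
  name <- match.arg(name)
  m <- if (name == "short")
    list(name = name, extract_len = 430L, min_edit_distance = 100L,
         product_range = c(250L, 350L), relax_size_step = 80L,
         relax_extend = 40L)
  else
    list(name = name, extract_len = 4000L, min_edit_distance = 1000L,
         product_range = c(3300L, 3700L), relax_size_step = 300L,
         relax_extend = 150L)
  class(m) <- "PrimerMode"
  m
}

#' Default thermodynamic constraints for primer filtering
#'
#' Primer3-style defaults: Tm 57-63 degrees C (optimum 60), pairwise delta-Tm
#' at most 3 degrees C, GC 20-80%, length 18-25 nt (optimum 20), and
#' complementarity-run caps standing in for the 3' self/pair dimer filters.
#'
#' @return named list of constraint values.
#' @export
primer_constraints <- function() {
  list(tm_min = 57, tm_opt = 60, tm_max = 63, dtm_max = 3,
       gc_min = 20, gc_max = 80, len_min = 18L, len_opt = 20L, len_max = 25L,
       any_comp_max = 8L, three_prime_comp_max = 4L)
}

#' Extract the genomic locus around an edit site
#'
#' @param genome a `GenomeIndex`.
#' @param chrom chromosome.
#' @param edit_site genomic coordinate of the edit.
#' @param mode a `PrimerMode`.
#' @param extension extra bp added on both ends (used by the relaxation
#'   ladder).
#' @return list with `sequence`, `genomic_start`, `edit_offset` (offset of
#'   the edit site within the locus sequence), `chrom`.
#' @export
extract_locus <- function(genome, chrom, edit_site, mode, extension = 0) {
  L <- genome$lengths[[chrom]]
  if (is.null(L) || edit_site < 1 || edit_site > L)
    stop("edit site ", edit_site, " outside chromosome ", chrom)
  half <- mode$extract_len %/% 2L
  start <- edit_site - half - extension
  end <- edit_site + (mode$extract_len - half - 1L) + extension
  if (start < 1 || end > L) {
    warning("locus window clipped at chromosome ends")
    start <- max(1, start); end <- min(L, end)
  }
  list(sequence = get_sequence(genome, chrom, start, end),
       genomic_start = as.integer(start),
       edit_offset = as.integer(edit_site - start + 1L),
       chrom = chrom)
}

## longest run of primer 3'-terminal bases complementary to any region of
## `other` (i.e. the longest suffix of `primer` occurring in revcomp(other))
three_prime_comp_run <- function(primer, other) {
  rc <- revcomp(other)
  n <- nchar(primer)
  run <- 0L
  for (k in seq_len(min(n, 12L))) {
    if (grepl(substr(primer, n - k + 1, n), rc, fixed = TRUE)) run <- k
    else break
  }
  run
}

## longest contiguous complementary stretch between two primers
any_comp_run <- function(primer, other, cap = 12L) {
  rc <- revcomp(other)
  best <- 0L
  n <- nchar(primer)
  for (k in seq_len(min(n, cap))) {
    found <- FALSE
    for (i in seq_len(n - k + 1)) {
      if (grepl(substr(primer, i, i + k - 1), rc, fixed = TRUE)) {
        found <- TRUE; break
      }
    }
    if (found) best <- k else break
  }
  best
}

## single-primer candidates on one side of the locus.
## side "fwd": + strand primers whose 3' end is at least min_dist left of the
## edit; side "rev": - strand primers at least min_dist right of it.
side_candidates <- function(locus, mode, cons, side, beam = 60L) {
  s <- locus$sequence
  L <- nchar(s)
  e <- locus$edit_offset
  out <- list()
  for (len in cons$len_min:cons$len_max) {
    if (side == "fwd") {
      ends <- seq_len(max(0, min(L, e - mode$min_edit_distance) - len + 1)) +
        len - 1L
      starts <- ends - len + 1L
    } else {
      starts <- seq2(e + mode$min_edit_distance, L - len + 1L)
      ends <- starts + len - 1L
    }
    for (i in seq_along(starts)) {
      sub <- substr(s, starts[i], ends[i])
      if (grepl("[^ACGT]", sub)) next
      primer <- if (side == "fwd") sub else revcomp(sub)
      gc <- gc_percent(primer)
      if (gc < cons$gc_min || gc > cons$gc_max) next
      tm <- tm_nn(primer)
      if (tm < cons$tm_min || tm > cons$tm_max) next
      if (three_prime_comp_run(primer, primer) > cons$three_prime_comp_max) next
      if (any_comp_run(primer, primer) > cons$any_comp_max) next
      out[[length(out) + 1]] <- data.frame(
        sequence = primer, start = starts[i], end = ends[i],
        length = len, tm = tm, gc = gc,
        penalty = abs(tm - cons$tm_opt) + 0.2 * abs(len - cons$len_opt))
    }
  }
  if (!length(out))
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), length = integer(0), tm = numeric(0),
                      gc = numeric(0), penalty = numeric(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$penalty, df$start), , drop = FALSE]
  utils::head(df, beam)
}

#' Enumerate candidate primer pairs for a locus
#'
#' Per-primer filters (Tm, GC, length, self-complementarity caps), the
#' positional exclusion around the edit site, the product-size window and
#' the pairwise delta-Tm cap. Candidates per side are capped to the best
#' `beam` by penalty before pairing.
#'
#' @param locus from [extract_locus()].
#' @param mode a `PrimerMode`.
#' @param cons constraint list from [primer_constraints()] (possibly
#'   relaxed).
#' @param product_range overrides the mode's product range (relaxation).
#' @param beam per-side candidate cap.
#' @return data.frame of pairs: fwd/rev sequence, positions (locus offsets),
#'   Tm, GC, `product_size`, `penalty`.
#' @export
enumerate_candidates <- function(locus, mode, cons = primer_constraints(),
                                 product_range = mode$product_range,
                                 beam = 60L) {
  fwd <- side_candidates(locus, mode, cons, "fwd", beam)
  rev_ <- side_candidates(locus, mode, cons, "rev", beam)
  empty <- data.frame(fwd_seq = character(0), rev_seq = character(0),
                      fwd_start = integer(0), fwd_end = integer(0),
                      rev_start = integer(0), rev_end = integer(0),
                      fwd_tm = numeric(0), rev_tm = numeric(0),
                      fwd_gc = numeric(0), rev_gc = numeric(0),
                      product_size = integer(0), penalty = numeric(0))
  if (!nrow(fwd) || !nrow(rev_)) return(empty)
  grid <- expand.grid(i = seq_len(nrow(fwd)), j = seq_len(nrow(rev_)))
  size <- rev_$end[grid$j] - fwd$start[grid$i] + 1L
  ok <- size >= product_range[1] & size <= product_range[2] &
    abs(fwd$tm[grid$i] - rev_$tm[grid$j]) <= cons$dtm_max
  grid <- grid[ok, , drop = FALSE]
  if (!nrow(grid)) return(empty)
  keep <- vapply(seq_len(nrow(grid)), function(k) {
    a <- fwd$sequence[grid$i[k]]; b <- rev_$sequence[grid$j[k]]
    three_prime_comp_run(a, b) <= cons$three_prime_comp_max &&
      three_prime_comp_run(b, a) <= cons$three_prime_comp_max
  }, logical(1))
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) return(empty)
  df <- data.frame(
    fwd_seq = fwd$sequence[grid$i], rev_seq = rev_$sequence[grid$j],
    fwd_start = fwd$start[grid$i], fwd_end = fwd$end[grid$i],
    rev_start = rev_$start[grid$j], rev_end = rev_$end[grid$j],
    fwd_tm = fwd$tm[grid$i], rev_tm = rev_$tm[grid$j],
    fwd_gc = fwd$gc[grid$i], rev_gc = rev_$gc[grid$j],
    product_size = rev_$end[grid$j] - fwd$start[grid$i] + 1L,
    penalty = fwd$penalty[grid$i] + rev_$penalty[grid$j])
  df <- df[order(df$penalty, df$fwd_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Find genome-wide annealing sites of a primer
#'
#' All sites on both strands within the mismatch budget (3 in `fast` mode,
#' 4 in `sensitive` mode) whose final 3'-terminal base matches the genome
#' exactly; sites failing the 3'-anchor rule are discarded.
#'
#' @param primer primer sequence (5'->3').
#' @param genome a `GenomeIndex`.
#' @param aligner_mode `"fast"` (<= 3 mismatches) or `"sensitive"` (<= 4).
#' @return data.frame `chrom`, `start`, `end` (genomic footprint), `strand`,
#'   `mismatches`, `three_prime_exact` (always TRUE).
#' @export
find_annealing_sites <- function(primer, genome,
                                 aligner_mode = c("fast", "sensitive")) {
  aligner_mode <- match.arg(aligner_mode)
  max_mm <- if (aligner_mode == "fast") 3L else 4L
  sites <- scan_mismatch_sites(genome, primer, max_mm)
  if (!nrow(sites)) {
    sites$three_prime_exact <- logical(0)
    return(sites)
  }
  last <- substr(primer, nchar(primer), nchar(primer))
  keep <- vapply(seq_len(nrow(sites)), function(i) {
    site_seq <- get_sequence(genome, sites$chrom[i], sites$start[i],
                             sites$end[i], sites$strand[i])
    substr(site_seq, nchar(primer), nchar(primer)) == last
  }, logical(1))
  sites <- sites[keep, , drop = FALSE]
  sites$three_prime_exact <- TRUE
  rownames(sites) <- NULL
  sites
}

## convergent products between two annealing-site tables: a + strand site of
## `a` left of a - strand site of `b` (3' ends facing), same chromosome,
## within max_size
convergent_products <- function(a, b, max_size, combo) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), size = integer(0),
                      combo = character(0))
  ap <- which(a$strand == "+")
  bm <- which(b$strand == "-")
  if (!length(ap) || !length(bm)) return(empty)
  grid <- expand.grid(i = ap, j = bm)
  ok <- a$chrom[grid$i] == b$chrom[grid$j] &
    b$end[grid$j] >= a$start[grid$i] &
    (b$end[grid$j] - a$start[grid$i] + 1L) <= max_size
  if (!any(ok)) return(empty)
  grid <- grid[ok, , drop = FALSE]
  data.frame(chrom = a$chrom[grid$i], start = a$start[grid$i],
             end = b$end[grid$j],
             size = b$end[grid$j] - a$start[grid$i] + 1L, combo = combo)
}

#' Detect unintended PCR products of a primer pair
#'
#' A product is predicted wherever two annealing sites sit on opposite
#' strands of the same chromosome with their 3' ends facing each other within
#' `max_size`; all three combinations (forward+reverse, forward+forward,
#' reverse+reverse) are checked. The intended product (identified by
#' coordinates) is excluded.
#'
#' @param fwd_sites,rev_sites annealing-site tables from
#'   [find_annealing_sites()].
#' @param intended list with `chrom`, `start`, `end` of the intended
#'   amplicon, or `NULL`.
#' @param max_size maximum predicted amplicon (default 6000 bp).
#' @return data.frame of off-target products (`chrom`, `start`, `end`,
#'   `size`, `combo`).
#' @export
detect_unintended_products <- function(fwd_sites, rev_sites, intended = NULL,
                                       max_size = 6000) {
  prods <- rbind(
    convergent_products(fwd_sites, rev_sites, max_size, "fwd+rev"),
    convergent_products(rev_sites, fwd_sites, max_size, "rev+fwd"),
    convergent_products(fwd_sites, fwd_sites, max_size, "fwd+fwd"),
    convergent_products(rev_sites, rev_sites, max_size, "rev+rev"))
  if (!is.null(intended) && nrow(prods)) {
    keep <- !(prods$chrom == intended$chrom & prods$start == intended$start &
                prods$end == intended$end)
    prods <- prods[keep, , drop = FALSE]
  }
  rownames(prods) <- NULL
  prods
}

#' Constraint relaxation ladder
#'
#' Attempts 1-3 raise the pairwise delta-Tm cap by 1 degree C each (3 to 6);
#' attempts 2, 4 and 6 raise the product-size upper limit by the mode's step
#' (80 bp short / 300 bp long) and extend the extracted locus by the mode's
#' extension (40 / 150 bp per end), cumulatively.
#'
#' @param mode a `PrimerMode`.
#' @param attempt integer 0-6 (0 = defaults).
#' @return list with `cons` (relaxed constraint list), `product_range`,
#'   `extension`.
#' @export
relax_constraints <- function(mode, attempt) {
  stopifnot(attempt >= 0, attempt <= 6)
  cons <- primer_constraints()
  cons$dtm_max <- cons$dtm_max + min(attempt, 3L)
  n_size <- sum(attempt >= c(2L, 4L, 6L))
  pr <- mode$product_range
  pr[2] <- pr[2] + n_size * mode$relax_size_step
  list(cons = cons, product_range = pr,
       extension = n_size * mode$relax_extend)
}

#' Design genotyping primers for an edited locus
#'
#' Runs the full pipeline: locus extraction, candidate filtering, off-target
#' annealing-site search and unintended-product rejection, escalating
#' through the six-attempt relaxation ladder until at least one pair passes.
#' Returns up to three passing pairs ranked by thermodynamic penalty.
#'
#' @param genome a `GenomeIndex`.
#' @param chrom chromosome of the edit.
#' @param edit_site genomic coordinate of the edit.
#' @param mode `"short"` or `"long"` (or a `PrimerMode`).
#' @param aligner_mode `"fast"` or `"sensitive"` off-target search.
#' @param max_product_size off-target amplicon cap (default 6000 bp).
#' @param beam per-side candidate cap passed to [enumerate_candidates()].
#' @return a `PrimerDesignReport`: list with `pairs` (data.frame; up to 3
#'   rows with sequences, Tm, GC, product size, annealing suggestion,
#'   attempt, verdict), `attempt`, `failed`, `failure_reason`.
#' @export
design_genotyping_primers <- function(genome, chrom, edit_site,
                                      mode = "short",
                                      aligner_mode = "fast",
                                      max_product_size = 6000,
                                      beam = 60L) {
  if (!inherits(mode, "PrimerMode")) mode <- primer_mode(mode)
  site_cache <- new.env(parent = emptyenv())
  sites_of <- function(primer) {
    if (is.null(site_cache[[primer]]))
      site_cache[[primer]] <- find_annealing_sites(primer, genome,
                                                   aligner_mode)
    site_cache[[primer]]
  }
  ## the relaxation ladder only loosens constraints, so the candidate set at
  ## attempt n+1 is a superset of attempt n's: off-target verdicts per
  ## (fwd, rev, intended-product) triple are cached across attempts
  verdict_cache <- new.env(parent = emptyenv())
  for (attempt in 0:6) {
    rx <- relax_constraints(mode, attempt)
    locus <- extract_locus(genome, chrom, edit_site, mode, rx$extension)
    pairs <- enumerate_candidates(locus, mode, rx$cons, rx$product_range,
                                  beam)
    passing <- list()
    for (i in seq_len(nrow(pairs))) {
      p <- pairs[i, ]
      intended <- list(chrom = locus$chrom,
                       start = locus$genomic_start + p$fwd_start - 1L,
                       end = locus$genomic_start + p$rev_end - 1L)
      key <- paste(p$fwd_seq, p$rev_seq, intended$start, intended$end)
      clean <- verdict_cache[[key]]
      if (is.null(clean)) {
        fs <- sites_of(p$fwd_seq)
        rs <- sites_of(p$rev_seq)
        prods <- detect_unintended_products(fs, rs, intended,
                                            max_product_size)
        clean <- nrow(prods) == 0
        verdict_cache[[key]] <- clean
      }
      if (!clean) next
      p$attempt <- attempt
      p$verdict <- "pass"
      p$annealing_temp_suggestion <- min(p$fwd_tm, p$rev_tm) - 1
      p$fwd_genomic_start <- intended$start
      p$rev_genomic_end <- intended$end
      passing[[length(passing) + 1]] <- p
      if (length(passing) == 3) break
    }
    if (length(passing)) {
      res <- list(pairs = do.call(rbind, passing), attempt = attempt,
                  failed = FALSE, failure_reason = NA_character_)
      class(res) <- "PrimerDesignReport"
      return(res)
    }
  }
  res <- list(pairs = NULL, attempt = 6L, failed = TRUE,
              failure_reason = paste("no primer pair free of unintended",
                                     "products after 6 relaxation attempts"))
  class(res) <- "PrimerDesignReport"
  res
}

#' @export
print.PrimerDesignReport <- function(x, ...) {
  if (x$failed) cat("Primer design FAILED:", x$failure_reason, "\n")
  else cat("Primer design:", nrow(x$pairs), "pair(s) at attempt",
           x$attempt, "\n")
  invisible(x)
}
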