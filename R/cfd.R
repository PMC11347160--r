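## Cutting Frequency Determination (CFD) scoring: per-position mismatch
## factors times a PAM factor predict the residual cutting potential of a
## mutated (or off-target) site. Model tables are vendored under
## inst/extdata; the mismatch tables are synthetic model tables (see the
## methods vignette) with the documented qualitative structure.

.cfd_env <- new.env(parent = emptyenv())

## mismatch factor array [position 1..20 (PAM-distal = 1), guide base 1..4,
## site base 1..4]; diagonal = 1
load_cfd_mismatch <- function(file) {
  tab <- read_table_csv(file)
  arr <- array(1, dim = c(20, 4, 4))
  gi <- match(tab$guide_base, BASES)
  si <- match(tab$site_base, BASES)
  arr[cbind(tab$position, gi, si)] <- tab$factor
  arr
}

load_cfd_pam <- function(file, klen) {
  tab <- read_table_csv(file)
  v <- numeric(4^klen)
  idx <- vapply(tab$pam, function(p) {
    b <- match(str_chars(p), BASES)
    sum((b - 1) * 4^((klen - 1):0)) + 1
  }, numeric(1))
  v[idx] <- tab$factor
  v
}

#' CFD scoring model for an enzyme
#'
#' @param enzyme a `CasEnzyme` (from [cas_enzyme()]).
#' @return a `CFDModel`: mismatch factor array, PAM factor lookup, enzyme.
#' @export
cfd_model <- function(enzyme) {
  key <- enzyme$name
  if (is.null(.cfd_env[[key]])) {
    mm_file <- switch(key,
      "SpCas9" = "cfd_mismatch_synthetic_spcas9.csv",
      "SpCas9-VQR" = "cfd_mismatch_synthetic_spcas9.csv",
      "enAsCas12a" = "cfd_mismatch_synthetic_encas12a.csv")
    pam_file <- switch(key,
      "SpCas9" = "cfd_pam_spcas9.csv",
      "SpCas9-VQR" = "cfd_pam_vqr_synthetic.csv",
      "enAsCas12a" = "cfd_pam_encas12a_synthetic.csv")
    ## SpCas9/VQR PAM factors are keyed on the 2 bases after the leading N
    pam_klen <- if (enzyme$pam_side == "3prime") 2L else 4L
    m <- list(mismatch = load_cfd_mismatch(mm_file),
              pam = load_cfd_pam(pam_file, pam_klen),
              pam_klen = pam_klen,
              enzyme = enzyme)
    class(m) <- "CFDModel"
    .cfd_env[[key]] <- m
  }
  .cfd_env[[key]]
}

## table position index for spacer index j (5'->3' along the protospacer):
## PAM-distal = 1, so 3'-PAM enzymes use j directly, 5'-PAM enzymes reverse
table_pos <- function(enzyme, j) {
  if (enzyme$pam_side == "3prime") j else enzyme$spacer_length + 1L - j
}

pam_factor <- function(model, pam_seq) {
  enz <- model$enzyme
  key <- if (enz$pam_side == "3prime") substr(pam_seq, 2, pam_length(enz))
         else pam_seq
  b <- match(str_chars(key), BASES)
  if (anyNA(b)) return(0)
  model$pam[sum((b - 1) * 4^((model$pam_klen - 1):0)) + 1]
}

#' CFD score of a guide against a site
#'
#' Product of per-position mismatch factors and the PAM factor. Non-ACGT
#' bases in the site are treated as mismatches with the minimal factor for
#' that position.
#'
#' @param protospacer 20-nt guide protospacer (5'->3').
#' @param site site sequence of length spacer + PAM, with the PAM on the
#'   enzyme's PAM side, read 5'->3' on the protospacer strand.
#' @param model a `CFDModel`.
#' @return score in `[0, 1]`.
#' @export
cfd_score <- function(protospacer, site, model) {
  enz <- model$enzyme
  sl <- enz$spacer_length; pl <- pam_length(enz)
  if (nchar(site) != sl + pl)
    stop("site must be spacer + PAM (", sl + pl, " nt)")
  if (enz$pam_side == "3prime") {
    proto_site <- substr(site, 1, sl); pam_site <- substr(site, sl + 1, sl + pl)
  } else {
    pam_site <- substr(site, 1, pl); proto_site <- substr(site, pl + 1, pl + sl)
  }
  g <- base_ints(protospacer); s <- base_ints(proto_site)
  score <- pam_factor(model, pam_site)
  for (j in seq_len(sl)) {
    if (s[j] == g[j]) next
    p <- table_pos(enz, j)
    f <- if (s[j] == 5L) min(model$mismatch[p, g[j], ])
         else model$mismatch[p, g[j], s[j]]
    score <- score * f
  }
  score
}

## per-window CFD scores over every position of one strand of a donor,
## vectorised. Returns numeric vector over window starts.
cfd_scan_strand <- function(seq_ints, guide_ints, model) {
  enz <- model$enzyme
  sl <- enz$spacer_length; pl <- pam_length(enz)
  wl <- sl + pl
  L <- length(seq_ints)
  n <- L - wl + 1L
  if (n < 1) return(numeric(0))
  ## guide-specific factor matrix F[j, b]: factor contributed by observing
  ## site base b at spacer position j
  F <- matrix(1, nrow = sl, ncol = 5)
  for (j in seq_len(sl)) {
    p <- table_pos(enz, j)
    for (b in 1:4) F[j, b] <- if (b == guide_ints[j]) 1 else
      model$mismatch[p, guide_ints[j], b]
    F[j, 5] <- min(model$mismatch[p, guide_ints[j], ])
  }
  sp_off <- if (enz$pam_side == "3prime") 0L else pl
  logs <- numeric(n)
  for (j in seq_len(sl)) {
    b <- seq_ints[(sp_off + j):(sp_off + j + n - 1L)]
    logs <- logs + log(F[cbind(j, b)])
  }
  ## PAM factor per window
  pk <- model$pam_klen
  pam_off <- if (enz$pam_side == "3prime") sl + (pl - pk) else 0L
  idx <- rep(0, n); bad <- rep(FALSE, n)
  for (j in seq_len(pk)) {
    b <- seq_ints[(pam_off + j):(pam_off + j + n - 1L)]
    bad <- bad | b == 5L
    idx <- idx + (pmin(b, 4L) - 1L) * 4^(pk - j)
  }
  pamf <- model$pam[idx + 1]
  pamf[bad] <- 0
  pamf * exp(logs)
}

#' Maximal CFD score over every window of a donor
#'
#' Scans both strands of the donor with the guide's CFD model and returns
#' the maximal score with its location.
#'
#' @param donor_seq donor nucleotide string.
#' @param protospacer the guide protospacer.
#' @param model a `CFDModel`.
#' @return list with `score`, `offset` (1-based start of the maximal
#'   spacer+PAM window on the given donor strand), `strand` (`"+"` = donor
#'   sense).
#' @export
max_cfd_in_donor <- function(donor_seq, protospacer, model) {
  wl <- model$enzyme$spacer_length + pam_length(model$enzyme)
  L <- nchar(donor_seq)
  if (L < wl) return(list(score = 0, offset = NA_integer_, strand = NA))
  g <- base_ints(protospacer)
  fwd <- cfd_scan_strand(base_ints(donor_seq), g, model)
  rev_ <- cfd_scan_strand(base_ints(revcomp(donor_seq)), g, model)
  bf <- if (length(fwd)) which.max(fwd) else NA
  br <- if (length(rev_)) which.max(rev_) else NA
  if (is.na(br) || (!is.na(bf) && fwd[bf] >= rev_[br])) {
    list(score = fwd[bf], offset = bf, strand = "+")
  } else {
    ## map reverse-scan window start back to + strand coordinates
    list(score = rev_[br], offset = L - br - wl + 2L, strand = "-")
  }
}
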