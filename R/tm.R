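## Nearest-neighbour melting temperature: unified SantaLucia parameters with
## SantaLucia entropy salt correction and von Ahsen divalent-cation
## correction, under standard PCR primer conditions (50 nM each strand,
## 50 mM monovalent, 1.5 mM Mg2+, 0.6 mM dNTPs).

.tm_env <- new.env(parent = emptyenv())

nn_params <- function() {
  if (is.null(.tm_env$nn)) {
    tab <- read_table_csv("nn_santalucia.csv")
    dH <- stats::setNames(tab$dH, tab$key)
    dS <- stats::setNames(tab$dS, tab$key)
    ## precompute per-dinucleotide stacks as 4x4 matrices indexed by base
    ## ints (first base, second base); unlisted keys fall back to the
    ## 180-degree-rotated duplex
    dHm <- matrix(NA_real_, 4, 4); dSm <- matrix(NA_real_, 4, 4)
    for (a in 1:4) for (b in 1:4) {
      d <- paste0(BASES[a], BASES[b])
      key <- nn_key(d)
      if (!key %in% names(dH)) key <- nn_key(revcomp(d))
      dHm[a, b] <- dH[[key]]; dSm[a, b] <- dS[[key]]
    }
    .tm_env$nn <- list(dH = dH, dS = dS, dHm = dHm, dSm = dSm)
  }
  .tm_env$nn
}

## duplex key: top dinucleotide / its complement read in the same direction
nn_key <- function(dinuc) {
  paste0(dinuc, "/",
         paste0(complement_base(str_chars(dinuc)), collapse = ""))
}

#' Nearest-neighbour primer melting temperature
#'
#' Unified nearest-neighbour duplex parameters (SantaLucia & Hicks 2004)
#' with initiation and terminal A/T terms, entropy salt correction
#' `dS + 0.368 (N-1) ln[mon]` and the von Ahsen conversion of divalent
#' cations to monovalent equivalents
#' (`mon + 120 sqrt(Mg - dNTPs)`).
#'
#' @param seq primer sequence (A/C/G/T).
#' @param dnac1,dnac2 strand concentrations in nM (defaults 25/25, i.e. the
#'   usual 50 nM total primer / 4 duplex factor).
#' @param Na,Mg,dNTPs ion/nucleotide concentrations in mM.
#' @return melting temperature in degrees C.
#' @export
tm_nn <- function(seq, dnac1 = 25, dnac2 = 25, Na = 50, Mg = 1.5,
                  dNTPs = 0.6) {
  seq <- toupper(seq)
  stopifnot(!grepl("[^ACGT]", seq), nchar(seq) >= 2)
  p <- nn_params()
  n <- nchar(seq)
  v <- base_ints(seq)
  dH <- p$dH[["init"]]; dS <- p$dS[["init"]]
  for (e in v[c(1L, n)]) {
    key <- if (e %in% c(1L, 4L)) "init_A/T" else "init_G/C"
    dH <- dH + p$dH[[key]]; dS <- dS + p$dS[[key]]
  }
  idx <- cbind(v[-n], v[-1])
  dH <- dH + sum(p$dHm[idx])
  dS <- dS + sum(p$dSm[idx])
  mon <- Na + 120 * sqrt(max(Mg - dNTPs, 0))      # mM monovalent equivalent
  dS_corr <- dS + 0.368 * (n - 1) * log(mon / 1000)
  k <- (dnac1 - dnac2 / 2) * 1e-9
  1000 * dH / (dS_corr + 1.987 * log(k)) - 273.15
}
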