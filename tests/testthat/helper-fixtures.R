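## Shared fixtures and independent oracles. Fixture genomes are generated
## once per test run and cached; all expected values for searches come from
## brute-force re-implementations kept deliberately separate from the
## package's vectorised scan paths.

.fix_cache <- new.env(parent = emptyenv())

## standard two-chromosome fixture with a plus- and a minus-strand gene
std_fixture <- function() {
  if (is.null(.fix_cache$std)) {
    dir <- file.path(tempdir(), "kid_std_fixture")
    spec <- fixture_spec(
      seed = 424242,
      chromosomes = data.frame(name = c("chr1", "chr2"),
                               length = c(12000L, 6000L)),
      genes = list(
        list(chrom = "chr1", at = 3000L, strand = "+", n_exons = 3,
             cds_codons = 120L, utr5_len = 60L, utr3_len = 80L,
             intron_len = 90L),
        list(chrom = "chr1", at = 7000L, strand = "-", n_exons = 2,
             cds_codons = 80L, utr5_len = 40L, utr3_len = 50L,
             intron_len = 70L)))
    fx <- generate_fixture(spec, dir)
    genome <- load_genome(fx$fasta)
    models <- build_transcript_models(fx$gff3, genome)
    .fix_cache$std <- list(fx = fx, genome = genome, models = models)
  }
  .fix_cache$std
}

## tiny genome assembled directly from strings (no annotation)
string_genome <- function(...) {
  seqs <- c(...)
  dir <- tempfile()
  dir.create(dir)
  fa <- file.path(dir, "g.fa")
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), fa)
  load_genome(fa)
}

## deterministic non-repetitive background with no >=5-nt homopolymer runs
bg_seq <- function(len, seed, gc = 0.5) {
  set.seed(seed)
  s <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                     prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
              collapse = "")
  knockinDesign:::squash_runs(s)
}

## ---- brute-force oracles -------------------------------------------------

## naive sliding-window mismatch counter over every position of every
## chromosome, substring-based (independent of the package's shift-compare
## scan)
oracle_mismatch_sites <- function(genome, pattern, max_mm) {
  k <- nchar(pattern)
  pat <- strsplit(pattern, "")[[1]]
  out <- list()
  for (chrom in names(genome$sequences)) {
    for (strand in c("+", "-")) {
      s <- genome$sequences[[chrom]]
      if (strand == "-") s <- revcomp(s)
      L <- nchar(s)
      if (L < k) next
      starts <- seq_len(L - k + 1)
      wins <- substring(s, starts, starts + k - 1)
      mm <- vapply(wins, function(w)
        sum(strsplit(w, "")[[1]] != pat), integer(1), USE.NAMES = FALSE)
      hit <- which(mm <= max_mm)
      if (!length(hit)) next
      gs <- if (strand == "+") hit else L - (hit + k - 1) + 1
      out[[length(out) + 1]] <- data.frame(chrom = chrom, start = gs,
                                           end = gs + k - 1,
                                           strand = strand,
                                           mismatches = mm[hit])
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0)))
  do.call(rbind, out)
}

## brute-force in-silico PCR: all-pairs scan over two annealing-site tables
oracle_pcr_products <- function(a_sites, b_sites, max_size) {
  prods <- list()
  for (i in seq_len(nrow(a_sites))) {
    for (j in seq_len(nrow(b_sites))) {
      if (a_sites$chrom[i] != b_sites$chrom[j]) next
      if (a_sites$strand[i] == "+" && b_sites$strand[j] == "-") {
        size <- b_sites$end[j] - a_sites$start[i] + 1
        if (size >= 1 && size <= max_size)
          prods[[length(prods) + 1]] <- c(a_sites$start[i], b_sites$end[j])
      }
    }
  }
  prods
}

## apply a recoding plan's mutations back onto a genome copy
mutate_genome <- function(genome, mutations) {
  for (i in seq_len(nrow(mutations))) {
    g <- mutations$genomic[i]
    if (is.na(g)) next
    substr(genome$sequences[[mutations$chrom_name[i]]], g, g) <-
      mutations$alt[i]
  }
  genome
}

## exhaustive minimal re-cut plan search (independent of the greedy
## planner): candidate pool = every allowed single-base change inside any
## donor window scoring >= threshold; subsets of growing size are tried
oracle_min_recut_size <- function(donor, ann, protospacer, mdl, genome,
                                  threshold = 0.03, max_size = 3,
                                  coding_only = FALSE) {
  enz <- mdl$enzyme
  wl <- enz$spacer_length + knockinDesign:::pam_length(enz)
  L <- nchar(donor$sequence)
  si_f <- knockinDesign:::base_ints(donor$sequence)
  si_r <- knockinDesign:::base_ints(revcomp(donor$sequence))
  gi <- knockinDesign:::base_ints(protospacer)
  sf <- knockinDesign:::cfd_scan_strand(si_f, gi, mdl)
  sr <- knockinDesign:::cfd_scan_strand(si_r, gi, mdl)
  hot <- sort(unique(c(
    unlist(lapply(which(sf >= threshold), function(i) i:(i + wl - 1))),
    unlist(lapply(which(sr >= threshold), function(i) {
      j <- L - i - wl + 2; j:(j + wl - 1)
    })))))
  cands <- knockinDesign:::recut_candidates(hot, ann, donor, donor$sequence,
                                            genome, codon_usage(),
                                            coding_only)
  if (max_cfd_in_donor(donor$sequence, protospacer, mdl)$score < threshold)
    return(0L)
  apply_set <- function(set) {
    s <- donor$sequence
    for (cd in set) substr(s, cd$offset, cd$offset) <- cd$alt
    s
  }
  for (size in seq_len(max_size)) {
    combos <- utils::combn(length(cands), size, simplify = FALSE)
    for (cb in combos) {
      offs <- vapply(cands[cb], `[[`, 0L, "offset")
      if (anyDuplicated(offs)) next
      if (max_cfd_in_donor(apply_set(cands[cb]), protospacer,
                           mdl)$score < threshold)
        return(size)
    }
  }
  NA_integer_
}
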