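## shared fixture for primer tests: a clean 20-kb chromosome plus a decoy
primer_fixture <- function(planted = list(), seed = 7,
                           lengths = c(20000L, 9000L)) {
  dir <- tempfile()
  spec <- fixture_spec(seed = seed,
                       chromosomes = data.frame(name = c("chr1", "chr2"),
                                                length = lengths),
                       planted = planted)
  fx <- generate_fixture(spec, dir)
  load_genome(fx$fasta)
}

test_that("locus extraction is centered, sized per mode and clipped at ends", {
  g <- primer_fixture()
  short <- primer_mode("short")
  loc <- extract_locus(g, "chr1", 10000, short)
  expect_equal(nchar(loc$sequence), 430)
  expect_equal(loc$edit_offset, 216)     # centered
  loc2 <- extract_locus(g, "chr1", 10000, short, extension = 40)
  expect_equal(nchar(loc2$sequence), 510)
  expect_warning(loc3 <- extract_locus(g, "chr1", 100, short), "clipped")
  expect_lt(nchar(loc3$sequence), 430)
  expect_error(extract_locus(g, "chr1", 10^6, short), "outside chromosome")
})

test_that("candidate pairs satisfy every thermodynamic and positional filter", {
  g <- primer_fixture()
  mode <- primer_mode("short")
  loc <- extract_locus(g, "chr1", 10000, mode)
  cons <- primer_constraints()
  pairs <- enumerate_candidates(loc, mode, cons)
  expect_gt(nrow(pairs), 0)
  expect_true(all(pairs$product_size >= 250 & pairs$product_size <= 350))
  expect_true(all(abs(pairs$fwd_tm - pairs$rev_tm) <= 3))
  expect_true(all(pairs$fwd_tm >= 57 & pairs$fwd_tm <= 63))
  expect_true(all(pairs$rev_tm >= 57 & pairs$rev_tm <= 63))
  expect_true(all(pairs$fwd_gc >= 20 & pairs$fwd_gc <= 80))
  ## positional exclusion: both primers at least 100 bp from the edit
  expect_true(all(loc$edit_offset - pairs$fwd_end >= 100))
  expect_true(all(pairs$rev_start - loc$edit_offset >= 100))
  ## primer lengths within [18, 25]
  expect_true(all(nchar(pairs$fwd_seq) >= 18 & nchar(pairs$fwd_seq) <= 25))
  ## a pure-repeat locus yields no candidates
  loc_rep <- list(sequence = strrep("ACGTACGTAC", 43), genomic_start = 1L,
                  edit_offset = 216L, chrom = "chrR")
  expect_equal(nrow(enumerate_candidates(loc_rep, mode, cons)), 0)
})

test_that("annealing-site search enforces the mismatch budget and 3' anchor", {
  primer <- "GCTAGACCTAGGATCAGGTA"
  flip <- function(s, i) {
    substr(s, i, i) <- setdiff(c("A", "C", "G", "T"), substr(s, i, i))[1]
    s
  }
  mm3 <- flip(flip(flip(primer, 2), 8), 14)
  mm4 <- flip(mm3, 17)
  bad3p <- flip(primer, 20)
  bg1 <- bg_seq(50, 3); bg2 <- bg_seq(50, 4)
  g <- string_genome(chr1 = paste0(bg1, primer, bg2),
                     chr2 = paste0(bg1, mm3, bg2, mm4, bg2, bad3p, bg2,
                                   revcomp(primer), bg1))
  sites <- find_annealing_sites(primer, g, "fast")
  ## exact copy, 3-mismatch copy and the reverse-complement placement are
  ## found; the 4-mismatch copy and the 3'-terminal-mismatch copy are not
  expect_equal(nrow(sites), 3)
  expect_true(all(sites$mismatches <= 3))
  expect_equal(sum(sites$strand == "-"), 1)
  ## sensitive mode admits the 4-mismatch site (its 3' base is intact)
  sens <- find_annealing_sites(primer, g, "sensitive")
  expect_equal(nrow(sens), 4)
  ## the 3'-anchor rule holds for every reported site
  for (i in seq_len(nrow(sens))) {
    s <- get_sequence(g, sens$chrom[i], sens$start[i], sens$end[i],
                      sens$strand[i])
    expect_equal(substr(s, nchar(primer), nchar(primer)),
                 substr(primer, nchar(primer), nchar(primer)))
  }
})

test_that("unintended products are detected for convergent sites within 6 kb", {
  fwd <- data.frame(chrom = c("chr1", "chr3"), start = c(100L, 1000L),
                    end = c(119L, 1019L), strand = c("+", "+"))
  rev_ <- data.frame(chrom = c("chr1", "chr3"), start = c(380L, 2981L),
                     end = c(399L, 3000L), strand = c("-", "-"))
  intended <- list(chrom = "chr1", start = 100L, end = 399L)
  prods <- detect_unintended_products(fwd, rev_, intended)
  ## the chr3 convergent pair (2001 bp) is the only unintended product
  expect_equal(nrow(prods), 1)
  expect_equal(prods$chrom, "chr3")
  expect_equal(prods$size, 2001L)
  ## beyond 6 kb no product forms
  rev_far <- rev_; rev_far$start[2] <- 8000L; rev_far$end[2] <- 8019L
  expect_equal(nrow(detect_unintended_products(fwd, rev_far, intended)), 0)
  ## fwd+fwd convergent pair on another chromosome is reported
  fwd2 <- rbind(fwd, data.frame(chrom = "chr4", start = c(500L, 1500L),
                                end = c(519L, 1519L),
                                strand = c("+", "-")))
  prods2 <- detect_unintended_products(fwd2, rev_[0, ], intended)
  expect_true(any(prods2$combo == "fwd+fwd"))
})

test_that("in-silico PCR agrees with the brute-force all-pairs oracle", {
  g <- primer_fixture(planted = list(
    list(type = "sequence", chrom = "chr2",
         seq = "GCTAGACCTAGGATCAGGTA", pos = 1000L),
    list(type = "sequence", chrom = "chr2",
         seq = revcomp("TCCGATTGACGATCGGAGCT"), pos = 3200L)))
  fwd <- "GCTAGACCTAGGATCAGGTA"
  rev_ <- "TCCGATTGACGATCGGAGCT"
  fs <- find_annealing_sites(fwd, g)
  rs <- find_annealing_sites(rev_, g)
  mine <- detect_unintended_products(fs, rs, NULL)
  oracle <- oracle_pcr_products(fs, rs, 6000)
  fr <- mine[mine$combo == "fwd+rev", ]
  expect_equal(nrow(fr), length(oracle))
  if (length(oracle))
    expect_setequal(paste(fr$start, fr$end),
                    vapply(oracle, function(p) paste(p[1], p[2]),
                           character(1)))
})

test_that("the relaxation ladder loosens delta-Tm then product size, cumulatively", {
  short <- primer_mode("short")
  r0 <- relax_constraints(short, 0)
  expect_equal(r0$cons$dtm_max, 3)
  expect_equal(r0$product_range, c(250L, 350L))
  expect_equal(r0$extension, 0)
  r1 <- relax_constraints(short, 1)
  expect_equal(r1$cons$dtm_max, 4)
  expect_equal(r1$product_range, c(250L, 350L))
  r2 <- relax_constraints(short, 2)
  expect_equal(r2$cons$dtm_max, 5)
  expect_equal(r2$product_range, c(250L, 430L))  # +80
  expect_equal(r2$extension, 40)
  r6 <- relax_constraints(short, 6)
  expect_equal(r6$cons$dtm_max, 6)
  expect_equal(r6$product_range, c(250L, 590L))  # three +80 steps
  expect_equal(r6$extension, 120)
  long <- primer_mode("long")
  expect_equal(relax_constraints(long, 4)$product_range, c(3300L, 4300L))
  expect_error(relax_constraints(short, 7))
})

test_that("relaxed attempts admit a superset of earlier candidate pairs", {
  g <- primer_fixture()
  mode <- primer_mode("short")
  keyset <- function(attempt) {
    rx <- relax_constraints(mode, attempt)
    loc <- extract_locus(g, "chr1", 10000, mode, rx$extension)
    pr <- enumerate_candidates(loc, mode, rx$cons, rx$product_range,
                               beam = 5000)  # effectively uncapped
    paste(pr$fwd_seq, pr$rev_seq)
  }
  k0 <- keyset(0); k2 <- keyset(2); k4 <- keyset(4)
  expect_true(all(k0 %in% k2))
  expect_true(all(k2 %in% k4))
})

test_that("a unique locus yields passing pairs and a duplicated locus yields none", {
  g <- primer_fixture()
  rep <- design_genotyping_primers(g, "chr1", 10000, "short")
  expect_false(rep$failed)
  expect_lte(nrow(rep$pairs), 3)
  expect_true(all(rep$pairs$product_size >= 250 &
                    rep$pairs$product_size <= 350))
  expect_true(all(rep$pairs$fwd_tm <= 63 & rep$pairs$rev_tm <= 63))
  expect_equal(rep$attempt, 0)
  ## both primers at least 100 bp from the edit site
  edit <- 10000
  expect_true(all(edit - (rep$pairs$fwd_genomic_start +
                            nchar(rep$pairs$fwd_seq) - 1) >= 100))
  expect_true(all(rep$pairs$rev_genomic_end - nchar(rep$pairs$rev_seq) + 1 -
                    edit >= 100))

  ## a verbatim cross-chromosome duplication longer than any extended locus
  ## defeats every pair (all six relaxation attempts)
  g2 <- primer_fixture(planted = list(
    list(type = "duplication", src_chrom = "chr1", src_start = 9550L,
         src_end = 10550L, chrom = "chr2", pos = 3000L)))
  rep2 <- design_genotyping_primers(g2, "chr1", 10000, "short")
  expect_true(rep2$failed)
  expect_match(rep2$failure_reason, "unintended")
})
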