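test_that("donor assembly is faithful to the genome and to arm defaults", {
  std <- std_fixture()
  g <- std$genome
  ## empty payload: donor equals the genomic window
  d0 <- assemble_donor(g, "chr1", 5000, "", 200, 200)
  expect_equal(d0$sequence, get_sequence(g, "chr1", 4801, 5200))
  ## dsDNA defaults give 500/500 arms when unclipped
  d1 <- assemble_donor(g, "chr1", 5000, "ACGTACGT", 500, 500)
  expect_equal(d1$arm5_len, 500)
  expect_equal(d1$arm3_len, 500)
  expect_equal(nchar(d1$sequence), 1008)
  ## reference reconstruction strips the payload exactly
  expect_equal(donor_reference_reconstruction(d1),
               get_sequence(g, "chr1", 4501, 5500))
  ## arms are clipped at chromosome ends with a warning
  expect_warning(dc <- assemble_donor(g, "chr1", 100, "", 500, 500),
                 "clipped")
  expect_equal(dc$arm5_len, 100)
  expect_error(assemble_donor(g, "chr1", 5000, "ACGXT", 100, 100),
               "non-ACGT")
})

test_that("C-terminal insertion abuts the last sense codon before the stop", {
  std <- std_fixture()
  m <- std$models$FIXT1
  tgt <- knockinDesign:::resolve_target("FIXT1,C", std$models)
  ## the three bases after the insertion point are the stop codon
  stopc <- get_sequence(std$genome, m$chrom, tgt$insert_site + 1,
                        tgt$insert_site + 3)
  expect_true(stopc %in% c("TAA", "TAG", "TGA"))
  ## N-terminal: the three bases before the insertion point are ATG
  tgtN <- knockinDesign:::resolve_target("FIXT1,N", std$models)
  expect_equal(get_sequence(std$genome, m$chrom, tgtN$insert_site - 2,
                            tgtN$insert_site), "ATG")
  ## minus-strand transcript: same invariants in transcript orientation
  tgt2 <- knockinDesign:::resolve_target("FIXT2,N", std$models)
  m2 <- std$models$FIXT2
  expect_equal(get_sequence(std$genome, m2$chrom, tgt2$insert_site + 1,
                            tgt2$insert_site + 3, "-"), "ATG")
})

test_that("synthesis flag thresholds are exact boundaries", {
  ## pads built from the other three bases so they never extend the run
  mk <- function(run) {
    b <- substr(run, 1, 1)
    o <- setdiff(c("A", "C", "G", "T"), b)
    paste0(strrep(paste0(o[1], o[2]), 20), run,
           strrep(paste0(o[2], o[3]), 20))
  }
  expect_equal(nrow(flag_synthesis_problems(mk(strrep("A", 9)))$homopolymers), 0)
  expect_equal(nrow(flag_synthesis_problems(mk(strrep("A", 10)))$homopolymers), 1)
  expect_equal(nrow(flag_synthesis_problems(mk(strrep("T", 9)))$homopolymers), 0)
  expect_equal(nrow(flag_synthesis_problems(mk(strrep("T", 10)))$homopolymers), 1)
  expect_equal(nrow(flag_synthesis_problems(mk(strrep("G", 5)))$homopolymers), 0)
  expect_equal(nrow(flag_synthesis_problems(mk(strrep("G", 6)))$homopolymers), 1)
  expect_equal(nrow(flag_synthesis_problems(mk(strrep("C", 5)))$homopolymers), 0)
  expect_equal(nrow(flag_synthesis_problems(mk(strrep("C", 6)))$homopolymers), 1)
  ## homopolymer offset is reported at the run start
  f <- flag_synthesis_problems(mk(strrep("G", 6)))
  expect_equal(f$homopolymers$offset, 41)  # 40-nt pad precedes the run
  expect_equal(f$homopolymers$length, 6)
  ## global GC boundaries: >65 or <25 flag; exactly 65 / 25 do not
  mkgc <- function(pct, n = 1000) {
    ngc <- round(pct * n / 100)
    paste0(paste(rep(c("G", "C"), length.out = ngc), collapse = ""),
           paste(rep(c("A", "T"), length.out = n - ngc), collapse = ""))
  }
  expect_false(flag_synthesis_problems(mkgc(65))$gc_global$flagged)
  expect_true(flag_synthesis_problems(mkgc(66))$gc_global$flagged)
  expect_false(flag_synthesis_problems(mkgc(25))$gc_global$flagged)
  expect_true(flag_synthesis_problems(mkgc(24))$gc_global$flagged)
  ## window skew: all-GC block next to all-AT block differs by 100 > 52
  expect_true(flag_synthesis_problems(mkgc(50, 200))$gc_window_skew$flagged)
  ## uniform alternation has zero skew
  expect_false(flag_synthesis_problems(
    strrep("GCAT", 50))$gc_window_skew$flagged)
  ## sequences under 50 bp: skew not evaluated, noted in output
  short <- flag_synthesis_problems("ACGTACGTAC")
  expect_false(short$gc_window_skew$evaluated)
})

test_that("arm trimming halts at feature removal or the minimum length", {
  std <- std_fixture()
  g <- std$genome
  ## build a donor and plant a 10xA run at arm5 offset 450 from the payload
  d <- assemble_donor(g, "chr1", 5000, "ACGTACGT", 500, 500)
  s <- d$sequence
  hp_at <- d$arm5_len - 450 + 1   # 450 bp from the payload junction
  substr(s, hp_at, hp_at + 9) <- strrep("A", 10)
  d$sequence <- s
  t1 <- trim_arms(d, min_arm_len = 100)
  expect_lte(t1$arm5_len, 450)
  expect_gte(t1$arm5_len, 100)
  expect_equal(nrow(flag_synthesis_problems(t1$sequence)$homopolymers), 0)
  ## trimming never shortens below the minimum: homopolymer at offset 50
  ## persists and stays flagged
  d2 <- assemble_donor(g, "chr1", 5000, "ACGTACGT", 500, 500)
  s2 <- d2$sequence
  hp_at2 <- d2$arm5_len - 50 + 1
  substr(s2, hp_at2, hp_at2 + 9) <- strrep("A", 10)
  d2$sequence <- s2
  t2 <- trim_arms(d2, min_arm_len = 100)
  expect_equal(t2$arm5_len, 100)
  expect_equal(nrow(t2$flags$homopolymers), 1)
  ## no flags: donor unchanged (fixpoint)
  d3 <- assemble_donor(g, "chr1", 5000, "ACGTACGT", 300, 300)
  t3 <- trim_arms(d3, min_arm_len = 100)
  expect_equal(t3$sequence, d3$sequence)
  ## trimming a forbidden motif
  d4 <- assemble_donor(g, "chr1", 5000, "ACGTACGT", 300, 300)
  s4 <- d4$sequence
  motif_at <- nchar(s4) - 50
  substr(s4, motif_at, motif_at + 5) <- "GAATTC"
  d4$sequence <- s4
  t4 <- trim_arms(d4, min_arm_len = 100, forbidden_motifs = "GAATTC")
  expect_equal(nrow(t4$flags$forbidden_motif_hits), 0)
  expect_gte(t4$arm3_len, 100)
})

test_that("trimming never increases flag counts (monotonicity property)", {
  std <- std_fixture()
  set.seed(17)
  for (rep in 1:5) {
    d <- assemble_donor(std$genome, "chr1",
                        sample(2000:9000, 1), "ACGTACGT", 400, 400)
    s <- d$sequence
    for (k in seq_len(sample(0:2, 1))) {
      at <- sample(seq(10, nchar(s) - 20), 1)
      substr(s, at, at + 9) <- strrep(sample(c("A", "T", "G", "C"), 1), 10)
    }
    d$sequence <- s
    n_pre <- nrow(flag_synthesis_problems(d$sequence)$homopolymers)
    t <- trim_arms(d, min_arm_len = 150)
    expect_lte(nrow(t$flags$homopolymers), n_pre)
    expect_gte(t$arm5_len, 150)
    expect_gte(t$arm3_len, 150)
  }
})

test_that("ssODN strand selection follows the annealing-polarity rule", {
  ## cut 5' of the insert on + strand: minus strand favored
  expect_equal(select_ssodn_strand(980, 1000, "+", NA, "auto"), "-")
  expect_equal(select_ssodn_strand(1020, 1000, "+", NA, "auto"), "+")
  ## cut == insert: deterministic non-target default
  expect_equal(select_ssodn_strand(1000, 1000, "+", NA, "auto"), "-")
  expect_equal(select_ssodn_strand(1000, 1000, "-", NA, "auto"), "+")
  ## explicit modes
  expect_equal(select_ssodn_strand(980, 1000, "-", NA, "target"), "-")
  expect_equal(select_ssodn_strand(980, 1000, "-", NA, "non_target"), "+")
  expect_equal(select_ssodn_strand(980, 1000, "+", "-", "transcribed"), "+")
  expect_equal(select_ssodn_strand(980, 1000, "+", "-", "non_transcribed"), "-")
  expect_error(select_ssodn_strand(980, 1000, "+", NA, "transcribed"),
               "transcript context")
})

test_that("mirroring the locus flips the auto-selected ssODN strand", {
  ## antisymmetry: reverse-complementing the genome swaps the relative
  ## order of cut and insert, so the auto strand must flip
  L <- 5000
  for (case in list(c(2000, 2015), c(3000, 2980), c(1500, 1500))) {
    cut <- case[1]; ins <- case[2]
    fwd <- select_ssodn_strand(cut, ins, "+", NA, "auto")
    ## mirrored coordinates on the reverse-complemented genome
    cut_m <- L - cut + 1 - 1   # left-base convention shifts by one
    ins_m <- L - ins + 1 - 1
    rev_ <- select_ssodn_strand(cut_m, ins_m, "-", NA, "auto")
    expect_true(fwd != rev_)
  }
})

test_that("ssODN capping respects the payload, the cap and the cut site", {
  std <- std_fixture()
  g <- std$genome
  payload <- strrep("GATTAC", 10)   # 60 nt
  d <- assemble_donor(g, "chr1", 5000, payload, 200, 200, "ssODN")
  capped <- cap_ssodn(d, 200)
  expect_lte(nchar(capped$sequence), 200)
  expect_lte(capped$arm5_len, 70)
  expect_lte(capped$arm3_len, 70)
  ## payload is intact
  expect_equal(substr(capped$sequence, capped$payload_start,
                      capped$payload_end), payload)
  ## already under the cap: unchanged
  d2 <- assemble_donor(g, "chr1", 5000, payload, 50, 50, "ssODN")
  expect_equal(cap_ssodn(d2, 200)$sequence, d2$sequence)
  ## asymmetric preservation: cut 15 bp 5' of the insert stays inside
  d3 <- assemble_donor(g, "chr1", 5000, strrep("ACGT", 40), 200, 200, "ssODN")
  capped3 <- cap_ssodn(d3, 200, cut_site = 4985)
  cut_off <- knockinDesign:::genomic_to_donor_offset(capped3, 4985)
  expect_false(is.na(cut_off))
  expect_gte(cut_off, 1)
  ## payload longer than the cap errors, naming the minimum
  expect_error(cap_ssodn(assemble_donor(g, "chr1", 5000, strrep("A", 4) |>
                                          paste0(strrep("GATC", 60)),
                                        100, 100, "ssODN"), 200),
               "minimum required cap")
})

test_that("recoded stretches are excluded from effective homology arms", {
  cs_env <- std_fixture()
  g <- cs_env$genome
  d <- assemble_donor(g, "chr1", 5000, "ACGTACGT", 300, 300)
  plan <- knockinDesign:::new_recoding_plan(
    data.frame(offset = c(280L, 320L), genomic = c(4979L, 5012L),
               ref = substring(d$sequence, c(280, 320), c(280, 320)),
               alt = c("T", "A"), class = "noncoding_transversion",
               region = "recut"),
    0.001, "prevent_recut")
  ## force distinct alt bases
  plan$mutations$alt <- ifelse(plan$mutations$ref == "T", "A", "T")
  d2 <- apply_recoding_plan(d, plan)
  expect_equal(d2$effective_arm5_len, 279)
  expect_equal(d2$effective_arm3_len, nchar(d2$sequence) - 320)
  ## reference reconstruction reverts recoding and payload
  expect_equal(donor_reference_reconstruction(d2),
               get_sequence(g, "chr1", d$win_start, d$win_end))
})
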