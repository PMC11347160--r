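## helper: set up a donor around a chosen guide at a given cut-to-insert
## distance on a fixture transcript, with the protospacer left intact in an
## arm when the distance exceeds the PAM-side protospacer extent
recoding_case <- function(tid, dist, payload = strrep("GGATCCGAATTC", 5),
                          arm = 300) {
  std <- std_fixture()
  m <- std$models[[tid]]
  enz <- cas_enzyme("SpCas9")
  lo <- min(m$cds$start) + 30; hi <- max(m$cds$end) - 30
  cand <- enumerate_protospacers(std$genome, enz, m$chrom, lo, hi)
  cand <- cand[cand$strand == "+", , drop = FALSE]
  guide <- cand[which.max(cand$start), ]
  insert_site <- guide$cut_site - dist   # payload 5' of the cut
  donor <- assemble_donor(std$genome, m$chrom, insert_site, payload,
                          arm, arm, "dsDNA")
  ann <- annotate_donor(donor, m)
  list(std = std, m = m, enz = enz, guide = guide, donor = donor, ann = ann,
       mdl = cfd_model(enz))
}

test_that("synonymous substitution maximizes divergence and excludes rare codons", {
  usage <- codon_usage()
  expect_true(is.na(synonymous_substitution("ATG", usage)))  # Met: no synonym
  expect_true(is.na(synonymous_substitution("TGG", usage)))  # Trp: no synonym
  ## synthetic uniform table except TTA is rare (< 7e-3): TTA never chosen
  syn_usage <- usage
  syn_usage[] <- 1 / 64
  syn_usage["TTA"] <- 6e-3
  for (cod in c("CTG", "CTC", "TTG")) {
    alt <- synonymous_substitution(cod, syn_usage)
    expect_false(is.na(alt))
    expect_true(alt != "TTA")
    expect_equal(knockinDesign:::aa_of(alt), knockinDesign:::aa_of(cod))
  }
  ## with all six Leu codons eligible, CTG pairs with a maximally divergent
  ## synonym: brute-force over the synonym group confirms the divergence
  syn_usage["TTA"] <- 1 / 64
  alt <- synonymous_substitution("CTG", syn_usage)
  divs <- vapply(setdiff(knockinDesign:::synonyms_of("CTG"), "CTG"),
                 function(s) sum(strsplit(s, "")[[1]] !=
                                   strsplit("CTG", "")[[1]]), integer(1))
  expect_equal(sum(strsplit(alt, "")[[1]] != strsplit("CTG", "")[[1]]),
               max(divs))
  ## half-median rule: GCG (Ala) is below half the group's median in the
  ## vendored human table, so it is never chosen
  expect_false(identical(synonymous_substitution("GCT", usage), "GCG"))
  expect_false(knockinDesign:::codon_eligible("GCG", usage))
})

test_that("splice protection masks the conserved junction dinucleotides", {
  std <- std_fixture()
  m <- std$models$FIXT1
  mask <- splice_protection_mask(m, m$tx_start, m$tx_end)
  ## first two intronic bases (GT) and last two (AG) of every intron
  ex <- m$exons[order(m$exons$start), ]
  for (k in seq_len(nrow(ex) - 1)) {
    expect_true(all(c(ex$end[k] + 1, ex$end[k] + 2) %in% mask))   # GT
    expect_true(all(c(ex$start[k + 1] - 1, ex$start[k + 1] - 2) %in% mask))
  }
  ## window with no junction -> empty mask
  expect_length(splice_protection_mask(m, m$tx_start - 500,
                                       m$tx_start - 400), 0)
  ## mask is clipped to the window
  j1 <- m$exons$end[1]
  clipped <- splice_protection_mask(m, j1 - 1, j1 + 1)
  expect_true(all(clipped >= j1 - 1 & clipped <= j1 + 1))
})

test_that("a guide destroyed by payload insertion needs no recoding", {
  cs <- recoding_case("FIXT1", dist = 0)
  plan <- plan_recut_mutations(cs$donor, cs$ann, cs$guide$protospacer,
                               cs$mdl, cs$std$genome)
  expect_equal(nrow(plan$mutations), 0)
  expect_lt(plan$residual_max_cfd, 0.03)
  expect_true(plan$feasible)
})

test_that("intact protospacer is recoded below threshold with PAM priority", {
  cs <- recoding_case("FIXT1", dist = 30)
  pre <- max_cfd_in_donor(cs$donor$sequence, cs$guide$protospacer, cs$mdl)
  expect_equal(pre$score, 1.0)    # site intact in the arm
  plan <- plan_recut_mutations(cs$donor, cs$ann, cs$guide$protospacer,
                               cs$mdl, cs$std$genome)
  expect_true(plan$feasible)
  expect_lt(plan$residual_max_cfd, 0.03)
  expect_gt(nrow(plan$mutations), 0)
  ## independent audit: apply mutations and re-scan window by window
  donor2 <- apply_recoding_plan(cs$donor, plan, cs$guide$protospacer, cs$mdl)
  expect_equal(donor2$recoding$residual_max_cfd, plan$residual_max_cfd)
  slow_max <- max(vapply(
    seq_len(nchar(donor2$sequence) - 22),
    function(i) max(
      cfd_score(cs$guide$protospacer,
                substr(donor2$sequence, i, i + 22), cs$mdl),
      cfd_score(cs$guide$protospacer,
                substr(revcomp(donor2$sequence), i, i + 22), cs$mdl)),
    numeric(1)))
  expect_equal(slow_max, plan$residual_max_cfd, tolerance = 1e-12)
  ## PAM priority: with the PAM in unprotected sequence, the first mutation
  ## falls in the PAM window
  wo <- knockinDesign:::window_offsets(pre, cs$enz)
  expect_true(plan$mutations$offset[1] %in% wo$pam)
})

test_that("protected or coding-only constraints push mutations into the protospacer", {
  cs <- recoding_case("FIXT1", dist = 30)
  pre <- max_cfd_in_donor(cs$donor$sequence, cs$guide$protospacer, cs$mdl)
  wo <- knockinDesign:::window_offsets(pre, cs$enz)
  ann <- cs$ann
  ann$protected[wo$pam] <- TRUE          # forbid the PAM region
  plan <- plan_recut_mutations(cs$donor, ann, cs$guide$protospacer, cs$mdl,
                               cs$std$genome)
  if (nrow(plan$mutations) > 0)
    expect_false(any(plan$mutations$offset %in% wo$pam))
  if (plan$feasible) expect_lt(plan$residual_max_cfd, 0.03)
})

test_that("recut plans on a randomized design panel preserve protein and pass audit", {
  std <- std_fixture()
  usage <- codon_usage()
  n_checked <- 0
  for (tid in c("FIXT1", "FIXT2")) {
    for (dist in c(0, 12, 18, 25, 30)) {
      cs <- recoding_case(tid, dist)
      plan <- plan_recut_mutations(cs$donor, cs$ann, cs$guide$protospacer,
                                   cs$mdl, cs$std$genome)
      donor2 <- apply_recoding_plan(cs$donor, plan, cs$guide$protospacer,
                                    cs$mdl)
      ## audit: recomputing the residual reproduces the plan's value
      expect_equal(max_cfd_in_donor(donor2$sequence, cs$guide$protospacer,
                                    cs$mdl)$score,
                   donor2$recoding$residual_max_cfd)
      expect_true(donor2$recoding$feasible)
      ## translation preservation via genome-level mutation
      mm <- donor2$recoding$mutations
      if (nrow(mm)) {
        mm$chrom_name <- cs$m$chrom
        gm <- mutate_genome(std$genome, mm)
        expect_identical(translate_dna(cds_sequence(cs$m, gm)),
                         translate_dna(cds_sequence(cs$m, std$genome)))
        ## silent mutations only inside CDS; transversions map
        ## purine <-> pyrimidine
        for (i in seq_len(nrow(mm))) {
          if (mm$class[i] == "noncoding_transversion") {
            pur <- c("A", "G")
            expect_true(xor(mm$ref[i] %in% pur, mm$alt[i] %in% pur))
          }
        }
        ## no mutation in a protected position
        expect_false(any(cs$ann$protected[mm$offset]))
      }
      ## minimality against the exhaustive oracle for small plans
      if (nrow(plan$mutations) <= 3) {
        osize <- oracle_min_recut_size(cs$donor, cs$ann,
                                       cs$guide$protospacer, cs$mdl,
                                       std$genome)
        if (!is.na(osize)) expect_equal(nrow(plan$mutations), osize)
      }
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 10)
})

test_that("repair-track recoding covers the cut-to-insert region at bounded density", {
  cs <- recoding_case("FIXT1", dist = 0)
  ## cut == insert: empty plan
  cut_off <- knockinDesign:::genomic_to_donor_offset(cs$donor,
                                                     cs$guide$cut_site)
  plan0 <- plan_repair_track_mutations(
    cs$donor, cs$ann, knockinDesign:::genomic_to_donor_offset(
      cs$donor, cs$donor$insert_site), cs$std$genome)
  expect_equal(nrow(plan0$mutations), 0)

  ## 15-bp non-coding region: at most 5 bases mutated, all transversions
  bg <- bg_seq(400, 31)
  g <- string_genome(chrN = bg)
  donor <- assemble_donor(g, "chrN", 200, strrep("ACGT", 10), 150, 150)
  ann <- annotate_donor(donor, NULL)
  cut_off <- donor$payload_end + 15L   # cut 15 bp 3' of the payload
  plan <- plan_repair_track_mutations(donor, ann, cut_off, g)
  m <- plan$mutations
  expect_lte(nrow(m), 5)
  expect_gt(nrow(m), 0)
  expect_true(all(m$class == "noncoding_transversion"))
  pur <- c("A", "G")
  expect_true(all(xor(m$ref %in% pur, m$alt %in% pur)))
  ## density bound: any 3-base window of the recoded region holds <= 1
  ## mutated base
  offs <- sort(m$offset)
  if (length(offs) > 1) expect_true(all(diff(offs) >= 3))

  ## coding region: codons with no synonym (ATG/TGG) stay untouched and
  ## protein is preserved
  cs2 <- recoding_case("FIXT1", dist = 25)
  cut2 <- knockinDesign:::genomic_to_donor_offset(cs2$donor,
                                                  cs2$guide$cut_site)
  plan2 <- plan_repair_track_mutations(cs2$donor, cs2$ann, cut2,
                                       cs2$std$genome)
  m2 <- plan2$mutations
  if (nrow(m2)) {
    m2$chrom_name <- cs2$m$chrom
    donor2 <- apply_recoding_plan(cs2$donor, plan2)
    gm <- mutate_genome(cs2$std$genome, m2)
    expect_identical(translate_dna(cds_sequence(cs2$m, gm)),
                     translate_dna(cds_sequence(cs2$m, cs2$std$genome)))
  }
})
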