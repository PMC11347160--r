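## Deterministic synthetic mini-genomes: seeded random background with
## planted gene models (valid start/stop codons, GT..AG introns, CDS a
## multiple of 3) and planted sequence features (protospacer copies,
## homopolymers, GC blocks, duplications, primer decoys), written as
## FASTA + GFF3 with a ground-truth manifest.

random_background <- function(len, gc = 0.5) {
  paste0(sample(BASES, len, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

## rewrite background so no homopolymer run reaches 5 nt: planted
## homopolymers are then the only flaggable runs in the genome
squash_runs <- function(seq, max_run = 4) {
  ch <- str_chars(seq)
  run <- 1L
  for (i in 2:length(ch)) {
    if (ch[i] == ch[i - 1]) run <- run + 1L else run <- 1L
    if (run > max_run) {
      ch[i] <- BASES[(match(ch[i], BASES)) %% 4 + 1]
      run <- 1L
    }
  }
  paste0(ch, collapse = "")
}

## build one gene region in transcript orientation: returns the region
## sequence plus feature intervals relative to the region start (1-based)
build_gene_region <- function(n_exons, cds_codons, utr5_len, utr3_len,
                              intron_len) {
  ncod <- cds_codons                       # payload codons excluding ATG/stop
  body <- paste0(sample(setdiff(names(GENETIC_CODE_VEC)[
    GENETIC_CODE_VEC != "*"], "ATG"), ncod, replace = TRUE), collapse = "")
  cds <- paste0("ATG", body, "TAA")
  tx <- paste0(random_background(utr5_len), cds, random_background(utr3_len))
  tx_len <- nchar(tx)
  ## split the transcript into n_exons exons at interior points within the CDS
  if (n_exons > 1) {
    lo <- utr5_len + 4; hi <- utr5_len + nchar(cds) - 4
    cuts <- sort(sample(seq(lo, hi), n_exons - 1))
  } else cuts <- integer(0)
  ex_start_tx <- c(1, cuts + 1)
  ex_end_tx <- c(cuts, tx_len)
  region <- ""
  pos <- 0L
  exons <- data.frame(start = integer(0), end = integer(0))
  introns <- data.frame(start = integer(0), end = integer(0))
  tx2region <- integer(tx_len)             # transcript pos -> region pos
  for (k in seq_len(n_exons)) {
    exseq <- substr(tx, ex_start_tx[k], ex_end_tx[k])
    exons <- rbind(exons, data.frame(start = pos + 1L,
                                     end = pos + nchar(exseq)))
    tx2region[ex_start_tx[k]:ex_end_tx[k]] <- pos + seq_len(nchar(exseq))
    region <- paste0(region, exseq)
    pos <- pos + nchar(exseq)
    if (k < n_exons) {
      inseq <- paste0("GT", squash_runs(random_background(intron_len - 4)), "AG")
      introns <- rbind(introns, data.frame(start = pos + 1L,
                                           end = pos + nchar(inseq)))
      region <- paste0(region, inseq)
      pos <- pos + nchar(inseq)
    }
  }
  cds_tx <- c(utr5_len + 1, utr5_len + nchar(cds))
  list(sequence = region, exons = exons, introns = introns,
       utr5_tx = if (utr5_len > 0) c(1, utr5_len) else NULL,
       cds_tx = cds_tx,
       utr3_tx = if (utr3_len > 0) c(cds_tx[2] + 1, tx_len) else NULL,
       tx2region = tx2region, tx_len = tx_len)
}

## map a transcript interval to region intervals (split at introns)
tx_interval_to_region <- function(map, lo, hi) {
  p <- map[lo:hi]
  r <- IRanges::reduce(IRanges::IRanges(p, p))
  data.frame(start = IRanges::start(r), end = IRanges::end(r))
}

## mirror region-relative intervals for minus-strand placement
mirror_intervals <- function(df, region_len) {
  out <- data.frame(start = region_len - df$end + 1L,
                    end = region_len - df$start + 1L)
  out[order(out$start), , drop = FALSE]
}

#' Fixture genome specification
#'
#' @param seed integer RNG seed; the same seed and spec produce
#'   byte-identical FASTA/GFF3 output.
#' @param chromosomes data.frame with `name` and `length`.
#' @param genes list of gene descriptions: `chrom`, `at` (region start),
#'   `strand`, `n_exons`, `cds_codons` (coding codons between ATG and stop),
#'   `utr5_len`, `utr3_len`, `intron_len`.
#' @param planted list of planted features; each a list with `type` in
#'   `"sequence"`, `"homopolymer"`, `"gc_block"`, `"protospacer_copy"`,
#'   `"duplication"` plus type-specific fields (see the methods vignette).
#' @param gc background GC fraction (default 0.5).
#' @param emit_utrs write explicit UTR features to the GFF3 (default TRUE).
#' @return a `FixtureSpec` list.
#' @export
fixture_spec <- function(seed, chromosomes, genes = list(),
                         planted = list(), gc = 0.5, emit_utrs = TRUE) {
  spec <- list(seed = seed, chromosomes = chromosomes, genes = genes,
               planted = planted, gc = gc, emit_utrs = emit_utrs)
  class(spec) <- "FixtureSpec"
  spec
}

#' Generate a synthetic genome fixture
#'
#' Writes `genome.fa`, `annotation.gff3` and `manifest.csv` into `dir`.
#' Background sequence is seeded uniform ACGT at the requested GC fraction
#' with homopolymer runs >= 5 nt squashed, so planted homopolymers are the
#' only flaggable runs; genes are planted first, then other features, and
#' any overlap between planted footprints is an error listing the conflicts.
#'
#' @param spec a `FixtureSpec`.
#' @param dir output directory (created if needed).
#' @return list with `fasta`, `gff3`, `manifest` (data.frame of planted
#'   feature coordinates) and `manifest_path`.
#' @export
generate_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, {
    chroms <- stats::setNames(
      vapply(spec$chromosomes$length, function(L)
        squash_runs(random_background(L, spec$gc)), character(1)),
      spec$chromosomes$name)
    manifest <- list()
    claims <- list()   # occupied footprints per chromosome
    claim <- function(chrom, start, end, what) {
      prev <- claims[[chrom]]
      if (!is.null(prev)) {
        bad <- prev$start <= end & prev$end >= start
        if (any(bad))
          stop("fixture packing conflict on ", chrom, " [", start, ",", end,
               "] (", what, ") overlaps: ",
               paste(prev$what[bad], collapse = ", "))
      }
      claims[[chrom]] <<- rbind(prev,
        data.frame(start = start, end = end, what = what))
    }
    write_at <- function(chrom, pos, s) {
      stopifnot(pos >= 1, pos + nchar(s) - 1 <= nchar(chroms[[chrom]]))
      substr(chroms[[chrom]], pos, pos + nchar(s) - 1) <- s
      chroms[chrom] <<- chroms[chrom]
    }
    add_manifest <- function(...) {
      manifest[[length(manifest) + 1]] <<- data.frame(...)
    }

    gff <- c("##gff-version 3")
    for (gi in seq_along(spec$genes)) {
      g <- spec$genes[[gi]]
      strand <- if (is.null(g$strand)) "+" else g$strand
      reg <- build_gene_region(g$n_exons, g$cds_codons,
                               g$utr5_len %||% 30L, g$utr3_len %||% 30L,
                               g$intron_len %||% 60L)
      rl <- nchar(reg$sequence)
      at <- g$at
      claim(g$chrom, at, at + rl - 1, paste0("gene", gi))
      placed <- if (strand == "-") revcomp(reg$sequence) else reg$sequence
      write_at(g$chrom, at, placed)
      shift <- function(df) data.frame(start = df$start + at - 1L,
                                       end = df$end + at - 1L)
      orient <- function(df) if (strand == "-") mirror_intervals(df, rl) else df
      exons <- shift(orient(reg$exons))
      cds <- shift(orient(tx_interval_to_region(reg$tx2region,
                                                reg$cds_tx[1], reg$cds_tx[2])))
      utr5 <- if (!is.null(reg$utr5_tx))
        shift(orient(tx_interval_to_region(reg$tx2region,
                                           reg$utr5_tx[1], reg$utr5_tx[2])))
      utr3 <- if (!is.null(reg$utr3_tx))
        shift(orient(tx_interval_to_region(reg$tx2region,
                                           reg$utr3_tx[1], reg$utr3_tx[2])))
      gene_id <- paste0("FIXG", gi)
      tx_id <- paste0("FIXT", gi)
      line <- function(type, s, e, attrs)
        paste(g$chrom, "fixture", type, s, e, ".", strand, ".", attrs,
              sep = "\t")
      gff <- c(gff,
        line("gene", at, at + rl - 1,
             paste0("ID=", gene_id, ";biotype=protein_coding")),
        line("mRNA", at, at + rl - 1,
             paste0("ID=", tx_id, ";Parent=", gene_id)))
      feat <- function(df, type) {
        for (k in seq_len(NROW(df)))
          gff <<- c(gff, line(type, df$start[k], df$end[k],
                              paste0("Parent=", tx_id)))
      }
      feat(exons, "exon")
      feat(cds, "CDS")
      if (spec$emit_utrs) {
        if (!is.null(utr5)) feat(utr5, "five_prime_UTR")
        if (!is.null(utr3)) feat(utr3, "three_prime_UTR")
      }
      add_manifest(type = "gene", chrom = g$chrom, start = at,
                   end = at + rl - 1, strand = strand, detail = tx_id)
    }

    for (pi in seq_along(spec$planted)) {
      p <- spec$planted[[pi]]
      s <- switch(p$type,
        sequence = p$seq,
        homopolymer = strrep(p$base, p$len),
        gc_block = with_gc_block(p$len, p$gc),
        protospacer_copy = planted_protospacer(p),
        duplication = substr(chroms[[p$src_chrom]], p$src_start, p$src_end),
        stop("unknown planted feature type: ", p$type))
      if (!is.null(p$strand) && p$strand == "-") s <- revcomp(s)
      claim(p$chrom, p$pos, p$pos + nchar(s) - 1, paste0(p$type, pi))
      write_at(p$chrom, p$pos, s)
      add_manifest(type = p$type, chrom = p$chrom, start = p$pos,
                   end = p$pos + nchar(s) - 1,
                   strand = p$strand %||% "+",
                   detail = p$label %||% "")
    }

    fasta <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(chroms), fasta)
    gff3 <- file.path(dir, "annotation.gff3")
    writeLines(gff, gff3)
    manifest_df <- if (length(manifest)) do.call(rbind, manifest) else
      data.frame(type = character(0), chrom = character(0),
                 start = integer(0), end = integer(0),
                 strand = character(0), detail = character(0))
    manifest_path <- file.path(dir, "manifest.csv")
    utils::write.csv(manifest_df, manifest_path, row.names = FALSE)
    list(fasta = fasta, gff3 = gff3, manifest = manifest_df,
         manifest_path = manifest_path)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_gc_block <- function(len, gc) random_background(len, gc)

## protospacer copy with k mismatches at seeded positions plus a chosen PAM,
## in protospacer orientation (PAM side per `pam_side`)
planted_protospacer <- function(p) {
  sp <- p$protospacer
  if (p$mismatches > 0) {
    idx <- sort(sample(nchar(sp), p$mismatches))
    ch <- str_chars(sp)
    for (i in idx) ch[i] <- setdiff(BASES, ch[i])[sample(3, 1)]
    sp <- paste0(ch, collapse = "")
  }
  if ((p$pam_side %||% "3prime") == "3prime") paste0(sp, p$pam)
  else paste0(p$pam, sp)
}

#' Reference primer panel with frozen independent-oracle melting temperatures
#'
#' A fixed panel of 18-25-mers whose Tm was computed once with an
#' independent nearest-neighbour implementation and stored; used to audit
#' the package's own thermodynamic engine.
#'
#' @return data.frame with `sequence` and `tm_oracle` (degrees C).
#' @export
reference_panel <- function() {
  read_table_csv("tm_reference_panel.csv")
}
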