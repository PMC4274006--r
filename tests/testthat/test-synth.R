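test_that("panel generation is deterministic and books SNP columns exactly", {
  tr1 <- amomum_panel(seed = 5)
  tr2 <- amomum_panel(seed = 5)
  tr1$seed <- tr2$seed <- NULL
  expect_identical(tr1, tr2)

  counts <- table(factor(tr1$planted_snps$locus,
                         levels = names(tr1$references)))
  expect_equal(as.integer(counts[c("ITS", "LSU_D1_D3", "rbcL", "matK",
                                   "trnH_psbA")]),
               c(19L, 11L, 4L, 1L, 0L))
  expect_equal(nrow(tr1$planted_snps), 35L)

  # every planted column has at least one carrier whose allele differs
  for (k in seq_len(nrow(tr1$planted_snps))) {
    row <- tr1$planted_snps[k, ]
    carriers <- strsplit(row$carriers, ",")[[1]]
    alleles <- vapply(carriers, function(id)
      substr(tr1$sample_genotypes[[id]][[row$locus]], row$position,
             row$position), character(1))
    expect_true(all(alleles != row$ref_base))
  }

  # reference sample carries the reference genotype everywhere
  ref <- tr1$sample_genotypes[[tr1$reference_sample]]
  expect_identical(unname(ref[names(tr1$references)]),
                   unname(tr1$references))
})

test_that("a panel with no planted SNPs has a single genotype", {
  tr <- make_panel(c(A = 5L), list(locus_spec("L1", 400)), c(L1 = 0L),
                   seed = 3)
  gts <- vapply(tr$sample_genotypes, `[[`, character(1), "L1")
  expect_length(unique(gts), 1L)
  expect_identical(unique(gts), unname(tr$references["L1"]))
})

test_that("requesting more SNPs than positions is a configuration error", {
  expect_error(make_panel(c(A = 4L), list(locus_spec("L1", 300)),
                          c(L1 = 300L), seed = 1),
               "exceeds available positions")
})

test_that("reverse reads reverse-complement back onto the genotype", {
  tr <- small_panel(seed = 21)
  reads <- simulate_reads(tr, trace_model(noiseless = TRUE), seed = 9,
                          n_individuals = 1L)
  for (id in c("A01", "C01")) {
    fwd <- reads[[sprintf("%s|L1|i1|f", id)]]
    rev <- reads[[sprintf("%s|L1|i1|r", id)]]
    gt <- tr$sample_genotypes[[id]][["L1"]]
    expect_identical(fwd$bases, gt)
    expect_identical(reverse_complement(rev$bases), gt)
    # cross-check the complement table against Biostrings
    expect_identical(
      reverse_complement(rev$bases),
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(rev$bases))))
  }
})

test_that("planted heterozygotes show the secondary fraction on both strands", {
  tr <- make_panel(c(A = 6L), list(locus_spec("L1", 400)), c(L1 = 6L),
                   seed = 2, p_het = 1)  # every private variant heterozygous
  expect_gt(nrow(tr$planted_het_sites), 0)
  model <- trace_model(noiseless = TRUE, het_secondary_fraction = 0.6)
  reads <- simulate_reads(tr, model, seed = 4, n_individuals = 1L)
  for (k in seq_len(nrow(tr$planted_het_sites))) {
    hs <- tr$planted_het_sites[k, ]
    fwd <- reads[[sprintf("%s|%s|i1|f", hs$sample, hs$locus)]]
    rev <- reads[[sprintf("%s|%s|i1|r", hs$sample, hs$locus)]]
    L <- nchar(fwd$bases)
    expect_equal(fwd$secondary_fraction[hs$position], 0.6)
    expect_equal(rev$secondary_fraction[L - hs$position + 1], 0.6)
    # the two strands carry complementary allele pairs
    pair_f <- sort(c(substr(fwd$bases, hs$position, hs$position),
                     fwd$second_base[hs$position]))
    expect_setequal(pair_f, sort(c(hs$allele1, hs$allele2)))
  }
})

test_that("forced repeat failure drives sequencing success to zero", {
  tr <- make_panel(c(A = 4L),
                   list(locus_spec("L1", 700,
                                   failure_mode = "mononucleotide_repeat",
                                   repeat_run_length = 12L)),
                   c(L1 = 0L), seed = 6)
  model <- trace_model(noiseless = TRUE, repeat_fail_frac = 1)
  reads <- simulate_reads(tr, model, seed = 8)
  metrics <- do.call(rbind, lapply(reads, trace_metrics))
  expect_equal(success_rate(metrics), 0)

  # and with no failures, every noiseless read passes
  model0 <- trace_model(noiseless = TRUE, repeat_fail_frac = 0)
  reads0 <- simulate_reads(tr, model0, seed = 8)
  metrics0 <- do.call(rbind, lapply(reads0, trace_metrics))
  expect_equal(success_rate(metrics0), 100)
})

test_that("FASTQ + sidecar round trip preserves reads", {
  tr <- make_panel(c(A = 3L), list(locus_spec("L1", 320)), c(L1 = 2L),
                   seed = 13, p_het = 1)
  # exact round trip in the noiseless limit (no background fractions)
  reads <- simulate_reads(tr, trace_model(noiseless = TRUE), seed = 14,
                          n_individuals = 1L)
  fq <- tempfile(fileext = ".fastq"); sc <- tempfile(fileext = ".tsv")
  write_reads_fastq(reads, fq, sc)
  back <- read_reads_fastq(fq, sc)
  expect_setequal(names(back), names(reads))
  for (rid in names(reads)) {
    expect_identical(back[[rid]]$bases, reads[[rid]]$bases)
    expect_identical(back[[rid]]$qv, reads[[rid]]$qv)
    expect_identical(back[[rid]]$second_base, reads[[rid]]$second_base)
    expect_equal(back[[rid]]$secondary_fraction,
                 reads[[rid]]$secondary_fraction, tolerance = 1e-6)
    expect_identical(back[[rid]]$direction, reads[[rid]]$direction)
  }

  # with background noise, fractions at/above the persistence floor survive
  noisy <- simulate_reads(tr, trace_model(), seed = 14, n_individuals = 1L)
  write_reads_fastq(noisy, fq, sc)
  back2 <- read_reads_fastq(fq, sc)
  for (rid in names(noisy)) {
    keep <- noisy[[rid]]$secondary_fraction >= 0.1
    expect_equal(back2[[rid]]$secondary_fraction[keep],
                 noisy[[rid]]$secondary_fraction[keep], tolerance = 1e-6)
    expect_true(all(back2[[rid]]$secondary_fraction[!keep] < 0.1))
    expect_identical(back2[[rid]]$second_base, noisy[[rid]]$second_base)
  }
})
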