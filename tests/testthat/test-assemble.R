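trimmed_from <- function(read) {
  tr <- trim_read(read, window = 1L, qv_floor = 0L, max_bad = 99L)
  tr
}

# a forward/reverse pair reading the same template
pair_from_template <- function(template, rev_shift = 0L) {
  n <- nchar(template)
  fwd <- make_read(rep(40L, n), bases = template, id = "f")
  rc <- reverse_complement(template)
  rev_bases <- substr(rc, 1, n - rev_shift)
  rev <- make_read(rep(40L, nchar(rev_bases)), bases = rev_bases, id = "r",
                   direction = "reverse")
  list(fwd = trimmed_from(fwd), rev = trimmed_from(rev))
}

test_that("reverse complement is an involution, IUPAC included", {
  s <- "ACGTWMRYSKN"
  expect_identical(reverse_complement(reverse_complement(s)), s)
  withr::local_seed(17)
  for (i in 1:10) {
    x <- paste(sample(names(snptyper:::IUPAC_PAIRS), 50, TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(x)), x)
  }
})

test_that("identical full-overlap reads self-assemble into the template", {
  withr::local_seed(23)
  template <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  p <- pair_from_template(template)
  cg <- assemble_pair(p$fwd, p$rev)
  expect_true(cg$accepted)
  expect_identical(cg$consensus, template)
  expect_length(cg$het_positions, 0)
  expect_equal(cg$offset, 0L)
  expect_true(all(cg$support == "both_strands"))
})

test_that("overlap and match thresholds decide acceptance as computed directly", {
  withr::local_seed(29)
  template <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  # reverse read covers only the last 400 bases: overlap 400 = 0.8 x 400? no —
  # 0.8 x min(500, 400) = 320, so the overlap of 400 passes the overlap rule
  p <- pair_from_template(template, rev_shift = 100L)
  cg <- assemble_pair(p$fwd, p$rev)
  expect_true(cg$accepted)
  expect_equal(cg$overlap, 400L)
  expect_identical(cg$consensus, template)

  # plant 9 mismatches in the overlap: 391/400 = 0.9775 < 0.98 -> rejected
  rev_bad <- p$rev
  ch <- strsplit(rev_bad$bases, "")[[1]]
  pos <- sample(length(ch), 9)
  ch[pos] <- vapply(ch[pos], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  rev_bad$bases <- paste(ch, collapse = "")
  cg_bad <- assemble_pair(p$fwd, rev_bad)
  expect_false(cg_bad$accepted)
  expect_lt(cg_bad$pct_match, 0.98)

  # 7 mismatches: 393/400 = 0.9825 >= 0.98 -> accepted
  rev_ok <- p$rev
  ch <- strsplit(rev_ok$bases, "")[[1]]
  pos <- sample(length(ch), 7)
  ch[pos] <- vapply(ch[pos], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  rev_ok$bases <- paste(ch, collapse = "")
  cg_ok <- assemble_pair(p$fwd, rev_ok)
  expect_true(cg_ok$accepted)
  expect_gte(cg_ok$pct_match, 0.98)

  # too little overlap: reverse read covers 300 of 500 -> 300 < 0.8 x 300? no:
  # min(|fwd|,|rev|) = 300, need >= 240; shrink further to force rejection
  p2 <- pair_from_template(template, rev_shift = 350L)  # rev length 150
  # chop the forward read so the true overlap is only 100 bases
  fwd_short <- make_read(rep(40L, 450), bases = substr(template, 1, 450))
  cg2 <- assemble_pair(trimmed_from(fwd_short), p2$rev)
  # overlap of the true placement = 100 < 0.8 x 150 -> only accepted if a
  # spurious placement beats the thresholds, which match scoring prevents
  expect_false(cg2$accepted)
})

test_that("heterozygote calls need the secondary peak on both strands", {
  # bidirectional 0.6 secondary with agreeing pair -> IUPAC code
  expect_equal(call_heterozygote("A", "A", "G", "G", 0.6, 0.6, 40, 40)$base, "R")
  # at/below the 0.40 threshold -> primary base
  expect_equal(call_heterozygote("A", "A", "G", "G", 0.39, 0.39, 40, 40)$base, "A")
  expect_equal(call_heterozygote("A", "A", "G", "G", 0.40, 0.40, 40, 40)$base, "A")
  # single-strand secondary -> primary base
  expect_equal(call_heterozygote("A", "A", "G", NA, 0.6, 0, 40, 40)$base, "A")
  # strand conflict without het evidence -> higher-QV base, flagged
  res <- call_heterozygote("A", "G", NA, NA, 0, 0, 50, 30)
  expect_equal(res$base, "A")
  expect_true(res$conflict)
  res2 <- call_heterozygote("A", "G", NA, NA, 0, 0, 30, 50)
  expect_equal(res2$base, "G")
})

test_that("noiseless planted heterozygotes are recovered exactly", {
  tr <- make_panel(c(A = 6L), list(locus_spec("L1", 400)), c(L1 = 6L),
                   seed = 2, p_het = 1)
  reads <- simulate_reads(tr, trace_model(noiseless = TRUE), seed = 4,
                          n_individuals = 1L)
  for (id in names(tr$sample_genotypes)) {
    fwd <- trim_read(reads[[sprintf("%s|L1|i1|f", id)]])
    rev <- trim_read(reads[[sprintf("%s|L1|i1|r", id)]])
    cg <- assemble_pair(fwd, rev)
    expect_true(cg$accepted)
    expect_identical(cg$consensus, tr$sample_genotypes[[id]][["L1"]])
    planted <- tr$planted_het_sites
    want <- sort(planted$position[planted$sample == id])
    expect_equal(sort(cg$het_positions), want)
  }
})
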