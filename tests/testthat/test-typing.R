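# Noiseless typing fixture: SNP calls straight from the truth genotypes.
typing_fixture <- function(truth) {
  loci <- names(truth$references)
  snp_calls <- lapply(truth$sample_genotypes, function(g) {
    out <- lapply(loci, function(lc) call_snps(g[[lc]], truth$references[[lc]]))
    names(out) <- loci
    out
  })
  consensus <- lapply(truth$sample_genotypes, function(g) as.list(g[loci]))
  list(snp_calls = snp_calls, consensus = consensus,
       references = as.list(truth$references))
}

test_that("SNP calling recovers planted substitutions in reference coordinates", {
  tr <- small_panel(seed = 31)
  # the reference sample yields an empty call set
  ref_calls <- call_snps(tr$sample_genotypes[[tr$reference_sample]][["L1"]],
                         tr$references[["L1"]])
  expect_equal(nrow(ref_calls), 0L)

  ps <- tr$planted_snps
  for (id in names(tr$sample_genotypes)) {
    for (lc in c("L1", "L2")) {
      calls <- call_snps(tr$sample_genotypes[[id]][[lc]],
                         tr$references[[lc]])
      carried <- ps[ps$locus == lc &
                      vapply(strsplit(ps$carriers, ","), function(cs)
                        id %in% cs, logical(1)), ]
      expect_equal(sort(calls$position), sort(carried$position))
      expect_true(all(calls$ref_base ==
                        carried$ref_base[match(calls$position,
                                               carried$position)]))
    }
  }
})

test_that("an IUPAC code over a pure reference base counts as one SNP site", {
  ref <- "ACGTACGTAC"
  sam <- "ACGTRCGTAC"
  calls <- call_snps(sam, ref)
  expect_equal(calls$position, 5L)
  expect_equal(calls$ref_base, "A")
  expect_equal(calls$sample_base, "R")
})

test_that("ST assignment is a first-occurrence bijection on distinct vectors", {
  m <- matrix(c("A", "A",
                "G", "A",
                "A", "A",
                "G", "C"), ncol = 2, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("c1", "c2")))
  reg <- assign_sts(m)
  expect_equal(unname(reg$st), c(1L, 2L, 1L, 3L))
  expect_equal(reg$members$ST1, c("s1", "s3"))

  all_same <- matrix("A", 5, 3, dimnames = list(paste0("s", 1:5), NULL))
  expect_length(assign_sts(all_same)$members, 1L)

  all_diff <- matrix(c("A", "C", "G", "T"), 4, 1,
                     dimnames = list(paste0("s", 1:4), NULL))
  expect_length(assign_sts(all_diff)$members, 4L)

  # permutation invariance of the induced partition
  perm <- sample(nrow(m))
  reg2 <- assign_sts(m[perm, , drop = FALSE])
  part1 <- unname(lapply(reg$members, sort))
  part2 <- unname(lapply(reg2$members, sort))
  expect_setequal(vapply(part1, paste, "", collapse = ","),
                  vapply(part2, paste, "", collapse = ","))
})

test_that("combination SNP counts are additive and ST counts monotone", {
  tr <- small_panel(seed = 37, n_snps = c(L1 = 5L, L2 = 3L))
  fx <- typing_fixture(tr)
  rep <- evaluate_combinations(fx$snp_calls, fx$consensus, fx$references,
                               list(L1 = "L1", L2 = "L2",
                                    `L1+L2` = c("L1", "L2")))
  n1 <- rep$n_snps[rep$combination == "L1"]
  n2 <- rep$n_snps[rep$combination == "L2"]
  n12 <- rep$n_snps[rep$combination == "L1+L2"]
  expect_equal(n12, n1 + n2)
  expect_equal(n12, 8L)
  expect_gte(rep$n_sts[rep$combination == "L1+L2"],
             max(rep$n_sts[rep$combination != "L1+L2"]))
})

test_that("Pearson r and p match the published counts and a direct formula", {
  counts <- amomum_reported_counts()
  expect_equal(nrow(counts), 15L)
  res <- pearson_snp_st(counts)
  expect_equal(round(res$r, 4), 0.9182)
  expect_lt(res$p, 1e-5)

  # perfectly proportional columns
  prop <- data.frame(n_snps = c(2, 4, 6, 8), n_sts = c(1, 2, 3, 4))
  expect_equal(pearson_snp_st(prop)$r, 1)

  # random table vs covariance/sigma oracle
  withr::local_seed(41)
  rnd <- data.frame(n_snps = rpois(15, 10), n_sts = rpois(15, 6))
  r_hand <- {
    x <- rnd$n_snps; y <- rnd$n_sts
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(pearson_snp_st(rnd)$r, r_hand)

  flat <- data.frame(n_snps = c(3, 3, 3), n_sts = c(1, 2, 3))
  expect_error(pearson_snp_st(flat), "zero variance")
})

test_that("diagnostic sites are detected by allele-set disjointness", {
  tr <- amomum_panel(seed = 42)
  tp <- true_profiles(tr, c("ITS", "LSU_D1_D3", "rbcL", "matK"))
  ds <- diagnostic_sites(tp, tr$species)

  # planted design: 18 C-diagnostic columns, the 5 triallelic ITS columns
  # split all three species
  expect_length(ds$C_vs_rest, 18L)
  expect_length(ds$all_species, 5L)
  expect_true(all(grepl("^ITS:", ds$all_species)))
  expect_true(all(ds$all_species %in% ds$C_vs_rest))

  # a column with an allele shared between species is not diagnostic
  m <- matrix(c("A", "G", "G"), ncol = 1,
              dimnames = list(c("x1", "x2", "y1"), "L:1"))
  sp <- c(x1 = "A", x2 = "A", y1 = "C")
  expect_length(diagnostic_sites(m, sp)$C_vs_rest, 0L)

  # three alleles, one per species -> pairwise split
  m3 <- matrix(c("A", "C", "G"), ncol = 1,
               dimnames = list(c("a", "b", "c"), "L:1"))
  sp3 <- c(a = "A", b = "B", c = "C")
  expect_equal(diagnostic_sites(m3, sp3)$all_species, "L:1")
})

test_that("19 STs among 29 samples give 65.5 percent resolution", {
  # 29 single-column profiles with exactly 19 distinct values
  vals <- c(paste0("v", 1:19), paste0("v", sample(1:19, 10, replace = TRUE)))
  m <- matrix(vals, ncol = 1, dimnames = list(paste0("s", 1:29), "c1"))
  reg <- assign_sts(m)
  expect_length(reg$members, 19L)
  expect_equal(round_half_up(100 * length(reg$members) / nrow(m), 1), 65.5)
})
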