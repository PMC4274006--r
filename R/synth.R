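## Synthetic panel generator: reference sequences, landrace genotypes with
## planted substitution SNPs and heterozygous sites, and simulated
## bidirectional quality reads with a mononucleotide-repeat failure mode.

#' Describe one barcode locus
#'
#' @param locus_id short locus name (e.g. `"ITS"`).
#' @param length locus length in bp; must lie in `[300, 1200]`.
#' @param failure_mode `"none"` or `"mononucleotide_repeat"`. The repeat mode
#'   plants homopolymer runs in the reference that interrupt sequencing in a
#'   configurable fraction of reads (see [trace_model()]), emulating loci such
#'   as trnH-psbA whose traces collapse downstream of poly-A/T runs.
#' @param repeat_run_length homopolymer run length in bp (>= 8), used only for
#'   the repeat failure mode.
#' @return A `locus_spec` object.
#' @export
locus_spec <- function(locus_id, length,
                       failure_mode = c("none", "mononucleotide_repeat"),
                       repeat_run_length = 12L) {
  failure_mode <- match.arg(failure_mode)
  stopifnot(is.character(locus_id), nchar(locus_id) > 0)
  if (length < 300 || length > 1200)
    stop("locus length must be within [300, 1200] bp")
  if (failure_mode == "mononucleotide_repeat" && repeat_run_length < 8)
    stop("repeat_run_length must be >= 8 for the mononucleotide_repeat mode")
  structure(list(locus_id = locus_id, length = as.integer(length),
                 failure_mode = failure_mode,
                 repeat_run_length = as.integer(repeat_run_length)),
            class = "locus_spec")
}

#' Trace simulation model
#'
#' Parameterizes the simulated Sanger-style traces. Quality values (QV) follow
#' a flat peak then a linear decay with Gaussian noise, clipped to `[0, 60]`.
#' Basecall errors follow Phred semantics (per-base substitution probability
#' `10^(-qv/10)`) plus an optional flat `error_rate`; heterozygous positions
#' carry a secondary-peak fraction on both strands.
#'
#' @param peak_qv modal quality value of the clean part of a trace.
#' @param qv_decay_start read position (bp) where quality starts to decay.
#' @param qv_decay_slope QV lost per bp after `qv_decay_start`.
#' @param qv_noise_sd standard deviation of Gaussian QV noise.
#' @param het_secondary_fraction secondary-peak fraction planted at
#'   heterozygous sites, in `(0, 1]`; must exceed the 0.40 calling threshold
#'   for planted heterozygotes to be callable.
#' @param error_rate flat extra substitution rate per base (default 0; Phred
#'   errors still apply unless `phred_errors = FALSE`).
#' @param phred_errors if `TRUE`, draw substitutions at rate `10^(-qv/10)`.
#' @param hom_secondary_max homozygous positions get a uniform secondary-peak
#'   fraction in `[0, hom_secondary_max]` (background trace noise).
#' @param repeat_fail_frac fraction of reads of a repeat-mode locus whose
#'   signal collapses downstream of the first homopolymer run encountered in
#'   the read's own orientation.
#' @param fail_qv mean QV of the collapsed region.
#' @param noiseless convenience switch: zero noise, zero errors, zero
#'   background secondary fraction (repeat failures still occur).
#' @return A `trace_model` object.
#' @export
trace_model <- function(peak_qv = 55, qv_decay_start = 450, qv_decay_slope = 0.03,
                        qv_noise_sd = 2, het_secondary_fraction = 0.6,
                        error_rate = 0, phred_errors = TRUE,
                        hom_secondary_max = 0.05, repeat_fail_frac = 0.66,
                        fail_qv = 8, noiseless = FALSE) {
  if (noiseless) {
    qv_noise_sd <- 0; error_rate <- 0; phred_errors <- FALSE
    hom_secondary_max <- 0
  }
  stopifnot(peak_qv >= 0, peak_qv <= 60,
            het_secondary_fraction > 0, het_secondary_fraction <= 1,
            error_rate >= 0, repeat_fail_frac >= 0, repeat_fail_frac <= 1)
  structure(list(peak_qv = peak_qv, qv_decay_start = qv_decay_start,
                 qv_decay_slope = qv_decay_slope, qv_noise_sd = qv_noise_sd,
                 het_secondary_fraction = het_secondary_fraction,
                 error_rate = error_rate, phred_errors = phred_errors,
                 hom_secondary_max = hom_secondary_max,
                 repeat_fail_frac = repeat_fail_frac, fail_qv = fail_qv),
            class = "trace_model")
}

# length-safe sampler: never falls into sample(x, k)'s 1:x behaviour
sample_vec <- function(x, k) x[sample.int(length(x), k)]

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Relative positions of planted homopolymer runs. Two runs so that both read
# directions hit a run early in their own orientation.
REPEAT_REL_POSITIONS <- c(0.2, 0.8)

plant_repeats <- function(seq, run_len) {
  ch <- split_string(seq)
  runs <- data.frame(start = integer(0), end = integer(0))
  for (rel in REPEAT_REL_POSITIONS) {
    s <- max(2L, round(rel * length(ch)))
    e <- min(length(ch) - 1L, s + run_len - 1L)
    ch[s:e] <- "A"
    runs <- rbind(runs, data.frame(start = s, end = e))
  }
  # break any accidental flanking A so the run length is exactly as planted
  for (i in seq_len(nrow(runs))) {
    if (runs$start[i] > 1 && ch[runs$start[i] - 1L] == "A")
      ch[runs$start[i] - 1L] <- "C"
    if (runs$end[i] < length(ch) && ch[runs$end[i] + 1L] == "A")
      ch[runs$end[i] + 1L] <- "C"
  }
  list(seq = paste(ch, collapse = ""), runs = runs)
}

#' Generate a synthetic multi-locus landrace panel
#'
#' Builds per-locus reference sequences (the designated reference individual is
#' the first sample of species A), plants single-base substitution SNPs with
#' known carriers, and assigns species structure: species C carries fixed
#' diagnostic alleles at `n_diag_per_locus` columns (a distant species), and
#' species B differs from A only at `n_triallelic` of those columns, where it
#' carries a third allele (a near-variant of A). Remaining SNP columns are
#' private within-species variants distributed round-robin over non-founder
#' samples (at most `max_private` each); a fraction `p_het` of those variant
#' alleles are planted as IUPAC heterozygotes.
#'
#' @param n_samples_per_species named integer vector with names among
#'   `c("A","B","C")`; species A (which hosts the reference) must be present.
#' @param locus_specs list of [locus_spec()] objects.
#' @param n_snps_per_locus named integer vector (per locus id).
#' @param seed integer seed; identical inputs and seed give an identical panel.
#' @param n_diag_per_locus named integer vector of species-C-diagnostic column
#'   counts per locus (default: half the SNPs, rounded up; forced to 0 if C is
#'   absent).
#' @param n_triallelic number of diagnostic columns (on the first locus) where
#'   species B carries a third allele (default `min(5, diag columns)`; 0 if B
#'   absent).
#' @param founder_frac fraction of each species' samples sharing the founder
#'   genotype (at least one).
#' @param p_het probability that a private variant allele is heterozygous.
#' @param max_private maximum private SNP columns per sample.
#' @return A `panel_truth` object: `references`, `sample_genotypes`, `species`,
#'   `planted_snps`, `planted_het_sites`, `locus_specs`, `repeat_runs`,
#'   `reference_sample`.
#' @export
make_panel <- function(n_samples_per_species, locus_specs, n_snps_per_locus,
                       seed, n_diag_per_locus = NULL, n_triallelic = NULL,
                       founder_frac = 1 / 3, p_het = 0.15, max_private = 3L) {
  stopifnot(!is.null(names(n_samples_per_species)),
            all(names(n_samples_per_species) %in% c("A", "B", "C")),
            "A" %in% names(n_samples_per_species))
  loci <- vapply(locus_specs, `[[`, character(1), "locus_id")
  names(locus_specs) <- loci
  stopifnot(all(loci %in% names(n_snps_per_locus)) ||
              length(n_snps_per_locus) == length(loci))
  if (is.null(names(n_snps_per_locus))) names(n_snps_per_locus) <- loci
  n_snps_per_locus <- n_snps_per_locus[loci]
  for (lc in loci) {
    if (n_snps_per_locus[[lc]] >= locus_specs[[lc]]$length)
      stop("requested SNP count exceeds available positions for locus ", lc)
  }

  has_B <- (n_samples_per_species["B"] %||% 0) > 0 && !is.na(n_samples_per_species["B"])
  has_C <- (n_samples_per_species["C"] %||% 0) > 0 && !is.na(n_samples_per_species["C"])
  has_B <- isTRUE(has_B); has_C <- isTRUE(has_C)
  if (is.null(n_diag_per_locus)) {
    n_diag_per_locus <- if (has_C) ceiling(n_snps_per_locus / 2) else
      stats::setNames(rep(0L, length(loci)), loci)
  }
  n_diag_per_locus <- n_diag_per_locus[loci]
  n_diag_per_locus[is.na(n_diag_per_locus)] <- 0L
  if (!has_C) n_diag_per_locus[] <- 0L
  stopifnot(all(n_diag_per_locus <= n_snps_per_locus))
  if (is.null(n_triallelic))
    n_triallelic <- if (has_B) min(5L, n_diag_per_locus[[1]]) else 0L
  if (!has_B) n_triallelic <- 0L
  stopifnot(n_triallelic <= n_diag_per_locus[[1]] %||% 0)

  withr::local_seed(seed)

  ## references (the genotype of the reference individual, first sample of A)
  references <- character(0)
  repeat_runs <- data.frame(locus = character(0), start = integer(0),
                            end = integer(0))
  snp_positions <- list()
  for (lc in loci) {
    sp <- locus_specs[[lc]]
    ref <- random_sequence(sp$length)
    forbidden <- integer(0)
    if (sp$failure_mode == "mononucleotide_repeat") {
      pr <- plant_repeats(ref, sp$repeat_run_length)
      ref <- pr$seq
      repeat_runs <- rbind(repeat_runs,
                           cbind(locus = lc, pr$runs))
      forbidden <- unlist(Map(seq, pr$runs$start - 1L, pr$runs$end + 1L))
    }
    references[lc] <- ref
    avail <- setdiff(seq_len(sp$length), forbidden)
    k <- n_snps_per_locus[[lc]]
    snp_positions[[lc]] <- sort(sample_vec(avail, k))
  }

  ## samples: founders first within each species; reference sample is A01
  sample_ids <- character(0); species <- character(0)
  for (s in intersect(c("A", "B", "C"), names(n_samples_per_species))) {
    n <- n_samples_per_species[[s]]
    if (n > 0) {
      ids <- sprintf("%s%02d", s, seq_len(n))
      sample_ids <- c(sample_ids, ids)
      species <- c(species, stats::setNames(rep(s, n), ids))
    }
  }
  reference_sample <- names(species)[species == "A"][1]

  n_founder <- vapply(unique(species), function(s)
    max(1L, as.integer(round(sum(species == s) * founder_frac))), integer(1))
  is_founder <- stats::setNames(rep(FALSE, length(sample_ids)), sample_ids)
  for (s in unique(species)) {
    ids <- names(species)[species == s]
    is_founder[ids[seq_len(min(n_founder[[s]], length(ids)))]] <- TRUE
  }

  ## role assignment for SNP columns
  ref_chars <- lapply(references, split_string)
  alt_of <- function(exclude) sample_vec(setdiff(c("A", "C", "G", "T"), exclude), 1)

  columns <- list()   # per column: locus, pos, role, alleles
  for (lc in loci) {
    pos <- snp_positions[[lc]]
    nd <- n_diag_per_locus[[lc]]
    diag_pos <- if (nd > 0) sort(sample_vec(pos, nd)) else integer(0)
    tri_pos <- integer(0)
    if (lc == loci[1] && n_triallelic > 0)
      tri_pos <- sort(sample_vec(diag_pos, n_triallelic))
    for (p in pos) {
      refb <- ref_chars[[lc]][p]
      if (p %in% diag_pos) {
        altC <- alt_of(refb)
        altB <- if (p %in% tri_pos) alt_of(c(refb, altC)) else NA_character_
        columns[[length(columns) + 1L]] <-
          list(locus = lc, pos = p, role = "diag", ref = refb,
               altC = altC, altB = altB)
      } else {
        columns[[length(columns) + 1L]] <-
          list(locus = lc, pos = p, role = "within", ref = refb)
      }
    }
  }

  ## genotypes start from the reference everywhere
  genotypes <- lapply(sample_ids, function(id) ref_chars)
  names(genotypes) <- sample_ids

  planted <- list(); het_sites <- list()
  add_planted <- function(locus, pos, ref, alts, carriers) {
    planted[[length(planted) + 1L]] <<-
      data.frame(locus = locus, position = pos, ref_base = ref,
                 alt_alleles = paste(unique(alts), collapse = ","),
                 carriers = paste(carriers, collapse = ","))
  }

  C_ids <- names(species)[species == "C"]
  B_ids <- names(species)[species == "B"]
  for (cl in columns) {
    if (cl$role != "diag") next
    for (id in C_ids) genotypes[[id]][[cl$locus]][cl$pos] <- cl$altC
    alts <- cl$altC; carriers <- C_ids
    if (!is.na(cl$altB)) {
      for (id in B_ids) genotypes[[id]][[cl$locus]][cl$pos] <- cl$altB
      alts <- c(alts, cl$altB); carriers <- c(carriers, B_ids)
    }
    add_planted(cl$locus, cl$pos, cl$ref, alts, carriers)
  }

  ## private within-species variants, round-robin over non-founder samples
  within_cols <- Filter(function(cl) cl$role == "within", columns)
  within_cols <- within_cols[sample(length(within_cols))]
  variant_ids <- names(is_founder)[!is_founder]
  if (length(within_cols) > 0 && length(variant_ids) == 0)
    stop("within-species SNP columns requested but every sample is a founder")
  n_assigned <- stats::setNames(rep(0L, length(variant_ids)), variant_ids)
  queue <- rep(variant_ids, max_private)[order(rep(seq_len(max_private),
                                                   each = length(variant_ids)))]
  qi <- 1L
  for (cl in within_cols) {
    while (qi <= length(queue) && n_assigned[queue[qi]] >= max_private) qi <- qi + 1L
    if (qi > length(queue)) {
      carriers <- sample_vec(variant_ids, min(2L, length(variant_ids)))
      alt <- alt_of(cl$ref)
      for (id in carriers) genotypes[[id]][[cl$locus]][cl$pos] <- alt
      add_planted(cl$locus, cl$pos, cl$ref, alt, carriers)
      next
    }
    id <- queue[qi]; qi <- qi + 1L
    n_assigned[id] <- n_assigned[id] + 1L
    alt <- alt_of(cl$ref)
    if (stats::runif(1) < p_het) {
      code <- het_code(cl$ref, alt)
      genotypes[[id]][[cl$locus]][cl$pos] <- code
      het_sites[[length(het_sites) + 1L]] <-
        data.frame(sample = id, locus = cl$locus, position = cl$pos,
                   allele1 = cl$ref, allele2 = alt)
      add_planted(cl$locus, cl$pos, cl$ref, code, id)
    } else {
      genotypes[[id]][[cl$locus]][cl$pos] <- alt
      add_planted(cl$locus, cl$pos, cl$ref, alt, id)
    }
  }

  planted_snps <- if (length(planted)) do.call(rbind, planted) else
    data.frame(locus = character(0), position = integer(0),
               ref_base = character(0), alt_alleles = character(0),
               carriers = character(0))
  planted_snps <- planted_snps[order(match(planted_snps$locus, loci),
                                     planted_snps$position), , drop = FALSE]
  rownames(planted_snps) <- NULL
  planted_het_sites <- if (length(het_sites)) do.call(rbind, het_sites) else
    data.frame(sample = character(0), locus = character(0),
               position = integer(0), allele1 = character(0),
               allele2 = character(0))

  sample_genotypes <- lapply(genotypes, function(g)
    vapply(g, paste, character(1), collapse = ""))

  structure(list(references = references,
                 sample_genotypes = sample_genotypes,
                 species = species,
                 planted_snps = planted_snps,
                 planted_het_sites = planted_het_sites,
                 locus_specs = locus_specs,
                 repeat_runs = repeat_runs,
                 reference_sample = reference_sample,
                 seed = seed),
            class = "panel_truth")
}

#' @export
print.panel_truth <- function(x, ...) {
  cat("Synthetic panel:", length(x$sample_genotypes), "samples,",
      length(x$references), "loci,", nrow(x$planted_snps), "planted SNP columns\n")
  cat("  species:", paste(sprintf("%s=%d", names(table(x$species)),
                                  table(x$species)), collapse = " "), "\n")
  cat("  reference sample:", x$reference_sample, "\n")
  invisible(x)
}

#' True SNP-profile matrix of a panel
#'
#' The genotype of every sample at the planted SNP columns of the given loci
#' (all loci by default), in (locus order, position ascending) column order —
#' the partition of its rows is the planted ST partition.
#'
#' @param truth a `panel_truth`.
#' @param loci locus ids to include.
#' @return Character matrix, rows = samples, columns named `<locus>:<pos>`.
#' @export
true_profiles <- function(truth, loci = names(truth$references)) {
  ps <- truth$planted_snps
  ps <- ps[ps$locus %in% loci, , drop = FALSE]
  ps <- ps[order(match(ps$locus, loci), ps$position), , drop = FALSE]
  ids <- names(truth$sample_genotypes)
  m <- matrix("", nrow = length(ids), ncol = nrow(ps),
              dimnames = list(ids, paste0(ps$locus, ":", ps$position)))
  for (j in seq_len(nrow(ps))) {
    lc <- ps$locus[j]; p <- ps$position[j]
    m[, j] <- vapply(ids, function(id)
      substr(truth$sample_genotypes[[id]][[lc]], p, p), character(1))
  }
  m
}

#' Default Amomi-Fructus-like panel
#'
#' The package's standard study emulation: 29 samples over three species
#' (A = 21, the majority species hosting the reference; B = 2, a near-variant
#' of A; C = 6, a distant species), four informative loci with planted SNP
#' counts (19, 11, 4, 1) — species-C-diagnostic at (9, 4, 4, 1) columns, five
#' of the first locus' diagnostic columns carrying a third allele in species B
#' — plus a fifth locus with a mononucleotide-repeat sequencing failure mode
#' and no planted SNPs.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [make_panel()].
#' @return A `panel_truth`.
#' @export
amomum_panel <- function(seed, ...) {
  specs <- list(
    locus_spec("ITS", 660),
    locus_spec("LSU_D1_D3", 714),
    locus_spec("rbcL", 568),
    locus_spec("matK", 818),
    locus_spec("trnH_psbA", 715, failure_mode = "mononucleotide_repeat",
               repeat_run_length = 12)
  )
  args <- list(
    n_samples_per_species = c(A = 21L, B = 2L, C = 6L),
    locus_specs = specs,
    n_snps_per_locus = c(ITS = 19L, LSU_D1_D3 = 11L, rbcL = 4L, matK = 1L,
                         trnH_psbA = 0L),
    n_diag_per_locus = c(ITS = 9L, LSU_D1_D3 = 4L, rbcL = 4L, matK = 1L,
                         trnH_psbA = 0L),
    n_triallelic = 5L,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(make_panel, args)
}

## ---- read simulation --------------------------------------------------------

new_quality_read <- function(read_id, sample_id, locus_id, individual,
                             direction, bases, qv, secondary_fraction,
                             second_base) {
  n <- nchar(bases)
  stopifnot(length(qv) == n, length(secondary_fraction) == n,
            length(second_base) == n, all(qv >= 0 & qv <= 60),
            direction %in% c("forward", "reverse"))
  structure(list(read_id = read_id, sample_id = sample_id,
                 locus_id = locus_id, individual = individual,
                 direction = direction, bases = bases, qv = as.integer(qv),
                 secondary_fraction = secondary_fraction,
                 second_base = second_base),
            class = "quality_read")
}

#' @export
print.quality_read <- function(x, ...) {
  cat(sprintf("<quality_read %s: %d bp, %s, mean QV %.1f>\n",
              x$read_id, nchar(x$bases), x$direction, mean(x$qv)))
  invisible(x)
}

simulate_one_read <- function(genotype_chars, ref_chars, direction, model,
                              runs = NULL) {
  L <- length(genotype_chars)
  primary <- character(L); second <- rep(NA_character_, L)
  frac <- numeric(L)
  expand <- iupac_expand(genotype_chars)
  is_het <- lengths(expand) == 2L
  for (i in which(is_het)) {
    pair <- expand[[i]]
    pri <- if (ref_chars[i] %in% pair) ref_chars[i] else min(pair)
    primary[i] <- pri
    second[i] <- setdiff(pair, pri)[1]
    frac[i] <- model$het_secondary_fraction
  }
  primary[!is_het] <- genotype_chars[!is_het]
  if (model$hom_secondary_max > 0)
    frac[!is_het] <- stats::runif(sum(!is_het), 0, model$hom_secondary_max)

  if (direction == "reverse") {
    primary <- rev(unname(IUPAC_COMPLEMENT[primary]))
    second <- rev(ifelse(is.na(second), NA_character_,
                         unname(IUPAC_COMPLEMENT[second])))
    frac <- rev(frac)
    is_het <- rev(is_het)
  }

  pos <- seq_len(L)
  qv <- model$peak_qv - pmax(0, pos - model$qv_decay_start) * model$qv_decay_slope
  if (model$qv_noise_sd > 0) qv <- qv + stats::rnorm(L, 0, model$qv_noise_sd)

  failed <- FALSE
  if (!is.null(runs) && nrow(runs) > 0 &&
      stats::runif(1) < model$repeat_fail_frac) {
    failed <- TRUE
    ends <- if (direction == "forward") runs$end else L - runs$start + 1L
    cut <- min(ends)
    if (cut < L) {
      idx <- (cut + 1L):L
      qv[idx] <- stats::rnorm(length(idx), model$fail_qv, 2)
    }
  }
  qv <- as.integer(pmin(60, pmax(0, round(qv))))

  p_err <- model$error_rate + if (model$phred_errors) 10^(-qv / 10) else 0
  err <- !is_het & stats::runif(L) < p_err
  if (any(err)) {
    for (i in which(err)) {
      primary[i] <- sample_vec(setdiff(c("A", "C", "G", "T"), primary[i]), 1)
    }
  }
  list(bases = paste(primary, collapse = ""), qv = qv, frac = frac,
       second = second, failed = failed)
}

#' Simulate bidirectional quality reads for a panel
#'
#' For every sample x locus, `n_individuals` independently amplified templates
#' are each sequenced in both directions (the study default of 2 individuals x
#' 2 directions gives 4 traces per sample x locus). Reverse reads are
#' reverse-complemented relative to the genotype; heterozygous positions carry
#' the model's secondary-peak fraction on both strands; repeat-mode loci lose
#' quality downstream of the first homopolymer run (in read orientation) in a
#' `repeat_fail_frac` fraction of reads.
#'
#' @param truth a `panel_truth` from [make_panel()].
#' @param model a [trace_model()].
#' @param seed integer seed.
#' @param n_individuals templates per sample x locus (default 2).
#' @return A list of `quality_read` objects (class `read_set`).
#' @export
simulate_reads <- function(truth, model = trace_model(), seed,
                           n_individuals = 2L) {
  withr::local_seed(seed)
  reads <- list()
  for (id in names(truth$sample_genotypes)) {
    for (lc in names(truth$references)) {
      g <- split_string(truth$sample_genotypes[[id]][[lc]])
      refc <- split_string(truth$references[[lc]])
      runs <- truth$repeat_runs[truth$repeat_runs$locus == lc, , drop = FALSE]
      if (nrow(runs) == 0) runs <- NULL
      for (ind in seq_len(n_individuals)) {
        for (dir in c("forward", "reverse")) {
          r <- simulate_one_read(g, refc, dir, model, runs)
          rid <- sprintf("%s|%s|i%d|%s", id, lc, ind,
                         substr(dir, 1, 1))
          reads[[rid]] <- new_quality_read(rid, id, lc, ind, dir, r$bases,
                                           r$qv, r$frac, r$second)
        }
      }
    }
  }
  structure(reads, class = "read_set")
}
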