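## SNP calling against the reference sample, SNP-genotype (ST) assignment,
## discriminatory-power evaluation of region combinations, and
## species-diagnostic site detection.

#' Call SNPs of a consensus contig against a reference sequence
#'
#' The contig is placed on the reference by the best ungapped offset (a contig
#' that cannot be aligned without internal gaps is the caller's
#' responsibility to exclude upstream; this routine refuses alignments below
#' `min_identity` with an `unalignable` marker). Every covered position whose
#' call differs from the reference (including an IUPAC code over a pure base)
#' is reported in 1-based reference coordinates.
#'
#' @param contig a `locus_contig` (accepted) or a plain consensus string.
#' @param reference reference sequence string of the same locus.
#' @param min_identity minimum match fraction over the aligned interval for
#'   the placement to be trusted.
#' @return A data frame `(position, ref_base, sample_base)`; attribute
#'   `"coverage"` holds the covered reference interval `c(from, to)`. If the
#'   contig cannot be placed, `NULL` with a warning.
#' @export
call_snps <- function(contig, reference, min_identity = 0.90) {
  cons <- if (inherits(contig, "locus_contig")) {
    stopifnot(isTRUE(contig$accepted))
    contig$consensus
  } else contig
  c_ch <- split_string(cons)
  r_ch <- split_string(reference)
  if (length(c_ch) == length(r_ch)) {
    off <- 0L; ia <- seq_along(r_ch)
  } else {
    b <- best_offset(r_ch, c_ch)
    if (is.na(b$offset) || b$matches / b$overlap < min_identity) {
      warning("contig could not be placed on the reference without gaps")
      return(NULL)
    }
    off <- b$offset
    ia <- max(1L, 1L + off):min(length(r_ch), length(c_ch) + off)
  }
  ib <- ia - off
  ident <- sum(c_ch[ib] == r_ch[ia]) / length(ia)
  if (ident < min_identity && length(c_ch) == length(r_ch)) {
    warning("contig could not be placed on the reference without gaps")
    return(NULL)
  }
  diff <- which(c_ch[ib] != r_ch[ia])
  out <- data.frame(position = ia[diff], ref_base = r_ch[ia][diff],
                    sample_base = c_ch[ib][diff])
  attr(out, "coverage") <- c(min(ia), max(ia))
  aligned <- r_ch                     # uncovered flanks fall back to reference
  aligned[ia] <- c_ch[ib]
  attr(out, "aligned") <- paste(aligned, collapse = "")
  out
}

#' Build the SNP-profile matrix for a set of samples over a locus combination
#'
#' The SNP columns of a combination are the union, over samples, of positions
#' where any sample differs from the reference, ordered by (locus order in the
#' combination, position ascending). Each sample's profile is its allele
#' symbol at every column (IUPAC heterozygote codes are distinct symbols).
#' Samples missing any locus of the combination are excluded.
#'
#' @param snp_calls nested list: `snp_calls[[sample]][[locus]]` is the data
#'   frame from [call_snps()] (or `NULL` if that sample x locus is missing).
#' @param consensus nested list of consensus strings, same shape (used to
#'   read each sample's base at columns where it matches the reference).
#' @param references named list/vector of reference strings.
#' @param combination character vector of locus ids.
#' @return Character matrix (samples x SNP columns) with column names
#'   `<locus>:<position>`; attribute `"excluded"` lists dropped samples.
#' @export
snp_profile_matrix <- function(snp_calls, consensus, references, combination) {
  samples <- names(snp_calls)
  has_all <- vapply(samples, function(id)
    all(vapply(combination, function(lc)
      !is.null(snp_calls[[id]][[lc]]), logical(1))), logical(1))
  excluded <- samples[!has_all]
  samples <- samples[has_all]
  if (length(samples) == 0) stop("no sample has data for every locus of the combination")

  cols <- list()
  for (lc in combination) {
    pos <- sort(unique(unlist(lapply(samples, function(id)
      snp_calls[[id]][[lc]]$position))))
    if (length(pos))
      cols[[lc]] <- data.frame(locus = lc, position = pos)
  }
  cols <- if (length(cols)) do.call(rbind, cols) else
    data.frame(locus = character(0), position = integer(0))

  m <- matrix("", nrow = length(samples), ncol = nrow(cols),
              dimnames = list(samples,
                              if (nrow(cols)) paste0(cols$locus, ":", cols$position)
                              else character(0)))
  for (j in seq_len(nrow(cols))) {
    lc <- cols$locus[j]; p <- cols$position[j]
    for (id in samples) {
      calls <- snp_calls[[id]][[lc]]
      hit <- calls$sample_base[calls$position == p]
      m[id, j] <- if (length(hit)) hit else substr(consensus[[id]][[lc]], p, p)
    }
  }
  attr(m, "excluded") <- excluded
  m
}

#' Assign SNP genotypes (STs)
#'
#' Identical allele vectors share an ST; distinct vectors get distinct STs,
#' numbered 1..K by first occurrence in row order.
#'
#' @param profiles character matrix of allele symbols (samples x SNP columns),
#'   all rows over the same combination.
#' @return An `st_registry`: `st` (named integer vector per sample),
#'   `members` (list of sample ids per ST), `profiles` (one representative
#'   row per ST).
#' @export
assign_sts <- function(profiles) {
  stopifnot(is.matrix(profiles))
  keys <- apply(profiles, 1, paste, collapse = "\r")
  ids <- match(keys, unique(keys))
  st <- stats::setNames(ids, rownames(profiles))
  members <- split(rownames(profiles), ids)
  names(members) <- paste0("ST", names(members))
  reps <- profiles[!duplicated(keys), , drop = FALSE]
  rownames(reps) <- paste0("ST", seq_len(nrow(reps)))
  structure(list(st = st, members = members, profiles = reps),
            class = "st_registry")
}

#' @export
print.st_registry <- function(x, ...) {
  cat(sprintf("<st_registry: %d samples, %d STs>\n", length(x$st),
              length(x$members)))
  invisible(x)
}

#' Evaluate discriminatory power of locus combinations
#'
#' One row per combination with its total SNP-column count and number of
#' distinct STs; the resolution percentage (100 x STs / samples) is included
#' per row.
#'
#' @param snp_calls,consensus,references as in [snp_profile_matrix()].
#' @param combinations named list of character vectors of locus ids.
#' @return Data frame `(combination, n_loci, n_snps, n_sts, n_samples,
#'   resolution_pct, complete)`; `complete` is `FALSE` when samples had to be
#'   excluded for missing loci.
#' @export
evaluate_combinations <- function(snp_calls, consensus, references,
                                  combinations) {
  if (is.null(names(combinations)))
    names(combinations) <- vapply(combinations, paste, character(1),
                                  collapse = "+")
  rows <- lapply(names(combinations), function(nm) {
    comb <- combinations[[nm]]
    m <- snp_profile_matrix(snp_calls, consensus, references, comb)
    reg <- assign_sts(m)
    data.frame(combination = nm, n_loci = length(comb), n_snps = ncol(m),
               n_sts = length(reg$members), n_samples = nrow(m),
               resolution_pct = round_half_up(100 * length(reg$members) /
                                                nrow(m), 1),
               complete = length(attr(m, "excluded")) == 0)
  })
  do.call(rbind, rows)
}

#' Pearson correlation between SNP and ST counts
#'
#' Product-moment correlation over the `(n_snps, n_sts)` pairs of a
#' combination report, with the two-tailed p-value from the t transform with
#' n - 2 degrees of freedom.
#'
#' @param report a data frame with `n_snps` and `n_sts` columns (at least 3
#'   rows).
#' @return List with `r` and `p`.
#' @export
pearson_snp_st <- function(report) {
  stopifnot(nrow(report) >= 3)
  if (stats::var(report$n_snps) == 0 || stats::var(report$n_sts) == 0)
    stop("correlation undefined: zero variance in SNP or ST counts")
  ct <- stats::cor.test(report$n_snps, report$n_sts, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Species-diagnostic SNP columns
#'
#' A column is diagnostic for a species-vs-rest split iff the allele sets of
#' the two sides are disjoint; a column splits all species pairwise iff each
#' species' allele set is disjoint from every other's.
#'
#' @param profiles character matrix (samples x SNP columns).
#' @param species named character vector of species labels per sample.
#' @return List with one entry per species (`<sp>_vs_rest`: column names
#'   diagnostic for that species) and `all_species` (columns splitting all
#'   species pairwise).
#' @export
diagnostic_sites <- function(profiles, species) {
  species <- species[rownames(profiles)]
  stopifnot(!anyNA(species), length(unique(species)) >= 2)
  sps <- sort(unique(species))
  allele_sets <- function(j) lapply(sps, function(s)
    unique(profiles[species == s, j]))
  out <- stats::setNames(vector("list", length(sps) + 1L),
                         c(paste0(sps, "_vs_rest"), "all_species"))
  for (nm in names(out)) out[[nm]] <- character(0)
  for (j in seq_len(ncol(profiles))) {
    sets <- allele_sets(j)
    names(sets) <- sps
    for (s in sps) {
      rest <- unique(unlist(sets[setdiff(sps, s)]))
      if (length(intersect(sets[[s]], rest)) == 0)
        out[[paste0(s, "_vs_rest")]] <-
          c(out[[paste0(s, "_vs_rest")]], colnames(profiles)[j])
    }
    pairwise <- all(utils::combn(length(sps), 2, function(ij)
      length(intersect(sets[[ij[1]]], sets[[ij[2]]])) == 0))
    if (pairwise)
      out$all_species <- c(out$all_species, colnames(profiles)[j])
  }
  out
}

#' Reported SNP/ST counts of the three-species Amomi Fructus barcode study
#'
#' The published discriminatory-power table for six single barcode regions
#' and nine multi-locus combinations in 29 landraces of three Amomum species:
#' total SNP count and number of SNP genotypes (STs) per combination. Useful
#' as a fixed input for correlation and additivity checks.
#'
#' @return Data frame `(combination, n_loci, n_snps, n_sts)`.
#' @export
amomum_reported_counts <- function() {
  path <- system.file("extdata", "amomum_combination_counts.tsv",
                      package = "snptyper", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
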