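## Bidirectional consensus assembly: best ungapped offset alignment of the
## trimmed forward read against the reverse-complemented reverse read, with
## IUPAC heterozygote calls confirmed on both strands.

# Reverse-complement a trimmed/quality read's per-base channels.
revcomp_read <- function(read) {
  ch <- rev(unname(IUPAC_COMPLEMENT[split_string(read$bases)]))
  list(bases = ch,
       qv = rev(read$qv),
       secondary_fraction = rev(read$secondary_fraction),
       second_base = rev(ifelse(is.na(read$second_base), NA_character_,
                                unname(IUPAC_COMPLEMENT[read$second_base]))))
}

#' Call one overlap position, heterozygote-aware
#'
#' A two-base IUPAC code is emitted iff the secondary-peak fraction exceeds
#' `threshold` on BOTH strands and the strands agree on the allele pair
#' (bidirectional confirmation). Otherwise the primary base of the higher-QV
#' strand is returned; a strand disagreement without heterozygote evidence is
#' flagged as a conflict (resolved to the higher-QV base).
#'
#' @param fwd_base,rev_base primary base call of each strand.
#' @param fwd_second,rev_second secondary (minor-peak) base of each strand,
#'   `NA` when absent.
#' @param fwd_frac,rev_frac secondary-peak fraction of each strand.
#' @param fwd_qv,rev_qv per-base quality of each strand.
#' @param threshold secondary peak must exceed this fraction of the primary
#'   peak (default 0.40).
#' @return List with `base` (the call) and `conflict` (logical).
#' @export
call_heterozygote <- function(fwd_base, rev_base, fwd_second = NA,
                              rev_second = NA, fwd_frac = 0, rev_frac = 0,
                              fwd_qv = 0, rev_qv = 0, threshold = 0.40) {
  if (fwd_frac > threshold && rev_frac > threshold &&
      !is.na(fwd_second) && !is.na(rev_second)) {
    pair_f <- sort(c(fwd_base, fwd_second))
    pair_r <- sort(c(rev_base, rev_second))
    if (identical(pair_f, pair_r))
      return(list(base = het_code(pair_f[1], pair_f[2]), conflict = FALSE))
  }
  base <- if (fwd_qv >= rev_qv) fwd_base else rev_base
  list(base = base, conflict = fwd_base != rev_base)
}

# Enumerate ungapped offsets of b against a; return the best by match count
# (ties: larger overlap, then offset closer to 0). Offsets are visited in
# decreasing-overlap order so that an offset whose overlap cannot beat the
# running best match count is skipped outright.
# offset o means b[1] aligns with a[1 + o].
best_offset <- function(a_chars, b_chars) {
  syms <- names(IUPAC_PAIRS)
  ai <- match(a_chars, syms); bi <- match(b_chars, syms)
  if (anyNA(ai) || anyNA(bi)) stop("non-IUPAC symbol in read")
  cm <- .iupac_compat_matrix
  ns <- length(syms)
  na_ <- length(ai); nb_ <- length(bi)
  offsets <- seq(-(nb_ - 1L), na_ - 1L)
  ov <- pmin(na_, nb_ + offsets) - pmax(1L, 1L + offsets) + 1L
  ord <- order(-ov, abs(offsets))
  best <- list(offset = NA_integer_, overlap = 0L, matches = -1L)
  for (k in ord) {
    o <- offsets[k]
    if (ov[k] <= best$matches) break  # no remaining offset can do better
    lo_a <- max(1L, 1L + o); hi_a <- min(na_, nb_ + o)
    ia <- lo_a:hi_a
    m <- sum(cm[(bi[ia - o] - 1L) * ns + ai[ia]])
    if (m > best$matches)
      best <- list(offset = o, overlap = ov[k], matches = m)
  }
  best
}

#' Assemble a forward/reverse read pair into a consensus contig
#'
#' The reverse read is reverse-complemented and the best ungapped offset
#' against the forward read is found (maximum IUPAC-compatible matches). The
#' assembly is accepted iff the overlap spans at least `min_overlap_frac` of
#' the shorter read and the match fraction over the overlap is at least
#' `min_match`. The consensus covers the union of positions; overlap positions
#' go through [call_heterozygote()], single-strand positions take that
#' strand's call and can never be heterozygous.
#'
#' @param fwd,rev `trimmed_read`s (forward and reverse).
#' @param min_overlap_frac minimum overlap as a fraction of the shorter read.
#' @param min_match minimum fraction of matching positions in the overlap.
#' @param het_threshold secondary-peak threshold for heterozygote calls.
#' @return A `locus_contig` (fields `consensus`, `het_positions`, `support`,
#'   `offset`, `overlap`, `pct_match`, `conflicts`, `accepted = TRUE`) or an
#'   assembly-failure object (`accepted = FALSE`, with the best offset's
#'   diagnostics).
#' @export
assemble_pair <- function(fwd, rev, min_overlap_frac = 0.80, min_match = 0.98,
                          het_threshold = 0.40) {
  stopifnot(!isTRUE(fwd$empty), !isTRUE(rev$empty),
            nchar(fwd$bases) > 0, nchar(rev$bases) > 0)
  f_ch <- split_string(fwd$bases)
  r <- revcomp_read(rev)
  nf <- length(f_ch); nr <- length(r$bases)

  b <- best_offset(f_ch, r$bases)
  pct_match <- if (b$overlap > 0) b$matches / b$overlap else 0
  fail <- structure(list(sample_id = fwd$sample_id, locus_id = fwd$locus_id,
                         individual = fwd$individual, accepted = FALSE,
                         offset = b$offset, overlap = b$overlap,
                         pct_match = pct_match),
                    class = "locus_contig")
  if (is.na(b$offset) ||
      b$overlap < min_overlap_frac * min(nf, nr) ||
      pct_match < min_match) return(fail)

  o <- b$offset
  # contig coordinates: union of fwd [1, nf] and rev-complemented [1+o, nr+o]
  lo <- min(1L, 1L + o); hi <- max(nf, nr + o)
  len <- hi - lo + 1L
  cons <- character(len); support <- character(len)
  het_pos <- integer(0); conflicts <- 0L
  for (p in lo:hi) {
    i <- p                 # fwd coordinate
    j <- p - o             # rev (complemented) coordinate
    on_f <- i >= 1L && i <= nf
    on_r <- j >= 1L && j <= nr
    k <- p - lo + 1L
    if (on_f && on_r) {
      call <- call_heterozygote(f_ch[i], r$bases[j],
                                fwd$second_base[i], r$second_base[j],
                                fwd$secondary_fraction[i],
                                r$secondary_fraction[j],
                                fwd$qv[i], r$qv[j], het_threshold)
      cons[k] <- call$base
      support[k] <- "both_strands"
      if (call$base %in% c("W", "M", "R", "Y", "S", "K"))
        het_pos <- c(het_pos, k)
      if (call$conflict) conflicts <- conflicts + 1L
    } else if (on_f) {
      cons[k] <- f_ch[i]; support[k] <- "single_strand"
    } else {
      cons[k] <- r$bases[j]; support[k] <- "single_strand"
    }
  }
  structure(list(sample_id = fwd$sample_id, locus_id = fwd$locus_id,
                 individual = fwd$individual, accepted = TRUE,
                 consensus = paste(cons, collapse = ""),
                 het_positions = het_pos, support = support,
                 offset = o, overlap = b$overlap, pct_match = pct_match,
                 conflicts = conflicts),
            class = "locus_contig")
}

#' @export
print.locus_contig <- function(x, ...) {
  if (x$accepted) {
    cat(sprintf("<locus_contig %s/%s: %d bp, %d het site(s), %.4f match>\n",
                x$sample_id, x$locus_id, nchar(x$consensus),
                length(x$het_positions), x$pct_match))
  } else {
    cat(sprintf("<locus_contig %s/%s: ASSEMBLY FAILED (overlap %d, %.4f match)>\n",
                x$sample_id, x$locus_id, x$overlap, x$pct_match))
  }
  invisible(x)
}
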