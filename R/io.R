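## Text-format IO: FASTQ + secondary-peak sidecar, FASTA, TSV and Newick.

#' Write simulated reads as FASTQ plus a secondary-peak sidecar
#'
#' FASTQ (Phred+33) carries bases and quality; since FASTQ has no channel for
#' secondary-peak information, positions with a secondary fraction at or
#' above `min_fraction` (or a recorded minor base) go to a tab-separated
#' sidecar with columns `read_id`, `position`, `secondary_fraction`,
#' `second_base`. Sub-floor background fractions are not persisted: they sit
#' far below the 0.40 heterozygote threshold and would bloat the sidecar
#' with one row per base.
#'
#' @param reads a `read_set` from [simulate_reads()].
#' @param fastq_path,sidecar_path output file paths.
#' @param min_fraction noise floor below which secondary fractions are not
#'   written.
#' @return Invisibly, the two paths.
#' @export
write_reads_fastq <- function(reads, fastq_path, sidecar_path,
                              min_fraction = 0.1) {
  seqs <- Biostrings::DNAStringSet(vapply(reads, `[[`, character(1), "bases"))
  names(seqs) <- vapply(reads, `[[`, character(1), "read_id")
  qual <- Biostrings::PhredQuality(vapply(reads, function(r)
    intToUtf8(r$qv + 33L), character(1)))
  qs <- Biostrings::QualityScaledDNAStringSet(seqs, qual)
  withCallingHandlers(
    Biostrings::writeQualityScaledXStringSet(qs, fastq_path),
    warning = function(w) {
      # the writer's notice about dropped (empty) metadata columns is noise
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })

  side <- do.call(rbind, lapply(reads, function(r) {
    keep <- r$secondary_fraction >= min_fraction | !is.na(r$second_base)
    if (!any(keep)) return(NULL)
    data.frame(read_id = r$read_id, position = which(keep),
               secondary_fraction = r$secondary_fraction[keep],
               second_base = ifelse(is.na(r$second_base[keep]), ".",
                                    r$second_base[keep]))
  }))
  if (is.null(side))
    side <- data.frame(read_id = character(0), position = integer(0),
                       secondary_fraction = numeric(0),
                       second_base = character(0))
  utils::write.table(side, sidecar_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fastq_path, sidecar_path))
}

#' Read a FASTQ + sidecar pair back into a read set
#'
#' Read ids must follow the `sample|locus|i<k>|<f/r>` convention used by
#' [simulate_reads()].
#'
#' @param fastq_path,sidecar_path input file paths.
#' @return A `read_set`.
#' @export
read_reads_fastq <- function(fastq_path, sidecar_path) {
  qs <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(fastq_path),
    warning = function(w) {
      # the reader's notice about dropped (empty) metadata columns is noise
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  qv_list <- as(Biostrings::quality(qs), "IntegerList")
  side <- utils::read.delim(sidecar_path, stringsAsFactors = FALSE)
  side_by_read <- split(side, side$read_id)
  reads <- vector("list", length(qs))
  names(reads) <- names(qs)
  for (i in seq_along(qs)) {
    rid <- names(qs)[i]
    parts <- strsplit(rid, "|", fixed = TRUE)[[1]]
    stopifnot(length(parts) == 4)
    bases <- as.character(qs[[i]])
    n <- nchar(bases)
    frac <- numeric(n); second <- rep(NA_character_, n)
    s <- side_by_read[[rid]]
    if (!is.null(s)) {
      frac[s$position] <- s$secondary_fraction
      second[s$position] <- ifelse(s$second_base == ".", NA_character_,
                                   s$second_base)
    }
    reads[[i]] <- new_quality_read(
      rid, parts[1], parts[2], as.integer(sub("^i", "", parts[3])),
      if (parts[4] == "f") "forward" else "reverse",
      bases, as.integer(qv_list[[i]]), frac, second)
  }
  structure(reads, class = "read_set")
}

#' Write per-locus truth FASTA files for a panel
#'
#' One FASTA per locus holding the reference and every sample's true genotype
#' (IUPAC codes at heterozygous sites).
#'
#' @param truth a `panel_truth`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_panel_fasta <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (lc in names(truth$references)) {
    seqs <- c(stats::setNames(truth$references[lc], paste0("reference_", lc)),
              vapply(truth$sample_genotypes, `[[`, character(1), lc))
    ss <- Biostrings::BStringSet(seqs)  # BString: IUPAC het codes allowed
    path <- file.path(dir, paste0(lc, ".fasta"))
    Biostrings::writeXStringSet(ss, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write assembled consensus sequences as FASTA
#'
#' Description lines carry `het_positions=` as a comma-separated list.
#'
#' @param contigs list of accepted `locus_contig`s.
#' @param path output FASTA path.
#' @return Invisibly, the path.
#' @export
write_consensus_fasta <- function(contigs, path) {
  seqs <- vapply(contigs, `[[`, character(1), "consensus")
  names(seqs) <- vapply(contigs, function(cg)
    sprintf("%s|%s het_positions=%s", cg$sample_id, cg$locus_id,
            paste(cg$het_positions, collapse = ",")), character(1))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
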