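## End-to-end orchestration: panel -> reads -> QC -> assembly -> typing ->
## trees -> MST, with per-stage seeds derived from one master seed and an
## optional artifact directory with a content-hash manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the study's standard values as
#' defaults: QC pass thresholds TS >= 35 and CRL >= 200 bp; end-trimming with
#' a 25-base window, QV floor 25 and fewer than 3 bad bases; assembly with
#' minimum 80 percent overlap of the shorter read and 98 percent match;
#' heterozygote secondary-peak threshold 0.40; MST priority weights 10000
#' (single-SNP variants) and 10 (double-SNP variants); grouping at <= 2 SNPs.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param model a [trace_model()].
#' @param n_individuals sequenced templates per sample x locus.
#' @param ts_min,crl_min QC pass thresholds.
#' @param trim_window,trim_qv,trim_max_bad end-trimming parameters.
#' @param min_overlap_frac,min_match assembly acceptance thresholds.
#' @param het_threshold secondary-peak fraction above which a bidirectionally
#'   confirmed heterozygote is called.
#' @param combinations named list of locus-id vectors to evaluate (default:
#'   singles plus standard multi-locus combinations of the typable loci).
#' @param headline_combination locus ids of the combination used for ST
#'   assignment, trees and the MST (default: all typable loci).
#' @param bootstrap_reps parsimony bootstrap replicates.
#' @param mp_control,boot_control annealing schedules for the main search and
#'   the per-replicate bootstrap searches.
#' @param priority_weights MST priority weights `c(slv, dlv)`.
#' @param group_max_diff,group_min_size MST grouping rule.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, model = trace_model(), n_individuals = 2L,
                       ts_min = 35, crl_min = 200, trim_window = 25L,
                       trim_qv = 25L, trim_max_bad = 3L,
                       min_overlap_frac = 0.80, min_match = 0.98,
                       het_threshold = 0.40, combinations = NULL,
                       headline_combination = NULL, bootstrap_reps = 1000L,
                       mp_control = anneal_control(),
                       boot_control = anneal_control(t0 = 2, alpha = 0.90,
                                                     n_per_temp = 20,
                                                     t_min = 0.05),
                       priority_weights = c(10000, 10),
                       group_max_diff = 2L, group_min_size = 2L) {
  structure(as.list(environment()), class = "run_config")
}

default_combinations <- function(loci) {
  combos <- as.list(loci)
  names(combos) <- loci
  add <- function(lc) combos[[paste(lc, collapse = "+")]] <<- lc
  if (length(loci) >= 4) {
    add(loci[1:2]); add(loci[3:4])
    add(loci[c(1, 3, 4)]); add(loci[c(2, 3, 4)])
  }
  if (length(loci) >= 2) add(loci)
  combos
}

#' Run the full SNP-typing pipeline
#'
#' Stages: synthetic panel (unless `truth` is supplied) -> read simulation ->
#' trace QC -> bidirectional assembly per individual -> individual
#' reconciliation and SNP calling against the reference sample -> combination
#' evaluation with SNP/ST Pearson correlation -> ST assignment -> UPGMA and
#' annealed maximum-parsimony trees with column bootstrap -> priority-rule
#' MST with grouping and founder ranking. With `outdir` set, tabular and tree
#' artifacts are written along with an md5 manifest; re-running with the same
#' configuration reproduces identical artifacts.
#'
#' A sample x locus enters typing when at least one individual has an
#' accepted contig and, if both do, their SNP calls agree (discordant
#' individuals are flagged and excluded). Loci without a reference-sample
#' contig are dropped from typing (the fate of a locus that fails
#' sequencing, reflected in barcode recovery, not in the combination table).
#'
#' @param config a [run_config()].
#' @param truth optional `panel_truth` to use instead of the default
#'   [amomum_panel()].
#' @param outdir optional artifact directory.
#' @return A `pipeline_result` list; see Details for components.
#' @export
run_all <- function(config = run_config(), truth = NULL, outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("stage [", name, "] failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  seed <- config$seed

  truth <- stage("panel", truth %||% amomum_panel(stage_seed(seed, "panel")))
  reads <- stage("reads", simulate_reads(truth, config$model,
                                         stage_seed(seed, "reads"),
                                         config$n_individuals))

  ## trace QC
  qc <- stage("qc", {
    rows <- vector("list", length(reads))
    trimmed <- vector("list", length(reads))
    for (i in seq_along(reads)) {
      m <- trace_metrics(reads[[i]], config$ts_min, config$crl_min,
                         config$trim_window, config$trim_qv,
                         config$trim_max_bad)
      rows[[i]] <- m
      trimmed[[i]] <- attr(m, "trimmed")
    }
    metrics <- do.call(rbind, rows)
    names(trimmed) <- names(reads)
    list(metrics = metrics, trimmed = trimmed, report = qc_report(metrics))
  })

  ## assembly: one contig per sample x locus x individual whose two
  ## directions both pass QC
  assembly <- stage("assemble", {
    m <- qc$metrics
    key <- paste(m$sample_id, m$locus_id, m$individual, sep = "|")
    contigs <- list(); log <- list()
    for (k in unique(key)) {
      d <- m[key == k, ]
      if (nrow(d) != 2 || !all(d$passes)) next
      fwd <- qc$trimmed[[d$read_id[d$direction == "forward"]]]
      rev <- qc$trimmed[[d$read_id[d$direction == "reverse"]]]
      cg <- assemble_pair(fwd, rev, config$min_overlap_frac,
                          config$min_match, config$het_threshold)
      log[[k]] <- data.frame(sample_id = cg$sample_id,
                             locus_id = cg$locus_id,
                             individual = cg$individual,
                             offset = cg$offset %||% NA,
                             overlap = cg$overlap,
                             pct_match = round(cg$pct_match, 4),
                             accepted = cg$accepted)
      if (cg$accepted) contigs[[k]] <- cg
    }
    list(contigs = contigs,
         log = if (length(log)) do.call(rbind, c(log, make.row.names = FALSE))
               else NULL)
  })

  ## reconcile individuals, call SNPs against the reference sample's contigs
  typing <- stage("typing", {
    ref_id <- truth$reference_sample
    loci <- names(truth$references)
    get_contigs <- function(id, lc)
      Filter(Negate(is.null),
             lapply(seq_len(config$n_individuals), function(ind)
               assembly$contigs[[paste(id, lc, ind, sep = "|")]]))
    references <- list()
    for (lc in loci) {
      rc <- get_contigs(ref_id, lc)
      if (length(rc)) references[[lc]] <- rc[[1]]$consensus
    }
    typable <- names(references)

    samples <- names(truth$sample_genotypes)
    snp_calls <- stats::setNames(vector("list", length(samples)), samples)
    consensus <- stats::setNames(vector("list", length(samples)), samples)
    flagged <- list()
    for (id in samples) {
      snp_calls[[id]] <- stats::setNames(vector("list", length(typable)),
                                         typable)
      consensus[[id]] <- stats::setNames(vector("list", length(typable)),
                                         typable)
      for (lc in typable) {
        cgs <- get_contigs(id, lc)
        if (length(cgs) == 0) next
        calls <- lapply(cgs, call_snps, reference = references[[lc]])
        calls <- Filter(Negate(is.null), calls)
        if (length(calls) == 0) next
        if (length(calls) >= 2) {
          k1 <- paste(calls[[1]]$position, calls[[1]]$sample_base,
                      collapse = ";")
          k2 <- paste(calls[[2]]$position, calls[[2]]$sample_base,
                      collapse = ";")
          if (!identical(k1, k2)) {
            flagged[[length(flagged) + 1L]] <-
              data.frame(sample_id = id, locus_id = lc,
                         reason = "individuals_disagree")
            next
          }
        }
        snp_calls[[id]][[lc]] <- calls[[1]]
        consensus[[id]][[lc]] <- attr(calls[[1]], "aligned")
      }
    }
    coverage <- vapply(typable, function(lc)
      mean(vapply(samples, function(id)
        !is.null(snp_calls[[id]][[lc]]), logical(1))), numeric(1))
    list(references = references, snp_calls = snp_calls,
         consensus = consensus,
         flagged = if (length(flagged)) do.call(rbind, flagged) else NULL,
         typable = typable,
         # loci with < 90% sample coverage are excluded from the default
         # combination set (a locus that fails sequencing is dropped, not
         # padded with missing data)
         core = typable[coverage >= 0.9])
  })

  ## barcode recovery: a sample is recovered at a locus when an assembled
  ## bidirectional contig exists for at least one individual
  recovery <- stage("recovery", {
    samples <- names(truth$sample_genotypes)
    do.call(rbind, lapply(names(truth$references), function(lc) {
      rec <- vapply(samples, function(id)
        any(vapply(seq_len(config$n_individuals), function(ind)
          !is.null(assembly$contigs[[paste(id, lc, ind, sep = "|")]]),
          logical(1))), logical(1))
      data.frame(region = lc,
                 pct_recovered = round_half_up(100 * mean(rec), 1))
    }))
  })

  ## combination evaluation + headline ST assignment
  combos <- config$combinations %||% default_combinations(typing$core)
  combos <- lapply(combos, intersect, y = typing$typable)
  combos <- combos[lengths(combos) > 0]
  combo_report <- stage("combinations",
    evaluate_combinations(typing$snp_calls, typing$consensus,
                          typing$references, combos))
  pearson <- if (nrow(combo_report) >= 3 &&
                 stats::var(combo_report$n_snps) > 0 &&
                 stats::var(combo_report$n_sts) > 0)
    pearson_snp_st(combo_report) else NULL

  headline <- config$headline_combination %||% typing$core
  headline <- intersect(headline, typing$typable)
  profiles <- stage("profiles",
    snp_profile_matrix(typing$snp_calls, typing$consensus,
                       typing$references, headline))
  registry <- assign_sts(profiles)

  ## trees over ST representatives
  st_profiles <- registry$profiles
  phylo <- stage("trees", {
    D <- snp_distance_matrix(st_profiles)
    dendro <- if (nrow(D) >= 2) upgma(D) else NULL
    mp <- boot <- NULL
    if (nrow(st_profiles) >= 4 && ncol(st_profiles) >= 1) {
      mp <- mp_search(st_profiles, mode = "anneal",
                      seed = stage_seed(seed, "mp"),
                      control = config$mp_control)
      boot <- mp_bootstrap(st_profiles, mp$tree,
                           n_reps = config$bootstrap_reps,
                           seed = stage_seed(seed, "bootstrap"),
                           control = config$boot_control)
      mp$tree$node.label <- as.character(round(boot))
    }
    list(distance = D, upgma = dendro, mp = mp, bootstrap = boot)
  })

  ## priority-rule MST over STs
  mst <- stage("mst", {
    coll <- collapse_identical(profiles)
    D <- snp_distance_matrix(coll$profiles)
    g <- build_mst(coll$nodes, D, config$priority_weights)
    g <- find_groups(g, config$group_max_diff, config$group_min_size)
    g$founders <- founder_candidates(g)
    g
  })

  result <- structure(list(config = config, truth = truth,
                           qc_metrics = qc$metrics, qc_report = qc$report,
                           assembly_log = assembly$log,
                           recovery = recovery,
                           snp_calls = typing$snp_calls,
                           references = typing$references,
                           flagged = typing$flagged,
                           combo_report = combo_report, pearson = pearson,
                           profiles = profiles, registry = registry,
                           phylo = phylo, mst = mst),
                      class = "pipeline_result")
  if (!is.null(outdir)) write_artifacts(result, outdir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("SNP-typing pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  samples:", length(x$truth$sample_genotypes),
      " loci typed:", paste(names(x$references), collapse = ","), "\n")
  cat("  headline:", ncol(x$profiles), "SNP columns ->",
      length(x$registry$members), "STs\n")
  if (!is.null(x$pearson))
    cat(sprintf("  SNP/ST Pearson r = %.4f (p = %.3g)\n", x$pearson$r,
                x$pearson$p))
  if (!is.null(x$phylo$upgma))
    cat(sprintf("  UPGMA cophenetic r = %.4f\n", x$phylo$upgma$cophenetic_r))
  ng <- length(unique(stats::na.omit(x$mst$groups)))
  cat("  MST:", nrow(x$mst$nodes), "nodes,", ng, "group(s)\n")
  invisible(x)
}

write_artifacts <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv(df, p)
    paths <<- c(paths, p)
  }
  put(result$qc_report, "qc_report.tsv")
  put(result$recovery, "barcode_recovery.tsv")
  if (!is.null(result$assembly_log)) put(result$assembly_log, "assembly_log.tsv")
  put(result$combo_report, "combination_report.tsv")
  if (!is.null(result$pearson))
    put(data.frame(r = round(result$pearson$r, 4),
                   p = signif(result$pearson$p, 4)), "snp_st_pearson.tsv")
  prof <- data.frame(sample = rownames(result$profiles),
                     st = unname(result$registry$st[rownames(result$profiles)]),
                     result$profiles, check.names = FALSE)
  put(prof, "st_assignment.tsv")

  if (!is.null(result$phylo$upgma)) {
    p <- file.path(outdir, "upgma.nwk")
    ape::write.tree(result$phylo$upgma$phylo, p)
    paths <- c(paths, p)
    put(data.frame(cophenetic_r = round(result$phylo$upgma$cophenetic_r, 4)),
        "upgma_cophenetic.tsv")
  }
  if (!is.null(result$phylo$mp)) {
    p <- file.path(outdir, "mp.nwk")
    ape::write.tree(result$phylo$mp$tree, p)
    paths <- c(paths, p)
    put(data.frame(parsimony_score = result$phylo$mp$score), "mp_score.tsv")
  }
  put(result$mst$edges, "mst_edges.tsv")
  nodes <- result$mst$founders
  nodes$group <- result$mst$groups[as.character(nodes$st)]
  put(nodes, "mst_nodes.tsv")

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  manifest <- manifest[order(manifest$file), ]
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(paths)
}
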