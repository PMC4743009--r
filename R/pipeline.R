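# End-to-end orchestration: junctions -> differential usage -> event
# classification -> acceptor sequence context -> branchpoint assignment,
# with persisted stage tables and a run summary.

#' Pipeline configuration
#'
#' @param junctions path to the junction table (intron BED6 + counts TSV).
#' @param samples path to the sample sheet TSV.
#' @param genome path to the genome FASTA.
#' @param annotation path to the annotation junction BED.
#' @param catalogue optional path to an experimental branchpoint catalogue
#'   BED.
#' @param p_threshold,lfc_threshold differential selection thresholds.
#' @param distance_window acceptor-distance window for event summaries.
#' @param bp_window,bpprime_window branchpoint search windows.
#' @param intron_flank,exon_flank sequence-context window flanks.
#' @param seed integer seed recorded with the run.
#' @param outdir output directory.
#' @return list of class `bpshift_run_config` (not yet validated).
#' @export
pipeline_config <- function(junctions, samples, genome, annotation,
                            catalogue = NULL, p_threshold = 1e-5,
                            lfc_threshold = 1, distance_window = c(-50L, -1L),
                            bp_window = c(-44L, -16L),
                            bpprime_window = c(-18L, -9L),
                            intron_flank = 50L, exon_flank = 50L,
                            seed = 1L, outdir = tempfile("bpshift_run_")) {
  cfg <- list(junctions = junctions, samples = samples, genome = genome,
              annotation = annotation, catalogue = catalogue,
              p_threshold = p_threshold, lfc_threshold = lfc_threshold,
              distance_window = distance_window, bp_window = bp_window,
              bpprime_window = bpprime_window, intron_flank = intron_flank,
              exon_flank = exon_flank, seed = as.integer(seed),
              outdir = outdir)
  class(cfg) <- "bpshift_run_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Collects every problem at once rather than failing on the first; when
#' valid, returns the configuration with defaults echoed via the run log.
#'
#' @param config a [pipeline_config()].
#' @return the config, invisibly, when valid; otherwise an error listing all
#'   problems.
#' @export
validate_config <- function(config) {
  errs <- character()
  need <- c("junctions", "samples", "genome", "annotation")
  for (f in need) {
    p <- config[[f]]
    if (is.null(p) || !nzchar(p)) errs <- c(errs, paste0("missing required path: ", f))
    else if (!file.exists(p)) errs <- c(errs, paste0(f, ": no such file: ", p))
  }
  if (!is.null(config$catalogue) && !file.exists(config$catalogue))
    errs <- c(errs, paste0("catalogue: no such file: ", config$catalogue))
  if (config$p_threshold <= 0 || config$p_threshold > 1)
    errs <- c(errs, "p_threshold must lie in (0, 1]")
  if (config$lfc_threshold < 0)
    errs <- c(errs, "lfc_threshold must be >= 0")
  if (config$distance_window[1] > config$distance_window[2])
    errs <- c(errs, "distance_window must be ordered")
  for (w in c("bp_window", "bpprime_window")) {
    win <- config[[w]]
    if (length(win) != 2L || win[1] > win[2] || win[2] > -1L)
      errs <- c(errs, paste0(w, " must be two ordered negative offsets"))
  }
  if (length(errs)) stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  invisible(config)
}

run_log <- function(con, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' Stages: differential junction usage, event classification, acceptor
#' sequence context, branchpoint assignment (and catalogue overlap when a
#' catalogue is configured). Every stage table is written to
#' `config$outdir` as it completes; a stage failure aborts with the stage
#' name while earlier outputs persist. Deterministic given the inputs.
#'
#' @param config a validated [pipeline_config()].
#' @return invisible list: the run summary (selected counts, class counts,
#'   within-window count, periodicity, +1 composition per site group,
#'   branchpoint distance modes, catalogue overlap) plus stage tables.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(config$outdir, "run.log"), "w")
  on.exit(close(logcon))
  run_log(logcon, "bpshift run; seed=", config$seed,
          " p_threshold=", config$p_threshold,
          " lfc_threshold=", config$lfc_threshold,
          " bp_window=[", paste(config$bp_window, collapse = ","), "]",
          " bpprime_window=[", paste(config$bpprime_window, collapse = ","), "]")
  stage <- function(name, expr) {
    run_log(logcon, "stage ", name, " started")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  samples <- stage("load", {
    s <- read_sample_sheet(config$samples)
    junctions <- read_junction_bed(config$junctions, "intron-bed6", sample_sheet = s)
    annotation <- utils::read.delim(config$annotation, header = FALSE,
                                     stringsAsFactors = FALSE)[, 1:6]
    colnames(annotation) <- c("chrom", "start", "end", "id", "score", "strand")
    genome <- as_genome(config$genome)
    s
  })

  diff <- stage("diff", {
    d <- diff_junction_usage(junctions, samples,
                             p_threshold = config$p_threshold,
                             lfc_threshold = config$lfc_threshold)
    write_tsv_commented(cbind(d, junctions[match(d$id, junctions$id),
                                           c("chrom", "start", "end", "strand")]),
                        file.path(config$outdir, "differential.tsv"))
    d
  })
  run_log(logcon, "selected junctions: ", sum(diff$selected))

  events <- stage("classify", {
    sel <- diff$id[diff$selected]
    ev <- if (length(sel))
      build_pairs(sel, junctions, annotation,
                  sf = size_factors(count_matrix(junctions)))
    else data.frame(alt_id = character(), canonical_id = character(),
                    event_class = character(), acceptor_distance = integer(),
                    donor_distance = integer(), novel = logical())
    write_tsv_commented(ev, file.path(config$outdir, "events.tsv"))
    ev
  })
  summary_ev <- summarize_events(events, config$distance_window)
  write_tsv_commented(summary_ev$histogram,
                      file.path(config$outdir, "distance_histogram.tsv"))

  context <- stage("context", {
    alt3 <- events[events$event_class == "alt3", , drop = FALSE]
    if (nrow(alt3) == 0L) {
      NULL
    } else {
      jalt <- junctions[match(alt3$alt_id, junctions$id), ]
      jcan <- junctions[match(alt3$canonical_id, junctions$id), ]
      in_event <- junctions$id %in% c(alt3$alt_id, alt3$canonical_id)
      ann_key <- paste(annotation$chrom, annotation$start, annotation$end,
                       annotation$strand, sep = ":")
      jun_key <- paste(junctions$chrom, junctions$start, junctions$end,
                       junctions$strand, sep = ":")
      insens <- junctions[!in_event & jun_key %in% ann_key, ]
      sites <- list(agprime = acceptor_of(jalt), ag = acceptor_of(jcan),
                    insensitive = acceptor_of(insens))
      comp <- lapply(sites, function(s)
        if (nrow(s)) plus_one_composition(s, genome) else NULL)
      for (g in names(sites)) {
        if (nrow(sites[[g]]) == 0L) next
        ppm <- build_matrix(sites[[g]], genome, config$intron_flank,
                            config$exon_flank)
        write_matrix_tsv(ppm, file.path(config$outdir,
                                        paste0("ppm_", g, ".tsv")))
      }
      comp_df <- do.call(rbind, lapply(names(comp), function(g)
        if (!is.null(comp[[g]]))
          data.frame(group = g, base = names(comp[[g]]),
                     proportion = as.numeric(comp[[g]]))))
      write_tsv_commented(comp_df, file.path(config$outdir, "plus_one.tsv"))
      list(sites = sites, plus_one = comp)
    }
  })

  bp_stats <- stage("bp", {
    alt3 <- events[events$event_class == "alt3", , drop = FALSE]
    if (nrow(alt3) == 0L || is.null(context)) {
      NULL
    } else {
      asg <- lapply(seq_len(nrow(alt3)), function(i) {
        assign_branchpoints(context$sites$ag[i, ], context$sites$agprime[i, ],
                            genome, config$bp_window, config$bpprime_window)
      })
      take <- function(side, field) vapply(asg, function(a)
        if (is.null(a[[side]])) NA_real_ else a[[side]][[field]], numeric(1))
      adf <- data.frame(alt_id = alt3$alt_id,
                        bp_offset = take("bp", "offset"),
                        bp_score = take("bp", "pairing_score"),
                        bp_pos = take("bp", "genomic_pos"),
                        bpprime_offset = take("bpprime", "offset"),
                        bpprime_score = take("bpprime", "pairing_score"),
                        bpprime_pos = take("bpprime", "genomic_pos"))
      write_tsv_commented(adf, file.path(config$outdir, "branchpoints.tsv"))
      # insensitive acceptors scored with the canonical window
      insens_sites <- context$sites$insensitive
      ins_off <- if (nrow(insens_sites)) vapply(seq_len(nrow(insens_sites)), function(i) {
        a <- assign_branchpoints(insens_sites[i, ], insens_sites[i, ], genome,
                                 config$bp_window, config$bpprime_window)
        if (is.null(a$bp)) NA_real_ else a$bp$offset
      }, numeric(1)) else numeric()
      dist <- bp_distance_distribution(list(agprime = adf$bpprime_offset,
                                            ag = adf$bp_offset,
                                            insensitive = ins_off))
      overlap <- NULL
      if (!is.null(config$catalogue)) {
        cat <- read_branchpoint_catalogue(config$catalogue)
        overlap <- overlap_with_catalogue(context$sites$agprime, cat)
      }
      list(assignments = adf, distances = dist, overlap = overlap)
    }
  })

  summary <- list(
    n_junctions = nrow(junctions),
    n_selected = sum(diff$selected),
    class_counts = summary_ev$class_counts,
    n_within_window = summary_ev$n_within_window,
    periodicity = summary_ev$periodicity,
    novel_fraction = summary_ev$novel_fraction,
    plus_one = if (!is.null(context)) context$plus_one else NULL,
    bp_distance_modes = if (!is.null(bp_stats))
      lapply(bp_stats$distances, `[[`, "mode") else NULL,
    catalogue_overlap = if (!is.null(bp_stats)) bp_stats$overlap else NULL,
    seed = config$seed)
  sm <- c(n_junctions = summary$n_junctions, n_selected = summary$n_selected,
          summary$class_counts, n_within_window = summary$n_within_window,
          periodicity_fraction = if (!is.null(summary$periodicity))
            summary$periodicity$fraction else NA_real_)
  write_tsv_commented(data.frame(key = names(sm), value = unname(sm)),
                      file.path(config$outdir, "summary.tsv"))
  run_log(logcon, "run complete")
  invisible(list(summary = summary, differential = diff, events = events,
                 context = context, branchpoints = bp_stats))
}
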