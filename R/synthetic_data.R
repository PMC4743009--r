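# Seeded synthetic cohorts carrying the SF3B1-mutant splice signature:
# for each "sensitive" acceptor an alternative AG' is planted 3-50 nt
# upstream of the canonical AG (concentrated in -24..-12 with a
# multiple-of-3 enrichment), with a +1-G-depleted AG' context, a canonical
# branchpoint adenosine ~25 nt upstream of AG and a stronger alternative
# branchpoint 11-14 nt upstream of AG', and junction read counts that shift
# from AG to AG' in proportion to each sample's mutant transcript fraction.

LOCUS_LEN <- 600L
EXON1_OFF <- 50L   # exon1 [50,150), intron [150,450), exon2 [450,550)
INTRON_OFF <- 150L
INTRON_END_OFF <- 450L

#' Default AG' offset weights
#'
#' Probability weights over AG' acceptor distances (negative = upstream of
#' the canonical AG). Mass is concentrated on -24..-12 and offsets that are
#' multiples of 3 are enriched by a factor `rho`, reproducing the 3-nt
#' periodicity of the alternative acceptors. Offsets -1 and -2 are excluded
#' (they would overlap the canonical AG dinucleotide).
#'
#' @param rho multiple-of-3 enrichment factor (default 3).
#' @param support integer offsets (default -50..-3).
#' @param core offsets carrying the bulk of the mass (default -24..-12).
#' @param bg_weight relative weight of non-core offsets (default 0.02).
#' @return named numeric vector of probabilities summing to 1.
#' @export
default_distance_weights <- function(rho = 3, support = -50:-3,
                                     core = -24:-12, bg_weight = 0.02) {
  w <- ifelse(support %in% core, 1, bg_weight) *
    ifelse(support %% 3L == 0L, rho, 1)
  stats::setNames(w / sum(w), support)
}

#' Synthetic cohort configuration
#'
#' @param n_mut,n_wt sample counts per group (defaults 16 and 56, the cohort
#'   sizes of the tumour series being emulated).
#' @param n_acceptors total acceptor loci (default 200).
#' @param sensitive_fraction proportion of acceptors given an AG' (default
#'   0.3; the real-data rate is far lower, ~0.5% of junctions, but a desk
#'   cohort needs enough planted events to measure recovery).
#' @param shift_psi proportion of a fully mutant transcriptome's canonical
#'   reads redirected to AG' (effect size psi, default 0.5).
#' @param mutant_fractions per-MUT-sample transcript mutant fraction in
#'   \[0,1\]; default 0.5 for every MUT sample (heterozygous hotspot
#'   mutation). Cell-line-like values would be 0.30 or 0.14.
#' @param baseline_leak AG' usage proportion in WT samples (default 0.02;
#'   the faint AG' usage detectable in wild-type lines).
#' @param nb_mean expected canonical junction count (default 200).
#' @param nb_dispersion NB dispersion alpha, variance = mu + alpha mu^2
#'   (default 0.05).
#' @param distance_weights named probability vector over AG' offsets; see
#'   [default_distance_weights()].
#' @param agprime_plus_one_G probability that the base after AG' is G
#'   (default 0.20).
#' @param ag_plus_one_G same for the canonical AG (default 0.50).
#' @param bp_offset_AG canonical branchpoint A offset relative to AG
#'   (default -25).
#' @param bpprime_offset_range BP' A offset range relative to AG'
#'   (default -14..-11).
#' @param ppt_pyrimidine polypyrimidine-tract C/T probability over the
#'   -20..-3 intronic window (default 0.85).
#' @param seed integer seed; every random draw is keyed on
#'   (seed, acceptor, sample).
#' @return a list of class `bpshift_config`.
#' @export
synthetic_config <- function(n_mut = 16L, n_wt = 56L, n_acceptors = 200L,
                             sensitive_fraction = 0.30, shift_psi = 0.5,
                             mutant_fractions = rep(0.5, n_mut),
                             baseline_leak = 0.02, nb_mean = 200,
                             nb_dispersion = 0.05,
                             distance_weights = default_distance_weights(),
                             agprime_plus_one_G = 0.20, ag_plus_one_G = 0.50,
                             bp_offset_AG = -25L,
                             bpprime_offset_range = c(-14L, -11L),
                             ppt_pyrimidine = 0.85, seed = 1L) {
  props <- c(sensitive_fraction, shift_psi, baseline_leak,
             agprime_plus_one_G, ag_plus_one_G, ppt_pyrimidine, mutant_fractions)
  if (any(props < 0 | props > 1)) stop("all proportions must lie in [0,1]")
  stopifnot(n_mut >= 1, n_wt >= 1)
  if (length(mutant_fractions) != n_mut)
    stop("mutant_fractions must have one entry per MUT sample")
  if (abs(sum(distance_weights) - 1) > 1e-8)
    stop("distance_weights must sum to 1")
  offs <- as.integer(names(distance_weights))
  if (anyNA(offs) || any(offs >= -2L))
    stop("distance_weights support must be named integer offsets <= -3")
  cfg <- list(n_mut = as.integer(n_mut), n_wt = as.integer(n_wt),
              n_acceptors = as.integer(n_acceptors),
              sensitive_fraction = sensitive_fraction, shift_psi = shift_psi,
              mutant_fractions = mutant_fractions,
              baseline_leak = baseline_leak, nb_mean = nb_mean,
              nb_dispersion = nb_dispersion,
              distance_weights = distance_weights,
              agprime_plus_one_G = agprime_plus_one_G,
              ag_plus_one_G = ag_plus_one_G,
              bp_offset_AG = as.integer(bp_offset_AG),
              bpprime_offset_range = as.integer(bpprime_offset_range),
              ppt_pyrimidine = ppt_pyrimidine, seed = as.integer(seed))
  class(cfg) <- "bpshift_config"
  cfg
}

# Deterministic 31-bit seed keyed on (seed, acceptor index, sample index),
# so adding samples or acceptors never perturbs existing draws.
rng_key <- function(seed, acceptor = 0L, sample = 0L) {
  as.integer((as.double(seed) * 1000003 + as.double(acceptor) * 7919 +
                as.double(sample) * 104729) %% 2147483647)
}

# Map a transcript-relative acceptor position (-1 = last intronic base,
# +1 = first exonic base, no 0) to a 1-based index in the locus-local
# sequence. `anchor_local` = local index of the first exonic base.
tx_local <- function(pos, strand, anchor_local) {
  step <- ifelse(pos > 0L, pos - 1L, pos)
  if (strand == "+") anchor_local + step else anchor_local - step
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Write transcript-sense characters at transcript offsets into a locus-local
# character vector (complemented for minus strand).
plant <- function(loc, offsets, chars, strand, anchor_local) {
  idx <- tx_local(offsets, strand, anchor_local)
  if (strand == "-") chars <- unname(COMPLEMENT[chars])
  loc[idx] <- chars
  loc
}

BP_HEPTAMER <- "CACTAAC"    # canonical BP, pairing score 5.0
BPP_HEPTAMER <- "TACTAAC"   # alternative BP', perfect U2 pairing, score 6.0

draw_plus_one <- function(p_G) {
  if (stats::runif(1) < p_G) "G" else sample(c("A", "C", "T"), 1L)
}

# Plant one locus; returns list(loc = chars, d, bpq) or NULL if geometry
# infeasible for the drawn offsets (a planted branch A or AG was destroyed).
plant_locus_once <- function(loc, strand, anchor_local, sensitive, cfg) {
  ppt_off <- -20:-3
  pyr <- stats::runif(length(ppt_off)) < cfg$ppt_pyrimidine
  ppt <- ifelse(pyr, sample(c("C", "T"), length(ppt_off), replace = TRUE),
                sample(c("A", "G"), length(ppt_off), replace = TRUE))
  loc <- plant(loc, ppt_off, ppt, strand, anchor_local)
  bpA <- cfg$bp_offset_AG
  loc <- plant(loc, (bpA - 5L):(bpA + 1L), strsplit(BP_HEPTAMER, "")[[1]],
               strand, anchor_local)
  d <- NA_integer_; bpq <- NA_integer_
  if (sensitive) {
    offs <- as.integer(names(cfg$distance_weights))
    d <- sample(offs, 1L, prob = cfg$distance_weights)
    bpq <- sample(seq(cfg$bpprime_offset_range[1], cfg$bpprime_offset_range[2]), 1L)
    bppA <- d + bpq
    loc <- plant(loc, (bppA - 5L):(bppA + 1L), strsplit(BPP_HEPTAMER, "")[[1]],
                 strand, anchor_local)
    loc <- plant(loc, c(d - 2L, d - 1L), c("A", "G"), strand, anchor_local)
    loc <- plant(loc, d, draw_plus_one(cfg$agprime_plus_one_G), strand, anchor_local)
  }
  loc <- plant(loc, c(-2L, -1L), c("A", "G"), strand, anchor_local)
  loc <- plant(loc, 1L, draw_plus_one(cfg$ag_plus_one_G), strand, anchor_local)
  # audit: planted branch adenosines and dinucleotides must have survived
  tx_read <- function(p) {
    ch <- loc[tx_local(p, strand, anchor_local)]
    if (strand == "-") ch <- unname(COMPLEMENT[ch])
    ch
  }
  if (tx_read(bpA) != "A") return(NULL)
  if (sensitive) {
    if (tx_read(d + bpq) != "A") return(NULL)
    if (!identical(tx_read(c(d - 2L, d - 1L)), c("A", "G"))) return(NULL)
  }
  list(loc = loc, d = d, bpq = bpq)
}

#' Generate a synthetic cohort
#'
#' Builds a genome, a junction count table, the annotation (canonical)
#' junction list, a sample sheet and the ground truth, all deterministic in
#' `config$seed`. Acceptor loci alternate between plus and minus strand.
#' For each sensitive acceptor and sample, a Binomial share
#' `baseline_leak + shift_psi * mutant_fraction` of the NB-drawn locus reads
#' is redirected from the canonical AG junction to the AG' junction;
#' insensitive acceptors never emit AG' reads.
#'
#' @param config a [synthetic_config()].
#' @param outdir optional directory; when given, FASTA / junction TSV /
#'   annotation BED / sample sheet / ground-truth TSV are written there.
#' @param max_retries geometry resampling bound per acceptor (default 100).
#' @return list with `genome` (DNAStringSet), `junctions`, `annotation`,
#'   `samples`, `truth`, `config`, and `paths` when `outdir` was given.
#' @export
generate_cohort <- function(config, outdir = NULL, max_retries = 100L) {
  stopifnot(inherits(config, "bpshift_config"))
  n <- config$n_acceptors
  nsamp <- config$n_mut + config$n_wt
  samples <- data.frame(
    sample = c(sprintf("M%02d", seq_len(config$n_mut)),
               sprintf("W%02d", seq_len(config$n_wt))),
    group = c(rep("MUT", config$n_mut), rep("WT", config$n_wt)),
    mutant_fraction = c(config$mutant_fractions, rep(0, config$n_wt)),
    stringsAsFactors = FALSE)

  set.seed(rng_key(config$seed, 0L, 0L))
  n_sens <- round(n * config$sensitive_fraction)
  sens_idx <- sort(sample.int(n, n_sens))
  genome_chars <- character(n)

  truth <- vector("list", n)
  jrows <- vector("list", n)
  counts <- vector("list", n)
  for (i in seq_len(n)) {
    strand <- if (i %% 2L == 1L) "+" else "-"
    base <- (i - 1L) * LOCUS_LEN  # genomic 0-based offset of the locus
    sensitive <- i %in% sens_idx
    set.seed(rng_key(config$seed, i, 0L))
    loc0 <- sample(c("A", "C", "G", "T"), LOCUS_LEN, replace = TRUE)
    anchor_local <- if (strand == "+") INTRON_END_OFF + 1L else INTRON_OFF
    planted <- NULL
    for (try in seq_len(max_retries)) {
      planted <- plant_locus_once(loc0, strand, anchor_local, sensitive, config)
      if (!is.null(planted)) break
    }
    if (is.null(planted))
      stop("acceptor ", i, ": no feasible AG'/BP' geometry after ",
           max_retries, " retries")
    genome_chars[i] <- paste(planted$loc, collapse = "")
    d <- planted$d
    acc_id <- sprintf("a%04d", i)
    can_id <- paste0("jcan_", acc_id)
    alt_id <- paste0("jalt_", acc_id)
    can_anchor <- if (strand == "+") base + INTRON_END_OFF else base + INTRON_OFF - 1L
    # per-sample counts keyed on (seed, acceptor, sample)
    tot <- agp <- numeric(nsamp)
    for (s in seq_len(nsamp)) {
      set.seed(rng_key(config$seed, i, s))
      tot[s] <- stats::rnbinom(1, mu = config$nb_mean, size = 1 / config$nb_dispersion)
      if (sensitive) {
        p <- config$baseline_leak + config$shift_psi * samples$mutant_fraction[s]
        agp[s] <- stats::rbinom(1, tot[s], p)
      }
    }
    can_row <- data.frame(id = can_id, chrom = "chrS",
                          start = base + INTRON_OFF, end = base + INTRON_END_OFF,
                          strand = strand, stringsAsFactors = FALSE)
    if (sensitive) {
      alt_row <- can_row
      alt_row$id <- alt_id
      if (strand == "+") alt_row$end <- alt_row$end + d else alt_row$start <- alt_row$start - d
      jrows[[i]] <- rbind(can_row, alt_row)
      counts[[i]] <- rbind(tot - agp, agp)
    } else {
      jrows[[i]] <- can_row
      counts[[i]] <- matrix(tot, nrow = 1)
    }
    site <- list(strand = strand, anchor = can_anchor)
    truth[[i]] <- data.frame(
      acceptor = acc_id, chrom = "chrS", strand = strand,
      can_anchor = can_anchor, can_junction = can_id,
      sensitive = sensitive,
      alt_junction = if (sensitive) alt_id else NA_character_,
      agprime_offset = d,
      agprime_anchor = if (sensitive) genomic_position(site, d) else NA_integer_,
      bp_offset = config$bp_offset_AG,
      bp_pos = genomic_position(site, config$bp_offset_AG),
      bpprime_offset = planted$bpq,
      bpprime_pos = if (sensitive) genomic_position(site, d + planted$bpq) else NA_integer_,
      agprime_A_pos = if (sensitive) genomic_position(site, d - 2L) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  jdf <- do.call(rbind, jrows)
  cm <- do.call(rbind, counts)
  colnames(cm) <- samples$sample
  junctions <- junction_table(jdf$id, jdf$chrom, jdf$start, jdf$end, jdf$strand, cm)
  annotation <- junctions[startsWith(junctions$id, "jcan_"),
                          c("id", "chrom", "start", "end", "strand")]
  genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- "chrS"
  out <- list(genome = genome, junctions = junctions, annotation = annotation,
              samples = samples, truth = truth, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      genome = file.path(outdir, "genome.fa"),
      junctions = file.path(outdir, "junctions.tsv"),
      annotation = file.path(outdir, "annotation.bed"),
      samples = file.path(outdir, "samples.tsv"),
      truth = file.path(outdir, "truth.tsv"))
    Biostrings::writeXStringSet(genome, paths$genome)
    write_junction_bed(junctions, paths$junctions)
    ann <- data.frame(chrom = annotation$chrom, start = annotation$start,
                      end = annotation$end, id = annotation$id, score = 0L,
                      strand = annotation$strand)
    utils::write.table(ann, paths$annotation, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    write_sample_sheet(samples, paths$samples)
    write_tsv_commented(truth, paths$truth)
    out$paths <- paths
  }
  out
}

#' Analytic expected AG' usage for a sample
#'
#' The expectation of the AG' read share at a sensitive acceptor:
#' `baseline_leak + shift_psi * mutant_fraction` (WT samples have mutant
#' fraction 0 and sit at the baseline leak).
#'
#' @param config a [synthetic_config()].
#' @param sample sample id (as generated: `M01`.., `W01`..).
#' @return expected AG' usage proportion.
#' @export
expected_agprime_usage <- function(config, sample) {
  stopifnot(inherits(config, "bpshift_config"))
  ids <- c(sprintf("M%02d", seq_len(config$n_mut)),
           sprintf("W%02d", seq_len(config$n_wt)))
  i <- match(sample, ids)
  if (anyNA(i)) stop("unknown sample: ", paste(sample[is.na(i)], collapse = ", "))
  f <- c(config$mutant_fractions, rep(0, config$n_wt))[i]
  config$baseline_leak + config$shift_psi * f
}
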