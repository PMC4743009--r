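# Sequence context around splice acceptors: position probability matrices,
# +1 nucleotide composition, polypyrimidine content, and per-position
# composition contrasts between site groups.

BASES <- c("A", "C", "G", "T")

window_positions <- function(intron_flank, exon_flank) {
  c(seq(-intron_flank, -1L), seq_len(exon_flank))
}

extract_windows <- function(sites, genome, intron_flank, exon_flank) {
  genome <- as_genome(genome)
  seqs <- character(nrow(sites))
  ok <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- tryCatch(extract_window(genome, sites[i, ], intron_flank, exon_flank),
                  error = function(e) NA_character_)
    if (is.na(s)) next
    seqs[i] <- s; ok[i] <- TRUE
  }
  if (any(!ok))
    warning(sum(!ok), " site(s) skipped: window not extractable")
  seqs[ok]
}

#' Position probability matrix around acceptor sites
#'
#' Extracts `intron_flank + exon_flank` nt windows (transcript-oriented, AG
#' dinucleotide at intronic positions -2/-1) around each site and tabulates
#' per-position base probabilities and information content
#' (2 - Shannon entropy, bits). No pseudocount by default; `pseudocount`
#' adds a Laplace count per base for logo rendering of small site sets.
#'
#' @param sites data.frame with `chrom`, `strand`, `anchor`
#'   (see [acceptor_of()]).
#' @param genome DNAStringSet or FASTA path.
#' @param intron_flank,exon_flank window flanks (defaults 50/50).
#' @param pseudocount per-base Laplace count (default 0).
#' @return list of class `bpshift_ppm`: `prob` (position x base), `ic`
#'   (bits), `positions` (signed, no 0), `n_sites`.
#' @export
build_matrix <- function(sites, genome, intron_flank = 50L, exon_flank = 50L,
                         pseudocount = 0) {
  if (nrow(sites) == 0L) stop("no sites")
  seqs <- extract_windows(sites, genome, intron_flank, exon_flank)
  if (length(seqs) == 0L) stop("no extractable sites")
  chars <- do.call(rbind, strsplit(seqs, ""))
  counts <- apply(chars, 2, function(col) {
    tabulate(factor(col, levels = BASES), nbins = 4L)
  })
  counts <- t(counts) + pseudocount          # position x base
  colnames(counts) <- BASES
  prob <- counts / rowSums(counts)
  ent <- apply(prob, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  structure(list(prob = prob, ic = 2 - ent,
                 positions = window_positions(intron_flank, exon_flank),
                 n_sites = length(seqs)),
            class = "bpshift_ppm")
}

#' Composition of the first exonic base (+1)
#'
#' @param sites acceptor site data.frame.
#' @param genome DNAStringSet or FASTA path.
#' @return named proportions over A, C, G, T (sum 1).
#' @export
plus_one_composition <- function(sites, genome) {
  if (nrow(sites) == 0L) stop("no sites")
  seqs <- extract_windows(sites, genome, intron_flank = 0L, exon_flank = 1L)
  if (length(seqs) == 0L) stop("no extractable sites")
  tab <- tabulate(factor(substr(seqs, 1L, 1L), levels = BASES), nbins = 4L)
  stats::setNames(tab / sum(tab), BASES)
}

#' Pyrimidine fraction of an intronic window
#'
#' Fraction of C/T bases over transcript positions `window` (default
#' -20..-3, the polypyrimidine tract upstream of the AG).
#'
#' @param x either a transcript-oriented window string whose last character
#'   is position -1 (the G of the AG), or an acceptor site data.frame (with
#'   `genome` supplied).
#' @param window inclusive position window, both ends negative.
#' @param genome required when `x` is a site data.frame.
#' @return proportion in \[0,1\] (vector when `x` has several sites).
#' @export
pyrimidine_fraction <- function(x, window = c(-20L, -3L), genome = NULL) {
  stopifnot(window[1] <= window[2], window[2] <= -1L)
  if (is.character(x)) {
    n <- nchar(x)
    if (n < -window[1]) stop("window outside the provided sequence")
    sub <- substr(x, n + window[1] + 1L, n + window[2] + 1L)
    ch <- strsplit(sub, "")[[1]]
    return(mean(ch %in% c("C", "T")))
  }
  seqs <- extract_windows(x, genome, intron_flank = -window[1], exon_flank = 0L)
  vapply(seqs, function(s) {
    ch <- strsplit(substr(s, 1L, window[2] - window[1] + 1L), "")[[1]]
    mean(ch %in% c("C", "T"))
  }, numeric(1), USE.NAMES = FALSE)
}

base_at_position <- function(sites, genome, position) {
  stopifnot(position != 0L)
  iflank <- if (position < 0L) -position else 0L
  eflank <- if (position > 0L) position else 0L
  seqs <- extract_windows(sites, genome, iflank, eflank)
  substr(seqs, 1L, 1L)
}

#' Per-position composition contrast between two site groups
#'
#' Pearson chi-square (no continuity correction) on the 2 x 4 table of base
#' counts at `position`, or the 2 x 2 table when `collapse` names a target
#' base (that base versus the rest). A warning is attached when more than
#' 20% of expected cells fall below 5.
#'
#' @param sitesA,sitesB acceptor site data.frames.
#' @param genome DNAStringSet or FASTA path.
#' @param position transcript position (e.g. +1 for the first exonic base).
#' @param collapse optional single base, e.g. `"G"`.
#' @return list with `statistic`, `p_value`, `table`.
#' @export
composition_contrast <- function(sitesA, sitesB, genome, position = 1L,
                                 collapse = NULL) {
  if (nrow(sitesA) == 0L || nrow(sitesB) == 0L) stop("both groups must be non-empty")
  bA <- base_at_position(sitesA, genome, position)
  bB <- base_at_position(sitesB, genome, position)
  if (!is.null(collapse)) {
    tab <- rbind(A = c(sum(bA == collapse), sum(bA != collapse)),
                 B = c(sum(bB == collapse), sum(bB != collapse)))
    colnames(tab) <- c(collapse, paste0("not_", collapse))
  } else {
    tab <- rbind(A = tabulate(factor(bA, levels = BASES), 4L),
                 B = tabulate(factor(bB, levels = BASES), 4L))
    colnames(tab) <- BASES
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expected <- ht$expected
  if (mean(expected < 5) > 0.2)
    warning("more than 20% of expected cell counts are below 5")
  list(statistic = unname(ht$statistic), p_value = ht$p.value, table = tab)
}

#' Export a position probability matrix as TSV
#' @param ppm a `bpshift_ppm` from [build_matrix()].
#' @param path output path.
#' @export
write_matrix_tsv <- function(ppm, path) {
  df <- data.frame(position = ppm$positions, ppm$prob, ic = ppm$ic)
  write_tsv_commented(df, path)
}
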