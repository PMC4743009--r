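# Branchpoint candidates scored by U2 snRNA base-pairing potential.
#
# The branch adenosine is bulged out of the U2/intron duplex, so a
# branchpoint heptamer (consensus UACUAAC, branch A at position 6) pairs at
# its six non-bulged positions 1-5 and 7 with the U2 branch-recognition
# region GUAGUA (read 3'->5', i.e. partners A,U,G,A,U,G for heptamer
# positions 1,2,3,4,5,7). Watson-Crick pairs score 1, G.U wobbles 0.5.

U2_PARTNERS <- c("A", "U", "G", "A", "U", "G")  # heptamer pos 1..5, 7

pair_value <- function(base, partner, wobble = 0.5) {
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  if (identical(unname(wc[base]), partner)) return(1)
  if ((base == "G" && partner == "U") || (base == "U" && partner == "G"))
    return(wobble)
  0
}

#' U2 snRNA base-pairing score of a branchpoint heptamer
#'
#' Sum over the six non-bulged heptamer positions of the pairing value with
#' the U2 branch-recognition region: Watson-Crick pair 1.0, G.U wobble
#' `wobble` (default 0.5), otherwise 0. The consensus UACUAAC scores 6.0.
#' T and U spellings are equivalent. Position 6 must be the branch A.
#'
#' @param heptamer character vector of 7-letter strings over ACGT/ACGU.
#' @param wobble G.U wobble weight (default 0.5).
#' @return numeric scores in \[0, 6\].
#' @export
pairing_score <- function(heptamer, wobble = 0.5) {
  vapply(heptamer, function(h) {
    h <- chartr("acgut", "ACGUT", h)
    h <- chartr("T", "U", h)
    if (nchar(h) != 7L) stop("heptamer must have length 7: ", h)
    ch <- strsplit(h, "")[[1]]
    if (ch[6] != "A") stop("heptamer position 6 must be the branch A: ", h)
    sum(mapply(pair_value, ch[c(1:5, 7)], U2_PARTNERS,
               MoreArgs = list(wobble = wobble)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Enumerate branchpoint candidates upstream of a 3' splice site
#'
#' One candidate per adenosine with offset in `[-max_dist, -min_dist]`
#' (offset -1 = last intronic base). The heptamer spans positions A-5..A+1
#' in transcript orientation; the polypyrimidine score is the C/T fraction
#' between the branch A (exclusive) and the 3'ss.
#'
#' @param sequence transcript-oriented intronic sequence whose last
#'   character is position -1; must cover at least `max_dist + 6` bases
#'   (shorter sequences restrict the search window).
#' @param min_dist minimum A-to-3'ss distance (default 6).
#' @param max_dist maximum distance (default 100).
#' @param wobble G.U wobble weight for [pairing_score()].
#' @return data.frame with `offset`, `heptamer`, `pairing_score`,
#'   `ppt_score`; zero rows when no adenosine lies in the window.
#' @export
enumerate_candidates <- function(sequence, min_dist = 6L, max_dist = 100L,
                                 wobble = 0.5) {
  stopifnot(min_dist >= 1L, max_dist >= min_dist)
  s <- chartr("acgut", "ACGUT", sequence)
  s <- chartr("U", "T", s)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  empty <- data.frame(offset = integer(), heptamer = character(),
                      pairing_score = numeric(), ppt_score = numeric(),
                      stringsAsFactors = FALSE)
  offsets <- -(min_dist:min(max_dist, n - 5L))  # need 5 bases 5' of the A
  offsets <- offsets[ch[n + offsets + 1L] == "A"]
  if (length(offsets) == 0L) return(empty)
  rows <- lapply(sort(offsets), function(o) {
    i <- n + o + 1L                     # index of the branch A
    hept <- paste(ch[(i - 5L):(i + 1L)], collapse = "")
    between <- if (i + 1L <= n) ch[(i + 1L):n] else character()
    data.frame(offset = o, heptamer = hept,
               pairing_score = pairing_score(hept, wobble),
               ppt_score = if (length(between)) mean(between %in% c("C", "T")) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Rank candidates: higher pairing score, then higher ppt, then closer to the
# prior centre, then more upstream.
pick_candidate <- function(cand, prior_centre) {
  if (nrow(cand) == 0L) return(NULL)
  ord <- order(-cand$pairing_score, -cand$ppt_score,
               abs(cand$offset - prior_centre), cand$offset)
  cand[ord[1L], , drop = FALSE]
}

#' Assign BP and BP' for an alt-3' event
#'
#' The canonical branchpoint (BP) is the best-ranked candidate within
#' `bp_window` of the canonical AG, the alternative branchpoint (BP') the
#' best within `bpprime_window` of the AG'. Ranking: highest pairing score;
#' ties by higher polypyrimidine score, then proximity to the window's
#' prior centre (-25 for BP, the bpprime window midpoint for BP'), then the
#' more upstream candidate. Sides without a candidate are flagged
#' unassigned.
#'
#' @param can_site,alt_site one-row acceptor site data.frames (`chrom`,
#'   `strand`, `anchor`) for the canonical AG and the AG'.
#' @param genome DNAStringSet or FASTA path.
#' @param bp_window BP search window relative to AG (default c(-44, -16)).
#' @param bpprime_window BP' window relative to AG' (default c(-18, -9)).
#' @param wobble G.U wobble weight.
#' @details Candidates on the AG side that sit at BP'-valid spacing of the
#'   AG' (their offset relative to the AG' falls inside `bpprime_window`)
#'   are excluded from the BP search: a branchpoint at working distance of
#'   the upstream acceptor serves that acceptor, not the downstream AG.
#' @return list with `bp`, `bpprime` (one-row candidate data.frames with a
#'   `genomic_pos` column, or NULL), and flags `bp_unassigned`,
#'   `bpprime_unassigned`.
#' @export
assign_branchpoints <- function(can_site, alt_site, genome,
                                bp_window = c(-44L, -16L),
                                bpprime_window = c(-18L, -9L),
                                wobble = 0.5) {
  genome <- as_genome(genome)
  one_side <- function(site, window, prior_centre, exclude = integer()) {
    iflank <- -window[1] + 6L
    seq <- extract_window(genome, site, intron_flank = iflank, exon_flank = 0L)
    cand <- enumerate_candidates(seq, min_dist = -window[2], max_dist = -window[1],
                                 wobble = wobble)
    if (length(exclude) && nrow(cand)) {
      gpos <- vapply(cand$offset, function(o) genomic_position(site, o), integer(1))
      cand <- cand[!gpos %in% exclude, , drop = FALSE]
    }
    best <- pick_candidate(cand, prior_centre)
    if (is.null(best)) return(NULL)
    best$genomic_pos <- genomic_position(site, best$offset)
    best
  }
  # genomic positions at BP'-valid spacing of the AG' are reserved for it
  reserved <- vapply(seq(bpprime_window[1], bpprime_window[2]),
                     function(o) genomic_position(alt_site, o), integer(1))
  bp <- one_side(can_site, bp_window, -25L, exclude = reserved)
  bpp <- one_side(alt_site, bpprime_window, mean(bpprime_window))
  list(bp = bp, bpprime = bpp,
       bp_unassigned = is.null(bp), bpprime_unassigned = is.null(bpp))
}

#' Branchpoint-to-3'ss distance histograms
#'
#' Integer histograms of |branch A to 3'ss| distances for any number of
#' assignment groups (e.g. AG'-side, AG-side, insensitive), with the modal
#' distance per group.
#'
#' @param offsets named list of integer offset vectors (negative,
#'   transcript orientation).
#' @return list per group: `histogram` (data.frame distance/count) and
#'   `mode` (smallest modal distance, NA when empty).
#' @export
bp_distance_distribution <- function(offsets) {
  lapply(offsets, function(o) {
    o <- o[!is.na(o)]
    if (length(o) == 0L)
      return(list(histogram = data.frame(distance = integer(), count = integer()),
                  mode = NA_integer_))
    d <- abs(o)
    tab <- table(d)
    hist <- data.frame(distance = as.integer(names(tab)),
                       count = as.integer(tab))
    list(histogram = hist,
         mode = hist$distance[which.max(hist$count)])
  })
}

#' Overlap of AG' adenosines with an experimental branchpoint catalogue
#'
#' A catalogue branchpoint "coincides" with an AG' when its adenosine sits
#' at exactly the genomic position of the A of the AG' dinucleotide. Also
#' reports, among catalogue branchpoints upstream of a non-coincident AG'
#' (within `upstream_limit` nt in transcript orientation), the mean
#' upstream offset.
#'
#' @param agprime_sites data.frame with `chrom`, `strand`, `anchor` (AG'
#'   acceptor sites); the A of the dinucleotide is position -2.
#' @param catalogue data.frame from [read_branchpoint_catalogue()].
#' @param upstream_limit how far upstream to look for nearby catalogue
#'   branchpoints (default 50).
#' @return list: `n_total` (AG' with any catalogue BP at/upstream within the
#'   limit), `n_coincident`, `fraction_coincident`, `mean_upstream_offset`.
#' @export
overlap_with_catalogue <- function(agprime_sites, catalogue,
                                   upstream_limit = 50L) {
  if (nrow(catalogue) == 0L || nrow(agprime_sites) == 0L)
    return(list(n_total = 0L, n_coincident = 0L,
                fraction_coincident = NA_real_,
                mean_upstream_offset = NA_real_))
  n_co <- 0L; n_tot <- 0L; ups <- integer()
  for (i in seq_len(nrow(agprime_sites))) {
    site <- agprime_sites[i, ]
    a_pos <- genomic_position(site, -2L)  # the A of the AG' dinucleotide
    cat_chr <- catalogue[catalogue$chrom == site$chrom &
                           (catalogue$strand == "*" |
                              catalogue$strand == site$strand), , drop = FALSE]
    if (nrow(cat_chr) == 0L) next
    # catalogue positions as transcript offsets of the branch A rel. the AG'
    offs <- if (site$strand == "+") cat_chr$pos - site$anchor
            else site$anchor - cat_chr$pos
    offs <- offs[offs < 0L & offs >= -upstream_limit]
    if (length(offs) == 0L) next
    n_tot <- n_tot + 1L
    if (any(offs == -2L)) n_co <- n_co + 1L
    else ups <- c(ups, max(offs) - (-2L))  # nearest BP, nt upstream of the AG' A
  }
  list(n_total = n_tot, n_coincident = n_co,
       fraction_coincident = if (n_tot > 0L) n_co / n_tot else NA_real_,
       mean_upstream_offset = if (length(ups)) mean(abs(ups)) else NA_real_)
}

#' Per-position heptamer composition contrast across branchpoint groups
#'
#' Chi-square tests on the G x 4 base-count table at each heptamer position
#' (G = number of groups, typically canonical BP, alternative BP',
#' insensitive BP). Positions are reported both in heptamer indexing
#' (branch A at 6) and in an A-at-+5 indexing (position = heptamer - 1)
#' used in some descriptions of the motif.
#'
#' @param ... two or more named character vectors of heptamers.
#' @return data.frame with `position`, `position_A5`, `statistic`,
#'   `p_value`.
#' @export
bp_motif_contrast <- function(...) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]])) groups <- groups[[1]]
  if (length(groups) < 2L) stop("need at least two heptamer groups")
  if (any(lengths(groups) == 0L)) stop("all heptamer groups must be non-empty")
  mats <- lapply(groups, function(h) {
    h <- chartr("acgut", "ACGUT", h); h <- chartr("U", "T", h)
    do.call(rbind, strsplit(h, ""))
  })
  rows <- lapply(1:7, function(pos) {
    tab <- do.call(rbind, lapply(mats, function(m) {
      tabulate(factor(m[, pos], levels = BASES), 4L)
    }))
    colnames(tab) <- BASES
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2L) {
      stat <- 0; p <- 1  # same single base in every group
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat <- unname(ht$statistic); p <- ht$p.value
      if (!is.finite(stat)) { stat <- 0; p <- 1 }
    }
    data.frame(position = pos, position_A5 = pos - 1L,
               statistic = stat, p_value = p)
  })
  do.call(rbind, rows)
}
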