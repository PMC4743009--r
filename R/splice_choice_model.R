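# Mechanistic model of AG versus AG' choice.
#
# Two recognition regimes compete. U2 snRNP carrying wild-type SF3B1 is
# promiscuous about branchpoint strength and the acceptor choice is driven
# by U2AF affinity (polypyrimidine tract plus the AG-G preference of
# U2AF1). U2 snRNP carrying mutant SF3B1 has a stringent branchpoint
# requirement with a short BP-to-AG' spacing, and the acceptor choice is
# driven by the U2 pairing score of the branchpoint serving each acceptor.
# A branchpoint is claimed by the nearest downstream acceptor whose spacing
# falls inside the regime's window (AG-scanning exclusivity). Scores are
# converted to usage fractions by a softmax with temperature tau, and a
# sample with mutant transcript fraction f mixes the two regimes linearly.

#' U2AF affinity of an acceptor
#'
#' `ppt * (1 + g_bonus)` when the first exonic base is G (AG-G is part of
#' the U2AF1 recognition motif), `ppt` otherwise.
#'
#' @param ppt polypyrimidine fraction upstream of the acceptor.
#' @param plus_one first exonic base.
#' @param g_bonus bonus factor for +1 = G (default 0.5).
#' @return non-negative affinity.
#' @export
u2af_affinity <- function(ppt, plus_one, g_bonus = 0.5) {
  ppt * (1 + g_bonus * (plus_one == "G"))
}

#' A splice construct
#'
#' Wraps a transcript-sense sequence together with the index of the first
#' exonic base of its canonical (reference) acceptor. Positions are
#' addressed relative to that acceptor (-1 = last intronic base, +1 = first
#' exonic base).
#'
#' @param sequence character string (ACGT).
#' @param ag_index 1-based index of the first exonic base.
#' @return object of class `bpshift_construct`.
#' @export
splice_construct_new <- function(sequence, ag_index) {
  sequence <- toupper(sequence)
  stopifnot(ag_index >= 3L, ag_index <= nchar(sequence))
  x <- list(sequence = sequence, ag_index = as.integer(ag_index))
  class(x) <- "bpshift_construct"
  if (construct_base(x, -2L) != "A" || construct_base(x, -1L) != "G")
    stop("reference acceptor must carry an AG dinucleotide at -2/-1")
  x
}

construct_index <- function(construct, pos) {
  if (any(pos == 0L)) stop("position 0 does not exist")
  construct$ag_index + ifelse(pos > 0L, pos - 1L, pos)
}

construct_base <- function(construct, pos) {
  i <- construct_index(construct, pos)
  substring(construct$sequence, i, i)
}

#' Apply point mutations to a construct
#'
#' Mutations are given as strings like `"-17A>G"`: position relative to the
#' canonical AG, reference base, substituted base. The reference base must
#' match the sequence. Acceptor and branchpoint candidate sets are
#' re-derived from the mutated sequence by the model, so a destroyed AG
#' dinucleotide drops its acceptor and a newly created AG adds one.
#'
#' @param construct a `bpshift_construct`.
#' @param mutations character vector of mutation specs.
#' @return the mutated construct.
#' @export
apply_mutations <- function(construct, mutations) {
  ch <- strsplit(construct$sequence, "")[[1]]
  for (m in mutations) {
    p <- regmatches(m, regexec("^(-?[0-9]+)([ACGT])>([ACGT])$", m))[[1]]
    if (length(p) != 4L) stop("malformed mutation spec: ", m)
    pos <- as.integer(p[2])
    i <- construct_index(construct, pos)
    if (i < 1L || i > length(ch)) stop("mutation position outside sequence: ", m)
    if (ch[i] != p[3])
      stop("reference mismatch at position ", pos, ": sequence has ", ch[i],
           ", spec says ", p[3])
    ch[i] <- p[4]
  }
  out <- construct
  out$sequence <- paste(ch, collapse = "")
  out
}

# Acceptor candidates: the reference AG (offset 0) plus every intronic AG
# dinucleotide whose implied first exonic base lies in `search`.
find_acceptors <- function(construct, search = c(-50L, -3L)) {
  ch <- strsplit(construct$sequence, "")[[1]]
  offs <- integer()
  if (construct_base(construct, -2L) == "A" && construct_base(construct, -1L) == "G")
    offs <- 0L
  for (q in seq(search[1], search[2])) {
    i2 <- construct_index(construct, q - 2L)
    i1 <- construct_index(construct, q - 1L)
    if (i2 >= 1L && i1 <= length(ch) && ch[i2] == "A" && ch[i1] == "G")
      offs <- c(offs, q)
  }
  sort(unique(offs))
}

# All branchpoint candidates of the construct as offsets relative to the
# reference AG (branch A with a full heptamer inside the sequence).
construct_bp_candidates <- function(construct, wobble = 0.5) {
  ch <- strsplit(construct$sequence, "")[[1]]
  a_pos <- which(ch == "A")
  rows <- lapply(a_pos, function(i) {
    if (i - 5L < 1L || i + 1L > length(ch)) return(NULL)
    off <- i - construct$ag_index
    if (off >= -2L) return(NULL)  # offsets of intronic branch As only
    hept <- paste(ch[(i - 5L):(i + 1L)], collapse = "")
    data.frame(offset = off, heptamer = hept,
               pairing_score = pairing_score(hept, wobble),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(offset = integer(), heptamer = character(),
                      pairing_score = numeric()))
  do.call(rbind, rows)
}

# Spacing (acceptor - branch A) in nt; valid when inside `window`
# (offsets relative to the acceptor). A branchpoint is claimed by the first
# acceptor downstream of it at or beyond the window's minimum spacing; the
# maximum still applies to that acceptor.
claim_branchpoints <- function(bp, acceptor_offsets, window) {
  min_sp <- -window[2]; max_sp <- -window[1]
  owner <- rep(NA_integer_, nrow(bp))
  for (i in seq_len(nrow(bp))) {
    downstream <- acceptor_offsets[acceptor_offsets > bp$offset[i]]
    sp <- downstream - bp$offset[i]
    cand <- which(sp >= min_sp)
    if (!length(cand)) next
    first <- cand[which.min(sp[cand])]
    if (sp[first] <= max_sp) owner[i] <- downstream[first]
  }
  owner
}

#' Predict AG and AG' usage from sequence architecture
#'
#' Derives acceptor candidates (AG dinucleotides), branchpoint candidates
#' and their per-regime assignment from the construct sequence, then
#' computes usage fractions: the wild-type regime softmax-weights usable
#' acceptors by U2AF affinity, the mutant regime by the pairing score of
#' the best branchpoint claimed by each acceptor at mutant-valid spacing;
#' an acceptor is usable in a regime when it owns a branchpoint with
#' pairing score at least `s_floor` in that regime's window. Usage at
#' mutant transcript fraction f is `(1-f) * WT + f * MUT`.
#'
#' @param construct a `bpshift_construct` (see [splice_construct_new()],
#'   [tmem14c_like_construct()]).
#' @param f_mut numeric vector of mutant transcript fractions in \[0,1\].
#' @param tau softmax temperature (default 0.1).
#' @param s_floor minimum usable branchpoint pairing score (default 3).
#' @param g_bonus U2AF1 +1-G bonus (default 0.5).
#' @param wt_window branchpoint spacing window (offsets relative to the
#'   acceptor) in the wild-type regime (default c(-44, -16)).
#' @param mut_window spacing window in the mutant regime (default
#'   c(-18, -9), the 11-14 nt BP'-to-AG' distance with margin).
#' @param ppt_window polypyrimidine window relative to each acceptor.
#' @param wobble G.U wobble weight.
#' @param acceptor_search window in which AG dinucleotides are taken as
#'   alternative acceptors (default c(-50, -3)).
#' @return list of class `bpshift_prediction`: `acceptors` (data.frame with
#'   offsets, +1 base, ppt, U2AF affinity, per-regime best branchpoint and
#'   usability), `usage` (acceptors x f matrix), `usage_wt`, `usage_mut`,
#'   `agprime_index` (alternative over canonical usage per f; Inf when the
#'   canonical acceptor is unused, NA when no alternative exists), `f_mut`.
#' @export
predict_usage <- function(construct, f_mut, tau = 0.1, s_floor = 3,
                          g_bonus = 0.5, wt_window = c(-44L, -16L),
                          mut_window = c(-18L, -9L), ppt_window = c(-20L, -3L),
                          wobble = 0.5, acceptor_search = c(-50L, -3L)) {
  stopifnot(all(f_mut >= 0 & f_mut <= 1))
  acc <- find_acceptors(construct, acceptor_search)
  if (!length(acc)) stop("construct has no acceptor candidate")
  ch <- strsplit(construct$sequence, "")[[1]]
  ppt <- vapply(acc, function(q) {
    pos <- seq(q + ppt_window[1], q + ppt_window[2])
    pos <- pos[pos <= -1L | q > 0L]  # all intronic for upstream acceptors
    b <- ch[construct_index(construct, pos)]
    mean(b %in% c("C", "T"))
  }, numeric(1))
  plus_one <- vapply(acc, function(q) {
    construct_base(construct, if (q == 0L) 1L else q)
  }, character(1))
  aff <- u2af_affinity(ppt, plus_one, g_bonus)
  bp <- construct_bp_candidates(construct, wobble)
  best_by_mode <- function(window) {
    owner <- claim_branchpoints(bp, acc, window)
    vapply(acc, function(q) {
      sc <- bp$pairing_score[!is.na(owner) & owner == q]
      if (length(sc)) max(sc) else NA_real_
    }, numeric(1))
  }
  best_wt <- best_by_mode(wt_window)
  best_mut <- best_by_mode(mut_window)
  usable_wt <- !is.na(best_wt) & best_wt >= s_floor
  usable_mut <- !is.na(best_mut) & best_mut >= s_floor
  if (!any(usable_wt) && !any(usable_mut))
    stop("no acceptor with a usable branchpoint in either regime")
  softmax <- function(score, usable) {
    w <- rep(0, length(score))
    if (!any(usable)) {          # regime falls back to the other regime's set
      usable <- if (any(usable_wt)) usable_wt else usable_mut
    }
    s <- score[usable]
    s[is.na(s)] <- -Inf
    w[usable] <- exp((s - max(s, 0)) / tau)
    if (sum(w) == 0) w[usable] <- 1
    w / sum(w)
  }
  u_wt <- softmax(aff, usable_wt)
  u_mut <- softmax(best_mut, usable_mut)
  usage <- outer(u_wt, 1 - f_mut) + outer(u_mut, f_mut)
  rownames(usage) <- as.character(acc)
  colnames(usage) <- as.character(f_mut)
  alt <- acc != 0L
  idx <- vapply(seq_along(f_mut), function(k) {
    agp <- sum(usage[alt, k]); ag <- usage[!alt, k][1]
    if (!any(alt)) return(NA_real_)
    if (ag == 0) return(if (agp > 0) Inf else NA_real_)
    agp / ag
  }, numeric(1))
  structure(list(
    acceptors = data.frame(offset = acc, plus_one = plus_one, ppt = ppt,
                           u2af_affinity = aff, best_bp_wt = best_wt,
                           best_bp_mut = best_mut, usable_wt = usable_wt,
                           usable_mut = usable_mut, stringsAsFactors = FALSE),
    usage = usage, usage_wt = u_wt, usage_mut = u_mut,
    agprime_index = idx, f_mut = f_mut), class = "bpshift_prediction")
}

#' AG'/AG index
#'
#' Ratio of alternative to canonical acceptor abundance (counts or usage
#' fractions). `NA` (undefined) when the canonical abundance is 0 and the
#' alternative is positive, and when both are 0; 0 when only the
#' alternative is 0.
#'
#' @param agprime,ag non-negative abundances (vectorised).
#' @return numeric vector; the `undefined` attribute flags NA entries.
#' @export
agprime_index <- function(agprime, ag) {
  stopifnot(all(agprime >= 0), all(ag >= 0), length(agprime) == length(ag))
  out <- ifelse(ag == 0, NA_real_, agprime / ag)
  attr(out, "undefined") <- ag == 0
  out
}

#' Synthetic TMEM14C-like minigene construct
#'
#' A 70-nt construct reproducing the architecture dissected by branchpoint
#' mutagenesis: canonical AG with +1 G and a strong polypyrimidine tract; a
#' cryptic AG' 16 nt upstream with +1 C, sitting inside the canonical
#' tract; a suboptimal canonical branchpoint (pairing score 4.0) with its
#' branch A only 6 nt from the AG; and a stronger alternative branchpoint
#' (score 5.5) 13 nt upstream of the AG' with a second adenosine adjacent
#' to the branch A. All other positions carry no adenosine, so the planted
#' elements are the only branchpoint candidates.
#'
#' @return a `bpshift_construct`.
#' @export
tmem14c_like_construct <- function() {
  seq <- paste0(
    "TCTTCCTTCTCTTCCTTCTCTC",  # -60..-39 background, pyrimidine-only
    "CCCC",                    # -38..-35
    "TACTAAT",                 # -34..-28  BP' heptamer, branch A at -29, score 5.5
    "GGGG",                    # -27..-24
    "CCCCC",                   # -23..-19
    "AG",                      # -18..-17  AG' dinucleotide (acceptor at -16)
    "CCC",                     # -16..-14  (+1 of AG' = C)
    "A",                       # -13       neutral adenosine (weak heptamer)
    "T",                       # -12
    "TCCTCAC",                 # -11..-5   BP heptamer, branch A at -6, score 4.0
    "TC",                      # -4..-3
    "AG",                      # -2..-1    canonical AG
    "G",                       # +1
    "TCGTCCTTG")               # +2..+10 exon
  splice_construct_new(seq, ag_index = 61L)
}

#' Mutation series for the TMEM14C-like construct
#'
#' Named list of point-mutation sets mirroring the minigene mutagenesis:
#' destroy BP' (both adjacent adenosines), destroy the canonical BP,
#' destroy the AG' dinucleotide, a neutral adenosine change, turn the +1 of
#' AG' into G, make the canonical BP a perfect U2 match, and swap the BP
#' and BP' heptamers.
#'
#' @return named list of character vectors of mutation specs.
#' @export
construct_mutation_series <- function() {
  list(
    bpprime_destroy = c("-30A>G", "-29A>G"),
    bp_destroy = "-6A>G",
    agprime_destroy = "-18A>G",
    neutral = "-13A>G",
    agprime_plus_one_G = "-16C>G",
    bp_perfect = c("-10C>A", "-7C>A"),
    swap = c("-10C>A", "-7C>A", "-5C>T", "-33A>C", "-30A>C", "-28T>C"))
}

# windows used for the TMEM14C-like construct: its canonical branchpoint
# sits 6 nt from the AG, so the spacing minima are relaxed to 5 nt.
TMEM14C_WT_WINDOW <- c(-44L, -5L)
TMEM14C_MUT_WINDOW <- c(-18L, -5L)

label_outcome <- function(u_lo, u_hi, b_lo, b_hi, is_new, abolish_eps,
                          unchanged_tol) {
  if (is_new) return("new_site")
  if (is.na(b_hi)) return("used")
  if (b_hi > 0.05 && u_hi < abolish_eps) return("abolished")
  if (u_lo > b_lo + 0.01 && u_hi > b_hi + 0.01) return("strengthened")
  if (abs(u_lo - b_lo) <= unchanged_tol * max(b_lo, 0.01) &&
      abs(u_hi - b_hi) <= unchanged_tol * max(b_hi, 0.01)) return("unchanged")
  "used"
}

#' In-silico mutagenesis truth table
#'
#' Applies each mutation set of `series` to `construct`, predicts usage at
#' the wild-type-like and mutant-like transcript fractions, and labels each
#' acceptor's outcome relative to the unmutated construct: `abolished`
#' (usage below `abolish_eps` at the mutant-like fraction where the
#' baseline was used), `strengthened` (usage increased at both fractions),
#' `unchanged` (within `unchanged_tol` at both), `new_site` (acceptor
#' absent from the baseline), else `used`.
#'
#' @param construct a `bpshift_construct`
#'   (default [tmem14c_like_construct()]).
#' @param series named list of mutation spec vectors
#'   (default [construct_mutation_series()]).
#' @param f_pair wild-type-like and mutant-like mutant transcript fractions
#'   (default c(0, 0.3)).
#' @param wt_window,mut_window spacing windows (defaults relaxed to the
#'   construct's 6-nt BP spacing).
#' @param abolish_eps,unchanged_tol labelling thresholds.
#' @param ... further arguments to [predict_usage()].
#' @return data.frame: one row per (mutant, acceptor offset) with usage at
#'   both fractions, the baseline usage, and the outcome label.
#' @export
mutagenesis_truth_table <- function(construct = tmem14c_like_construct(),
                                    series = construct_mutation_series(),
                                    f_pair = c(0, 0.3),
                                    wt_window = TMEM14C_WT_WINDOW,
                                    mut_window = TMEM14C_MUT_WINDOW,
                                    abolish_eps = 0.02,
                                    unchanged_tol = 0.05, ...) {
  stopifnot(length(f_pair) == 2L)
  base <- predict_usage(construct, f_pair, wt_window = wt_window,
                        mut_window = mut_window, ...)
  base_acc <- base$acceptors$offset
  rows <- lapply(names(series), function(nm) {
    mut <- apply_mutations(construct, series[[nm]])
    pr <- predict_usage(mut, f_pair, wt_window = wt_window,
                        mut_window = mut_window, ...)
    acc <- pr$acceptors$offset
    # acceptors present in baseline but destroyed by the mutation: usage 0
    all_acc <- sort(unique(c(acc, base_acc)))
    u <- function(p, which_f) {
      v <- stats::setNames(rep(0, length(all_acc)), all_acc)
      v[as.character(p$acceptors$offset)] <- p$usage[, which_f]
      v
    }
    u_lo <- u(pr, 1L); u_hi <- u(pr, 2L)
    b_lo <- b_hi <- stats::setNames(rep(NA_real_, length(all_acc)), all_acc)
    b_lo[as.character(base_acc)] <- base$usage[, 1L]
    b_hi[as.character(base_acc)] <- base$usage[, 2L]
    data.frame(mutant = nm, acceptor_offset = all_acc,
               usage_f_lo = unname(u_lo), usage_f_hi = unname(u_hi),
               baseline_f_lo = unname(b_lo), baseline_f_hi = unname(b_hi),
               outcome = vapply(seq_along(all_acc), function(i) {
                 label_outcome(u_lo[i], u_hi[i], b_lo[i], b_hi[i],
                               is_new = !(all_acc[i] %in% base_acc),
                               abolish_eps, unchanged_tol)
               }, character(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- base
  out
}
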