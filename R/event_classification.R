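# Pairing of differential junctions with their canonical partners,
# alt-3'/alt-5' classification, signed acceptor distances, the 3-nt
# periodicity statistic and novelty flags.

donor_key <- function(junctions) {
  d <- donor_of(junctions)
  paste(d$chrom, d$strand, d$anchor, sep = ":")
}

acceptor_key <- function(junctions) {
  a <- acceptor_of(junctions)
  paste(a$chrom, a$strand, a$anchor, sep = ":")
}

#' Pair differential junctions with canonical partners and classify events
#'
#' For each differential junction, partner junctions are sought among the
#' annotated/expressed set sharing its donor (alternative 3'ss candidate)
#' and sharing its acceptor (alternative 5'ss candidate). Exactly one side
#' pairing gives the class (`alt3` or `alt5`); both or neither give
#' `ambiguous_both`. The canonical partner on a side is the annotated
#' junction with the highest mean count among candidates (ties broken by
#' smaller absolute distance). A junction is `novel` when absent from the
#' annotation list.
#'
#' @param diff_ids ids of the differential junctions.
#' @param junctions the full junction table (must contain `diff_ids`).
#' @param annotation data.frame of annotated junctions with `chrom`,
#'   `start`, `end`, `strand` (ids optional): the canonical-partner pool and
#'   the novelty reference.
#' @param sf optional size factors for the count columns; mean normalised
#'   counts rank canonical candidates.
#' @return data.frame with one row per differential junction: `alt_id`,
#'   `canonical_id`, `event_class`, `acceptor_distance`, `donor_distance`,
#'   `novel`.
#' @export
build_pairs <- function(diff_ids, junctions, annotation, sf = NULL) {
  if (!all(diff_ids %in% junctions$id))
    stop("differential junction(s) absent from the full junction set: ",
         paste(setdiff(diff_ids, junctions$id), collapse = ", "))
  cc <- count_columns(junctions)
  mean_count <- if (length(cc)) {
    m <- count_matrix(junctions)
    if (is.null(sf)) sf <- rep(1, ncol(m))
    rowMeans(sweep(m, 2, sf, "/"))
  } else rep(0, nrow(junctions))
  ann_key_coord <- paste(annotation$chrom, annotation$start, annotation$end,
                         annotation$strand, sep = ":")
  jun_key_coord <- paste(junctions$chrom, junctions$start, junctions$end,
                         junctions$strand, sep = ":")
  annotated <- jun_key_coord %in% ann_key_coord
  dk <- donor_key(junctions)
  ak <- acceptor_key(junctions)

  pick_partner <- function(cand, dist) {
    if (length(cand) == 0L) return(NA_integer_)
    best <- which(mean_count[cand] == max(mean_count[cand]))
    if (length(best) > 1L) best <- best[which.min(abs(dist[best]))]
    cand[best[1L]]
  }

  rows <- lapply(diff_ids, function(id) {
    j <- match(id, junctions$id)
    same_donor <- setdiff(which(dk == dk[j] & annotated), j)
    same_acceptor <- setdiff(which(ak == ak[j] & annotated), j)
    # a partner sharing both ends would be the same intron; exclude
    same_donor <- setdiff(same_donor, which(jun_key_coord == jun_key_coord[j]))
    same_acceptor <- setdiff(same_acceptor, which(jun_key_coord == jun_key_coord[j]))
    acc_dist_all <- if (junctions$strand[j] == "+")
      junctions$end[j] - junctions$end[same_donor]
    else junctions$start[same_donor] - junctions$start[j]
    don_dist_all <- if (junctions$strand[j] == "+")
      junctions$start[j] - junctions$start[same_acceptor]
    else junctions$end[same_acceptor] - junctions$end[j]
    has3 <- length(same_donor) > 0L
    has5 <- length(same_acceptor) > 0L
    cls <- if (has3 && !has5) "alt3" else if (has5 && !has3) "alt5" else "ambiguous_both"
    can <- NA_integer_; accd <- NA_integer_; dond <- NA_integer_
    if (cls == "alt3") {
      can <- pick_partner(same_donor, acc_dist_all)
      accd <- if (junctions$strand[j] == "+") junctions$end[j] - junctions$end[can]
              else junctions$start[can] - junctions$start[j]
    } else if (cls == "alt5") {
      can <- pick_partner(same_acceptor, don_dist_all)
      dond <- if (junctions$strand[j] == "+") junctions$start[j] - junctions$start[can]
              else junctions$end[can] - junctions$end[j]
    }
    data.frame(alt_id = id,
               canonical_id = if (is.na(can)) NA_character_ else junctions$id[can],
               event_class = cls,
               acceptor_distance = as.integer(accd),
               donor_distance = as.integer(dond),
               novel = !annotated[j], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Signed acceptor distance of an alt-3' event
#'
#' Transcript-oriented distance between the alternative and canonical 3'ss:
#' negative means the alternative acceptor (AG') lies upstream of the
#' canonical AG. Plus strand: `alt_end - can_end`; minus strand:
#' `can_start - alt_start`.
#'
#' @param events data.frame from [build_pairs()].
#' @return integer vector of distances for the alt3 rows.
#' @export
acceptor_distance <- function(events) {
  if (any(events$event_class != "alt3"))
    stop("acceptor_distance is defined for alt3 events only")
  events$acceptor_distance
}

#' Multiple-of-3 periodicity of acceptor distances
#'
#' Among distances within `window`, the fraction that are multiples of 3,
#' with a one-sided exact binomial test against the null success probability
#' 1/3 (no periodicity).
#'
#' @param distances integer acceptor distances.
#' @param window inclusive window, default c(-50, -1).
#' @return list with `n`, `n_inframe`, `fraction`, `p_value`; `NULL` if no
#'   distance falls in the window.
#' @export
periodicity_stat <- function(distances, window = c(-50L, -1L)) {
  d <- distances[!is.na(distances) & distances >= window[1] & distances <= window[2]]
  if (length(d) == 0L) return(NULL)
  k <- sum(d %% 3L == 0L)
  ht <- stats::binom.test(k, length(d), p = 1 / 3, alternative = "greater")
  list(n = length(d), n_inframe = k, fraction = k / length(d),
       p_value = ht$p.value)
}

#' Summarise classified events
#'
#' Class counts, the number of alt3 events with the alternative acceptor
#' within `window` of the canonical one, a 1-nt distance histogram, the
#' multiple-of-3 fraction and the novel fraction.
#'
#' @param events data.frame from [build_pairs()].
#' @param window acceptor-distance window, default c(-50, -1).
#' @return list with `class_counts`, `n_within_window`, `histogram`
#'   (data.frame distance/count), `periodicity`, `novel_fraction`, `n`.
#' @export
summarize_events <- function(events, window = c(-50L, -1L)) {
  classes <- c("alt3", "alt5", "ambiguous_both")
  if (nrow(events) == 0L)
    return(list(class_counts = stats::setNames(rep(0L, 3), classes),
                n_within_window = 0L,
                histogram = data.frame(distance = integer(), count = integer()),
                periodicity = NULL, novel_fraction = NA_real_, n = 0L))
  cc <- table(factor(events$event_class, levels = classes))
  d <- events$acceptor_distance[events$event_class == "alt3"]
  d <- d[!is.na(d)]
  inw <- d[d >= window[1] & d <= window[2]]
  hist <- as.data.frame(table(distance = inw), stringsAsFactors = FALSE)
  hist$distance <- as.integer(hist$distance)
  colnames(hist) <- c("distance", "count")
  list(class_counts = stats::setNames(as.integer(cc), classes),
       n_within_window = length(inw),
       histogram = hist,
       periodicity = periodicity_stat(d, window),
       novel_fraction = mean(events$novel),
       n = nrow(events))
}
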