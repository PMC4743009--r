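#' @keywords internal
#' @importFrom methods is
"_PACKAGE"

# All coordinates in this package are 0-based half-open (BED native).
# Transcript-relative positions use the splice-acceptor convention:
# -1 = last intronic base (the G of the AG dinucleotide), +1 = first exonic
# base; there is no position 0.

VALID_STRANDS <- c("+", "-")

#' Construct a junction table
#'
#' A junction is one intron observed in RNA-seq: genomic interval, strand and
#' one read count per sample. The table is a plain `data.frame` with columns
#' `id`, `chrom`, `start`, `end`, `strand` followed by one integer column per
#' sample (named by sample id).
#'
#' @param id character vector of unique junction ids.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open intron coordinates (`start < end`).
#' @param strand `"+"` or `"-"`.
#' @param counts matrix (junctions x samples) of non-negative read counts,
#'   with column names giving sample ids, or `NULL` for a coordinate-only
#'   table.
#' @return a `data.frame` of class `bpshift_junctions`.
#' @export
junction_table <- function(id, chrom, start, end, strand, counts = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (anyDuplicated(id)) stop("junction ids must be unique")
  if (any(start >= end)) stop("intron_start must be < intron_end")
  if (!all(strand %in% VALID_STRANDS)) stop("strand must be '+' or '-'")
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   start = start, end = end, strand = as.character(strand),
                   stringsAsFactors = FALSE)
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (nrow(counts) != nrow(df)) stop("counts rows must match junctions")
    if (is.null(colnames(counts))) stop("counts must carry sample ids as column names")
    if (any(counts < 0)) stop("counts must be non-negative")
    df <- cbind(df, as.data.frame(counts))
  }
  class(df) <- c("bpshift_junctions", "data.frame")
  df
}

#' Sample id columns of a junction table
#' @param junctions a junction table.
#' @return character vector of count column names (possibly empty).
#' @export
count_columns <- function(junctions) {
  setdiff(colnames(junctions), c("id", "chrom", "start", "end", "strand"))
}

#' Extract the count matrix from a junction table
#' @param junctions a junction table with count columns.
#' @return integer matrix, junctions x samples, rownames = junction ids.
#' @export
count_matrix <- function(junctions) {
  cc <- count_columns(junctions)
  if (length(cc) == 0L) stop("junction table carries no count columns")
  m <- as.matrix(junctions[, cc, drop = FALSE])
  rownames(m) <- junctions$id
  storage.mode(m) <- "double"
  m
}

#' Read a sample sheet
#'
#' Tab-separated file with columns `sample`, `group` (MUT or WT) and
#' optionally `mutant_fraction` (transcript-level mutant allele fraction in
#' \[0,1\], e.g. 0.30 for Mel202-like, 0.14 for a K666T knock-in line).
#'
#' @param path file path.
#' @return `data.frame` with columns `sample`, `group`, `mutant_fraction`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample sheet data.frame
#' @param df data.frame with `sample`, `group`, optional `mutant_fraction`.
#' @return the validated data.frame (mutant_fraction filled in: WT samples 0).
#' @export
validate_sample_sheet <- function(df) {
  if (!all(c("sample", "group") %in% colnames(df)))
    stop("sample sheet needs columns 'sample' and 'group'")
  if (anyDuplicated(df$sample)) stop("sample ids must be unique")
  if (!all(df$group %in% c("MUT", "WT")))
    stop("group labels must be 'MUT' or 'WT'")
  if (is.null(df$mutant_fraction))
    df$mutant_fraction <- ifelse(df$group == "MUT", NA_real_, 0)
  bad <- !is.na(df$mutant_fraction) &
    (df$mutant_fraction < 0 | df$mutant_fraction > 1)
  if (any(bad)) stop("mutant_fraction must lie in [0,1]")
  df
}

#' Write a sample sheet
#' @param sheet sample sheet data.frame.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parse_error <- function(path, lineno, msg) {
  stop(sprintf("%s: line %d: %s", path, lineno, msg), call. = FALSE)
}

#' Read splice junctions from BED
#'
#' Two dialects are supported. `"tophat-bed12"` is the TopHat `junctions.bed`
#' layout: each record spans the two anchoring exon fragments and exactly two
#' blocks, so the intron is `[chromStart + blockSize1, chromEnd - blockSize2)`;
#' the score column is taken as the read count. `"intron-bed6"` carries the
#' intron coordinates directly; the file may be a wide TSV with one count
#' column per sample after the six BED fields (a header line starting with
#' `#` names them).
#'
#' @param path input file.
#' @param dialect `"tophat-bed12"` or `"intron-bed6"`.
#' @param sample_sheet optional sample sheet; when given, count columns are
#'   checked (and ordered) against it. For single-count files the count is
#'   stored under the column name `count`.
#' @param sample for `tophat-bed12`, the sample id to store the score column
#'   under (default `"count"`).
#' @return a junction table (see [junction_table()]).
#' @export
read_junction_bed <- function(path, dialect = c("intron-bed6", "tophat-bed12"),
                              sample_sheet = NULL, sample = "count") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  header <- NULL
  is_comment <- grepl("^(#|track\\b)", lines)
  if (any(is_comment)) {
    hdr <- lines[is_comment]
    hdr <- hdr[grepl("^#", hdr)]
    if (length(hdr)) header <- strsplit(sub("^#\\s*", "", hdr[1]), "\t")[[1]]
  }
  keep <- which(!is_comment & nzchar(lines))
  if (length(keep) == 0L)
    return(junction_table(character(), character(), integer(), integer(), character(),
                          counts = NULL))
  fields <- strsplit(lines[keep], "\t")

  if (dialect == "tophat-bed12") {
    rows <- vector("list", length(keep))
    warn_blocks <- 0L
    for (k in seq_along(keep)) {
      f <- fields[[k]]
      if (length(f) < 12) parse_error(path, keep[k], "BED12 record has < 12 columns")
      chromStart <- suppressWarnings(as.integer(f[2]))
      chromEnd <- suppressWarnings(as.integer(f[3]))
      score <- suppressWarnings(as.numeric(f[5]))
      if (is.na(chromStart) || is.na(chromEnd) || is.na(score))
        parse_error(path, keep[k], "non-numeric coordinate or score")
      if (!f[6] %in% VALID_STRANDS)
        parse_error(path, keep[k], paste0("unknown strand '", f[6], "'"))
      nblocks <- suppressWarnings(as.integer(f[10]))
      sizes <- suppressWarnings(as.integer(strsplit(f[11], ",")[[1]]))
      if (is.na(nblocks) || nblocks != 2L || length(sizes) != 2L) {
        warn_blocks <- warn_blocks + 1L
        next
      }
      rows[[k]] <- data.frame(id = f[4], chrom = f[1],
                              start = chromStart + sizes[1],
                              end = chromEnd - sizes[2],
                              strand = f[6], n = score,
                              stringsAsFactors = FALSE)
    }
    if (warn_blocks > 0L)
      warning(sprintf("%d BED12 record(s) without exactly two blocks rejected", warn_blocks))
    rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(rows))
      return(junction_table(character(), character(), integer(), integer(), character()))
    counts <- matrix(rows$n, ncol = 1, dimnames = list(NULL, sample))
    return(junction_table(rows$id, rows$chrom, rows$start, rows$end, rows$strand, counts))
  }

  # intron-bed6 (+ optional wide count columns)
  ncol_max <- max(lengths(fields))
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    f <- fields[[k]]
    if (length(f) < 6) parse_error(path, keep[k], "intron BED6 record has < 6 columns")
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) parse_error(path, keep[k], "non-integer coordinates")
    if (!f[6] %in% VALID_STRANDS)
      parse_error(path, keep[k], paste0("unknown strand '", f[6], "'"))
    cnt <- suppressWarnings(as.numeric(f[-(1:6)]))
    if (length(cnt) && anyNA(cnt)) parse_error(path, keep[k], "non-numeric count")
    score <- suppressWarnings(as.numeric(f[5]))
    rows[[k]] <- list(id = f[4], chrom = f[1], start = start, end = end,
                      strand = f[6], score = score, counts = cnt)
  }
  id <- vapply(rows, `[[`, character(1), "id")
  chrom <- vapply(rows, `[[`, character(1), "chrom")
  start <- vapply(rows, `[[`, integer(1), "start")
  end <- vapply(rows, `[[`, integer(1), "end")
  strand <- vapply(rows, `[[`, character(1), "strand")
  ncnt <- lengths(lapply(rows, `[[`, "counts"))
  if (length(unique(ncnt)) > 1) stop(path, ": inconsistent number of count columns")
  if (ncnt[1] > 0L) {
    counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
    cn <- if (!is.null(header) && length(header) == 6 + ncnt[1]) header[-(1:6)]
          else paste0("S", seq_len(ncnt[1]))
    colnames(counts) <- cn
  } else {
    # score column doubles as the single count when per-sample counts absent
    counts <- matrix(vapply(rows, `[[`, numeric(1), "score"), ncol = 1,
                     dimnames = list(NULL, sample))
  }
  if (!is.null(sample_sheet)) {
    missing <- setdiff(sample_sheet$sample, colnames(counts))
    if (length(missing))
      stop("count columns missing for sample(s): ", paste(missing, collapse = ", "))
    counts <- counts[, sample_sheet$sample, drop = FALSE]
  }
  junction_table(id, chrom, start, end, strand, counts)
}

#' Write a junction table as intron BED6 + count columns
#'
#' The canonical on-disk form: six BED fields (score = total count) followed
#' by one column per sample, with a `#`-prefixed header line naming all
#' columns. [read_junction_bed()] with `dialect = "intron-bed6"` reads it
#' back losslessly.
#'
#' @param junctions junction table.
#' @param path output path.
#' @export
write_junction_bed <- function(junctions, path) {
  cc <- count_columns(junctions)
  total <- if (length(cc)) as.integer(round(rowSums(junctions[, cc, drop = FALSE])))
           else 0L
  bed <- data.frame(chrom = junctions$chrom, start = junctions$start,
                    end = junctions$end, id = junctions$id, score = total,
                    strand = junctions$strand, stringsAsFactors = FALSE)
  if (length(cc)) bed <- cbind(bed, junctions[, cc, drop = FALSE])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(colnames(bed), collapse = "\t")), con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Acceptor (3'ss) of each junction
#'
#' Returns the splice-acceptor site in transcript orientation. `anchor` is
#' the 0-based genomic coordinate of the first exonic base (+1): for plus
#' strand this is `intron_end`; for minus strand it is `intron_start - 1`,
#' with positions increasing 5'->3' along the transcript (so position -1,
#' the G of the AG, maps to the genomic base at `intron_start`).
#'
#' @param junctions junction table.
#' @return data.frame with `id`, `chrom`, `strand`, `anchor`.
#' @export
acceptor_of <- function(junctions) {
  anchor <- ifelse(junctions$strand == "+", junctions$end, junctions$start - 1L)
  data.frame(id = junctions$id, chrom = junctions$chrom,
             strand = junctions$strand, anchor = as.integer(anchor),
             stringsAsFactors = FALSE)
}

#' Donor (5'ss) of each junction
#'
#' Symmetric counterpart of [acceptor_of()]: `anchor` is the 0-based genomic
#' coordinate of the last exonic base of the upstream exon.
#' @param junctions junction table.
#' @return data.frame with `id`, `chrom`, `strand`, `anchor`.
#' @export
donor_of <- function(junctions) {
  anchor <- ifelse(junctions$strand == "+", junctions$start - 1L, junctions$end)
  data.frame(id = junctions$id, chrom = junctions$chrom,
             strand = junctions$strand, anchor = as.integer(anchor),
             stringsAsFactors = FALSE)
}

#' Map transcript-relative acceptor positions to 0-based genomic coordinates
#'
#' @param site one-row data.frame (or list) with `strand` and `anchor` as
#'   produced by [acceptor_of()].
#' @param pos integer transcript positions (-1 = last intronic base,
#'   +1 = first exonic base; 0 is invalid).
#' @return integer genomic 0-based coordinates.
#' @export
genomic_position <- function(site, pos) {
  if (any(pos == 0L)) stop("transcript position 0 does not exist")
  step <- ifelse(pos > 0L, pos - 1L, pos)
  if (site$strand == "+") as.integer(site$anchor + step)
  else as.integer(site$anchor - step)
}

#' Extract a transcript-oriented window around an acceptor site
#'
#' Returns `intron_flank + exon_flank` bases, reverse-complemented for minus
#' strand, with the AG acceptor dinucleotide at window positions
#' `intron_flank - 1` and `intron_flank` (1-based).
#'
#' @param genome a named `Biostrings::DNAStringSet` (or the path of a FASTA
#'   file, which is read with `Biostrings::readDNAStringSet`).
#' @param site one-row data.frame with `chrom`, `strand`, `anchor`.
#' @param intron_flank,exon_flank number of intronic / exonic bases.
#' @return a single character string (upper case).
#' @export
extract_window <- function(genome, site, intron_flank = 50L, exon_flank = 50L) {
  genome <- as_genome(genome)
  nm <- sub(" .*", "", names(genome))
  i <- match(site$chrom, nm)
  if (is.na(i))
    stop("contig '", site$chrom, "' absent from FASTA; available: ",
         paste(nm, collapse = ", "))
  len <- Biostrings::width(genome)[i]
  if (site$strand == "+") {
    from0 <- site$anchor - intron_flank        # 0-based inclusive
    to0 <- site$anchor + exon_flank - 1L
  } else {
    from0 <- site$anchor - exon_flank + 1L
    to0 <- site$anchor + intron_flank
  }
  if (from0 < 0L || to0 >= len)
    stop("window [", from0, ",", to0 + 1L, ") outside contig '", site$chrom,
         "' of length ", len)
  s <- Biostrings::subseq(genome[[i]], start = from0 + 1L, end = to0 + 1L)
  if (site$strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or a FASTA path")
  genome
}

#' Read an experimental branchpoint catalogue
#'
#' BED-like file of single-base branchpoint adenosine positions (0-based).
#' Intervals longer than one base are reduced to their midpoint with a
#' warning. Empty files yield an empty catalogue.
#'
#' @param path BED6 file path.
#' @return data.frame with `chrom`, `pos` (0-based), `id`, `strand`.
#' @export
read_branchpoint_catalogue <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      id = character(), strand = character(),
                      stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(lines, "\t"))
  if (ncol(f) < 3) stop(path, ": need at least 3 BED columns")
  start <- as.integer(f[, 2]); end <- as.integer(f[, 3])
  wide <- end - start != 1L
  if (any(wide)) {
    warning(sprintf("%d catalogue interval(s) not single-base; midpoint taken", sum(wide)))
  }
  pos <- ifelse(wide, start + (end - start) %/% 2L, start)
  data.frame(chrom = f[, 1], pos = as.integer(pos),
             id = if (ncol(f) >= 4) f[, 4] else paste0("bp", seq_along(pos)),
             strand = if (ncol(f) >= 6) f[, 6] else "*",
             stringsAsFactors = FALSE)
}

#' Write a TSV with a commented header line
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv_commented <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(colnames(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_commented()]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_commented <- function(path) {
  hdr <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#", "", hdr), "\t")[[1]]
  df <- utils::read.delim(path, comment.char = "#", header = FALSE,
                          stringsAsFactors = FALSE)
  colnames(df) <- cols
  df
}
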