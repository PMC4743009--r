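test_that("pairing score closed forms and T/U equivalence", {
  expect_equal(pairing_score("UACUAAC"), 6.0)
  expect_equal(pairing_score("TACTAAC"), 6.0)
  expect_equal(pairing_score("CACUAAC"), 5.0)
  expect_equal(pairing_score("UAUUAAC"), 5.5)
  expect_equal(pairing_score("tactaac"), 6.0)
  expect_error(pairing_score("UACUAUC"), "branch A")
  expect_error(pairing_score("UACUAACA"), "length 7")
})

test_that("single substitutions from consensus lose exactly 0.5 (wobble) or 1.0 (mismatch)", {
  consensus <- strsplit("TACTAAC", "")[[1]]
  partners <- c("A", "U", "G", "A", "U", "G")  # heptamer pos 1..5, 7
  paired_pos <- c(1:5, 7)
  for (k in seq_along(paired_pos)) {
    pos <- paired_pos[k]
    for (b in setdiff(c("A", "C", "G", "T"), consensus[pos])) {
      h <- consensus
      h[pos] <- b
      wobble <- (partners[k] == "U" && b == "G") ||
        (partners[k] == "G" && b == "T")
      delta <- if (wobble) 0.5 else 1.0
      expect_equal(pairing_score(paste(h, collapse = "")), 6.0 - delta,
                   label = paste("pos", pos, "base", b))
    }
  }
})

test_that("candidate enumeration respects the distance window", {
  # single A at offset -25 in a pyrimidine background
  s <- paste0(strrep("CT", 12), "A", strrep("CT", 12))  # 49 nt, A at -25
  cand <- enumerate_candidates(s, min_dist = 6, max_dist = 40)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$offset, -25L)
  expect_equal(nchar(cand$heptamer), 7L)
  expect_equal(cand$ppt_score, 1)
  # A at -3 is excluded by the 6-nt minimum
  s2 <- paste0(strrep("C", 20), "ACC")
  expect_equal(nrow(enumerate_candidates(s2, min_dist = 6, max_dist = 20)), 0L)
  expect_equal(enumerate_candidates(s2, min_dist = 3, max_dist = 20)$offset, -3L)
  # poly-A: one candidate per A with a complete heptamer in the window
  sA <- strrep("A", 30)
  candA <- enumerate_candidates(sA, min_dist = 6, max_dist = 100)
  expect_equal(nrow(candA), 20L)  # offsets -6..-25 (heptamer needs 5 bases 5')
  expect_equal(sort(candA$offset), -25:-6)
})

test_that("ranking prefers score, then ppt, then proximity to the prior, then upstream", {
  cand <- data.frame(offset = c(-20L, -30L), heptamer = "TACTAAC",
                     pairing_score = 5, ppt_score = 0.8)
  expect_equal(bpshift:::pick_candidate(cand, -25)$offset, -30L)  # tie: upstream
  cand2 <- cand; cand2$offset <- c(-20L, -28L)
  expect_equal(bpshift:::pick_candidate(cand2, -25)$offset, -28L) # closer to -25
  cand3 <- cand; cand3$ppt_score <- c(0.9, 0.8)
  expect_equal(bpshift:::pick_candidate(cand3, -25)$offset, -20L) # ppt beats prior
  cand4 <- cand; cand4$pairing_score <- c(4, 5)
  expect_equal(bpshift:::pick_candidate(cand4, -25)$offset, -30L) # score first
})

test_that("planted BP' is recovered at the exact position in >= 95% of events", {
  co <- default_cohort()
  tr <- sensitive_truth(co)
  alt <- alt_sites_of(co); can <- can_sites_of(co)
  hits <- bp_off <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    a <- assign_branchpoints(can[i, ], alt[i, ], co$genome)
    hits[i] <- !a$bpprime_unassigned && a$bpprime$genomic_pos == tr$bpprime_pos[i]
    bp_off[i] <- if (a$bp_unassigned) NA_real_ else a$bp$offset
  }
  expect_gte(mean(hits), 0.95)
  dist <- bp_distance_distribution(list(ag = bp_off))
  expect_equal(dist$ag$mode, 25L)
})

test_that("an AG' with no upstream adenosine is flagged unassigned", {
  g <- toy_genome(c(ct = paste0(strrep("CT", 40), "AG", "GTCGTC")))
  can <- data.frame(chrom = "ct", strand = "+", anchor = 82L)
  alt <- data.frame(chrom = "ct", strand = "+", anchor = 66L)
  a <- assign_branchpoints(can, alt, g,
                           bp_window = c(-30L, -16L), bpprime_window = c(-18L, -9L))
  expect_true(a$bpprime_unassigned)
  expect_true(a$bp_unassigned)
})

test_that("distance distributions report per-group histograms and modes", {
  d <- bp_distance_distribution(list(one = -13L, none = integer(),
                                     multi = c(-25L, -25L, -13L)))
  expect_equal(nrow(d$one$histogram), 1L)
  expect_equal(d$one$mode, 13L)
  expect_true(is.na(d$none$mode))
  expect_equal(d$multi$mode, 25L)
})

test_that("insensitive acceptors have a unimodal BP distribution at the planted offset", {
  co <- default_cohort()
  tr <- co$truth[!co$truth$sensitive, ][1:40, ]
  offs <- vapply(seq_len(nrow(tr)), function(i) {
    site <- data.frame(chrom = tr$chrom[i], strand = tr$strand[i],
                       anchor = tr$can_anchor[i])
    a <- assign_branchpoints(site, site, co$genome,
                             bpprime_window = c(-2L, -1L))
    if (a$bp_unassigned) NA_real_ else a$bp$offset
  }, numeric(1))
  d <- bp_distance_distribution(list(ins = offs))
  expect_equal(d$ins$mode, 25L)
  expect_gte(mean(offs == -25, na.rm = TRUE), 0.8)
})

test_that("catalogue overlap counts exact coincidences of the branch A with the AG' A", {
  # toy: catalogue BP exactly at the A of the AG' (position -2)
  alt <- data.frame(chrom = "c", strand = "+", anchor = 100L)
  cat_hit <- data.frame(chrom = "c", pos = 98L, id = "b1", strand = "+")
  ov <- overlap_with_catalogue(alt, cat_hit)
  expect_equal(ov$n_coincident, 1L)
  expect_equal(ov$fraction_coincident, 1)
  # upstream, non-coincident: mean offset measured from the AG' A
  cat_up <- data.frame(chrom = "c", pos = 93L, id = "b2", strand = "+")
  ov2 <- overlap_with_catalogue(alt, cat_up)
  expect_equal(ov2$n_coincident, 0L)
  expect_equal(ov2$mean_upstream_offset, 5)
  empty <- overlap_with_catalogue(alt, cat_hit[0, ])
  expect_equal(empty$n_total, 0L)
  expect_true(is.na(empty$fraction_coincident))
})

test_that("synthetic catalogue overlap equals the truth-derived coincidence fraction", {
  co <- default_cohort()
  tr <- sensitive_truth(co)
  catalogue <- data.frame(chrom = tr$chrom, pos = tr$bp_pos,
                          id = tr$acceptor, strand = tr$strand)
  ov <- overlap_with_catalogue(alt_sites_of(co), catalogue)
  # coincidence <=> planted canonical BP A == A of the AG' dinucleotide
  expected <- tr$bp_pos == tr$agprime_A_pos
  has_upstream <- tr$bp_offset - tr$agprime_offset < 0
  expect_equal(ov$n_coincident, sum(expected))
  expect_equal(ov$n_total, sum(has_upstream | expected))
})

test_that("motif contrast is zero for identical groups and matches a hand chi-square", {
  h <- rep("TACTAAC", 10)
  mc <- bp_motif_contrast(a = h, b = h, c = h)
  expect_equal(mc$statistic, rep(0, 7))
  expect_equal(mc$p_value, rep(1, 7))
  expect_equal(mc$position_A5, 0:6)
  # three groups pure in distinct bases at position 1: chi2 = 60 by hand
  mc2 <- bp_motif_contrast(a = rep("TACTAAC", 10), b = rep("CACTAAC", 10),
                           c = rep("GACTAAC", 10))
  expect_equal(mc2$statistic[1], 60, tolerance = 1e-6)
  expect_equal(mc2$statistic[2:7], rep(0, 6))
  expect_error(bp_motif_contrast(a = h, b = character()), "non-empty")
})

test_that("planted BP and BP' heptamer families differ significantly", {
  co <- default_cohort()
  tr <- sensitive_truth(co)
  hept_at <- function(anchor_off, i) {
    site <- data.frame(chrom = tr$chrom[i], strand = tr$strand[i],
                       anchor = tr$can_anchor[i])
    w <- extract_window(co$genome, site, 80, 0)
    substr(w, 81 + anchor_off[i] - 5, 81 + anchor_off[i] + 1)
  }
  n <- nrow(tr)
  bp_h <- vapply(seq_len(n), function(i) hept_at(tr$bp_offset, i), character(1))
  bpp_h <- vapply(seq_len(n), function(i)
    hept_at(tr$agprime_offset + tr$bpprime_offset, i), character(1))
  ins <- co$truth[!co$truth$sensitive, ]
  ins_h <- vapply(seq_len(nrow(ins)), function(i) {
    site <- data.frame(chrom = ins$chrom[i], strand = ins$strand[i],
                       anchor = ins$can_anchor[i])
    w <- extract_window(co$genome, site, 80, 0)
    substr(w, 81 + ins$bp_offset[i] - 5, 81 + ins$bp_offset[i] + 1)
  }, character(1))
  mc <- bp_motif_contrast(canonical = bp_h, alternative = bpp_h,
                          insensitive = ins_h)
  # planted difference between CACTAAC-like and TACTAAC-like at position 1
  expect_lt(mc$p_value[1], 0.01)
  expect_equal(mc$position[mc$position_A5 == 5], 6L)
})
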