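test_that("U2AF affinity formula", {
  expect_equal(u2af_affinity(1.0, "G"), 1.5)
  expect_equal(u2af_affinity(1.0, "C"), 1.0)
  expect_equal(u2af_affinity(0, "G"), 0)
})

test_that("the TMEM14C-like construct carries the described architecture", {
  con <- tmem14c_like_construct()
  expect_equal(nchar(con$sequence), 70L)
  b <- function(p) bpshift:::construct_base(con, p)
  expect_equal(paste0(b(-2), b(-1)), "AG")
  expect_equal(paste0(b(-18), b(-17)), "AG")   # AG' dinucleotide
  expect_equal(b(-16), "C")                     # +1 of AG'
  expect_equal(b(1), "G")                       # +1 of AG
  hept <- function(a) paste(vapply((a - 5):(a + 1), b, character(1)), collapse = "")
  expect_equal(pairing_score(hept(-6)), 4.0)    # canonical BP
  expect_equal(pairing_score(hept(-29)), 5.5)   # BP' stronger than BP
  acc <- bpshift:::find_acceptors(con)
  expect_equal(acc, c(-16L, 0L))
})

test_that("mutations are validated and reshape the candidate sets", {
  con <- tmem14c_like_construct()
  expect_error(apply_mutations(con, "-13G>A"), "mismatch")
  expect_error(apply_mutations(con, "bogus"), "malformed")
  # destroying the AG' dinucleotide removes the acceptor
  no_agp <- apply_mutations(con, "-18A>G")
  expect_equal(bpshift:::find_acceptors(no_agp), 0L)
  # creating an upstream AG adds a new acceptor
  new_site <- apply_mutations(con, "-28T>A")
  expect_true(-26L %in% bpshift:::find_acceptors(new_site))
  # a neutral adenosine change leaves acceptors untouched
  neut <- apply_mutations(con, "-13A>G")
  expect_equal(bpshift:::find_acceptors(neut), c(-16L, 0L))
})

test_that("usage at f = 0 is the wild-type regime and mixes linearly in f", {
  con <- tmem14c_like_construct()
  fs <- c(0, 0.25, 0.5, 0.75, 1)
  pr <- predict_usage(con, fs, wt_window = c(-44L, -5L),
                      mut_window = c(-18L, -5L))
  expect_equal(unname(pr$usage[, 1]), pr$usage_wt)
  expect_equal(unname(pr$usage[, 5]), pr$usage_mut)
  for (k in seq_along(fs))
    expect_equal(unname(pr$usage[, k]),
                 (1 - fs[k]) * pr$usage_wt + fs[k] * pr$usage_mut)
  expect_equal(unname(colSums(pr$usage)), rep(1, 5))
})

test_that("symmetric architecture gives equal usage in both regimes", {
  # two acceptors with identical ppt, +1 base and equal-score branchpoints
  bg <- function(n) strrep("CT", ceiling(n / 2))
  seq <- paste0(
    substr(bg(12), 1, 12),      # -62..-51
    "CACTAAC",                  # -50..-44  BP of AG' (A at -45)
    substr(bg(10), 1, 10),      # -43..-34
    "AG", "C",                  # -33..-31  AG' dinucleotide, +1 = C
    substr(bg(12), 1, 12),      # -30..-19
    "CACTAAC",                  # -18..-12  BP of AG (A at -13)
    substr(bg(9), 1, 9),        # -11..-3
    "AG", "C", "TCCTT")         # canonical AG, +1 = C, exon
  con <- splice_construct_new(seq, ag_index = nchar(seq) - 5L)
  pr <- predict_usage(con, c(0, 1), wt_window = c(-44L, -9L),
                      mut_window = c(-18L, -9L), acceptor_search = c(-40L, -3L))
  expect_equal(pr$acceptors$offset, c(-31L, 0L))
  expect_equal(pr$usage_wt, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(pr$usage_mut, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("AG'/AG index rises strictly with the mutant transcript fraction", {
  # canonical AG (+1 G) with BP score 5.0 at -25; AG' at -16 (+1 C) with a
  # perfect BP' 13 nt upstream of it (-29 relative to AG)
  seq <- paste0(
    strrep("CT", 8),            # -58..-43
    "CCCC",                     # -42..-39
    "CCCC",                     # -38..-35
    "TACTAACTAAC",              # -34..-24  BP' (A -29, 6.0) + BP (A -25, 5.0)
    "CCCTC",                    # -23..-19
    "AG", "C",                  # -18..-16  AG' dinucleotide, +1 = C
    "TTCCTTCCTTCC",             # -15..-4
    "C",                        # -3
    "AG", "G", "TCGTC")         # canonical AG, +1 = G, exon
  con <- splice_construct_new(seq, ag_index = nchar(seq) - 5L)
  b <- function(p) bpshift:::construct_base(con, p)
  hept <- function(a) paste(vapply((a - 5):(a + 1), b, character(1)), collapse = "")
  expect_equal(pairing_score(hept(-29)), 6.0)
  expect_equal(pairing_score(hept(-25)), 5.0)
  fs <- c(0, 0.14, 0.30, 1)
  pr <- predict_usage(con, fs)
  idx <- pr$agprime_index
  expect_true(all(diff(idx) > 0))
  agp_usage <- pr$usage["-16", ]
  expect_true(all(diff(agp_usage) > 0))
})

test_that("the mutagenesis truth table reproduces all seven qualitative outcomes", {
  tt <- mutagenesis_truth_table()
  out <- function(mutant, acc) tt$outcome[tt$mutant == mutant &
                                            tt$acceptor_offset == acc]
  usage_hi <- function(mutant, acc) tt$usage_f_hi[tt$mutant == mutant &
                                                    tt$acceptor_offset == acc]
  base <- attr(tt, "baseline")
  base_agp <- base$usage["-16", 2]
  # 1. destroying BP' abolishes the AG' at every mutant fraction
  expect_equal(out("bpprime_destroy", -16), "abolished")
  expect_equal(tt$usage_f_lo[tt$mutant == "bpprime_destroy" &
                               tt$acceptor_offset == -16], 0)
  expect_equal(usage_hi("bpprime_destroy", -16), 0)
  # 2. destroying the canonical BP abolishes AG; all flux moves to AG'
  expect_equal(out("bp_destroy", 0), "abolished")
  expect_equal(usage_hi("bp_destroy", -16), 1)
  # 3. destroying the AG' dinucleotide abolishes AG'
  expect_equal(out("agprime_destroy", -16), "abolished")
  # 4. a neutral adenosine change leaves usage unchanged
  expect_equal(out("neutral", -16), "unchanged")
  expect_equal(out("neutral", 0), "unchanged")
  # 5. +1 of AG' turned into G strengthens the alternative site
  expect_equal(out("agprime_plus_one_G", -16), "strengthened")
  # 6. perfect canonical BP pairing drives AG' usage to ~0
  expect_equal(out("bp_perfect", -16), "abolished")
  expect_lt(usage_hi("bp_perfect", -16), 0.02)
  # 7. swapping BP and BP' decreases AG' usage
  expect_lt(usage_hi("swap", -16), base_agp)
})

test_that("the swap mutation exchanges the two heptamer pairing scores exactly", {
  con <- tmem14c_like_construct()
  swapped <- apply_mutations(con, construct_mutation_series()$swap)
  hept <- function(x, a) paste(vapply((a - 5):(a + 1), function(p)
    bpshift:::construct_base(x, p), character(1)), collapse = "")
  expect_equal(pairing_score(hept(swapped, -6)), pairing_score(hept(con, -29)))
  expect_equal(pairing_score(hept(swapped, -29)), pairing_score(hept(con, -6)))
})

test_that("usage responds monotonically to branchpoint and U2AF strength", {
  con <- tmem14c_like_construct()
  args <- list(f_mut = c(0, 0.3), wt_window = c(-44L, -5L),
               mut_window = c(-18L, -5L))
  base <- do.call(predict_usage, c(list(con), args))
  # raising the BP' score (5.5 -> 6.0) must not decrease AG' usage at f > 0
  up_bpp <- do.call(predict_usage, c(list(apply_mutations(con, "-28T>C")), args))
  expect_gte(up_bpp$usage["-16", 2], base$usage["-16", 2])
  # raising the canonical BP score must not increase AG' usage
  up_bp <- do.call(predict_usage,
                   c(list(apply_mutations(con, c("-10C>A", "-7C>A"))), args))
  expect_lte(up_bp$usage["-16", 2], base$usage["-16", 2])
  # raising AG's U2AF affinity side must not increase AG' usage at f < 1:
  # removing the G bonus from AG lowers its affinity and raises AG' leak
  less_aff <- do.call(predict_usage, c(list(con), args, g_bonus = 0))
  expect_gte(less_aff$usage["-16", 1], base$usage["-16", 1])
})

test_that("AG'/AG index conventions", {
  expect_equal(agprime_index(60, 100), 0.6, ignore_attr = TRUE)
  expect_equal(agprime_index(0, 100), 0, ignore_attr = TRUE)
  i <- agprime_index(10, 0)
  expect_true(is.na(i))
  expect_true(attr(i, "undefined"))
  expect_true(is.na(agprime_index(0, 0)))
})
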