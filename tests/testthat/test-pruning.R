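test_that("edit_distance_to_reference matches the worked values and a naive oracle", {
  X <- "AACGTATCGACG"
  expect_identical(edit_distance_to_reference("CGTA", X), 0L)  # substring
  expect_identical(edit_distance_to_reference("AACT", X), 1L)
  expect_identical(edit_distance_to_reference("AACTG", X), 1L)  # delete T
  expect_identical(edit_distance_to_reference("AACTG", X, "substitution_only"), 2L)
  set.seed(111)
  for (rep in 1:15) {
    Xr <- rand_dna(sample(10:25, 1L))
    w <- rand_dna(sample(2:8, 1L))
    expect_identical(edit_distance_to_reference(w, Xr), brute_edit_to_ref(w, Xr))
  }
})

test_that("basic D-array: worked example, substring case, oracle recurrence", {
  X <- "AACGTATCGACG"
  rev_fm <- build_fm_index(revstring(X))
  expect_identical(calculate_d_basic("AACTGA", rev_fm), c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_identical(calculate_d_basic("GTATCG", rev_fm), rep(0L, 6L))
  set.seed(121)
  X2 <- rand_dna(1000)
  rev_fm2 <- build_fm_index(revstring(X2))
  for (rep in 1:50) {
    at <- sample(900L, 1L)
    W <- substr(X2, at + 1L, at + 40L)
    for (p in sample(40L, sample(0:3, 1L))) {
      substr(W, p, p) <- sample(c("A", "C", "G", "T"), 1L)
    }
    expect_identical(calculate_d_basic(W, rev_fm2), brute_d_basic(W, X2))
  }
})

test_that("pattern mining filters by frequency, edit value and byte budget", {
  # training reads all substrings of the reference: nothing qualifies
  ref <- "ACGTACGTACGTACGTACGT"
  subs <- rep(c("ACGTAC", "GTACGT"), 10L)
  p <- mine_frequent_patterns(subs, ref, byte_budget = 1e6, min_freq = 5L)
  expect_identical(nrow(p), 0L)

  # CC needs two substitutions against an all-A reference, CA only one
  refA <- strrep("A", 10L)
  reads <- rep("CCACC", 12L)
  p <- mine_frequent_patterns(reads, refA, byte_budget = 1e6, min_freq = 10L,
                              model = "substitution_only")
  expect_true("CC" %in% p$pattern)
  expect_false("CA" %in% p$pattern)
  expect_false("C" %in% p$pattern)   # e = 1
  expect_identical(unique(p$e_value), 2L)
  expect_true(all(p$frequency >= 10L))
  # ordered by frequency descending, ties lexicographic
  expect_true(all(diff(p$frequency) <= 0L))

  # budget for exactly one pattern: the most frequent qualifying substring
  full <- mine_frequent_patterns(reads, refA, byte_budget = 1e6, min_freq = 10L,
                                 model = "substitution_only")
  top <- full$pattern[1L]
  one <- mine_frequent_patterns(reads, refA,
                                byte_budget = (1L + nchar(top)) * 64L,
                                min_freq = 10L, model = "substitution_only")
  expect_identical(one$pattern, top)

  expect_error(mine_frequent_patterns(character(0), refA, 1e6), "nonempty")
})

test_that("AC automaton structure: goto, failure links, leaves", {
  a <- build_ac_automaton(c("AA", "AC", "AG", "C", "G", "T"))
  # from state "A", input T falls back to the leaf for "T"
  stateA <- which(a$state_str == "A")
  stateT <- which(a$state_str == "T")
  expect_identical(a$goto[stateA, 4L], stateT)
  expect_true(a$leaf_pat[stateT] > 0L)

  # empty pattern set: root-only automaton, no matches ever
  a0 <- build_ac_automaton(character(0))
  expect_identical(length(a0$fail), 1L)
  expect_identical(nrow(scan_patterns(a0, "ACGTACGT")), 0L)

  # duplicate patterns collapse
  expect_identical(nrow(build_ac_automaton(c("AC", "AC"))$patterns), 1L)

  # failure links equal brute-force longest-proper-suffix computation
  set.seed(131)
  for (rep in 1:10) {
    pats <- unique(vapply(seq_len(sample(3:12, 1L)),
                          function(i) rand_dna(sample(1:5, 1L)), character(1L)))
    a <- build_ac_automaton(pats)
    prefixes <- a$state_str
    for (st in seq_along(a$state_str)[-1L]) {
      want <- brute_fail_target(a$state_str[st], prefixes)
      expect_identical(a$state_str[a$fail[st]], want)
    }
  }
})

test_that("scan_patterns is greedy, non-overlapping, reset-on-match", {
  a <- build_ac_automaton(c("AA", "AC", "AG", "C", "G", "T"))
  res <- scan_patterns(a, "CAT")
  expect_identical(res$end, c(0L, 2L))
  expect_identical(res$pattern, c("C", "T"))
  expect_identical(nrow(scan_patterns(build_ac_automaton("GG"), "ACTACT")), 0L)
  set.seed(141)
  for (rep in 1:20) {
    pats <- unique(vapply(seq_len(sample(2:8, 1L)),
                          function(i) rand_dna(sample(1:4, 1L)), character(1L)))
    a <- build_ac_automaton(pats)
    W <- rand_dna(sample(5:30, 1L))
    expect_identical(scan_patterns(a, W), brute_greedy_scan(pats, W),
                     info = paste(W, paste(pats, collapse = ",")))
  }
})

test_that("DCDC D-array: worked example and fallback equivalence", {
  X <- "AACGTATCGACG"
  rev_fm <- build_fm_index(revstring(X))
  aut <- build_ac_automaton("AACTG")
  expect_identical(calculate_d_dcdc("AACTGA", rev_fm, aut),
                   c(0L, 0L, 0L, 1L, 2L, 2L))
  # no patterns: identical to the basic recurrence
  a0 <- build_ac_automaton(character(0))
  set.seed(151)
  for (rep in 1:10) {
    W <- rand_dna(sample(10:40, 1L))
    expect_identical(calculate_d_dcdc(W, rev_fm, a0),
                     calculate_d_basic(W, rev_fm))
  }
})

test_that("both D-arrays are true D-metric lower bounds; DCDC is tighter", {
  set.seed(161)
  for (rep in 1:8) {
    X <- rand_dna(sample(200:1000, 1L))
    rev_fm <- build_fm_index(revstring(X))
    # patterns whose recorded e-value (2) equals their true D-metric cost
    pats <- character(0)
    while (length(pats) < 3L) {
      cand <- rand_dna(sample(4:7, 1L))
      if (edit_distance_to_reference(cand, X) == 2L) pats <- c(pats, cand)
    }
    aut <- build_ac_automaton(pats)
    for (r in 1:6) {
      W <- rand_dna(sample(10:50, 1L))
      db <- calculate_d_basic(W, rev_fm)
      dd <- calculate_d_dcdc(W, rev_fm, aut)
      truth <- dp_prefix_bounds(W, X)
      expect_true(all(db <= truth))
      expect_true(all(dd <= truth))
      expect_true(all(dd >= db))          # never looser
      expect_true(all(diff(db) >= 0L))    # monotone
      expect_true(all(diff(dd) >= 0L))
      expect_true(all(db >= 0L))
    }
  }
})
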