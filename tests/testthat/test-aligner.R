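# Verify an edit script against the actual reference window: M columns must
# equal the read base, X columns must differ, D consumes reference only, I
# consumes read only.
check_script <- function(read, ref, pos0, script) {
  ops <- strsplit(script, "")[[1L]]
  rc <- strsplit(read, "")[[1L]]
  xc <- strsplit(ref, "")[[1L]]
  ri <- 1L; xi <- pos0 + 1L
  for (op in ops) {
    if (op == "M") {
      if (rc[ri] != xc[xi]) return(FALSE)
      ri <- ri + 1L; xi <- xi + 1L
    } else if (op == "X") {
      if (rc[ri] == xc[xi]) return(FALSE)
      ri <- ri + 1L; xi <- xi + 1L
    } else if (op == "I") {
      ri <- ri + 1L
    } else if (op == "D") {
      xi <- xi + 1L
    } else return(FALSE)
  }
  ri == length(rc) + 1L
}

test_that("z = 0 reproduces exact backward search", {
  set.seed(171)
  ref <- rand_dna(800)
  fm <- build_fm_index(ref)
  for (rep in 1:20) {
    at <- sample(760L, 1L)
    W <- substr(ref, at + 1L, at + 30L)
    h <- inexact_search(W, fm, integer(30L), search_params(z = 0L))
    expect_identical(nrow(h), 1L)
    expect_identical(c(h$k, h$l), as.integer(fm_query_interval(fm, W)))
    expect_identical(h$ndiff, 0L)
    expect_identical(h$script, strrep("M", 30L))
  }
  # absent string: no hits at z = 0
  h <- inexact_search(strrep("A", 25L), fm, integer(25L), search_params(z = 0L))
  expect_identical(nrow(h), 0L)
})

test_that("substitution-only completeness: planted origins always recovered", {
  set.seed(181)
  for (rep in 1:4) {
    ref <- rand_dna(1000)
    fm <- build_fm_index(ref)
    rev_fm <- build_fm_index(revstring(ref))
    for (z in 1:2) {
      for (r in 1:5) {
        at <- sample(970L, 1L)
        W <- substr(ref, at + 1L, at + 24L)
        for (p in sample(24L, z)) {
          repeat {
            b <- sample(c("A", "C", "G", "T"), 1L)
            if (b != substr(W, p, p)) { substr(W, p, p) <- b; break }
          }
        }
        D <- calculate_d_basic(W, rev_fm)
        h <- inexact_search(W, fm, D, search_params(z = z, max_gap_opens = 0L))
        pos <- unique(unlist(lapply(seq_len(nrow(h)), function(i)
          locate(fm, c(h$k[i], h$l[i])))))
        expect_true(at %in% pos)
      }
    }
  }
})

test_that("pruning on/off gives identical hit sets for gapless settings", {
  set.seed(191)
  ref <- rand_dna(600)
  fm <- build_fm_index(ref)
  rev_fm <- build_fm_index(revstring(ref))
  pars <- search_params(z = 2L, max_gap_opens = 0L)
  for (rep in 1:15) {
    at <- sample(570L, 1L)
    W <- substr(ref, at + 1L, at + 20L)
    for (p in sample(20L, sample(0:2, 1L))) {
      substr(W, p, p) <- sample(c("A", "C", "G", "T"), 1L)
    }
    D <- calculate_d_basic(W, rev_fm)
    on <- inexact_search(W, fm, D, pars)
    off <- inexact_search(W, fm, integer(20L), pars)
    o1 <- on[order(on$k, on$l), c("k", "l", "ndiff")]
    o2 <- off[order(off$k, off$l), c("k", "l", "ndiff")]
    rownames(o1) <- rownames(o2) <- NULL
    expect_identical(o1, o2)
  }
})

test_that("search results are invariant to STA vs raw FM intervals", {
  set.seed(201)
  ref <- rand_dna(700)
  bundle <- build_index_bundle(ref, trie_size = 9000L)
  rev_fm <- bundle$rev_fm
  for (rep in 1:10) {
    at <- sample(650L, 1L)
    W <- substr(ref, at + 1L, at + 40L)
    substr(W, 12L, 12L) <- sample(c("A", "C", "G", "T"), 1L)
    D <- calculate_d_basic(W, rev_fm)
    pars <- search_params(z = 2L)
    h_sta <- inexact_search(W, bundle$sta, D, pars)
    h_fm <- inexact_search(W, bundle$fm, D, pars)
    o1 <- h_sta[order(h_sta$k, h_sta$l), ]
    o2 <- h_fm[order(h_fm$k, h_fm$l), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_identical(o1, o2)
  }
})

test_that("align_read: strands, unmapped reads, script replay", {
  set.seed(211)
  ref <- rand_dna(2000)
  bundle <- build_index_bundle(ref)
  r <- substr(ref, 301L, 360L)
  h <- align_read(r, bundle, search_params(z = 1L), name = "fwd")
  expect_true(h$mapped)
  expect_identical(h$pos, 301L)
  expect_identical(h$strand, "+")
  expect_identical(h$ndiff, 0L)
  expect_identical(h$cigar, "60M")
  expect_identical(h$nm, 0L)
  expect_identical(h$mapq, 37L)

  h2 <- align_read(revcomp(r), bundle, search_params(z = 1L), name = "rev")
  expect_true(h2$mapped)
  expect_identical(h2$pos, 301L)
  expect_identical(h2$strand, "-")

  # read absent from a short reference at z = 0: unmapped
  small <- build_index_bundle("ACGTACGTACGTACGTACGT")
  repeat {
    rr <- rand_dna(12L)
    if (brute_count("ACGTACGTACGTACGTACGT", rr) == 0L) break
  }
  h3 <- align_read(rr, small, search_params(z = 0L), name = "none")
  expect_false(h3$mapped)

  expect_false(align_read("A", bundle, name = "tiny")$mapped)

  # scripts replay to exact reference matches (with gaps and substitutions)
  for (rep in 1:15) {
    at <- sample(1900L, 1L)
    W <- substr(ref, at + 1L, at + 50L)
    k <- sample(1:2, 1L)
    for (p in sample(45L, k)) substr(W, p, p) <- sample(c("A", "C", "G", "T"), 1L)
    h <- align_read(W, bundle, search_params(z = 3L), name = "r")
    expect_true(h$mapped)
    if (h$strand == "+") {
      hits <- inexact_search(W, bundle$fm,
                             calculate_d_basic(W, bundle$rev_fm),
                             search_params(z = 3L))
      best <- hits[hits$ndiff == min(hits$ndiff), ]
      for (b in seq_len(nrow(best))) {
        for (p in locate(bundle$fm, c(best$k[b], best$l[b]))) {
          expect_true(check_script(W, ref, p, best$script[b]))
        }
      }
    }
  }
})

test_that("mapping quality scheme is as documented and feeds confidence", {
  expect_identical(mapping_quality(1L, 0L), 37L)
  expect_identical(mapping_quality(2L, 0L), 0L)
  expect_identical(mapping_quality(5L, 3L), 0L)
  expect_identical(mapping_quality(0L), 0L)
  q <- vapply(1:10, function(s) mapping_quality(1L, s), integer(1L))
  expect_true(all(diff(q) <= 0L))            # decreasing in competition
  expect_true(all(q >= 0L & q <= 60L))
  # repetitive reference: co-optimal placements force mapq 0
  bundle <- build_index_bundle(strrep("ACGTGGTCAC", 30L))
  h <- align_read("ACGTGGTCACACGTGGTCAC", bundle, search_params(z = 0L))
  expect_true(h$mapped)
  expect_gt(h$n_best, 1L)
  expect_identical(h$mapq, 0L)
})

test_that("gap-extension asymmetry: the constructed two-gap case diverges", {
  # Deterministic construction: reference avoids the dinucleotide TT; the read
  # carries a 3-base insertion (open + 2 free extensions), a 1-base deletion
  # and two substitutions -- search cost 4 at z = 5.  Under the D-metric every
  # gap column costs 1, so the pattern-tightened bound legitimately reaches 3
  # at the critical position while the basic bound stays at 2; with 3 edits
  # already consumed there, only the basic-pruned search survives.
  case <- make_divergence_case()
  X <- case$X; W <- case$W; P <- case$P

  expect_false(grepl("TT", X))
  expect_identical(edit_distance_to_reference(P, X), 2L)

  fm <- build_fm_index(X)
  rev_fm <- build_fm_index(revstring(X))
  db <- calculate_d_basic(W, rev_fm)
  dd <- calculate_d_dcdc(W, rev_fm, build_ac_automaton(P))
  expect_identical(db[16L], 2L)  # basic bound at the critical position
  expect_identical(dd[16L], 3L)  # tightened bound: prunes at 5 - 3 consumed

  pars <- search_params(z = 5L, max_gap_opens = 2L, max_gap_extensions = 3L)
  hb <- inexact_search(W, fm, db, pars)
  hd <- inexact_search(W, fm, dd, pars)
  origin <- case$origin
  pos_b <- unique(unlist(lapply(seq_len(nrow(hb)), function(r)
    locate(fm, c(hb$k[r], hb$l[r])))))
  pos_d <- if (nrow(hd)) unique(unlist(lapply(seq_len(nrow(hd)), function(r)
    locate(fm, c(hd$k[r], hd$l[r]))))) else integer(0)
  expect_true(origin %in% pos_b)    # found with the basic bound
  expect_false(origin %in% pos_d)   # pruned with the tightened bound
  expect_identical(hb$ndiff[match(TRUE, vapply(seq_len(nrow(hb)), function(r)
    origin %in% locate(fm, c(hb$k[r], hb$l[r])), logical(1L)))], 4L)
})
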