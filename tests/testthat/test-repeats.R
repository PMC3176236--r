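# Tandem repeat detection, unit reports and the stem-loop pairing proxy.

test_that("an exact 11 x 10 bp array is recovered with every unit identical", {
  res <- find_tandem_repeats(strrep("TTTTGTTAAA", 11))
  expect_length(res, 1)
  a <- res[[1]]
  expect_equal(a$period, 10L)
  expect_equal(a$copy_number, 11.0)
  expect_equal(a$n_exact_units, 11L)
  expect_equal(a$consensus, "TTTTGTTAAA")
  expect_equal(c(a$start, a$end), c(1L, 110L))
  expect_true(all(a$unit_identities == 100))
})

test_that("short or non-repetitive input yields no calls", {
  expect_length(find_tandem_repeats("ACGT"), 0)
  set.seed(2)
  # a single unit cannot make an array (copy_number >= 2 invariant)
  expect_length(find_tandem_repeats(paste0(rand_seq(9), rand_seq(9))), 0)
})

test_that("a 13.7-copy 35-bp array with two mutated units is characterized correctly", {
  unit <- "TACTTATAATGTAAAATATTTAATATCAATTTAAA"   # 35 nt
  arr <- with_seed(7, build_repeat_array(unit, 13.7, 0))
  ch <- strsplit(arr$seq, "", fixed = TRUE)[[1]]
  mask <- c()
  for (u in c(3, 8)) for (off in c(4, 12, 20)) {
    i <- (u - 1) * 35 + off
    ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    mask <- c(mask, i)
  }
  seqd <- paste(ch, collapse = "")
  res <- find_tandem_repeats(seqd)
  a <- main_array(res)
  expect_equal(a$period, 35L)
  expect_equal(a$copy_number, 13.7)
  expect_equal(a$n_full_units, 13L)
  expect_equal(a$n_exact_units, 11L)   # 13 full units, 2 carry substitutions
  expect_equal(a$consensus, unit)

  # unit report: mismatch positions equal the mutation mask
  ur <- unit_report(a, seqd)
  expect_equal(nrow(ur), 14L)   # 13 full + 1 partial
  expect_true(ur$partial[14])
  hit <- unlist(lapply(seq_len(nrow(ur)), function(k) {
    off <- as.integer(strsplit(ur$mismatch_positions[k], ",")[[1]])
    if (length(off)) ur$start[k] + off - 1L else integer(0)
  }))
  expect_setequal(hit, mask)
  expect_equal(sort(unique(ur$identity[1:13])), c(100 * (1 - 3 / 35), 100),
               tolerance = 1e-9)
})

test_that("per-unit identities are simple mismatch arithmetic", {
  a <- find_tandem_repeats(strrep("GATTACAGAT", 4))[[1]]
  ur <- unit_report(a, strrep("GATTACAGAT", 4))
  expect_true(all(ur$identity == 100))
  s2 <- paste0("GATTACAGAT", "GATTACAGAT", "GATAACAGAT", "GATTACAGAT")
  a2 <- main_array(find_tandem_repeats(s2))
  ur2 <- unit_report(a2, s2)
  expect_equal(sum(ur2$identity == 90), 1L)
})

test_that("calls are invariant under non-repetitive flanking sequence", {
  arr <- strrep("TTTTGTTAAA", 11)
  base <- find_tandem_repeats(arr)[[1]]
  set.seed(17)
  for (i in 1:15) {
    fl <- flanked(arr, 10, flank_len = sample(15:60, 1),
                  freqs = c(A = .4, C = .1, G = .1, T = .4))
    a <- main_array(find_tandem_repeats(fl$seq))
    expect_equal(a$start, base$start + fl$offset)
    expect_equal(a$end, base$end + fl$offset)
    expect_equal(a$period, base$period)
    expect_equal(a$copy_number, base$copy_number)
    expect_equal(a$consensus, base$consensus)
  }
})

test_that("the detector recovers period and copy number across the design envelope", {
  ok <- 0L
  n_trials <- 200L
  for (i in seq_len(n_trials)) {
    set.seed(i)
    p <- sample(5:60, 1)
    copies <- round(runif(1, 2, 20), 1)
    rate <- runif(1, 0, 0.05)
    unit <- rand_seq(p, c(A = .3, C = .2, G = .2, T = .3))
    arr <- build_repeat_array(unit, copies, rate)
    fl <- flanked(arr$seq, p)
    res <- find_tandem_repeats(fl$seq)
    if (length(res) == 0) next
    a <- main_array(res)
    true_cp <- round(nchar(arr$seq) / p, 1)
    if (a$period == p && abs(a$copy_number - true_cp) <= 0.1) ok <- ok + 1L
  }
  expect_gte(ok / n_trials, 0.95)
})

test_that("maximum nested pairing matches exhaustive enumeration up to 12 nt", {
  expect_equal(stemloop_score("GGGAAACCC")$max_pairs, 3L)
  expect_equal(stemloop_score("AAAAAAA")$max_pairs, 0L)
  # perfect inverted repeat: stem 10 + loop 4 pairs fully
  stem <- "GGCGGTGGCG"
  hp <- paste0(stem, "AAAA", revcomp(stem))
  expect_equal(stemloop_score(hp)$max_pairs, 10L)
  # exhaustive check across lengths, random and structured sequences
  set.seed(23)
  for (len in 1:12) {
    for (rep_i in 1:12) {
      s <- rand_seq(len)
      expect_equal(stemloop_score(s)$max_pairs, bruteforce_max_pairs(s),
                   label = paste("len", len, s))
    }
  }
  for (s in c("GCGCGCGCGCGC", "AUAUAUAUAUAU", "GGGGGGCCCCCC", "GTGTGTACACAC"))
    expect_equal(stemloop_score(s)$max_pairs, bruteforce_max_pairs(s))
})

test_that("dot-bracket structures are well-formed and consistent with the score", {
  set.seed(29)
  for (i in 1:15) {
    s <- rand_seq(sample(8:40, 1))
    r <- stemloop_score(s)
    db <- strsplit(r$structure, "", fixed = TRUE)[[1]]
    expect_equal(sum(db == "("), r$max_pairs)
    expect_equal(sum(db == ")"), r$max_pairs)
    depth <- cumsum((db == "(") - (db == ")"))
    expect_true(all(depth >= 0))
    expect_equal(depth[length(depth)], 0)
    expect_equal(r$paired_fraction, 2 * r$max_pairs / nchar(s))
  }
})
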