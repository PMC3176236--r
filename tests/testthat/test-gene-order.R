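# Signed circular orders: extraction, adjacency, classification,
# breakpoints, inverted blocks and TDRL feasibility.

test_that("signed order extraction follows start coordinates and anchors at cox1", {
  ann <- read_fixture()
  ord <- extract_signed_order(ann)
  expect_equal(length(ord$labels), 37L)
  expect_equal(ord$labels[1:3], c("cox1", "cox2", "trnK"))
  expect_equal(utils::tail(ord$labels, 2), c("trnW", "trnC"))
  expect_equal(utils::tail(ord$orientation, 2), c("J", "N"))
  # sort idempotence: shuffled input rows give the same order
  g <- ann$genes[sample(nrow(ann$genes)), ]
  ord2 <- extract_signed_order(mito_annotation(g, genome_length = 14491))
  expect_true(order_equal(ord, ord2))
  # one-gene annotation
  single <- mito_annotation(
    data.frame(name = "cox1", start = 1, end = 100, strand = "J"))
  expect_equal(extract_signed_order(single)$labels, "cox1")
})

test_that("the two clade ground patterns differ only in trnL2 placement", {
  arth <- ground_pattern("arthropod")
  panc <- ground_pattern("pancrustacean")
  expect_equal(sort(arth$labels), sort(panc$labels))
  drop_l2 <- function(o) o$labels[o$labels != "trnL2"]
  expect_equal(drop_l2(arth), drop_l2(panc))
  expect_true(check_adjacency(panc, c("cox1", "trnL2", "cox2")))
  expect_false(check_adjacency(arth, c("cox1", "trnL2", "cox2")))
  # the arthropod N-strand block reads rrnL-trnL1-trnL2-nad1 in
  # transcription direction
  expect_true(check_adjacency(arth, c("rrnL", "trnL1", "trnL2", "nad1")))
})

test_that("adjacency checks are circular, direction-tolerant and spacer-blind", {
  ord <- extract_signed_order(read_fixture())
  expect_true(check_adjacency(ord, c("cox1", "cox2")))
  expect_false(check_adjacency(ord, c("cox1", "trnL2", "cox2")))
  # trnD -> atp8 have a 1-nt spacer but still count as adjacent
  expect_true(check_adjacency(ord, c("trnD", "atp8")))
  # circular wrap: trnC (last) abuts cox1 (first)
  expect_true(check_adjacency(ord, c("trnC", "cox1")))
  # reverse reading accepted unless strand_sensitive
  expect_true(check_adjacency(ord, c("cox2", "cox1")))
  expect_false(check_adjacency(ord, c("cox2", "cox1"), strand_sensitive = TRUE))
  expect_warning(res <- check_adjacency(ord, c("cox1", "trnX9")), "absent")
  expect_false(res)
})

test_that("trnL2 pattern classification separates the three junction states", {
  expect_equal(classify_trnl2_pattern(
    extract_signed_order(read_fixture()))$classification,
    "ancestral_arthropod")
  expect_equal(classify_trnl2_pattern(
    ground_pattern("pancrustacean"))$classification, "pancrustacean")
  # relocating trnL2 next to trnK breaks both patterns
  moved <- apply_events(ground_pattern("pancrustacean"),
                        list(event_translocation("trnL2", after = "trnK")))
  expect_equal(classify_trnl2_pattern(moved$order)$classification, "other")
  # junction-only record: cox1 + cox2 alone classifies on that junction
  two <- signed_gene_order(c("cox1", "cox2"), c("J", "J"))
  cl <- classify_trnl2_pattern(two)
  expect_equal(cl$classification, "ancestral_arthropod")
  expect_true(cl$junctions$cox1_cox2)
  expect_false(cl$junctions$cox1_trnL2_cox2)
  expect_true(is.na(cl$junctions$rrnL_trnL1_nad1))
})

test_that("pancrustacean-style synthetic orders keep their classification unless the junction is touched", {
  set.seed(21)
  for (i in 1:20) {
    base <- ground_pattern("pancrustacean")
    # random event away from the cox1/trnL2/cox2 junction
    repeat {
      blk <- random_block(base, sample(2:5, 1))
      if (!any(c("cox1", "cox2", "trnL2") %in% blk)) break
    }
    kind <- sample(c("inversion", "translocation"), 1)
    ev <- if (kind == "inversion") event_inversion(blk) else {
      repeat {
        dest <- sample(setdiff(base$labels, c(blk, "cox1", "trnL2")), 1)
        if (!dest %in% blk) break
      }
      event_translocation(blk, after = dest)
    }
    out <- apply_events(base, list(ev), seed = i)
    expect_equal(classify_trnl2_pattern(out$order)$classification,
                 "pancrustacean")
  }
})

test_that("breakpoint counts match hand-enumerated adjacencies", {
  ord <- extract_signed_order(read_fixture())
  expect_equal(breakpoint_count(ord, ord), 0L)
  # toy circle (a,b,c,d) vs (a,c,b,d): exhaustive listing gives 3
  r <- signed_gene_order(letters[1:4], "J", anchor = "a")
  o <- signed_gene_order(c("a", "c", "b", "d"), "J", anchor = "a")
  expect_equal(breakpoint_count(o, r), 3L)
  # a single inverted block of length k >= 2 creates exactly 2 breakpoints
  set.seed(8)
  for (i in 1:10) {
    base <- ground_pattern("arthropod")
    blk <- random_block(base, sample(2:6, 1))
    out <- apply_events(base, list(event_inversion(blk)), seed = i)
    expect_equal(breakpoint_count(out$order, base), 2L)
  }
  # symmetry and zero-iff-rotation-equal
  set.seed(9)
  for (i in 1:10) {
    base <- ground_pattern("pancrustacean")
    blk <- random_block(base, 2)
    dest <- sample(setdiff(base$labels, c(blk, "cox1")), 1)
    out <- apply_events(base, list(event_translocation(blk, after = dest)),
                        seed = i)
    expect_equal(breakpoint_count(out$order, base),
                 breakpoint_count(base, out$order))
    expect_equal(breakpoint_count(out$order, base) == 0L,
                 order_equal(out$order, base))
  }
  expect_error(breakpoint_count(r, signed_gene_order(letters[2:5], "J")),
               "label sets")
})

test_that("inverted blocks and strand flips are separated as in the proturan order", {
  ord <- extract_signed_order(read_fixture())
  arth <- ground_pattern("arthropod")
  inv <- find_inverted_blocks(ord, arth)
  blocks <- lapply(inv$blocks, sort)
  expect_true(list(sort(c("rrnS", "trnV", "rrnL"))) %in% blocks ||
                any(vapply(blocks, identical, TRUE,
                           sort(c("rrnS", "trnV", "rrnL")))))
  expect_true(any(vapply(blocks, identical, TRUE, "nad1")))
  # trnL1/trnL2 kept their relative reading order, so they are strand
  # flips, not a clean inversion
  expect_setequal(intersect(inv$strand_flips, c("trnL1", "trnL2")),
                  c("trnL1", "trnL2"))
  # reference vs reference: nothing
  self <- find_inverted_blocks(arth, arth)
  expect_length(self$blocks, 0)
  expect_length(self$strand_flips, 0)
  # toy: (a, -d, -c, -b, e) vs (a..e) recovers the b..d block
  r5 <- signed_gene_order(letters[1:5], "J", anchor = "a")
  o5 <- signed_gene_order(c("a", "d", "c", "b", "e"),
                          c("J", "N", "N", "N", "J"), anchor = "a")
  i5 <- find_inverted_blocks(o5, r5)
  expect_length(i5$blocks, 1)
  expect_setequal(i5$blocks[[1]], c("b", "c", "d"))
})

test_that("applied inversions are recovered exactly when blocks stand alone", {
  set.seed(31)
  for (i in 1:25) {
    base <- ground_pattern(sample(c("arthropod", "pancrustacean"), 1))
    blk <- random_block(base, sample(1:6, 1))
    out <- apply_events(base, list(event_inversion(blk)), seed = i)
    inv <- find_inverted_blocks(out$order, base)
    expect_length(inv$blocks, 1)
    expect_setequal(inv$blocks[[1]], blk)
  }
})

test_that("one-step TDRL feasibility matches the duplication-loss enumeration oracle", {
  # the proturan trnI..trnY reshuffle, with its published witness
  ref <- c("trnI", "trnQ", "trnM", "nad2", "trnW", "trnC", "trnY")
  ors <- c("J", "N", "J", "J", "J", "N", "N")
  obs <- c("trnI", "nad2", "trnY", "trnQ", "trnM", "trnW", "trnC")
  obs_or <- ors[match(obs, ref)]
  td <- tdrl_feasible(ref, obs, ors, obs_or)
  expect_true(td$feasible)
  expect_equal(td$index_sequence, c(1L, 4L, 7L, 2L, 3L, 5L, 6L))
  expect_equal(td$witness$copy1, c("trnI", "nad2", "trnY"))
  expect_equal(td$witness$copy2, c("trnQ", "trnM", "trnW", "trnC"))

  # identity is trivially feasible with an empty second copy
  td0 <- tdrl_feasible(letters[1:4], letters[1:4])
  expect_true(td0$feasible)
  expect_length(td0$witness$copy2, 0)

  # full reversal needs three descents' worth of disorder
  expect_false(tdrl_feasible(c("a", "b", "c"), c("c", "b", "a"))$feasible)

  # orientation mismatch is refused outright
  tdo <- tdrl_feasible(c("a", "b"), c("a", "b"),
                       reference_orientation = c("J", "J"),
                       observed_orientation = c("J", "N"))
  expect_false(tdo$feasible)
  expect_match(tdo$reason, "orientation")

  expect_error(tdrl_feasible(c("a", "b"), c("a", "c")), "label sets")

  # oracle agreement over every permutation of n <= 7
  for (n in 1:7) {
    feasible_set <- tdrl_outcomes_bruteforce(n)
    labs <- letters[1:n]
    for (p in all_perms(n)) {
      got <- tdrl_feasible(labs, labs[p])$feasible
      expect_identical(got, paste(p, collapse = ",") %in% feasible_set,
                       label = sprintf("n=%d perm=%s", n,
                                       paste(p, collapse = "")))
    }
  }
})

test_that("feasibility is closed under contiguous sub-blocks of the witness", {
  set.seed(13)
  labs <- letters[1:7]
  for (i in 1:30) {
    # draw a guaranteed one-step TDRL outcome: retained copy-1 genes in
    # order, then retained copy-2 genes in order
    keep1 <- sort(sample(7, sample(0:7, 1)))
    p <- c(keep1, setdiff(1:7, keep1))
    td <- tdrl_feasible(labs, labs[p])
    expect_true(td$feasible)
    for (len in 2:6) for (s in 1:(7 - len + 1)) {
      sub_obs <- labs[p][s:(s + len - 1)]
      sub_ref <- labs[sort(match(sub_obs, labs))]
      expect_true(tdrl_feasible(sub_ref, sub_obs)$feasible)
    }
  }
})

test_that("compare_orders assembles the full rearrangement report", {
  ord <- extract_signed_order(read_fixture())
  arth <- ground_pattern("arthropod")
  rep <- compare_orders(ord, arth,
                        tdrl_blocks = list(c("trnI", "trnQ", "trnM", "nad2",
                                             "trnW", "trnC", "trnY")))
  expect_s3_class(rep, "rearrangement_report")
  expect_gt(rep$breakpoints, 0)
  expect_true(rep$tdrl_results[[1]]$feasible)
  # every gene the displacement scan names fails neighbor conservation
  expect_true(all(c("trnF", "trnP", "rrnS", "rrnL", "nad1") %in%
                    rep$displaced))
})
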