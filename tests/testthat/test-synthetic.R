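# Synthetic-data generator: events, genome emission, tRNA emission,
# determinism and end-to-end recovery.

test_that("rearrangement events transform orders as defined", {
  arth <- ground_pattern("arthropod")
  # inversion of the ribosomal block flips order and orientation
  blk <- c("nad1", "trnL2", "trnL1", "rrnL", "trnV", "rrnS")
  out <- apply_events(arth, list(event_inversion(blk)))
  i <- match("rrnS", out$order$labels)
  got <- out$order$labels[i:(i + 5)]
  expect_equal(got, rev(blk))
  expect_true(all(out$order$orientation[i:(i + 5)] == "J"))   # N -> J

  # TDRL with an explicit retention mask reproduces the proturan fragment
  panc <- ground_pattern("pancrustacean")
  tblk <- c("trnI", "trnQ", "trnM", "nad2", "trnW", "trnC", "trnY")
  mask <- c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE)
  out2 <- apply_events(panc, list(event_tdrl(tblk, loss_mask = mask)))
  j <- match("trnI", out2$order$labels)
  frag <- out2$order$labels[j:(j + 6)]
  expect_equal(frag, c("trnI", "nad2", "trnY", "trnQ", "trnM", "trnW",
                       "trnC"))

  # empty event list leaves the pattern unchanged
  expect_true(order_equal(apply_events(arth, list())$order, arth))

  # events on non-contiguous blocks are refused
  expect_error(apply_events(arth, list(event_inversion(c("cox1", "cox3")))),
               "contiguous")

  # the log records every event with its context
  expect_length(out2$log, 1)
  expect_equal(out2$log[[1]]$kind, "tdrl")
})

test_that("emitted genomes validate cleanly and carry their ground truth", {
  for (seed in c(1, 23)) {
    g <- emit_genome(genome_spec(seed = seed))
    expect_equal(nrow(validate_annotation(g$annotation)), 0L)
    ord <- extract_signed_order(g$annotation)
    expect_equal(ord$labels, g$truth$order$labels)
    expect_equal(ord$orientation, g$truth$order$orientation)
    # control region truth coordinates hold a real repeat array
    cr <- g$truth$control_region
    win <- substr(g$annotation$sequence, cr$array_start, cr$array_end)
    expect_equal(nchar(win), round(cr$copies * cr$period))
    expect_equal(substr(win, 1, cr$period), cr$unit)
  }
})

test_that("emission is byte-identical for identical spec and seed", {
  a <- emit_genome(genome_spec(seed = 77))
  b <- emit_genome(genome_spec(seed = 77))
  expect_identical(a$annotation$sequence, b$annotation$sequence)
  expect_identical(a$annotation$genes, b$annotation$genes)
  expect_identical(a$truth, b$truth)
  c <- emit_genome(genome_spec(seed = 78))
  expect_false(identical(a$annotation$sequence, c$annotation$sequence))

  t1 <- emit_trna(seed = 5)
  t2 <- emit_trna(seed = 5)
  expect_identical(t1, t2)

  dir <- withr::local_tempdir()
  p1 <- write_genome_files(a, file.path(dir, "a"))
  p2 <- write_genome_files(b, file.path(dir, "b"))
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
})

test_that("skew targets are recovered within binomial tolerance", {
  g <- emit_genome(genome_spec(seed = 2))
  tab <- per_gene_composition(g$annotation)
  wg <- tab[tab$region == "whole_genome", ]
  L <- g$annotation$genome_length
  target <- skew_stats(c(A = 0.252, C = 0.073, G = 0.151, T = 0.524))
  expect_lt(abs(wg$at_skew - target$at_skew), 3 / sqrt(L))
  expect_lt(abs(wg$gc_skew - target$gc_skew), 3 / sqrt(L))
  expect_lt(abs(wg$at_content - target$at_content), 3 / sqrt(L))
})

test_that("incomplete stop codons and codon termini are written as declared", {
  g <- emit_genome(genome_spec(incomplete_stops = c(cox2 = "T", nad4 = "TA"),
                               seed = 31))
  ann <- g$annotation
  row <- ann$genes[ann$genes$label == "cox2", ]
  expect_equal(row$stop_codon, "T--")
  cds <- substr(ann$sequence, row$start, row$end)
  if (row$strand == "N") cds <- revcomp(cds)
  expect_true(substr(cds, 1, 2) == "AT")          # ATN start
  expect_equal(substr(cds, nchar(cds), nchar(cds)), "T")
  expect_equal(codon_usage(cds)$partial, "T")
  row2 <- ann$genes[ann$genes$label == "nad4", ]
  expect_equal(row2$stop_codon, "TA-")
})

test_that("single injected events are identified by the order analysis", {
  set.seed(123)
  n_inv <- 0L; inv_ok <- 0L
  n_tra <- 0L; tra_ok <- 0L
  n_tdrl <- 0L; tdrl_ok <- 0L
  for (i in 1:50) {
    base_name <- sample(c("arthropod", "pancrustacean"), 1)
    base <- ground_pattern(base_name)
    kind <- sample(c("inversion", "translocation", "tdrl"), 1)
    blk <- random_block(base, sample(2:6, 1))
    if (kind == "inversion") {
      out <- apply_events(base, list(event_inversion(blk)), seed = i)
      inv <- find_inverted_blocks(out$order, base)
      n_inv <- n_inv + 1L
      if (any(vapply(inv$blocks, setequal, TRUE, blk))) inv_ok <- inv_ok + 1L
    } else if (kind == "translocation") {
      dest <- sample(setdiff(base$labels, c(blk, "cox1")), 1)
      out <- apply_events(base, list(event_translocation(blk, after = dest)),
                          seed = i)
      if (order_equal(out$order, base)) next   # destination was a no-op
      n_tra <- n_tra + 1L
      # a clean block translocation severs exactly three junctions; the
      # block edges lose a neighbor while interior members keep both
      disp <- displaced_genes(out$order, base)
      edges <- blk[c(1, length(blk))]
      if (breakpoint_count(out$order, base) == 3L && all(edges %in% disp) &&
            length(find_inverted_blocks(out$order, base)$blocks) == 0L)
        tra_ok <- tra_ok + 1L
    } else {
      out <- apply_events(base, list(event_tdrl(blk)), seed = i)
      n_tdrl <- n_tdrl + 1L
      obs <- mitoarch:::.subset_order(out$order, blk)
      ref <- mitoarch:::.subset_order(base, blk)
      if (tdrl_feasible(ref, obs)$feasible) tdrl_ok <- tdrl_ok + 1L
    }
  }
  # inversions and translocations must always be seen; TDRL-generated
  # orders must always test feasible
  expect_equal(inv_ok, n_inv)
  expect_equal(tra_ok, n_tra)
  expect_equal(tdrl_ok, n_tdrl)
})

test_that("emitted tRNAs match their declared structure and length classes", {
  full <- emit_trna(seed = 3)
  expect_true(nchar(full$sequence) >= 68 && nchar(full$sequence) <= 75)
  ch <- strsplit(full$sequence, "", fixed = TRUE)[[1]]
  comp_ok <- c("AT", "TA", "GC", "CG")
  for (r in seq_len(nrow(full$truth$pairs))) {
    pr <- paste0(ch[full$truth$pairs[r, 1]], ch[full$truth$pairs[r, 2]])
    expect_true(pr %in% comp_ok)
  }
  not <- emit_trna(c("acceptor", "D", "anticodon"), seed = 4)
  expect_lt(nchar(not$sequence), 60)   # truncated layouts run ~54 nt
  expect_error(emit_trna(c("acceptor", "D"), seed = 1), "mandatory")
})
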