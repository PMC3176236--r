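# Seeded synthetic-data generator. Every emitted object carries full ground
# truth so each analysis stage is verifiable offline. One RNG seed per spec;
# components draw from sub-streams derived by fixed offsets, so adding a
# component never perturbs the draws of another.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded generation never perturbs
#' the caller's RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Random nucleotide sequence at target frequencies
#'
#' @param n length.
#' @param freqs named probabilities for A, C, G, T (normalized internally).
#' @return nucleotide string. Uses the current RNG state.
#' @export
rand_seq <- function(n, freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(all(c("A", "C", "G", "T") %in% names(freqs)))
  p <- as.numeric(freqs[c("A", "C", "G", "T")])
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p / sum(p)),
        collapse = "")
}

# ---------------------------------------------------------------------------
# rearrangement events

#' Rearrangement event constructors
#'
#' Build event records for [apply_events()]: block translocation (optionally
#' inverting), block inversion, one-step tandem duplication random loss with
#' an explicit or random loss mask, strand flip, and control-region
#' relocation.
#'
#' @param block character vector of labels, contiguous (in reading order) in
#'   the order the event is applied to; for `event_strand_flip` any labels.
#' @param after label after which the block (or control region) is
#'   reinserted, in J-direction reading.
#' @param invert also invert the translocated block.
#' @param loss_mask logical vector along `block`: `TRUE` keeps the gene's
#'   first (ancestral-position) copy, `FALSE` the second; `NULL` draws a
#'   random mask when the event is applied.
#' @return a list of class `rearrangement_event`.
#' @export
event_translocation <- function(block, after, invert = FALSE) {
  structure(list(kind = "translocation", block = block, after = after,
                 invert = isTRUE(invert)), class = "rearrangement_event")
}

#' @rdname event_translocation
#' @export
event_inversion <- function(block) {
  structure(list(kind = "inversion", block = block),
            class = "rearrangement_event")
}

#' @rdname event_translocation
#' @export
event_tdrl <- function(block, loss_mask = NULL) {
  if (!is.null(loss_mask)) stopifnot(length(loss_mask) == length(block))
  structure(list(kind = "tdrl", block = block, loss_mask = loss_mask),
            class = "rearrangement_event")
}

#' @rdname event_translocation
#' @export
event_strand_flip <- function(block) {
  structure(list(kind = "strand_flip", block = block),
            class = "rearrangement_event")
}

#' @rdname event_translocation
#' @export
event_cr_relocation <- function(after) {
  structure(list(kind = "cr_relocation", after = after),
            class = "rearrangement_event")
}

# indices of `block` in order, verified contiguous in reading order
.block_indices <- function(order, block) {
  n <- length(order$labels)
  i0 <- match(block[1], order$labels)
  if (is.na(i0)) stop("block gene absent: ", block[1])
  idx <- ((i0 - 1L + seq_along(block) - 1L) %% n) + 1L
  if (!all(order$labels[idx] == block))
    stop("block not contiguous in the current order: ",
         paste(block, collapse = ", "))
  idx
}

#' Apply rearrangement events to a signed gene order
#'
#' Events are applied in sequence to the evolving order. A TDRL event with
#' an explicit loss mask is deterministic; a `NULL` mask is drawn from the
#' RNG seeded with `seed`. The returned log records each event with the
#' before/after adjacency context of the affected block.
#'
#' @param pattern a [signed_gene_order()] or a [ground_pattern()] name.
#' @param events list of events from the `event_*()` constructors.
#' @param seed integer seed (used only for random TDRL masks).
#' @return list with `order` (the rearranged [signed_gene_order()]),
#'   `cr_after` (label preceding the control region, when tracked) and
#'   `log` (one record per event).
#' @export
#' @examples
#' ev <- event_inversion(c("nad1", "trnL2", "trnL1", "rrnL", "trnV", "rrnS"))
#' apply_events(ground_pattern("arthropod"), list(ev), seed = 1)$order
apply_events <- function(pattern, events = list(), seed = 1L) {
  order <- if (inherits(pattern, "signed_gene_order")) pattern
           else ground_pattern(pattern)
  cr_after <- attr(order, "cr_after")
  if (is.null(cr_after)) cr_after <- "rrnS"   # ancestral CR position
  log <- list()
  with_seed(seed, {
    for (ev in events) {
      stopifnot(inherits(ev, "rearrangement_event"))
      before <- format(order)
      if (ev$kind == "cr_relocation") {
        if (!ev$after %in% order$labels) stop("unknown gene: ", ev$after)
        cr_after <- ev$after
      } else if (ev$kind == "strand_flip") {
        idx <- match(ev$block, order$labels)
        if (anyNA(idx)) stop("unknown gene(s) in strand_flip")
        order$orientation[idx] <- ifelse(order$orientation[idx] == "J",
                                         "N", "J")
      } else {
        idx <- .block_indices(order, ev$block)
        if (ev$kind == "inversion") {
          order$labels[idx] <- rev(order$labels[idx])
          order$orientation[idx] <-
            ifelse(rev(order$orientation[idx]) == "J", "N", "J")
        } else if (ev$kind == "translocation") {
          labs <- order$labels[idx]; ors <- order$orientation[idx]
          if (ev$invert) { labs <- rev(labs); ors <- ifelse(rev(ors) == "J", "N", "J") }
          keep <- setdiff(seq_along(order$labels), idx)
          l2 <- order$labels[keep]; o2 <- order$orientation[keep]
          at <- match(ev$after, l2)
          if (is.na(at)) stop("destination gene absent or inside block: ",
                              ev$after)
          order$labels <- append(l2, labs, after = at)
          order$orientation <- append(o2, ors, after = at)
        } else if (ev$kind == "tdrl") {
          mask <- ev$loss_mask
          if (is.null(mask))
            mask <- sample(c(TRUE, FALSE), length(idx), replace = TRUE)
          new_idx <- c(idx[mask], idx[!mask])
          order$labels[idx] <- order$labels[new_idx]
          order$orientation[idx] <- order$orientation[new_idx]
          ev$loss_mask <- mask
        } else stop("unknown event kind: ", ev$kind)
      }
      log[[length(log) + 1]] <- list(kind = ev$kind, event = ev,
                                     before = before, after = format(order))
    }
  })
  order <- canonicalize_order(order)
  list(order = order, cr_after = cr_after, log = log)
}

# ---------------------------------------------------------------------------
# genome emission

# default per-gene lengths (nucleotides), realistic for a compact ~14.5 kb
# arthropod mitogenome with strongly reduced tRNAs
.default_gene_lengths <- c(
  cox1 = 1532L, cox2 = 652L, trnK = 62L, trnD = 55L, atp8 = 146L,
  atp6 = 647L, cox3 = 783L, trnG = 55L, nad3 = 339L, trnA = 53L,
  trnR = 54L, trnN = 59L, trnF = 56L, trnS1 = 55L, trnE = 55L,
  nad5 = 1599L, trnH = 53L, nad4 = 1282L, nad4L = 278L, trnT = 54L,
  nad6 = 420L, cob = 1098L, trnS2 = 62L, rrnS = 690L, trnV = 53L,
  rrnL = 996L, trnL2 = 55L, trnL1 = 55L, nad1 = 892L, trnP = 55L,
  trnI = 57L, nad2 = 894L, trnY = 57L, trnQ = 66L, trnM = 56L,
  trnW = 68L, trnC = 54L)

#' Specify a synthetic mitogenome
#'
#' Defaults emulate the study conditions of a compact, extremely AT-rich
#' proturan-like mitogenome: J-strand frequencies T 0.524, A 0.252, G 0.151,
#' C 0.073 (AT-skew -0.351), realistic per-gene lengths, and a control
#' region carrying a 10-bp tandem repeat in 11 exact copies.
#'
#' @param base_pattern [ground_pattern()] name or a `signed_gene_order`.
#' @param events list of `event_*()` records applied to the base pattern.
#' @param gene_lengths named vector overriding default per-gene lengths.
#' @param frequencies genome-wide J-strand A/C/G/T proportions.
#' @param gene_frequencies optional named list of per-gene frequency
#'   vectors overriding `frequencies`.
#' @param control_region list with `unit`, `copies` (fractional),
#'   `substitution_rate` (per site across the array), `flank` (two
#'   integers: non-repetitive padding inside the control region).
#' @param incomplete_stops named character vector mapping PCG labels to
#'   `"T"` or `"TA"` for incomplete (polyadenylation-completed) stop codons.
#' @param seed integer RNG seed.
#' @return list of class `genome_spec`.
#' @export
genome_spec <- function(base_pattern = "pancrustacean", events = list(),
                        gene_lengths = NULL,
                        frequencies = c(A = 0.252, C = 0.073,
                                        G = 0.151, T = 0.524),
                        gene_frequencies = NULL,
                        control_region = list(unit = "TTTTGTTAAA",
                                              copies = 11,
                                              substitution_rate = 0,
                                              flank = c(30L, 30L)),
                        incomplete_stops = NULL,
                        seed = 1L) {
  lens <- .default_gene_lengths
  if (!is.null(gene_lengths)) lens[names(gene_lengths)] <- gene_lengths
  stopifnot(all(lens >= 1))
  p <- as.numeric(frequencies[c("A", "C", "G", "T")])
  if (abs(sum(p) - 1) > 1e-9) stop("frequencies must sum to 1")
  structure(list(base_pattern = base_pattern, events = events,
                 gene_lengths = lens, frequencies = frequencies,
                 gene_frequencies = gene_frequencies,
                 control_region = control_region,
                 incomplete_stops = incomplete_stops, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Build a tandem repeat array string with ground truth
#'
#' `copies` full units plus a trailing partial copy rounded from the
#' fractional part; substitutions drawn per site at `substitution_rate`
#' (always to a different base). Uses the current RNG state.
#'
#' @param unit repeat unit string.
#' @param copies fractional copy number (>= 2).
#' @param substitution_rate per-site substitution probability.
#' @return list with `seq`, `mutated_positions` (1-based offsets within the
#'   array), `n_full`, `partial_len`.
#' @export
build_repeat_array <- function(unit, copies, substitution_rate = 0) {
  unit <- toupper(unit)
  p <- nchar(unit)
  n_full <- floor(copies)
  partial_len <- round((copies - n_full) * p)
  arr <- paste0(strrep(unit, n_full), substr(unit, 1, partial_len))
  ch <- strsplit(arr, "", fixed = TRUE)[[1]]
  mut <- integer(0)
  if (substitution_rate > 0) {
    mut <- which(runif(length(ch)) < substitution_rate)
    for (i in mut) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  list(seq = paste(ch, collapse = ""), mutated_positions = mut,
       n_full = n_full, partial_len = partial_len)
}

#' Emit a synthetic mitogenome with full ground truth
#'
#' Applies the spec's events to the base pattern, then assembles the
#' J-strand gene by gene with multinomial draws at the target frequencies.
#' N-strand genes are placed as reverse complements of a J-frequency draw,
#' so J-strand counts match the targets in expectation. Protein-coding
#' genes receive an ATN start codon and a complete (`TAA`) or incomplete
#' (`T`/`TA`) stop on their coding strand. The control region (repeat array
#' plus AT-rich non-repetitive flanks) is inserted at the tracked
#' control-region position. Deterministic for a given spec.
#'
#' @param spec a [genome_spec()].
#' @return list with `annotation` (a [mito_annotation()] carrying the
#'   sequence) and `truth` (order, event log, control-region coordinates
#'   and mutation mask, per-gene bounds, frequencies, seed).
#' @export
emit_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  evo <- apply_events(spec$base_pattern, spec$events, seed = spec$seed + 10L)
  ord <- evo$order
  lens <- spec$gene_lengths

  genes <- list()
  seq_parts <- character(0)
  cursor <- 0L
  cr_truth <- NULL

  with_seed(spec$seed + 1L, {
    for (i in seq_along(ord$labels)) {
      lab <- ord$labels[i]
      strand <- ord$orientation[i]
      L <- lens[[lab]]
      fr <- spec$frequencies
      if (!is.null(spec$gene_frequencies) &&
            !is.null(spec$gene_frequencies[[lab]]))
        fr <- spec$gene_frequencies[[lab]]
      cls <- gene_class_of(lab)
      start_codon <- NA_character_; stop_token <- NA_character_
      if (cls == "PCG") {
        start_codon <- sample(c("ATG", "ATA", "ATT"), 1)
        stop_nt <- "TAA"; stop_token <- "TAA"
        inc <- spec$incomplete_stops
        if (!is.null(inc) && lab %in% names(inc)) {
          stop_nt <- inc[[lab]]
          stop_token <- c("T" = "T--", "TA" = "TA-")[[stop_nt]]
        }
        # draw the coding body at frequencies whose reverse complement is
        # the J-strand target, so the placed J-strand matches the target
        body_fr <- if (strand == "J") fr else
          c(A = fr[["T"]], C = fr[["G"]], G = fr[["C"]], T = fr[["A"]])
        body <- rand_seq(max(0L, L - nchar(start_codon) - nchar(stop_nt)),
                         body_fr)
        coding <- paste0(start_codon, body, stop_nt)
        jseq <- if (strand == "J") coding else revcomp(coding)
      } else {
        draw <- rand_seq(L, fr)
        jseq <- draw   # J-strand substring has target frequencies either way
      }
      genes[[length(genes) + 1]] <- data.frame(
        name = lab, start = cursor + 1L, end = cursor + L, strand = strand,
        start_codon = start_codon, stop_codon = stop_token,
        stringsAsFactors = FALSE)
      seq_parts <- c(seq_parts, jseq)
      cursor <- cursor + L

      if (lab == evo$cr_after) {
        cr <- spec$control_region
        arr <- with_seed(spec$seed + 2L,
                         build_repeat_array(cr$unit, cr$copies,
                                            cr$substitution_rate))
        flank <- rep_len(as.integer(cr$flank), 2L)
        at_rich <- c(A = 0.45, C = 0.05, G = 0.05, T = 0.45)
        f1 <- rand_seq(flank[1], at_rich)
        f2 <- rand_seq(flank[2], at_rich)
        # keep the non-repetitive flank from extending the array by chance:
        # force the bases abutting the array to break the period
        f1 <- .break_period(f1, arr$seq, nchar(cr$unit), side = "left")
        f2 <- .break_period(f2, arr$seq, nchar(cr$unit), side = "right")
        cr_seq <- paste0(f1, arr$seq, f2)
        cr_truth <- list(start = cursor + 1L,
                          end = cursor + nchar(cr_seq),
                          array_start = cursor + nchar(f1) + 1L,
                          array_end = cursor + nchar(f1) + nchar(arr$seq),
                          unit = toupper(cr$unit),
                          period = nchar(cr$unit),
                          copies = round(nchar(arr$seq) / nchar(cr$unit), 1),
                          mutated_positions = arr$mutated_positions,
                          n_full_units = arr$n_full)
        seq_parts <- c(seq_parts, cr_seq)
        cursor <- cursor + nchar(cr_seq)
      }
    }
  })

  gtab <- do.call(rbind, genes)
  gtab$declared_size <- gtab$end - gtab$start + 1L
  nxt <- c(seq_len(nrow(gtab))[-1], 1L)
  gap <- gtab$start[nxt] - gtab$end - 1L
  gap[nrow(gtab)] <- (cursor - gtab$end[nrow(gtab)]) + (gtab$start[1] - 1L)
  gtab$declared_intergenic <- gap
  ann <- mito_annotation(gtab, genome_id = sprintf("synthetic_seed%d", spec$seed),
                         genome_length = cursor, circular = TRUE,
                         sequence = paste(seq_parts, collapse = ""),
                         complete = setequal(gtab$name, mito_gene_labels()))
  truth <- list(order = list(labels = ord$labels,
                             orientation = ord$orientation),
                cr_after = evo$cr_after,
                events = evo$log,
                control_region = cr_truth,
                frequencies = as.list(spec$frequencies),
                seed = spec$seed)
  list(annotation = ann, truth = truth)
}

# mutate the three flank bases abutting the array so that the period-p
# match cannot extend across the array boundary by chance
.break_period <- function(flank, arr, p, side) {
  if (!nzchar(flank)) return(flank)
  f <- strsplit(flank, "", fixed = TRUE)[[1]]
  a <- strsplit(arr, "", fixed = TRUE)[[1]]
  for (j in seq_len(min(3L, length(f)))) {
    if (side == "left") {
      tgt <- a[p - j + 1L]              # base the period-match would need
      k <- length(f) - j + 1L
    } else {
      tgt <- a[length(a) - p + j]
      k <- j
    }
    if (f[k] == tgt) f[k] <- setdiff(c("A", "T", "G"), tgt)[1]
  }
  paste(f, collapse = "")
}

#' Write an emitted genome to files
#'
#' @param genome result of [emit_genome()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the named vector of paths written (`fasta`, `tsv`,
#'   `truth`).
#' @export
write_genome_files <- function(genome, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- genome$annotation
  paths <- c(fasta = file.path(dir, paste0(prefix, ".fasta")),
             tsv = file.path(dir, paste0(prefix, ".tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_fasta(setNames(ann$sequence, ann$genome_id), paths[["fasta"]])
  write_annotation_tsv(ann, paths[["tsv"]])
  jsonlite::write_json(genome$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

# ---------------------------------------------------------------------------
# tRNA emission

#' Emit a synthetic tRNA with known structure
#'
#' Builds a tRNA from complementary stems and random loops under a chosen
#' arm configuration. Acceptor and anticodon arms are mandatory; D and T
#' arms optional (their absence models the truncated tRNAs of highly
#' reduced mitogenomes: a T-less layout is ~54 nt). Optionally mutates
#' stem pairs to non-complementary bases.
#'
#' @param config character subset of `c("acceptor", "D", "anticodon", "T")`;
#'   must contain acceptor and anticodon.
#' @param seed integer seed (byte-identical output for identical input).
#' @param anticodon optional 3-mer placed at the anticodon position.
#' @param mutate_stem_pairs number of stem pairs to break (one random side
#'   of a randomly chosen pair is substituted).
#' @return list with `sequence`, `truth` (arm flags, layout lengths, paired
#'   positions, anticodon, mutated pair positions).
#' @export
emit_trna <- function(config = c("acceptor", "D", "anticodon", "T"),
                      seed = 1L, anticodon = NULL, mutate_stem_pairs = 0L) {
  config <- match.arg(config, several.ok = TRUE)
  if (!all(c("acceptor", "anticodon") %in% config))
    stop("acceptor and anticodon arms are mandatory")
  has_d <- "D" %in% config
  has_t <- "T" %in% config
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  with_seed(seed, {
    if (is.null(anticodon)) anticodon <- rand_seq(3)
    a <- 7L; s1 <- 2L; d <- 4L; dl <- 8L; s2 <- 1L; cc <- 5L
    v <- 4L; t <- 5L; tl <- 7L; tail <- 0L
    mk_stem <- function(len) {
      five <- strsplit(rand_seq(len), "", fixed = TRUE)[[1]]
      list(five = five, three = rev(unname(comp[five])))
    }
    acc <- mk_stem(a); dst <- if (has_d) mk_stem(d)
    ast <- mk_stem(cc); tst <- if (has_t) mk_stem(t)
    loop_freq <- c(A = 0.35, C = 0.1, G = 0.1, T = 0.45)
    parts <- c(paste(acc$five, collapse = ""), rand_seq(s1, loop_freq))
    pairs <- NULL
    pos <- a + s1
    if (has_d) {
      parts <- c(parts, paste(dst$five, collapse = ""),
                 rand_seq(dl, loop_freq), paste(dst$three, collapse = ""))
      pairs <- rbind(pairs, cbind(pos + seq_len(d),
                                  pos + 2L * d + dl + 1L - seq_len(d)))
      pos <- pos + 2L * d + dl
      parts <- c(parts, rand_seq(s2, loop_freq))
      pos <- pos + s2
    }
    acl <- paste0(rand_seq(2, loop_freq), anticodon, rand_seq(2, loop_freq))
    parts <- c(parts, paste(ast$five, collapse = ""), acl,
               paste(ast$three, collapse = ""))
    pairs <- rbind(pairs, cbind(pos + seq_len(cc),
                                pos + 2L * cc + 7L + 1L - seq_len(cc)))
    pos <- pos + 2L * cc + 7L
    parts <- c(parts, rand_seq(v, loop_freq))
    pos <- pos + v
    if (has_t) {
      parts <- c(parts, paste(tst$five, collapse = ""),
                 rand_seq(tl, loop_freq), paste(tst$three, collapse = ""))
      pairs <- rbind(pairs, cbind(pos + seq_len(t),
                                  pos + 2L * t + tl + 1L - seq_len(t)))
      pos <- pos + 2L * t + tl
    }
    parts <- c(parts, paste(acc$three, collapse = ""),
               if (tail > 0) rand_seq(tail, loop_freq))
    seqs <- paste(parts, collapse = "")
    n <- nchar(seqs)
    pairs <- rbind(cbind(seq_len(a), n - tail + 1L - seq_len(a)), pairs)

    mutated <- NULL
    if (mutate_stem_pairs > 0) {
      ch <- strsplit(seqs, "", fixed = TRUE)[[1]]
      rows <- sample(nrow(pairs), min(mutate_stem_pairs, nrow(pairs)))
      for (r in rows) {
        side <- pairs[r, sample(2, 1)]
        partner <- setdiff(pairs[r, ], side)
        # pick a base that pairs with neither partner base (no WC, no GU)
        bad <- switch(ch[partner],
                      A = c("A", "C", "G"), T = c("C", "T"),
                      G = c("A", "G"),      C = c("A", "C", "T"),
                      c("A", "C", "G", "T"))
        bad <- setdiff(bad, ch[side])
        if (length(bad)) ch[side] <- sample(bad, 1)
        mutated <- rbind(mutated, pairs[r, , drop = FALSE])
      }
      seqs <- paste(ch, collapse = "")
    }
    list(sequence = seqs,
         truth = list(arms = c(acceptor = TRUE, D = has_d,
                               anticodon = TRUE, T = has_t),
                      layout = c(acceptor = a, tail = tail, spacer1 = s1,
                                 d_stem = if (has_d) d else 0L,
                                 d_loop = if (has_d) dl else 0L,
                                 spacer2 = if (has_d) s2 else 0L,
                                 ac_stem = cc, variable = v,
                                 t_stem = if (has_t) t else 0L,
                                 t_loop = if (has_t) tl else 0L),
                      pairs = pairs, anticodon = toupper(anticodon),
                      mutated_pairs = mutated))
  })
}
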