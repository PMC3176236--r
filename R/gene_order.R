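# Signed circular gene orders and their comparison: junction (adjacency)
# checks, trnL2 pattern classification, breakpoint counts, inverted-block
# detection, and the one-step tandem-duplication-random-loss (TDRL)
# feasibility test.
#
# Orders are read along the J-strand (ascending coordinates); orientation J
# means the gene is transcribed from the J-strand, N from the opposite
# strand. The clade ground patterns are stored in the same J-direction
# reading: pattern strings quoted in transcription direction for N-strand
# blocks (e.g. "rrnL-trnL1-trnL2-nad1") appear reversed here
# (nad1, trnL2, trnL1, rrnL; all N).

#' Construct a signed circular gene order
#'
#' @param labels character vector of canonical gene labels (unique).
#' @param orientation vector of `"J"`/`"N"` (or `"+"`/`"-"`), recycled if
#'   length 1.
#' @param anchor label rotated to the front when present (default `cox1`);
#'   if the anchor sits on the N strand the circle is reflected (reversed
#'   and strand-flipped) so the anchor reads J, giving a canonical
#'   representation independent of which strand was called majority.
#' @return object of class `signed_gene_order`.
#' @export
signed_gene_order <- function(labels, orientation = "J", anchor = "cox1") {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop("duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  orientation <- .norm_strand(rep_len(orientation, length(labels)))
  x <- structure(list(labels = labels, orientation = orientation,
                      anchor = anchor),
                 class = "signed_gene_order")
  canonicalize_order(x)
}

#' Canonical rotation of a signed gene order
#'
#' @param x a `signed_gene_order`.
#' @return the same circle rotated so the anchor is first (and reflected so
#'   the anchor reads J); unchanged when the anchor is absent.
#' @export
canonicalize_order <- function(x) {
  stopifnot(inherits(x, "signed_gene_order"))
  i <- match(x$anchor, x$labels)
  if (is.na(i)) return(x)
  n <- length(x$labels)
  idx <- ((seq_len(n) + i - 2L) %% n) + 1L
  x$labels <- x$labels[idx]
  x$orientation <- x$orientation[idx]
  if (x$orientation[1] == "N") {
    # reflect: reverse reading direction and flip every orientation
    x$labels <- c(x$labels[1], rev(x$labels[-1]))
    x$orientation <- ifelse(c(x$orientation[1], rev(x$orientation[-1])) == "J",
                            "N", "J")
  }
  x
}

#' @export
print.signed_gene_order <- function(x, ...) {
  s <- paste0(ifelse(x$orientation == "N", "-", ""), x$labels)
  cat(sprintf("signed_gene_order (%d genes, circular):\n", length(x$labels)))
  cat(" ", paste(s, collapse = " "), "\n")
  invisible(x)
}

#' @export
format.signed_gene_order <- function(x, ...) {
  paste(paste0(ifelse(x$orientation == "N", "-", ""), x$labels),
        collapse = " ")
}

#' Rotation-invariant equality of signed circular orders
#'
#' @param a,b `signed_gene_order` objects.
#' @return `TRUE` iff some rotation of `b` matches `a` in both labels and
#'   orientations.
#' @export
order_equal <- function(a, b) {
  stopifnot(inherits(a, "signed_gene_order"), inherits(b, "signed_gene_order"))
  n <- length(a$labels)
  if (n != length(b$labels)) return(FALSE)
  if (n == 0) return(TRUE)
  for (r in seq_len(n)) {
    idx <- ((seq_len(n) + r - 2L) %% n) + 1L
    if (all(a$labels == b$labels[idx]) &&
        all(a$orientation == b$orientation[idx])) return(TRUE)
  }
  FALSE
}

#' Clade ground patterns of the arthropod mitogenome
#'
#' The inferred ancestral arthropod gene order (as in the horseshoe crab
#' *Limulus polyphemus*) and the pancrustacean ground pattern, which differs
#' only in the placement of `trnL2`: between `cox1` and `cox2` (J strand) in
#' Pancrustacea versus inside the N-strand block read
#' `rrnL-trnL1-trnL2-nad1` in transcription direction (J-direction reading:
#' `nad1, trnL2, trnL1, rrnL`) in the arthropod pattern. The control region
#' is not a gene and is excluded.
#'
#' @param name `"arthropod"` or `"pancrustacean"`.
#' @return a [signed_gene_order()] over the 37 canonical labels.
#' @export
ground_pattern <- function(name = c("arthropod", "pancrustacean")) {
  name <- match.arg(name)
  base <- list(
    c("cox1",  "J"), c("cox2",  "J"), c("trnK",  "J"), c("trnD",  "J"),
    c("atp8",  "J"), c("atp6",  "J"), c("cox3",  "J"), c("trnG",  "J"),
    c("nad3",  "J"), c("trnA",  "J"), c("trnR",  "J"), c("trnN",  "J"),
    c("trnS1", "J"), c("trnE",  "J"), c("trnF",  "N"), c("nad5",  "N"),
    c("trnH",  "N"), c("nad4",  "N"), c("nad4L", "N"), c("trnT",  "J"),
    c("trnP",  "N"), c("nad6",  "J"), c("cob",   "J"), c("trnS2", "J"),
    c("nad1",  "N"), c("trnL1", "N"), c("rrnL",  "N"), c("trnV",  "N"),
    c("rrnS",  "N"), c("trnI",  "J"), c("trnQ",  "N"), c("trnM",  "J"),
    c("nad2",  "J"), c("trnW",  "J"), c("trnC",  "N"), c("trnY",  "N"))
  labels <- vapply(base, `[`, "", 1)
  orient <- vapply(base, `[`, "", 2)
  if (name == "arthropod") {
    # trnL2 inside the N-strand ribosomal block: nad1, trnL2, trnL1, rrnL
    i <- match("nad1", labels)
    labels <- append(labels, "trnL2", after = i)
    orient <- append(orient, "N", after = i)
  } else {
    # trnL2 between cox1 and cox2, J strand
    labels <- append(labels, "trnL2", after = 1L)
    orient <- append(orient, "J", after = 1L)
  }
  signed_gene_order(labels, orient)
}

#' Extract the signed gene order from an annotation
#'
#' Genes in ascending start order along the J-strand, orientation taken from
#' the annotated strand, anchored at `cox1` when present.
#'
#' @param ann a [mito_annotation()].
#' @param anchor anchor label passed to [signed_gene_order()].
#' @return a [signed_gene_order()].
#' @export
extract_signed_order <- function(ann, anchor = "cox1") {
  stopifnot(inherits(ann, "mito_annotation"))
  g <- ann$genes
  if (anyNA(g$label))
    stop("annotation contains unmappable labels: ",
         paste(g$name[is.na(g$label)], collapse = ", "))
  signed_gene_order(g$label, g$strand, anchor = anchor)
}

#' Adjacency (junction) check on a circular order
#'
#' Tests whether `labels` occur consecutively on the circle with no
#' intervening gene. Non-coding spacers are invisible at this level, so a
#' junction with a short spacer still counts as adjacent. With
#' `strand_sensitive = FALSE` (default) the run may be read in either
#' direction; orientations are ignored. Any queried label absent from the
#' order returns `FALSE` with a warning, so partial (junction-only) records
#' can be queried safely.
#'
#' @param order a [signed_gene_order()].
#' @param labels character vector (length >= 2) of canonical labels.
#' @param strand_sensitive only accept the forward (J-direction) reading.
#' @return logical flag.
#' @export
#' @examples
#' check_adjacency(ground_pattern("pancrustacean"),
#'                 c("cox1", "trnL2", "cox2"))   # TRUE
check_adjacency <- function(order, labels, strand_sensitive = FALSE) {
  stopifnot(inherits(order, "signed_gene_order"), length(labels) >= 2)
  absent <- setdiff(labels, order$labels)
  if (length(absent)) {
    warning("label(s) absent from order: ", paste(absent, collapse = ", "))
    return(FALSE)
  }
  n <- length(order$labels)
  if (length(labels) > n) return(FALSE)
  hit <- function(seq_labels) {
    k <- length(seq_labels)
    i <- match(seq_labels[1], order$labels)
    idx <- ((i - 1L + seq_len(k) - 1L) %% n) + 1L
    all(order$labels[idx] == seq_labels)
  }
  if (hit(labels)) return(TRUE)
  if (!strand_sensitive && hit(rev(labels))) return(TRUE)
  FALSE
}

#' Classify the trnL2 junction pattern of an order
#'
#' `pancrustacean` iff `cox1-trnL2-cox2` are consecutive;
#' `ancestral_arthropod` iff `cox1-cox2` are consecutive and `trnL2` (when
#' present) lies between `rrnL` and `nad1` with only leucine tRNAs
#' intervening (adjacency to `trnL1` allowed, in either reading direction);
#' `other` otherwise. Partial records carrying only the `cox1/cox2` junction
#' classify on that junction alone. The individual junction flags are
#' returned alongside the label.
#'
#' @param order a [signed_gene_order()] containing at least `cox1`, `cox2`.
#' @return list with `classification` and logical/NA `junctions` flags
#'   (`cox1_trnL2_cox2`, `cox1_cox2`, `rrnL_trnL1_nad1`,
#'   `rrnL_trnL1_trnL2_nad1`); a flag is `NA` when its non-leucine genes are
#'   absent from the record.
#' @export
classify_trnl2_pattern <- function(order) {
  stopifnot(inherits(order, "signed_gene_order"))
  has <- function(l) l %in% order$labels
  if (!has("cox1") || !has("cox2"))
    stop("order must contain cox1 and cox2")
  adj <- function(l) suppressWarnings(check_adjacency(order, l))
  j <- list(
    cox1_trnL2_cox2 = if (has("trnL2")) adj(c("cox1", "trnL2", "cox2"))
                      else FALSE,
    cox1_cox2 = adj(c("cox1", "cox2")),
    rrnL_trnL1_nad1 =
      if (has("rrnL") && has("nad1"))
        (has("trnL1") && adj(c("rrnL", "trnL1", "nad1"))) else NA,
    rrnL_trnL1_trnL2_nad1 =
      if (has("rrnL") && has("nad1"))
        (has("trnL1") && has("trnL2") &&
           (adj(c("rrnL", "trnL1", "trnL2", "nad1")) ||
              adj(c("rrnL", "trnL2", "trnL1", "nad1")))) else NA)
  cls <- "other"
  if (isTRUE(j$cox1_trnL2_cox2)) {
    cls <- "pancrustacean"
  } else if (isTRUE(j$cox1_cox2)) {
    if (!has("trnL2")) {
      cls <- "ancestral_arthropod"   # junction-only record
    } else if (has("rrnL") && has("nad1") &&
                 .between_on_arc(order, "trnL2", "rrnL", "nad1",
                                 allowed = c("trnL1", "trnL2"))) {
      cls <- "ancestral_arthropod"
    }
  }
  list(classification = cls, junctions = j)
}

# is `gene` on a circular arc between `a` and `b` whose interior contains
# only genes from `allowed`? (both arc directions are examined)
.between_on_arc <- function(order, gene, a, b, allowed) {
  n <- length(order$labels)
  ia <- match(a, order$labels); ib <- match(b, order$labels)
  if (is.na(ia) || is.na(ib)) return(FALSE)
  arc <- function(from, to) {
    if (from == to) return(character(0))
    idx <- from
    out <- integer(0)
    repeat {
      idx <- (idx %% n) + 1L
      if (idx == to) break
      out <- c(out, idx)
    }
    order$labels[out]
  }
  for (interior in list(arc(ia, ib), arc(ib, ia))) {
    if (gene %in% interior && all(interior %in% allowed)) return(TRUE)
  }
  FALSE
}

# signed circular adjacencies of an order as "x|y" strings, where each gene
# carries a sign for N orientation; the reverse-complement reading -y|-x
# denotes the same physical junction.
.signed_adjacencies <- function(order) {
  n <- length(order$labels)
  s <- ifelse(order$orientation == "N", paste0("-", order$labels),
              order$labels)
  nxt <- c(seq_len(n)[-1], 1L)
  paste(s, s[nxt], sep = "|")
}

.flip_gene <- function(x) ifelse(grepl("^-", x), sub("^-", "", x),
                                 paste0("-", x))

.adj_revcomp <- function(adj) {
  parts <- strsplit(adj, "|", fixed = TRUE)
  vapply(parts, function(p) paste(.flip_gene(p[2]), .flip_gene(p[1]),
                                  sep = "|"), "")
}

#' Breakpoint count between two signed circular orders
#'
#' Number of signed circular adjacencies of `order` absent from `reference`
#' (an adjacency matches also when its reverse-complement reading occurs).
#' Zero iff the two circles are rotation-equal; symmetric in its arguments.
#'
#' @param order,reference [signed_gene_order()] objects over the same label
#'   set.
#' @return integer breakpoint count.
#' @export
breakpoint_count <- function(order, reference) {
  stopifnot(inherits(order, "signed_gene_order"),
            inherits(reference, "signed_gene_order"))
  if (!setequal(order$labels, reference$labels))
    stop("label sets differ")
  a <- .signed_adjacencies(order)
  b <- .signed_adjacencies(reference)
  b_all <- c(b, .adj_revcomp(b))
  sum(!(a %in% b_all))
}

#' Inverted-block and strand-flip detection against a reference order
#'
#' Walks the circle of `order` and cuts it into maximal runs whose genes
#' occupy consecutive positions of `reference` (position step +1: same
#' reading; -1: reversed). A reversed run whose genes all have flipped
#' orientation is a clean inverted block (a single displaced gene with
#' flipped orientation is a length-1 inversion). Genes in same-reading runs
#' that nonetheless changed strand are reported as `strand_flips` -- the
#' signature of a block whose members kept their relative order but not
#' their orientation, which a single inversion cannot produce.
#'
#' @param order,reference [signed_gene_order()] objects over the same label
#'   set.
#' @return list with `blocks` (list of character vectors, labels in `order`
#'   reading), `strand_flips` (character vector), and `runs` (data.frame of
#'   the run decomposition: `label`, `ref_pos`, `flipped`, `run`).
#' @export
find_inverted_blocks <- function(order, reference) {
  stopifnot(inherits(order, "signed_gene_order"),
            inherits(reference, "signed_gene_order"))
  if (!setequal(order$labels, reference$labels))
    stop("label sets differ")
  n <- length(order$labels)
  pos <- match(order$labels, reference$labels)
  ref_or <- reference$orientation[pos]
  flipped <- order$orientation != ref_or

  if (n == 0)
    return(list(blocks = list(), strand_flips = character(0),
                runs = data.frame()))

  # direction of the circular link i -> i+1 in reference position space:
  # +1 same reading, -1 reversed, 0 broken. Two adjacent non-broken links
  # can never disagree in direction (positions are distinct), so maximal
  # runs are simply the stretches between broken links.
  nxt <- c(seq_len(n)[-1], 1L)
  step <- (pos[nxt] - pos) %% n
  dirn <- ifelse(step == 1L, 1L, ifelse(step == n - 1L, -1L, 0L))

  run_of <- integer(n)
  run_dir <- integer(0)
  if (n == 1L || all(dirn != 0L)) {
    run_of[] <- 1L
    run_dir <- if (n == 1L) 0L else dirn[1]
    walk <- seq_len(n)
  } else {
    s0 <- (which(dirn == 0L)[1] %% n) + 1L  # first gene after a break
    walk <- ((s0 - 1L + seq_len(n) - 1L) %% n) + 1L
    rid <- 1L
    members <- integer(0)
    for (k in seq_len(n)) {
      i <- walk[k]
      run_of[i] <- rid
      members <- c(members, i)
      if (dirn[i] == 0L || k == n) {   # link to successor broken: close run
        run_dir[rid] <- if (length(members) == 1L) 0L
                        else dirn[members[1]]
        rid <- rid + 1L
        members <- integer(0)
      }
    }
  }

  blocks <- list()
  strand_flips <- character(0)
  rank <- match(seq_len(n), walk)   # position of each gene along the walk
  for (r in seq_along(run_dir)) {
    members <- which(run_of == r)
    members <- members[order(rank[members])]
    labs <- order$labels[members]
    fl <- flipped[members]
    if (run_dir[r] == -1L && all(fl)) {
      blocks[[length(blocks) + 1]] <- labs
    } else {
      # within an order-preserved (or mixed) run, an isolated flipped gene
      # is a length-1 inversion; a stretch of >= 2 consecutive flipped
      # genes kept their relative order, which no single inversion can do,
      # so those are strand flips
      rl <- rle(fl)
      at <- cumsum(rl$lengths) - rl$lengths + 1L
      for (k in seq_along(rl$lengths)) {
        if (!rl$values[k]) next
        stretch <- labs[at[k]:(at[k] + rl$lengths[k] - 1L)]
        if (length(stretch) == 1L)
          blocks[[length(blocks) + 1]] <- stretch
        else
          strand_flips <- c(strand_flips, stretch)
      }
    }
  }
  list(blocks = blocks, strand_flips = strand_flips,
       runs = data.frame(label = order$labels, ref_pos = pos,
                         flipped = flipped, run = run_of,
                         stringsAsFactors = FALSE))
}
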