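# Small-variant calling from alignment coordinate tables plus sequences:
# one-to-one collinear anchor chains per scaffold pair, SNVs from
# within-anchor mismatches, SNVs/indels from global alignment of
# inter-anchor gap pairs, left-align normalization, and diploid genotype
# merging. All reference coordinates are outgroup coordinates.

.empty_variants <- function() {
  data.frame(ref_id = character(0), pos = integer(0), ref = character(0),
             alt = character(0), vclass = character(0),
             stringsAsFactors = FALSE)
}

.empty_gaps <- function() {
  data.frame(ref_id = character(0), ref_start = integer(0),
             ref_end = integer(0), qry_id = character(0),
             qry_start = integer(0), qry_end = integer(0),
             strand = character(0), g_ref = integer(0), g_qry = integer(0),
             stringsAsFactors = FALSE)
}

#' Identify one-to-one collinear anchor runs per scaffold pair
#'
#' For each (reference scaffold, query scaffold) pair the majority strand
#' is the one carrying more aligned reference bp (ties to `+`); a maximal
#' chain of majority-strand blocks that is strictly increasing on both
#' sequences (weighted by aligned length) forms the run. Blocks left out
#' of every chain (paralogous multi-matches, minority-strand segments)
#' are returned separately; they still feed SV classification.
#'
#' @param blocks alignment block data.frame.
#' @return list with `runs` (list of block data.frames, one per pair) and
#'   `offchain` (blocks in no run).
#' @export
collinear_runs <- function(blocks) {
  runs <- list()
  off <- list()
  if (!nrow(blocks)) return(list(runs = runs, offchain = .empty_coords()))
  key <- paste(blocks$ref_id, blocks$qry_id, sep = "\r")
  for (k in unique(key)) {
    b <- blocks[key == k, , drop = FALSE]
    bp_fwd <- sum((b$ref_end - b$ref_start)[b$strand == "+"])
    bp_rev <- sum((b$ref_end - b$ref_start)[b$strand == "-"])
    maj <- if (bp_rev > bp_fwd) "-" else "+"
    mb <- b[b$strand == maj, , drop = FALSE]
    mb <- mb[order(mb$ref_start), , drop = FALSE]
    n <- nrow(mb)
    if (n == 0L) { off[[k]] <- b; next }
    # weighted longest increasing chain, non-overlapping on both sides
    w <- mb$ref_end - mb$ref_start
    best <- w
    prev <- rep(0L, n)
    for (i in seq_len(n)[-1L]) {
      for (j in seq_len(i - 1L)) {
        compat <- mb$ref_start[i] >= mb$ref_end[j] &&
          (if (maj == "+") mb$qry_start[i] >= mb$qry_end[j]
           else mb$qry_end[i] <= mb$qry_start[j])
        if (compat && best[j] + w[i] > best[i]) {
          best[i] <- best[j] + w[i]
          prev[i] <- j
        }
      }
    }
    i <- which.max(best)
    chain <- integer(0)
    while (i > 0L) { chain <- c(i, chain); i <- prev[i] }
    runs[[k]] <- mb[chain, , drop = FALSE]
    leftover <- rbind(b[b$strand != maj, , drop = FALSE],
                      mb[-chain, , drop = FALSE])
    if (nrow(leftover)) off[[k]] <- leftover
  }
  list(runs = runs,
       offchain = if (length(off)) do.call(rbind, c(off, make.row.names = FALSE))
                  else .empty_coords())
}

.empty_coords <- function() {
  data.frame(ref_id = character(0), ref_start = integer(0),
             ref_end = integer(0), qry_id = character(0),
             qry_start = integer(0), qry_end = integer(0),
             strand = character(0), identity = numeric(0),
             len1 = integer(0), len2 = integer(0), stringsAsFactors = FALSE)
}

# SNVs from positionwise comparison inside one gapless anchor block
.scan_block_mismatches <- function(block, ref_seqs, qry_seqs) {
  r <- seq_encode(substr(ref_seqs[[block$ref_id]], block$ref_start + 1L,
                         block$ref_end))
  q <- seq_encode(substr(qry_seqs[[block$qry_id]], block$qry_start + 1L,
                         block$qry_end))
  if (block$strand == "-") q <- revcomp_int(q)
  mm <- which(r != q & r != .CODE_N & q != .CODE_N)
  if (!length(mm)) return(NULL)
  data.frame(ref_id = block$ref_id, pos = block$ref_start + mm - 1L,
             ref = .BASES[r[mm]], alt = .BASES[q[mm]], vclass = "SNV",
             stringsAsFactors = FALSE)
}

# variants from a global alignment of one gap pair (both sides < 50 bp);
# returns anchored indels and SNVs in reference coordinates
.align_gap_pair <- function(ref_gap, qry_gap, ref_id, ref_off, ref_seq) {
  nr <- nchar(ref_gap); nq <- nchar(qry_gap)
  vars <- list()
  add_snv <- function(pos, rb, ab) {
    if (rb != ab && rb != "N" && ab != "N") {
      vars[[length(vars) + 1L]] <<- data.frame(
        ref_id = ref_id, pos = pos, ref = rb, alt = ab, vclass = "SNV",
        stringsAsFactors = FALSE)
    }
  }
  add_indel <- function(anchor_pos, del_seq, ins_seq) {
    anchor <- substr(ref_seq, anchor_pos + 1L, anchor_pos + 1L)
    vars[[length(vars) + 1L]] <<- data.frame(
      ref_id = ref_id, pos = anchor_pos,
      ref = paste0(anchor, del_seq), alt = paste0(anchor, ins_seq),
      vclass = if (nchar(del_seq)) "DEL" else "INS",
      stringsAsFactors = FALSE)
  }
  if (nr == 0L && nq > 0L) {
    add_indel(ref_off - 1L, "", qry_gap)
  } else if (nq == 0L && nr > 0L) {
    add_indel(ref_off - 1L, ref_gap, "")
  } else if (nr == 1L && nq == 1L) {
    add_snv(ref_off, ref_gap, qry_gap)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(qry_gap), Biostrings::DNAString(ref_gap),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 1, gapExtension = 1)
    qa <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1L]]
    ra <- strsplit(as.character(Biostrings::subject(pa)), "")[[1L]]
    rpos <- ref_off   # reference coordinate of next reference column
    i <- 1L
    ncol <- length(qa)
    while (i <= ncol) {
      if (ra[i] != "-" && qa[i] != "-") {
        add_snv(rpos, ra[i], qa[i])
        rpos <- rpos + 1L; i <- i + 1L
      } else if (ra[i] == "-") {
        j <- i
        while (j <= ncol && ra[j] == "-") j <- j + 1L
        add_indel(rpos - 1L, "", paste(qa[i:(j - 1L)], collapse = ""))
        i <- j
      } else {
        j <- i
        while (j <= ncol && qa[j] == "-") j <- j + 1L
        del <- paste(ra[i:(j - 1L)], collapse = "")
        add_indel(rpos - 1L, del, "")
        rpos <- rpos + (j - i)
        i <- j
      }
    }
  }
  if (length(vars)) do.call(rbind, vars) else NULL
}

#' Resolve inter-anchor gap pairs (and within-anchor mismatches) into
#' small variants
#'
#' Within each collinear run, adjacent anchor pairs with both gaps below
#' the small-variant threshold and at most `max_gap` are globally aligned
#' (match +1, mismatch -1, gap open -2, gap extend -1) and emitted as
#' SNVs/indels; gap pairs with >= `sv_min` bp on either side are passed
#' through unresolved as SV candidates. SNVs inside anchors come from
#' direct positionwise comparison. Overlapping anchors in a run are
#' malformed input and raise an error.
#'
#' @param runs list of collinear runs from [collinear_runs()].
#' @param ref_seqs,qry_seqs named character vectors of scaffolds.
#' @param max_gap maximum gap-pair side resolved by alignment (bp).
#' @param sv_min gap size at or above which a gap pair becomes an SV
#'   candidate instead of small variants.
#' @return list with `variants` (anchored, unnormalized) and
#'   `unresolved` (gap-pair records).
#' @export
resolve_gap_pairs <- function(runs, ref_seqs, qry_seqs, max_gap = 500L,
                              sv_min = 50L) {
  variants <- list()
  unresolved <- list()
  for (run in runs) {
    n <- nrow(run)
    if (!n) next
    if (n > 1L) {
      if (any(run$ref_start[-1L] < run$ref_end[-n])) {
        stop("overlapping anchors on the reference within a run")
      }
      qo <- if (run$strand[1L] == "+") {
        any(run$qry_start[-1L] < run$qry_end[-n])
      } else {
        any(run$qry_end[-1L] > run$qry_start[-n])
      }
      if (qo) stop("overlapping anchors on the query within a run")
    }
    for (i in seq_len(n)) {
      v <- .scan_block_mismatches(run[i, ], ref_seqs, qry_seqs)
      if (!is.null(v)) variants[[length(variants) + 1L]] <- v
    }
    if (n < 2L) next
    fwd <- run$strand[1L] == "+"
    for (i in seq_len(n - 1L)) {
      g_ref <- run$ref_start[i + 1L] - run$ref_end[i]
      g_qry <- if (fwd) run$qry_start[i + 1L] - run$qry_end[i]
               else run$qry_start[i] - run$qry_end[i + 1L]
      if (g_ref == 0L && g_qry == 0L) next
      if (g_ref >= sv_min || g_qry >= sv_min) {
        unresolved[[length(unresolved) + 1L]] <- data.frame(
          ref_id = run$ref_id[i], ref_start = run$ref_end[i],
          ref_end = run$ref_start[i + 1L],
          qry_id = run$qry_id[i],
          qry_start = if (fwd) run$qry_end[i] else run$qry_end[i + 1L],
          qry_end = if (fwd) run$qry_start[i + 1L] else run$qry_start[i],
          strand = run$strand[i], g_ref = g_ref, g_qry = g_qry,
          stringsAsFactors = FALSE)
        next
      }
      if (g_ref > max_gap || g_qry > max_gap) next
      ref_gap <- substr(ref_seqs[[run$ref_id[i]]], run$ref_end[i] + 1L,
                        run$ref_start[i + 1L])
      qry_gap <- if (fwd) {
        substr(qry_seqs[[run$qry_id[i]]], run$qry_end[i] + 1L,
               run$qry_start[i + 1L])
      } else {
        revcomp(substr(qry_seqs[[run$qry_id[i]]],
                       run$qry_end[i + 1L] + 1L, run$qry_start[i]))
      }
      v <- .align_gap_pair(ref_gap, qry_gap, run$ref_id[i],
                           run$ref_end[i], ref_seqs[[run$ref_id[i]]])
      if (!is.null(v)) variants[[length(variants) + 1L]] <- v
    }
  }
  list(
    variants = if (length(variants))
      do.call(rbind, c(variants, make.row.names = FALSE))
      else .empty_variants(),
    unresolved = if (length(unresolved))
      do.call(rbind, c(unresolved, make.row.names = FALSE))
      else .empty_gaps())
}

#' Left-align and normalize small variants
#'
#' Indels are shifted to their leftmost equivalent position and trimmed
#' to minimal anchored representation; SNVs are checked against the
#' reference. The operation is idempotent; an allele that contradicts
#' the reference raises an error.
#'
#' @param variants anchored variant data.frame (`ref_id, pos, ref, alt`).
#' @param ref_seqs named character vector of reference scaffolds.
#' @return the normalized variants, with `vclass` recomputed.
#' @export
normalize_variants <- function(variants, ref_seqs) {
  if (!nrow(variants)) return(variants)
  out <- variants
  for (i in seq_len(nrow(out))) {
    ref_seq <- ref_seqs[[out$ref_id[i]]]
    pos <- out$pos[i]; ref <- out$ref[i]; alt <- out$alt[i]
    if (nchar(ref) == 0L || nchar(alt) == 0L) {
      stop("variants must be anchored (non-empty alleles)")
    }
    if (substr(ref_seq, pos + 1L, pos + nchar(ref)) != ref) {
      stop(sprintf("allele/reference mismatch at %s:%d", out$ref_id[i],
                   pos + 1L))
    }
    if (nchar(ref) == 1L && nchar(alt) == 1L) next
    # trim common suffix (keep at least one base each)
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, nchar(ref), nchar(ref)) ==
             substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
    # trim extra common prefix beyond the single anchor
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &&
           substr(ref, 2L, 2L) == substr(alt, 2L, 2L)) {
      ref <- substring(ref, 2L); alt <- substring(alt, 2L)
      pos <- pos + 1L
    }
    if (nchar(ref) > 1L && nchar(alt) > 1L) {
      # complex substitution left after trimming: keep as is
      out$pos[i] <- pos; out$ref[i] <- ref; out$alt[i] <- alt
      next
    }
    # pure indel: left shift
    is_del <- nchar(ref) > 1L
    seq_body <- if (is_del) substring(ref, 2L) else substring(alt, 2L)
    d <- pos + 1L   # 0-based start of the inserted/deleted run
    L <- nchar(seq_body)
    repeat {
      if (d <= 0L) break
      prev <- substr(ref_seq, d, d)          # ref base at d-1 (0-based)
      last <- substr(seq_body, L, L)
      if (prev != last) break
      seq_body <- paste0(prev, substr(seq_body, 1L, L - 1L))
      d <- d - 1L
    }
    anchor_pos <- d - 1L
    if (anchor_pos < 0L) {
      # shifted to the scaffold start: anchor on the following base
      follow <- substr(ref_seq, L + 1L, L + 1L)
      out$pos[i] <- 0L
      out$ref[i] <- if (is_del) paste0(seq_body, follow) else follow
      out$alt[i] <- if (is_del) follow else paste0(seq_body, follow)
    } else {
      anchor <- substr(ref_seq, anchor_pos + 1L, anchor_pos + 1L)
      out$pos[i] <- anchor_pos
      out$ref[i] <- if (is_del) paste0(anchor, seq_body) else anchor
      out$alt[i] <- if (is_del) anchor else paste0(anchor, seq_body)
    }
  }
  out$vclass <- ifelse(nchar(out$ref) == 1L & nchar(out$alt) == 1L, "SNV",
                       ifelse(nchar(out$ref) > nchar(out$alt), "DEL", "INS"))
  out
}

#' Merge two haplotype call sets into diploid variants with zygosity
#'
#' Identical `(scaffold, pos, ref, alt)` on both haplotypes is `fixed`;
#' presence on exactly one is `het`. Different alt alleles at one site
#' are both kept as het records (multi-allelic) with a warning.
#'
#' @param hap1,hap2 normalized variant data.frames in shared (reference)
#'   coordinates.
#' @return combined variant data.frame with a `zygosity` column.
#' @export
genotype_merge <- function(hap1, hap2) {
  key <- function(v) paste(v$ref_id, v$pos, v$ref, v$alt, sep = "\r")
  k1 <- key(hap1); k2 <- key(hap2)
  both <- intersect(k1, k2)
  out <- rbind(
    cbind(hap1[k1 %in% both, , drop = FALSE], zygosity = "fixed"),
    cbind(hap1[!k1 %in% both, , drop = FALSE], zygosity = "het"),
    cbind(hap2[!k2 %in% both, , drop = FALSE], zygosity = "het"))
  site <- function(v) paste(v$ref_id, v$pos, sep = "\r")
  het <- out$zygosity == "het"
  if (any(duplicated(site(out[het, , drop = FALSE])))) {
    warning("multi-allelic site(s): conflicting alt alleles kept as het")
  }
  rownames(out) <- NULL
  out
}

#' Callable regions of the reference for one focal haplotype
#'
#' A reference position is callable when it is covered by exactly one
#' alignment block overall and that block belongs to a collinear run
#' (duplicated-region matches are excluded from variant calling).
#'
#' @param blocks all alignment blocks for the genome pair.
#' @param runs collinear runs from [collinear_runs()].
#' @return BED-like data.frame of callable reference intervals.
#' @export
callable_regions <- function(blocks, runs) {
  if (!nrow(blocks)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  chain <- do.call(rbind, runs)
  out <- list()
  for (ch in unique(blocks$ref_id)) {
    b <- blocks[blocks$ref_id == ch, , drop = FALSE]
    cov <- IRanges::coverage(IRanges::IRanges(b$ref_start + 1L, b$ref_end))
    once <- IRanges::slice(cov, lower = 1L, upper = 1L, rangesOnly = TRUE)
    cb <- chain[chain$ref_id == ch, , drop = FALSE]
    if (!nrow(cb)) next
    keep <- IRanges::intersect(
      once, IRanges::IRanges(cb$ref_start + 1L, cb$ref_end))
    if (length(keep)) {
      out[[ch]] <- data.frame(chrom = ch,
                              start = IRanges::start(keep) - 1L,
                              end = IRanges::end(keep),
                              stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(chrom = character(0), start = integer(0),
                  end = integer(0), stringsAsFactors = FALSE)
}

#' Call small variants for one focal haplotype against the reference
#'
#' Convenience wrapper: chains anchors, scans mismatches, resolves gap
#' pairs, and left-aligns. Returns variants, unresolved SV-candidate
#' gaps, the runs, and callable regions.
#'
#' @param blocks alignment blocks (reference = outgroup).
#' @param ref_seqs,qry_seqs scaffold sequences.
#' @param max_gap maximum resolvable gap (bp).
#' @return list `variants, unresolved, runs, offchain, callable`.
#' @export
call_small_variants <- function(blocks, ref_seqs, qry_seqs,
                                max_gap = 500L) {
  cr <- collinear_runs(blocks)
  rg <- resolve_gap_pairs(cr$runs, ref_seqs, qry_seqs, max_gap = max_gap)
  v <- normalize_variants(rg$variants, ref_seqs)
  list(variants = v, unresolved = rg$unresolved, runs = cr$runs,
       offchain = cr$offchain,
       callable = callable_regions(blocks, cr$runs))
}
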