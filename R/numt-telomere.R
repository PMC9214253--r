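# NUMT detection against a rotated/self-concatenated mitogenome template
# using a deterministic seed-and-extend search, zygosity and synteny
# assignment, greedy identity clustering, insertion-bias testing, and
# the interstitial-telomere and repeat-ORF scanners.

#' Prepare a mitogenome search template
#'
#' The circular mitogenome is rotated so `anchor` sits at offset 0 (pass
#' NULL to keep the current origin) and concatenated with itself so
#' fragments spanning the origin are present without a break point.
#'
#' @param mito mitogenome sequence (string).
#' @param anchor anchor motif; must occur exactly once. NULL skips
#'   rotation.
#' @return a `mito_template` list: `rotated`, `doubled`, `length`,
#'   `anchor_offset`.
#' @export
prepare_template <- function(mito, anchor = NULL) {
  off <- 0L
  if (!is.null(anchor)) {
    hits <- gregexpr(anchor, mito, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) stop("anchor motif absent from the mitogenome")
    if (length(hits) > 1L) stop("anchor motif occurs more than once")
    off <- hits[1L] - 1L
  }
  rotated <- if (off > 0L) {
    paste0(substring(mito, off + 1L), substr(mito, 1L, off))
  } else mito
  structure(list(rotated = rotated, doubled = paste0(rotated, rotated),
                 length = nchar(mito), anchor_offset = off),
            class = "mito_template")
}

#' NUMT search parameters
#'
#' @param seed_k exact seed length (>= 8).
#' @param xdrop ungapped x-drop extension threshold.
#' @param min_identity minimum hit identity fraction.
#' @param min_length minimum genomic footprint (bp).
#' @param merge_gap merge hits separated by at most this many bp.
#' @return a `numt_search_params` list.
#' @export
numt_search_params <- function(seed_k = 12L, xdrop = 20L,
                               min_identity = 0.70, min_length = 100L,
                               merge_gap = 50L) {
  stopifnot(seed_k >= 8L)
  structure(list(seed_k = as.integer(seed_k), xdrop = as.integer(xdrop),
                 min_identity = min_identity,
                 min_length = as.integer(min_length),
                 merge_gap = as.integer(merge_gap)),
            class = "numt_search_params")
}

# 2-bit rolling k-mer codes; positions with any N give NA
.kmer_codes <- function(v, k) {
  n <- length(v)
  if (n < k) return(numeric(0))
  b <- ifelse(v == .CODE_N, NA_real_, as.numeric(v - 1L))
  m <- n - k + 1L
  val <- numeric(m)
  for (j in seq_len(k)) {
    val <- val + b[j:(j + m - 1L)] * 4^(j - 1L)
  }
  val
}

# ungapped x-drop extension along one diagonal; returns 0-based
# inclusive bounds within the comparison vectors
.xdrop_extend <- function(eq, from, to, xdrop) {
  # extend right of `to`
  n <- length(eq)
  right <- to
  if (to < n) {
    sc <- cumsum(ifelse(eq[(to + 1L):n], 1, -1))
    run <- sc - cummax(sc)
    stop_at <- which(run < -xdrop)[1L]
    lim <- if (is.na(stop_at)) length(sc) else stop_at
    best <- which.max(sc[seq_len(lim)])
    if (sc[best] > 0) right <- to + best
  }
  left <- from
  if (from > 1L) {
    sc <- cumsum(ifelse(eq[(from - 1L):1L], 1, -1))
    run <- sc - cummax(sc)
    stop_at <- which(run < -xdrop)[1L]
    lim <- if (is.na(stop_at)) length(sc) else stop_at
    best <- which.max(sc[seq_len(lim)])
    if (sc[best] > 0) left <- from - best
  }
  c(left, right)
}

.detect_numts_one <- function(gv, tv, strand, params, scaffold, mlen) {
  k <- params$seed_k
  gk <- .kmer_codes(gv, k)
  tk <- .kmer_codes(tv, k)
  ok_t <- which(!is.na(tk))
  if (!length(ok_t) || !length(gk)) return(NULL)
  # first template position per k-mer code
  first <- ok_t[!duplicated(tk[ok_t])]
  m <- match(gk, tk[first])
  hit_g <- which(!is.na(m))
  if (!length(hit_g)) return(NULL)
  hit_t <- first[m[hit_g]]
  diag <- hit_g - hit_t
  out <- list()
  for (d in unique(diag)) {
    gs <- sort(hit_g[diag == d])
    # split seed clusters separated by > merge_gap + k; extension uses a
    # two-hit rule (a lone exact seed is overwhelmingly k-mer noise)
    grp <- cumsum(c(1L, diff(gs) > params$merge_gap + k))
    for (cl in unique(grp)) {
      if (sum(grp == cl) < 2L) next
      span <- range(gs[grp == cl])
      # comparison vectors along the diagonal, windowed around the seed
      # cluster (x-drop extension cannot usefully travel further)
      win <- 4000L
      g_lo <- max(1L, 1L + max(0L, d), span[1L] - win)
      g_hi <- min(length(gv), length(tv) + d, span[2L] + k + win)
      if (g_hi - g_lo + 1L < k) next
      gseg <- gv[g_lo:g_hi]
      tseg <- tv[(g_lo - d):(g_hi - d)]
      eq <- gseg == tseg & gseg != .CODE_N
      from <- span[1L] - g_lo + 1L
      to <- span[2L] + k - 1L - g_lo + 1L
      ext <- .xdrop_extend(eq, from, to, params$xdrop)
      a <- ext[1L]; b <- ext[2L]
      out[[length(out) + 1L]] <- data.frame(
        scaffold = scaffold,
        start = g_lo + a - 2L,              # 0-based
        end = g_lo + b - 1L,
        t_start = g_lo + a - 2L - d,        # 0-based in template
        t_end = g_lo + b - 1L - d,
        strand = strand,
        matches = sum(eq[a:b]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  h <- do.call(rbind, out)
  h <- h[!duplicated(h[c("start", "end")]), , drop = FALSE]
  h
}

# merge hits on one scaffold/strand that overlap or sit within
# merge_gap AND lie on compatible diagonals (small indels shift the
# diagonal a little; the doubled template's second copy shifts it by a
# whole mitogenome length and must never merge)
.merge_numt_hits <- function(h, merge_gap, diag_tol = 60L) {
  h <- h[order(h$start), , drop = FALSE]
  d <- h$start - h$t_start
  n <- nrow(h)
  grp <- seq_len(n)
  if (n > 1L) {
    for (i in 2:n) {
      for (j in seq_len(i - 1L)) {
        if (grp[j] != grp[i] &&
            h$start[i] <= max(h$end[grp == grp[j]]) + merge_gap &&
            abs(d[i] - d[j]) <= diag_tol) {
          grp[grp == grp[i]] <- grp[j]
        }
      }
    }
  }
  out <- list()
  for (g in unique(grp)) {
    hh <- h[grp == g, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      scaffold = hh$scaffold[1L],
      start = min(hh$start), end = max(hh$end),
      t_start = min(hh$t_start), t_end = max(hh$t_end),
      strand = hh$strand[1L],
      matches = sum(hh$matches),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Detect NUMTs by seed-and-extend search
#'
#' Exact `seed_k`-mer matches between the genome and the doubled
#' template (both strands) are extended ungapped with an x-drop rule;
#' hits overlapping or within `merge_gap` are merged; hits below
#' `min_length` or `min_identity` are dropped. Mitogenome coordinates
#' are reported modulo the mitogenome length, and a fragment matched in
#' both copies of the doubled template is reported once.
#'
#' @param scaffolds named character vector of nuclear scaffolds.
#' @param template a [prepare_template()].
#' @param params a [numt_search_params()].
#' @return data.frame of NUMT hits: `scaffold, start, end, mito_start,
#'   mito_end, strand, identity, length_bp`.
#' @export
detect_numts <- function(scaffolds, template,
                         params = numt_search_params()) {
  tv_fwd <- seq_encode(template$doubled)
  tv_rev <- revcomp_int(tv_fwd)
  mlen <- template$length
  all <- list()
  for (ch in names(scaffolds)) {
    gv <- seq_encode(scaffolds[[ch]])
    for (strand in c("+", "-")) {
      tv <- if (strand == "+") tv_fwd else tv_rev
      h <- .detect_numts_one(gv, tv, strand, params, ch, mlen)
      if (is.null(h)) next
      h <- .merge_numt_hits(h, params$merge_gap)
      all[[length(all) + 1L]] <- h
    }
  }
  if (!length(all)) return(.empty_numts())
  h <- do.call(rbind, all)
  h$length_bp <- h$end - h$start
  h$identity <- h$matches / h$length_bp
  h <- h[h$length_bp >= params$min_length &
           h$identity >= params$min_identity, , drop = FALSE]
  if (!nrow(h)) return(.empty_numts())
  # template -> mitogenome coordinates (modulo length, strand-aware)
  dl <- 2L * mlen
  t_s <- ifelse(h$strand == "+", h$t_start, dl - h$t_end)
  t_e <- ifelse(h$strand == "+", h$t_end, dl - h$t_start)
  h$mito_start <- t_s %% mlen
  h$mito_end <- h$mito_start + (t_e - t_s)   # may exceed mlen: wraps origin
  h <- h[order(h$scaffold, h$start), , drop = FALSE]
  # overlapping duplicates of one locus (other strand, or the doubled
  # template's second copy): keep the best-supported hit
  keep <- rep(TRUE, nrow(h))
  if (nrow(h) > 1L) {
    for (i in seq_len(nrow(h))) {
      if (!keep[i]) next
      for (j in seq_len(nrow(h))) {
        if (i == j || !keep[j]) next
        if (h$scaffold[i] == h$scaffold[j] &&
            h$start[i] < h$end[j] && h$end[i] > h$start[j] &&
            h$matches[j] <= h$matches[i]) {
          keep[j] <- FALSE
        }
      }
    }
  }
  h <- h[keep, c("scaffold", "start", "end", "mito_start", "mito_end",
                 "strand", "identity", "length_bp")]
  rownames(h) <- NULL
  h
}

.empty_numts <- function() {
  data.frame(scaffold = character(0), start = integer(0), end = integer(0),
             mito_start = integer(0), mito_end = integer(0),
             strand = character(0), identity = numeric(0),
             length_bp = integer(0), stringsAsFactors = FALSE)
}

#' Zygosity of NUMT hits across the two haplotypes
#'
#' Hits are lifted to shared (reference) coordinates when maps are
#' given; hits overlapping by at least 1 bp across haplotypes are
#' `fixed`, the rest `het`.
#'
#' @param hits1,hits2 NUMT hit data.frames per haplotype.
#' @param map1,map2 optional [homology_map()]s to shared coordinates.
#' @return combined hits with `haplotype` and `zygosity` columns (and
#'   `shared_chr/shared_start/shared_end` when maps are given).
#' @export
numt_zygosity <- function(hits1, hits2, map1 = NULL, map2 = NULL) {
  lift_hits <- function(h, map) {
    h$shared_chr <- h$scaffold
    h$shared_start <- h$start
    h$shared_end <- h$end
    if (is.null(map) || !nrow(h)) return(h)
    for (i in seq_len(nrow(h))) {
      lifted <- lift_interval(map, h$scaffold[i], h$start[i], h$end[i])
      if (nrow(lifted)) {
        h$shared_chr[i] <- lifted$chr[1L]
        h$shared_start[i] <- lifted$start[1L]
        h$shared_end[i] <- lifted$end[1L]
      } else {
        h$shared_chr[i] <- NA_character_
      }
    }
    h
  }
  h1 <- lift_hits(hits1, map1); h2 <- lift_hits(hits2, map2)
  mark <- function(a, b) {
    if (!nrow(a)) return(character(0))
    z <- rep("het", nrow(a))
    for (i in seq_len(nrow(a))) {
      if (is.na(a$shared_chr[i])) next
      sel <- !is.na(b$shared_chr) & b$shared_chr == a$shared_chr[i] &
        b$shared_start < a$shared_end[i] & b$shared_end > a$shared_start[i]
      if (any(sel)) z[i] <- "fixed"
    }
    z
  }
  h1$zygosity <- mark(h1, h2); h1$haplotype <- rep(1L, nrow(h1))
  h2$zygosity <- mark(h2, h1); h2$haplotype <- rep(2L, nrow(h2))
  out <- rbind(h1, h2)
  rownames(out) <- NULL
  out
}

#' Group NUMTs into synteny groups across genomes
#'
#' Connected components under >= 1 bp overlap in shared (outgroup)
#' coordinates. Hits that could not be lifted become flagged singleton
#' groups.
#'
#' @param hits combined NUMT data.frame with `genome_id` and shared
#'   coordinates (`shared_chr, shared_start, shared_end`; NA = unliftable).
#' @return `hits` with `synteny_group` and `syntenous` columns, plus a
#'   `per_genome` attribute giving each genome's syntenous fraction.
#' @export
numt_synteny <- function(hits) {
  n <- nrow(hits)
  group <- seq_len(n)
  find <- function(i) { while (group[i] != i) i <- group[i]; i }
  liftable <- which(!is.na(hits$shared_chr))
  if (length(liftable) > 1L) {
    for (ii in seq_along(liftable)[-1L]) {
      i <- liftable[ii]
      for (jj in seq_len(ii - 1L)) {
        j <- liftable[jj]
        if (hits$shared_chr[i] == hits$shared_chr[j] &&
            hits$shared_start[i] < hits$shared_end[j] &&
            hits$shared_end[i] > hits$shared_start[j]) {
          group[find(i)] <- find(j)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  hits$synteny_group <- match(root, unique(root))
  size_by_genomes <- tapply(hits$genome_id, hits$synteny_group,
                            function(g) length(unique(g)))
  hits$syntenous <- size_by_genomes[as.character(hits$synteny_group)] >= 2L
  per_genome <- tapply(hits$syntenous, hits$genome_id, mean)
  attr(hits, "per_genome") <- per_genome
  hits
}

# identity of two sequences under an ends-free global alignment:
# matches / alignment columns, terminal gaps excluded
.alignment_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 2, gapExtension = 1)
  x <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1L]]
  y <- strsplit(as.character(Biostrings::subject(pa)), "")[[1L]]
  inner <- which(x != "-" | y != "-")
  if (!length(inner)) return(0)
  sum(x[inner] == y[inner]) / length(inner)
}

#' Greedy centroid clustering of NUMT sequences at an identity threshold
#'
#' Sequences are sorted by descending length; each sequence joins the
#' first existing centroid with alignment identity at or above
#' `threshold` after testing all centroids in order (no early
#' abandonment), otherwise it founds a new centroid. Identity is
#' matches over alignment columns with terminal gaps excluded.
#'
#' @param seqs character vector of NUMT sequences (names preserved).
#' @param threshold identity threshold (default 0.80).
#' @return data.frame `name, length, cluster, is_centroid` in
#'   processing order.
#' @export
cluster_numts <- function(seqs, threshold = 0.80) {
  if (is.null(names(seqs))) names(seqs) <- paste0("numt", seq_along(seqs))
  ord <- order(-nchar(seqs))
  seqs <- seqs[ord]
  # shared-12-mer prescreen: two sequences with no exact 12-mer in
  # common cannot align at >= 80% identity over >= 100 bp
  kmers <- lapply(seqs, function(s) {
    unique(.kmer_codes(seq_encode(s), 12L))
  })
  centroids <- integer(0)
  cluster <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    assigned <- 0L
    for (ci in seq_along(centroids)) {
      j <- centroids[ci]
      if (!any(kmers[[i]] %in% kmers[[j]])) next
      if (.alignment_identity(seqs[[i]], seqs[[j]]) >= threshold) {
        assigned <- ci
        break
      }
    }
    if (assigned == 0L) {
      centroids <- c(centroids, i)
      assigned <- length(centroids)
    }
    cluster[i] <- assigned
  }
  data.frame(name = names(seqs), length = nchar(seqs), cluster = cluster,
             is_centroid = seq_along(seqs) %in% centroids,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Binomial test of NUMT insertion bias by chromosome class
#'
#' Two-sided exact binomial test of the observed number of NUMTs on a
#' chromosome class against the fraction of classified windows in that
#' class, with the Clopper-Pearson 95% interval for the proportion.
#'
#' @param n_on_class NUMTs observed on the class.
#' @param n_total total NUMTs.
#' @param expected_proportion fraction of classified windows in the
#'   class (the null probability).
#' @param conf confidence level.
#' @return a [flux_test()].
#' @export
insertion_bias_test <- function(n_on_class, n_total, expected_proportion,
                                conf = 0.95) {
  if (n_total == 0) stop("no NUMTs to test")
  exact_binomial(n_on_class, n_total, expected_proportion, conf)
}

#' Scan for (interstitial) telomeric repeat arrays
#'
#' Maximal runs of at least `min_units` tandem perfect TTAGGG (or
#' CCCTAA) copies; a run is interstitial when it starts at least
#' `end_margin` bp from the scaffold start and ends at least
#' `end_margin` bp before the scaffold end.
#'
#' @param scaffolds named character vector.
#' @param min_units minimum tandem copies.
#' @param end_margin distance from scaffold ends defining "interstitial".
#' @return data.frame `scaffold, start, end, motif, unit_count,
#'   interstitial`.
#' @export
scan_interstitial_telomeres <- function(scaffolds, min_units = 3L,
                                        end_margin = 1000L) {
  out <- list()
  for (ch in names(scaffolds)) {
    s <- scaffolds[[ch]]
    n <- nchar(s)
    for (motif in c("TTAGGG", "CCCTAA")) {
      m <- gregexpr(paste0("(?:", motif, ")+"), s)[[1L]]
      if (m[1L] == -1L) next
      len <- attr(m, "match.length")
      units <- len %/% 6L
      keep <- units >= min_units
      if (!any(keep)) next
      st <- m[keep] - 1L
      en <- st + units[keep] * 6L
      out[[length(out) + 1L]] <- data.frame(
        scaffold = ch, start = st, end = en, motif = motif,
        unit_count = units[keep],
        interstitial = st >= end_margin & en <= n - end_margin,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) {
    res <- do.call(rbind, c(out, make.row.names = FALSE))
    res[order(res$scaffold, res$start), , drop = FALSE]
  } else {
    data.frame(scaffold = character(0), start = integer(0),
               end = integer(0), motif = character(0),
               unit_count = integer(0), interstitial = logical(0),
               stringsAsFactors = FALSE)
  }
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# longest ORF (ATG..stop, nt length including the stop codon) over the
# six frames of a sequence
longest_orf <- function(s) {
  best <- 0L
  for (seqstr in c(s, revcomp(s))) {
    n <- nchar(seqstr)
    for (off in 0:2) {
      ncod <- (n - off) %/% 3L
      if (ncod < 2L) next
      starts <- substring(seqstr, off + 1L + 3L * (0:(ncod - 1L)),
                          off + 3L * (1:ncod))
      atg <- which(starts == "ATG")
      stop_i <- which(starts %in% .STOP_CODONS)
      if (!length(atg) || !length(stop_i)) next
      nxt <- stop_i[findInterval(atg, stop_i) + 1L]
      ok <- !is.na(nxt)
      if (!any(ok)) next
      len <- (nxt[ok] - atg[ok] + 1L) * 3L
      best <- max(best, len)
    }
  }
  best
}

#' Flag potentially active repeat copies by intact ORF length
#'
#' For each classed repeat interval, the longest ORF across six frames
#' (ATG to stop, no internal stop) is measured; the copy is potentially
#' active when that length reaches the class threshold (LINE 2000 bp,
#' LTR 2200 bp, DNA 1200 bp).
#'
#' @param seqs named character vector of scaffolds.
#' @param repeats data.frame `chrom, start, end, class`.
#' @param thresholds named nt-length thresholds per class.
#' @return `repeats` with `orf_len` and `active` columns; unknown
#'   classes are skipped with a warning.
#' @export
scan_repeat_orfs <- function(seqs, repeats,
                             thresholds = c(LINE = 2000L, LTR = 2200L,
                                            DNA = 1200L)) {
  known <- repeats$class %in% names(thresholds)
  if (any(!known)) {
    warning("skipping repeat interval(s) of unknown class: ",
            paste(unique(repeats$class[!known]), collapse = ", "))
  }
  out <- repeats[known, , drop = FALSE]
  out$orf_len <- vapply(seq_len(nrow(out)), function(i) {
    longest_orf(substr(seqs[[out$chrom[i]]], out$start[i] + 1L,
                       out$end[i]))
  }, 0L)
  out$active <- out$orf_len >= thresholds[out$class]
  rownames(out) <- NULL
  out
}
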