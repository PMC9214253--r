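# Ancestral genome construction: a karyotype of macro-, intermediate- and
# micro-chromosomes with per-chromosome GC and CpG targets (micros higher
# in both, as in birds), planted repeat annotation, ancestral tandem
# pairs (the substrate for segmental deletions), optional terminal
# telomere arrays, and a circular mitogenome.

#' Specify an ancestral karyotype
#'
#' @param chromosomes data.frame with columns `chrom`, `length`,
#'   `gc` (target GC fraction), `cpg` (target CpG dinucleotides per bp;
#'   NA = the iid expectation for the GC target), `size_class`
#'   (`micro`, `intermediate`, `macro`).
#' @param repeat_density fraction of bp covered by planted repeat
#'   intervals (split across LINE/LTR/DNA classes).
#' @param n_tandem_pairs number of ancestral tandem duplication pairs to
#'   plant (each an adjacent exact copy pair; segmental deletions in
#'   descendants consume these).
#' @param tandem_len_range length range for one tandem copy, bp.
#' @param telomere_units terminal TTAGGG units planted at both ends of
#'   every chromosome (0 = none).
#' @param mito_length length of the circular mitogenome, bp.
#' @param mito_gc GC fraction of the mitogenome.
#' @return an `ancestor_spec` list.
#' @export
ancestor_spec <- function(chromosomes,
                          repeat_density = 0.06,
                          n_tandem_pairs = 8L,
                          tandem_len_range = c(200L, 800L),
                          telomere_units = 0L,
                          mito_length = 17000L,
                          mito_gc = 0.45) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length", "gc", "size_class") %in%
                  names(chromosomes)))
  if (is.null(chromosomes$cpg)) chromosomes$cpg <- NA_real_
  stopifnot(all(chromosomes$length > 0),
            all(chromosomes$gc > 0 & chromosomes$gc < 1),
            !anyDuplicated(chromosomes$chrom),
            all(chromosomes$size_class %in%
                  c("micro", "intermediate", "macro")))
  micro_gc <- chromosomes$gc[chromosomes$size_class == "micro"]
  macro_gc <- chromosomes$gc[chromosomes$size_class == "macro"]
  if (length(micro_gc) && length(macro_gc) &&
      min(micro_gc) < max(macro_gc)) {
    warning("micro chromosomes are expected to have GC >= macro GC")
  }
  structure(list(chromosomes = chromosomes,
                 repeat_density = repeat_density,
                 n_tandem_pairs = as.integer(n_tandem_pairs),
                 tandem_len_range = as.integer(tandem_len_range),
                 telomere_units = as.integer(telomere_units),
                 mito_length = as.integer(mito_length),
                 mito_gc = mito_gc),
            class = "ancestor_spec")
}

TELOMERE_UNIT <- "TTAGGG"

# one chromosome's sequence as an integer vector, hitting the GC and CpG
# targets. Enrichment above the iid expectation plants extra CG
# dinucleotides (base GC pre-compensated so realized GC stays on
# target); depletion below it -- the normal state of vertebrate genomes
# -- swaps CG -> GC at sampled sites, which destroys the CpG while
# conserving base composition exactly.
.build_chrom_seq <- function(len, gc, cpg_target) {
  iid_cpg <- (gc / 2)^2
  if (is.na(cpg_target)) cpg_target <- iid_cpg
  if (cpg_target > gc / 2) {
    stop("CpG target incompatible with GC target (needs > gc/2 C bases)")
  }
  if (cpg_target < 0.1 * iid_cpg) {
    stop("CpG target incompatible with GC target (too depleted to reach)")
  }
  if (cpg_target >= iid_cpg) {
    extra <- cpg_target - iid_cpg
    gc_base <- gc - extra * (2 - 2 * gc)
    if (gc_base <= 0) stop("CpG target incompatible with GC target")
    v <- random_seq_int(len, gc_base)
    n_extra <- round(extra * len)
    if (n_extra > 0L) {
      pos <- sample.int(len - 1L, n_extra)
      # avoid adjacent plants clobbering each other
      pos <- pos[!(pos + 1L) %in% pos]
      v[pos] <- .CODE_C
      v[pos + 1L] <- .CODE_G
    }
    return(v)
  }
  v <- random_seq_int(len, gc)
  target_n <- round(cpg_target * len)
  for (round_i in 1:12) {
    cg <- cpg_starts(v)
    excess <- length(cg) - target_n
    if (excess <= 0L) break
    pick <- if (length(cg) == 1L) cg else sample(cg, min(excess, length(cg)))
    v[pick] <- .CODE_G
    v[pick + 1L] <- .CODE_C
  }
  v
}

#' Build an ancestral genome from a spec
#'
#' Realized GC is checked to be within one percentage point of the target
#' and the CpG rate within 20% of its target; a spec whose targets cannot
#' be realized raises an error. Tandem pairs, repeat intervals, terminal
#' telomeres and the mitogenome are recorded in the returned annotations.
#'
#' @param spec an [ancestor_spec()].
#' @param seed integer seed; the same (spec, seed) gives byte-identical
#'   output.
#' @return list with `seqs` (named character vector), `mito` (string),
#'   `sizes` (chromosome size table with `size_class`), `tandem_pairs`,
#'   `repeats` (BED-like data.frame with `class`), `telomeres`
#'   (planted terminal arrays).
#' @export
build_ancestor <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "ancestor_spec"))
  set.seed(seed)
  ch <- spec$chromosomes
  tel <- if (spec$telomere_units > 0L)
    seq_encode(strrep(TELOMERE_UNIT, spec$telomere_units)) else integer(0)
  tel_len <- length(tel)

  seqs <- vector("list", nrow(ch))
  names(seqs) <- ch$chrom
  telomeres <- NULL
  for (i in seq_len(nrow(ch))) {
    len <- as.integer(ch$length[i])
    core <- .build_chrom_seq(len - 2L * tel_len, ch$gc[i], ch$cpg[i])
    v <- c(tel, core, tel)
    if (tel_len > 0L) {
      telomeres <- rbind(telomeres, data.frame(
        chrom = ch$chrom[i],
        start = c(0L, len - tel_len), end = c(tel_len, len),
        terminal = TRUE, stringsAsFactors = FALSE))
    }
    seqs[[i]] <- v
  }

  # ancestral tandem pairs: overwrite [p, p+2L) with copy||copy so the
  # chromosome length is unchanged
  tandem <- NULL
  if (spec$n_tandem_pairs > 0L) {
    big <- which(ch$length >= 4L * max(spec$tandem_len_range) + 2L * tel_len)
    host <- sample(rep(big, length.out = spec$n_tandem_pairs))
    for (k in seq_len(spec$n_tandem_pairs)) {
      i <- host[k]
      L <- sample(seq(spec$tandem_len_range[1L], spec$tandem_len_range[2L]),
                  1L)
      lo <- tel_len + 1L
      hi <- as.integer(ch$length[i]) - tel_len - 2L * L
      p <- sample(seq(lo, hi), 1L)   # 1-based start of copy 1
      copy <- seqs[[i]][p:(p + L - 1L)]
      seqs[[i]][(p + L):(p + 2L * L - 1L)] <- copy
      tandem <- rbind(tandem, data.frame(
        pair_id = k, chrom = ch$chrom[i],
        c1_start = p - 1L, c1_end = p - 1L + L,
        c2_start = p - 1L + L, c2_end = p - 1L + 2L * L,
        stringsAsFactors = FALSE))
    }
  }

  # planted repeat annotation intervals (LINE/LTR/DNA)
  repeats <- NULL
  if (spec$repeat_density > 0) {
    for (i in seq_len(nrow(ch))) {
      len <- as.integer(ch$length[i])
      n_bp <- round(spec$repeat_density * len)
      n_iv <- max(1L, round(n_bp / 600))
      iv_len <- pmax(80L, as.integer(stats::rexp(n_iv, 1 / 600)))
      st <- sort(sample.int(max(1L, len - max(iv_len) - 1L), n_iv))
      en <- pmin(st + iv_len, len)
      keep <- c(TRUE, st[-1L] > en[-n_iv])   # drop overlapping draws
      repeats <- rbind(repeats, data.frame(
        chrom = ch$chrom[i], start = st[keep] - 1L, end = en[keep],
        class = sample(c("LINE", "LTR", "DNA"), sum(keep), replace = TRUE,
                       prob = c(0.7, 0.15, 0.15)),
        stringsAsFactors = FALSE))
    }
  }

  out_seqs <- vapply(seqs, seq_decode, "")
  realized_gc <- vapply(seqs, function(v) gc_fraction(v), 0)
  if (any(abs(realized_gc - ch$gc) > 0.01)) {
    stop("realized GC missed its target by more than 1 percentage point")
  }
  cpg_rate <- vapply(seqs, function(v) length(cpg_starts(v)) / length(v), 0)
  cpg_target <- ifelse(is.na(ch$cpg), (ch$gc / 2)^2, ch$cpg)
  if (any(abs(cpg_rate - cpg_target) > 0.2 * cpg_target)) {
    stop("realized CpG rate missed its target by more than 20%")
  }

  mito <- seq_decode(random_seq_int(spec$mito_length, spec$mito_gc))
  sizes <- data.frame(chrom = ch$chrom, length = as.integer(ch$length),
                      sex = "autosome", size_class = ch$size_class,
                      stringsAsFactors = FALSE)
  list(seqs = out_seqs, mito = mito, sizes = sizes,
       tandem_pairs = tandem, repeats = repeats, telomeres = telomeres,
       spec = spec)
}
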