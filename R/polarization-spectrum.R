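# Polarization of private small variants against the outgroup and the
# AT-GC substitution layer: panel-wide CpG masking, private-variant
# selection under callability in all genomes, ancestral->derived
# spectra stratified by zygosity and CpG mode, the GC->AT odds ratio
# with its 1-df goodness-of-fit chi-square, equilibrium GC content, the
# window-level pseudocount odds ratio, indel balance tests, and
# branch-specific shared-variant counts.

#' Build the panel-wide CpG mask in reference coordinates
#'
#' A reference position is masked when it, or any position aligned to it
#' in any panel haplotype, is the C or the G of a CG dinucleotide in that
#' genome. Masking in *any* genome suffices.
#'
#' @param ref_seqs named character vector: the reference (outgroup)
#'   scaffolds.
#' @param panel list of haplotype entries, each `list(seqs, map)` with
#'   `map` a [homology_map()] from that haplotype to reference
#'   coordinates.
#' @return named list (per reference scaffold) of sorted 0-based masked
#'   positions.
#' @export
build_cpg_mask <- function(ref_seqs, panel = list()) {
  mask <- lapply(ref_seqs, function(s) {
    v <- seq_encode(s)
    cpg_context_sites(v) - 1L
  })
  for (hp in panel) {
    for (ch in names(hp$seqs)) {
      v <- seq_encode(hp$seqs[[ch]])
      sites <- cpg_context_sites(v) - 1L
      if (!length(sites)) next
      lifted <- lift_positions(hp$map, rep(ch, length(sites)), sites)
      ok <- !is.na(lifted$pos)
      if (!any(ok)) next
      for (rc in unique(lifted$chr[ok])) {
        sel <- ok & lifted$chr == rc
        mask[[rc]] <- c(mask[[rc]], lifted$pos[sel])
      }
    }
  }
  lapply(mask, function(p) sort(unique(p)))
}

.in_mask <- function(mask, chr, pos) {
  out <- logical(length(pos))
  for (ch in unique(chr)) {
    m <- mask[[ch]]
    sel <- chr == ch
    if (is.null(m) || !length(m)) next
    out[sel] <- !is.na(fastmatch_int(pos[sel], m))
  }
  out
}

fastmatch_int <- function(x, table) match(x, table)

.in_regions <- function(regions, chr, pos) {
  out <- logical(length(pos))
  for (ch in unique(chr)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    sel <- which(chr == ch)
    if (!nrow(r)) next
    r <- r[order(r$start), , drop = FALSE]
    idx <- findInterval(pos[sel], r$start)
    out[sel] <- idx >= 1L & pos[sel] < r$end[pmax(idx, 1L)]
  }
  out
}

#' Select private small variants per focal genome
#'
#' A variant is private to genome `g` when no other focal genome carries
#' any variant at the same reference position, and the position is
#' callable (aligned, single-coverage) in every focal genome. The
#' ancestral allele is the outgroup (reference) allele, i.e. pure
#' parsimony; the outgroup itself is never a focal genome.
#'
#' @param variant_sets named list (per focal genome) of diploid variant
#'   data.frames in reference coordinates.
#' @param callable named list (per focal genome) of callable-region
#'   data.frames (`chrom, start, end`).
#' @return named list of private variant data.frames.
#' @export
select_private_small_variants <- function(variant_sets, callable = NULL) {
  genomes <- names(variant_sets)
  site_key <- function(v) paste(v$ref_id, v$pos, sep = "\r")
  occupied <- lapply(variant_sets, function(v) unique(site_key(v)))
  out <- list()
  for (g in genomes) {
    v <- variant_sets[[g]]
    if (!nrow(v)) { out[[g]] <- v; next }
    others <- unlist(occupied[setdiff(genomes, g)], use.names = FALSE)
    priv <- !site_key(v) %in% others
    if (!is.null(callable)) {
      for (h in genomes) {
        priv <- priv & .in_regions(callable[[h]], v$ref_id, v$pos)
      }
    }
    out[[g]] <- v[priv, , drop = FALSE]
    rownames(out[[g]]) <- NULL
  }
  out
}

#' Tabulate an ancestral->derived substitution spectrum
#'
#' Counts private SNVs by (ancestral base, derived base), where the
#' ancestral base is the reference (outgroup) allele. In `no_cpg` mode,
#' variants at masked positions are dropped and the callable AT/GC site
#' tallies exclude masked sites as well.
#'
#' @param variants private SNV data.frame (`ref_id, pos, ref, alt`,
#'   optional `zygosity`).
#' @param cpg_mask mask from [build_cpg_mask()].
#' @param mode `"with_cpg"` or `"no_cpg"`.
#' @param zygosity optional filter (`"fixed"` or `"het"`).
#' @param callable optional callable-region data.frame used with
#'   `ref_seqs` to tally AT/GC callable sites.
#' @param ref_seqs optional reference scaffolds for the site tallies.
#' @return a `substitution_spectrum` list: `counts` (4x4 matrix),
#'   `n_gc_to_at`, `n_at_to_gc`, `n_at_sites`, `n_gc_sites`, `mode`,
#'   `zygosity`.
#' @export
tabulate_spectrum <- function(variants, cpg_mask = NULL,
                              mode = c("with_cpg", "no_cpg"),
                              zygosity = NULL, callable = NULL,
                              ref_seqs = NULL) {
  mode <- match.arg(mode)
  v <- variants[variants$vclass == "SNV", , drop = FALSE]
  if (!is.null(zygosity) && nrow(v)) {
    v <- v[v$zygosity == zygosity, , drop = FALSE]
  }
  if (mode == "no_cpg" && !is.null(cpg_mask) && nrow(v)) {
    v <- v[!.in_mask(cpg_mask, v$ref_id, v$pos), , drop = FALSE]
  }
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, 4L, 4L, dimnames = list(bases, bases))
  if (nrow(v)) {
    tb <- table(factor(v$ref, bases), factor(v$alt, bases))
    counts <- counts + unclass(tb)
  }
  is_gc <- c(FALSE, TRUE, TRUE, FALSE)
  n_gc_to_at <- sum(counts[is_gc, !is_gc])
  n_at_to_gc <- sum(counts[!is_gc, is_gc])
  n_at_sites <- NA_real_; n_gc_sites <- NA_real_
  if (!is.null(callable) && !is.null(ref_seqs)) {
    n_at_sites <- 0; n_gc_sites <- 0
    for (ch in unique(callable$chrom)) {
      r <- callable[callable$chrom == ch, , drop = FALSE]
      v_enc <- seq_encode(ref_seqs[[ch]])
      idx <- unlist(lapply(seq_len(nrow(r)),
                           function(i) (r$start[i] + 1L):r$end[i]))
      if (mode == "no_cpg" && !is.null(cpg_mask) &&
          length(cpg_mask[[ch]])) {
        idx <- setdiff(idx, cpg_mask[[ch]] + 1L)
      }
      b <- v_enc[idx]
      n_at_sites <- n_at_sites + sum(b == .CODE_A | b == .CODE_T)
      n_gc_sites <- n_gc_sites + sum(b == .CODE_C | b == .CODE_G)
    }
  }
  structure(list(counts = counts, n_gc_to_at = n_gc_to_at,
                 n_at_to_gc = n_at_to_gc, n_at_sites = n_at_sites,
                 n_gc_sites = n_gc_sites, mode = mode,
                 zygosity = zygosity %||% "all"),
            class = "substitution_spectrum")
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat(sprintf("substitution spectrum (%s, %s)\n", x$mode, x$zygosity))
  print(x$counts)
  cat(sprintf("GC->AT: %d   AT->GC: %d\n", x$n_gc_to_at, x$n_at_to_gc))
  invisible(x)
}

#' GC->AT odds ratio with goodness-of-fit chi-square
#'
#' The odds ratio is the raw count ratio `N(GC->AT) / N(AT->GC)` over
#' strand-symmetric base classes (changes within a class are excluded);
#' the chi-square is the 1-df goodness of fit of the two direction
#' counts against equal expectation. A zero count triggers the +1
#' pseudocount rule and sets `pseudocount = TRUE`.
#'
#' @param spectrum a `substitution_spectrum` (or a list with
#'   `n_gc_to_at`, `n_at_to_gc`).
#' @return an `odds_ratio_result` list: `or_value, chi2, df, p,
#'   n_gc_to_at, n_at_to_gc, pseudocount`.
#' @export
odds_ratio_test <- function(spectrum) {
  a <- spectrum$n_gc_to_at; b <- spectrum$n_at_to_gc
  if (a + b == 0) stop("no directional substitutions to compare")
  pseudo <- a == 0 || b == 0
  or_value <- if (pseudo) (a + 1) / (b + 1) else a / b
  chi2 <- (a - b)^2 / (a + b)
  structure(list(or_value = or_value, chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, 1L, lower.tail = FALSE),
                 n_gc_to_at = a, n_at_to_gc = b, pseudocount = pseudo),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR(GC->AT) = %.4f  (n = %d vs %d)%s\n", x$or_value,
              x$n_gc_to_at, x$n_at_to_gc,
              if (x$pseudocount) "  [pseudocount]" else ""))
  cat(sprintf("chi2 = %.4g (df = 1), p = %s\n", x$chi2,
              format.pval(x$p)))
  invisible(x)
}

#' Equilibrium GC content from a GC->AT odds ratio
#'
#' `eq_gc = 1 - OR / (1 + OR) = 1 / (1 + OR)`: the stationary GC
#' fraction at which the two substitution fluxes balance. `delta_pct`
#' is the difference from the current GC content in percentage points.
#'
#' @param or either an `odds_ratio_result` or a numeric odds ratio.
#' @param current_gc current GC fraction of the genome (optional).
#' @return an `equilibrium_result` list: `eq_gc, current_gc, delta_pct`.
#' @export
equilibrium_gc <- function(or, current_gc = NA_real_) {
  or_value <- if (inherits(or, "odds_ratio_result")) or$or_value else or
  stopifnot(or_value > 0)
  eq <- 1 / (1 + or_value)
  structure(list(eq_gc = eq, current_gc = current_gc,
                 delta_pct = (eq - current_gc) * 100),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("equilibrium GC = %.2f%%", 100 * x$eq_gc))
  if (!is.na(x$current_gc)) {
    cat(sprintf("  (current %.2f%%, delta %+.2f points)",
                100 * x$current_gc, x$delta_pct))
  }
  cat("\n")
  invisible(x)
}

#' Window-level odds ratio with +1 pseudocounts
#'
#' Upper-bound substitution odds ratio for sparse windows: one
#' substitution of each direction is added so windows lacking one class
#' give neither 0 nor infinity.
#'
#' @param n_gc_to_at,n_at_to_gc direction counts in the window.
#' @export
window_odds_ratio <- function(n_gc_to_at, n_at_to_gc) {
  (n_gc_to_at + 1) / (n_at_to_gc + 1)
}

#' Insertion/deletion balance summary and tests
#'
#' Counts and summed lengths of private insertions vs deletions for one
#' genome, with a two-sided exact binomial test on the counts (null
#' 0.5) and a Welch t test on the per-event lengths.
#'
#' @param variants private small-variant data.frame (uses INS/DEL rows).
#' @param svs optional private SV data.frame; its INS/DEL rows are
#'   summarized separately.
#' @return list with `small` and (when `svs` given) `large`, each
#'   holding `n_ins, n_del, bp_ins, bp_del, count_test, length_test`.
#' @export
indel_balance <- function(variants, svs = NULL) {
  summarize <- function(len_ins, len_del) {
    n_ins <- length(len_ins); n_del <- length(len_del)
    if (n_ins + n_del == 0L) {
      return(list(n_ins = 0L, n_del = 0L, bp_ins = 0L, bp_del = 0L,
                  count_test = NULL, length_test = NULL))
    }
    ct <- exact_binomial(n_ins, n_ins + n_del, 0.5)
    lt <- if (n_ins >= 2L && n_del >= 2L) {
      tryCatch(welch_t(len_ins, len_del), error = function(e) NULL)
    } else NULL
    list(n_ins = n_ins, n_del = n_del,
         bp_ins = sum(len_ins), bp_del = sum(len_del),
         count_test = ct, length_test = lt)
  }
  ind <- variants[variants$vclass %in% c("INS", "DEL"), , drop = FALSE]
  len <- abs(nchar(ind$ref) - nchar(ind$alt))
  out <- list(small = summarize(len[ind$vclass == "INS"],
                                len[ind$vclass == "DEL"]))
  if (!is.null(svs)) {
    s <- svs[svs$svtype %in% c("INS", "DEL"), , drop = FALSE]
    out$large <- summarize(s$length_bp[s$svtype == "INS"],
                           s$length_bp[s$svtype == "DEL"])
  }
  out
}

#' Assign shared variants to tree branches by their carrier sets
#'
#' Each non-private shared variant is assigned to the edge whose
#' descendant tip set equals its carrier set; carrier sets matching no
#' clade are homoplastic. Private variants (singleton carrier sets)
#' count on the terminal edges.
#'
#' @param tree rooted `ape::phylo` whose tip labels are the focal
#'   genomes.
#' @param carriers list of character vectors: the genomes carrying each
#'   variant.
#' @param vclass character vector parallel to `carriers`
#'   (`SNV`/`INS`/`DEL`).
#' @return list with `branch_counts` (data.frame edge x class counts)
#'   and `n_homoplastic`.
#' @export
branch_shared_counts <- function(tree, carriers, vclass) {
  stopifnot(inherits(tree, "phylo"), length(carriers) == length(vclass))
  tips <- tree$tip.label
  bad <- setdiff(unique(unlist(carriers)), tips)
  if (length(bad)) stop("unknown tip in carrier set: ", bad[1L])
  ntip <- length(tips)
  clade_key <- character(nrow(tree$edge))
  # descendant tip sets per edge
  desc <- vector("list", nrow(tree$edge))
  get_tips <- function(node) {
    if (node <= ntip) return(tips[node])
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, get_tips))
  }
  for (ei in seq_len(nrow(tree$edge))) {
    desc[[ei]] <- sort(get_tips(tree$edge[ei, 2L]))
    clade_key[ei] <- paste(desc[[ei]], collapse = "|")
  }
  edge_label <- vapply(seq_len(nrow(tree$edge)), function(ei) {
    node <- tree$edge[ei, 2L]
    if (node <= ntip) tips[node] else paste0("node", node)
  }, "")
  # virtual root edge: a variant carried by every tip
  edge_label <- c(edge_label, "root")
  clade_key <- c(clade_key, paste(sort(tips), collapse = "|"))

  classes <- c("SNV", "DEL", "INS")
  counts <- matrix(0L, length(edge_label), length(classes),
                   dimnames = list(edge_label, classes))
  n_homo <- 0L
  for (i in seq_along(carriers)) {
    key <- paste(sort(unique(carriers[[i]])), collapse = "|")
    ei <- match(key, clade_key)
    cl <- match(vclass[i], classes)
    if (is.na(ei)) {
      n_homo <- n_homo + 1L
    } else if (!is.na(cl)) {
      counts[ei, cl] <- counts[ei, cl] + 1L
    }
  }
  list(branch_counts = data.frame(edge = edge_label,
                                  clade = clade_key,
                                  n_snv = counts[, "SNV"],
                                  n_del = counts[, "DEL"],
                                  n_ins = counts[, "INS"],
                                  row.names = NULL,
                                  stringsAsFactors = FALSE),
       n_homoplastic = n_homo)
}
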