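# Lineage evolution: substitutions (with independently tunable GC->AT and
# AT->GC rates and a CpG-context multiplier), small indels, the five SV
# classes, and NUMT insertions, applied branch by branch down a tree.
# Every event is recorded in root coordinates, so planted variants remain
# addressable after any amount of downstream sequence change.

#' Evolution parameters for one simulated panel
#'
#' Rates are per site (or per bp for event classes) per unit branch
#' length; a branch of length `t` multiplies them all by `t`.
#'
#' @param rate_gc_to_at substitution rate from a G/C base to A/T (`u`).
#' @param rate_at_to_gc substitution rate from an A/T base to G/C (`v`).
#' @param rate_other within-class substitution rate (A<->T, G<->C).
#' @param cpg_multiplier multiplier (>= 1) applied to all substitution
#'   rates at CpG-context sites (the C and the G of each CG).
#' @param indel_rate small-indel rate per bp; lengths are
#'   `1 + Geometric(indel_geom_p)` capped at 49 bp.
#' @param indel_geom_p geometric length parameter for small indels.
#' @param sv_rates named vector of per-bp rates for the five SV classes
#'   `INS, DEL, INV, SEGDUP, SEGDEL` (lengths >= `sv_len_min`).
#' @param sv_len_min,sv_len_mean,sv_len_max SV length distribution:
#'   `min + Exp(mean - min)` truncated at `max`.
#' @param numt_rate NUMT insertion rate per bp.
#' @param numt_len_min,numt_len_mean NUMT fragment length distribution.
#' @param numt_divergence extra per-base divergence applied to the
#'   inserted mito fragment at insertion time.
#' @param numt_micro_weight relative NUMT insertion weight on micro-class
#'   scaffolds (0 reproduces the observed bias away from
#'   microchromosomes).
#' @param het_depth branch length evolved privately by each haplotype
#'   after the shared tip state (0 = haploid output).
#' @param mito_rate substitution rate on the mitogenome per unit branch.
#' @param min_event_gap minimum separation (bp) enforced between planted
#'   indel/SV/NUMT events on a branch, so every event keeps its own
#'   anchor context; events violating it are redrawn.
#' @return an `evolution_params` list.
#' @export
evolution_params <- function(rate_gc_to_at = 1.3e-3,
                             rate_at_to_gc = 1e-3,
                             rate_other = 5e-4,
                             cpg_multiplier = 7,
                             indel_rate = 1.5e-5,
                             indel_geom_p = 0.35,
                             sv_rates = c(INS = 2e-6, DEL = 2e-6,
                                          INV = 2e-6, SEGDUP = 2e-6,
                                          SEGDEL = 5e-7),
                             sv_len_min = 50L,
                             sv_len_mean = 400,
                             sv_len_max = 5000L,
                             numt_rate = 1.5e-6,
                             numt_len_min = 150L,
                             numt_len_mean = 600,
                             numt_divergence = 0.05,
                             numt_micro_weight = 0,
                             het_depth = 0.05,
                             mito_rate = 5e-3,
                             min_event_gap = 150L) {
  p <- as.list(environment())
  stopifnot(all(unlist(p[c("rate_gc_to_at", "rate_at_to_gc", "rate_other",
                           "indel_rate", "numt_rate")]) >= 0),
            p$cpg_multiplier >= 1,
            all(names(p$sv_rates) %in%
                  c("INS", "DEL", "INV", "SEGDUP", "SEGDEL")))
  structure(p, class = "evolution_params")
}

# ---- substitutions ---------------------------------------------------------

# apply branch substitutions to one integer-encoded scaffold; returns
# list(seq, subs = data.frame(pos (0-based), old, new, cpg))
.mutate_subs <- function(v, params, t) {
  n <- length(v)
  if (n == 0L || t <= 0) {
    return(list(seq = v, subs = NULL))
  }
  is_cpg <- logical(n)
  is_cpg[cpg_context_sites(v)] <- TRUE
  is_gc <- v == .CODE_C | v == .CODE_G
  is_at <- v == .CODE_A | v == .CODE_T
  m <- params$cpg_multiplier
  pick <- function(sites, rate) {
    if (!length(sites) || rate <= 0) return(integer(0))
    k <- stats::rbinom(1L, length(sites), min(1, rate))
    if (k == 0L) integer(0) else sample(sites, k)
  }
  gc_cpg <- which(is_gc & is_cpg); gc_non <- which(is_gc & !is_cpg)
  at_cpg <- which(is_at & is_cpg); at_non <- which(is_at & !is_cpg)
  flux <- c(pick(gc_cpg, params$rate_gc_to_at * m * t),
            pick(gc_non, params$rate_gc_to_at * t),
            pick(at_cpg, params$rate_at_to_gc * m * t),
            pick(at_non, params$rate_at_to_gc * t))
  other <- c(pick(gc_cpg, params$rate_other * m * t),
             pick(gc_non, params$rate_other * t),
             pick(at_cpg, params$rate_other * m * t),
             pick(at_non, params$rate_other * t))
  other <- setdiff(other, flux)
  pos <- c(flux, other)
  if (!length(pos)) return(list(seq = v, subs = NULL))
  old <- v[pos]
  new <- integer(length(pos))
  nf <- length(flux)
  if (nf) {
    from_gc <- is_gc[flux]
    new[seq_len(nf)] <- ifelse(from_gc,
                               sample(c(.CODE_A, .CODE_T), nf, TRUE),
                               sample(c(.CODE_G, .CODE_C), nf, TRUE))
  }
  if (length(other)) {
    # within-class swap: A<->T, G<->C
    swap <- c(.CODE_T, .CODE_G, .CODE_C, .CODE_A, .CODE_N)
    new[(nf + 1L):length(pos)] <- swap[v[other]]
  }
  v[pos] <- new
  list(seq = v,
       subs = data.frame(pos = pos - 1L, old = old, new = new,
                         cpg = is_cpg[pos]))
}

# ---- event drawing ---------------------------------------------------------

.rand_len <- function(n, lmin, lmean, lmax) {
  pmin(as.integer(lmin + stats::rexp(n, 1 / (lmean - lmin))), as.integer(lmax))
}

.extract_mito_fragment <- function(mito_v, start0, len, strand, divergence) {
  mlen <- length(mito_v)
  idx <- ((start0 + seq_len(len) - 1L) %% mlen) + 1L
  frag <- mito_v[idx]
  if (strand == "-") frag <- revcomp_int(frag)
  if (divergence > 0) {
    k <- stats::rbinom(1L, len, divergence)
    if (k > 0L) {
      p <- sample.int(len, k)
      frag[p] <- ((frag[p] - 1L + sample(1:3, k, TRUE)) %% 4L) + 1L
    }
  }
  frag
}

# lineage state: list(seqs = named list of int vectors, map (cur->root),
# mito = int vector, micro = named logical per scaffold)
.new_state <- function(seqs, mito, micro_flags) {
  enc <- lapply(seqs, seq_encode)
  list(seqs = enc, map = identity_map(seqs),
       mito = seq_encode(mito), micro = micro_flags)
}

# evolve one branch; env carries the global counters/registries:
#   env$vid        virtual insertion counter
#   env$tandem     tandem registry data.frame (root coords) or NULL
#   env$tandem_used logical vector alongside the registry
#   env$events     accumulating per-edge truth records
.evolve_branch <- function(state, params, t, edge, env) {
  scafs <- names(state$seqs)
  all_subs <- NULL
  # 1. substitutions (draw order fixed: subs, indels, SVs, NUMTs)
  for (ch in scafs) {
    r <- .mutate_subs(state$seqs[[ch]], params, t)
    state$seqs[[ch]] <- r$seq
    if (!is.null(r$subs) && nrow(r$subs)) {
      r$subs$chr <- ch
      all_subs <- rbind(all_subs, r$subs)
    }
  }
  # mito substitutions
  if (params$mito_rate > 0 && t > 0) {
    mv <- state$mito
    k <- stats::rbinom(1L, length(mv), min(1, params$mito_rate * t))
    if (k > 0L) {
      p <- sample.int(length(mv), k)
      mv[p] <- ((mv[p] - 1L + sample(1:3, k, TRUE)) %% 4L) + 1L
      state$mito <- mv
    }
  }

  # 2./3./4. indels, SVs, NUMTs as edits
  edits_by_scaf <- stats::setNames(vector("list", length(scafs)), scafs)
  truth_rows <- list()
  eid <- 0L
  lens <- vapply(state$seqs, length, 0L)
  add_edit <- function(ch, e) {
    edits_by_scaf[[ch]] <<- c(edits_by_scaf[[ch]], list(e))
  }
  scaffold_gc <- vapply(state$seqs, gc_fraction, 0)

  if (t > 0) {
    for (ch in scafs) {
      n <- lens[[ch]]
      # small indels
      ni <- stats::rpois(1L, n * params$indel_rate * t)
      if (ni > 0L) {
        ilen <- pmin(1L + stats::rgeom(ni, params$indel_geom_p), 49L)
        is_ins <- stats::runif(ni) < 0.5
        pos <- sample.int(n - 60L, ni)
        for (j in seq_len(ni)) {
          eid <- eid + 1L
          if (is_ins[j]) {
            env$vid <- env$vid + 1L
            add_edit(ch, new_edit(eid, pos[j], "SMALL_INS",
                                  ins = random_seq_int(ilen[j],
                                                       scaffold_gc[[ch]]),
                                  vchr = sprintf("v%07d", env$vid)))
          } else {
            add_edit(ch, new_edit(eid, pos[j], "SMALL_DEL",
                                  del_len = ilen[j]))
          }
        }
      }
      # large SVs (SEGDEL handled at genome level below)
      for (cls in c("INS", "DEL", "INV", "SEGDUP")) {
        rate <- params$sv_rates[[cls]] %||% 0
        if (is.na(rate) || rate <= 0) next
        nk <- stats::rpois(1L, n * rate * t)
        if (nk == 0L) next
        svl <- .rand_len(nk, params$sv_len_min, params$sv_len_mean,
                         params$sv_len_max)
        for (j in seq_len(nk)) {
          L <- svl[j]
          if (n < 2L * L + 100L) next
          p <- sample.int(n - 2L * L - 60L, 1L)
          eid <- eid + 1L
          e <- switch(cls,
            INS = {
              env$vid <- env$vid + 1L
              new_edit(eid, p, "INS",
                       ins = random_seq_int(L, scaffold_gc[[ch]]),
                       vchr = sprintf("v%07d", env$vid))
            },
            DEL = new_edit(eid, p, "DEL", del_len = L),
            INV = new_edit(eid, p, "INV", inv_len = L),
            SEGDUP = {
              env$vid <- env$vid + 1L
              new_edit(eid, p + L, "SEGDUP",
                       ins = state$seqs[[ch]][(p + 1L):(p + L)],
                       vchr = sprintf("v%07d", env$vid),
                       meta = list(src_start = p, src_end = p + L))
            })
          add_edit(ch, e)
        }
      }
    }
    # SEGDEL: consume ancestral tandem pairs
    rate_sd <- params$sv_rates[["SEGDEL"]] %||% 0
    if (!is.na(rate_sd) && rate_sd > 0 && !is.null(env$tandem)) {
      nk <- stats::rpois(1L, sum(lens) * rate_sd * t)
      avail <- which(!env$tandem_used)
      nk <- min(nk, length(avail))
      if (nk > 0L) {
        take <- if (length(avail) == 1L) avail else sample(avail, nk)
        for (pid in take) {
          tp <- env$tandem[pid, ]
          hit <- lift_interval(invert_map(state$map), tp$root_chr,
                               tp$c2_start, tp$c2_end)
          if (nrow(hit) != 1L || hit$partial[1L] || hit$strand[1L] != "+") {
            next
          }
          env$tandem_used[pid] <- TRUE
          eid <- eid + 1L
          add_edit(hit$chr[1L],
                   new_edit(eid, hit$start[1L], "SEGDEL",
                            del_len = hit$end[1L] - hit$start[1L],
                            meta = list(pair_id = tp$pair_id)))
        }
      }
    }
    # NUMTs: insertion probability proportional to scaffold length,
    # down-weighted (default zero) on micro-class scaffolds
    if (params$numt_rate > 0) {
      w <- lens * ifelse(state$micro[scafs], params$numt_micro_weight, 1)
      if (sum(w) > 0) {
        nk <- stats::rpois(1L, sum(w) * params$numt_rate * t)
        for (j in seq_len(nk)) {
          ch <- sample(scafs, 1L, prob = w)
          p <- sample.int(lens[[ch]] - 60L, 1L)
          L <- .rand_len(1L, params$numt_len_min, params$numt_len_mean,
                         length(state$mito) - 1L)
          mstart <- sample.int(length(state$mito), 1L) - 1L
          strand <- if (stats::runif(1L) < 0.5) "+" else "-"
          frag <- .extract_mito_fragment(state$mito, mstart, L, strand,
                                         params$numt_divergence)
          env$vid <- env$vid + 1L
          eid <- eid + 1L
          add_edit(ch, new_edit(eid, p, "NUMT", ins = frag,
                                vchr = sprintf("v%07d", env$vid),
                                meta = list(mito_start = mstart,
                                            mito_end = mstart + L,
                                            mito_strand = strand)))
        }
      }
    }
  }

  # resolve overlaps by redrawing positions (bounded retries). Ancestral
  # tandem-pair loci act as immovable barriers so no other edit lands in
  # them and destroys the paralog anchor geometry; the pair's own SEGDEL
  # deletion is exempt.
  margin <- params$min_event_gap %||% 0L
  barriers_by_scaf <- list()
  inv_map <- invert_map(state$map)
  zone_src <- NULL
  if (!is.null(env$tandem)) {
    zone_src <- data.frame(
      chr = env$tandem$root_chr,
      start = pmin(env$tandem$c1_start, env$tandem$c2_start),
      end = pmax(env$tandem$c1_end, env$tandem$c2_end),
      stringsAsFactors = FALSE)
  }
  if (!is.null(env$zones)) zone_src <- rbind(zone_src, env$zones)
  if (!is.null(zone_src)) {
    bid <- 0L
    for (i in seq_len(nrow(zone_src))) {
      r <- lift_interval(inv_map, zone_src$chr[i], zone_src$start[i],
                         zone_src$end[i])
      for (j in seq_len(nrow(r))) {
        if (r$chr[j] %in% scafs) {
          bid <- bid - 1L
          barriers_by_scaf[[r$chr[j]]] <-
            c(barriers_by_scaf[[r$chr[j]]],
              list(new_edit(bid, r$start[j], "BARRIER",
                            del_len = r$end[j] - r$start[j])))
        }
      }
    }
  }
  conflicts <- function(ed) {
    n <- length(ed)
    if (n < 2L) return(integer(0))
    iv <- t(vapply(ed, .edit_interval, numeric(2)))
    iv[, 2L] <- pmax(iv[, 2L], iv[, 1L] + 1L) + margin
    kind <- vapply(ed, `[[`, "", "kind")
    bad <- integer(0)
    o <- order(iv[, 1L])
    for (a in seq_len(n - 1L)) {
      i <- o[a]; j <- o[a + 1L]
      if (iv[i, 2L] > iv[j, 1L]) {
        fixed_kinds <- c("BARRIER", "SEGDEL")
        mov <- c(i, j)[!kind[c(i, j)] %in% fixed_kinds]
        if (length(mov)) bad <- c(bad, mov[1L])
      }
    }
    unique(bad)
  }
  for (ch in scafs) {
    ed <- c(edits_by_scaf[[ch]], barriers_by_scaf[[ch]])
    if (length(ed) >= 2L) {
      tries <- 0L
      bad <- conflicts(ed)
      while (length(bad) && tries < 1000L) {
        for (b in bad) {
          w <- max(ed[[b]]$del_len, ed[[b]]$inv_len, length(ed[[b]]$ins))
          ed[[b]]$pos <- sample.int(max(1L, lens[[ch]] - 2L * w - 60L), 1L)
        }
        tries <- tries + 1L
        bad <- conflicts(ed)
      }
      if (length(bad)) {
        stop("could not place non-overlapping SV edits after 1000 ",
             "retries on ", ch)
      }
    }
    edits_by_scaf[[ch]] <-
      ed[vapply(ed, `[[`, "", "kind") != "BARRIER"]
  }

  # record substitution truth (root coordinates via the pre-edit map),
  # dropping hits that a same-branch deletion or inversion will erase
  if (!is.null(all_subs) && nrow(all_subs)) {
    drop <- logical(nrow(all_subs))
    for (ch in scafs) {
      for (e in edits_by_scaf[[ch]]) {
        w <- max(e$del_len, e$inv_len)
        if (w > 0L) {
          drop <- drop | (all_subs$chr == ch & all_subs$pos >= e$pos &
                            all_subs$pos < e$pos + w)
        }
      }
    }
    all_subs <- all_subs[!drop, , drop = FALSE]
    lifted <- lift_positions(state$map, all_subs$chr, all_subs$pos)
    all_subs$root_chr <- lifted$chr
    all_subs$root_pos <- lifted$pos
    all_subs$root_strand <- lifted$strand
    all_subs$edge <- edge
  }

  # apply edits and record their truth
  for (ch in scafs) {
    ed <- edits_by_scaf[[ch]]
    if (!length(ed)) next
    pre_map <- state$map
    for (e in ed) {
      w <- max(e$del_len, e$inv_len)
      root <- if (w > 0L) {
        lift_interval(pre_map, ch, e$pos, e$pos + w)
      } else {
        lift_positions(pre_map, ch, max(0L, e$pos - 1L))
      }
      meta <- e$meta
      src_root <- NULL
      if (e$kind == "SEGDUP") {
        src_root <- lift_interval(pre_map, ch, meta$src_start, meta$src_end)
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        edge = edge, kind = e$kind,
        length = max(w, length(e$ins)),
        vchr = e$vchr,
        root_chr = if (w > 0L) root$chr[1L] %||% NA_character_
                   else root$chr[1L],
        root_start = if (w > 0L) root$start[1L] %||% NA_integer_
                     else root$pos[1L],
        root_end = if (w > 0L) root$end[1L] %||% NA_integer_
                   else root$pos[1L],
        n_root_pieces = if (w > 0L) nrow(root) else 1L,
        src_root_chr = if (!is.null(src_root) && nrow(src_root))
          src_root$chr[1L] else NA_character_,
        src_root_start = if (!is.null(src_root) && nrow(src_root))
          src_root$start[1L] else NA_integer_,
        src_root_end = if (!is.null(src_root) && nrow(src_root))
          src_root$end[1L] else NA_integer_,
        pair_id = if (e$kind == "SEGDEL") meta$pair_id else NA_integer_,
        mito_start = if (e$kind == "NUMT") meta$mito_start else NA_integer_,
        mito_end = if (e$kind == "NUMT") meta$mito_end else NA_integer_,
        mito_strand = if (e$kind == "NUMT") meta$mito_strand
                      else NA_character_,
        stringsAsFactors = FALSE)
    }
    sel <- state$map$f_chr == ch
    res <- apply_edits(state$seqs[[ch]], state$map[sel, , drop = FALSE], ed)
    state$seqs[[ch]] <- res$seq
    df <- as.data.frame(state$map)[!sel, , drop = FALSE]
    state$map <- homology_map(rbind(df, res$pieces))
  }

  # register event loci as exclusion zones for later branches, so no
  # lineage plants an event on top of (or immediately beside) another
  # lineage's event and corrupts both anchor contexts
  if (length(truth_rows)) {
    tdf <- do.call(rbind, truth_rows)
    zs <- list()
    for (i in which(tdf$kind %in% c("INS", "DEL", "INV", "SEGDUP",
                                    "SEGDEL", "NUMT"))) {
      if (!is.na(tdf$root_chr[i]) && !startsWith(tdf$root_chr[i], "v")) {
        zend <- if (tdf$kind[i] %in% c("DEL", "INV", "SEGDEL")) {
          tdf$root_end[i]
        } else tdf$root_start[i] + 1L
        zs[[length(zs) + 1L]] <- data.frame(
          chr = tdf$root_chr[i], start = tdf$root_start[i], end = zend,
          stringsAsFactors = FALSE)
      }
      if (!is.na(tdf$vchr[i])) {
        zs[[length(zs) + 1L]] <- data.frame(
          chr = tdf$vchr[i], start = 0L, end = tdf$length[i],
          stringsAsFactors = FALSE)
      }
    }
    if (length(zs)) env$zones <- rbind(env$zones, do.call(rbind, zs))
  }

  env$events[[edge]] <- list(
    snvs = all_subs,
    edits = if (length(truth_rows)) do.call(rbind, truth_rows) else NULL)
  state
}

#' Evolve a panel of diploid genomes down a tree
#'
#' The root genome is evolved along every edge of `tree` in preorder; at
#' each tip the shared state is split into two haplotypes that each
#' evolve a further `het_depth` of private branch length. All rates are
#' multiplied by branch length. Events on shared edges are `fixed` in
#' every descendant; events on haplotype branches are `het`.
#'
#' @param seqs named character vector: the root genome.
#' @param mito root mitogenome string.
#' @param params an [evolution_params()].
#' @param tree rooted `ape::phylo` with branch lengths; tip labels name
#'   the genomes.
#' @param micro_flags named logical: is each root scaffold micro-class
#'   (used for the NUMT insertion bias)? Default all FALSE.
#' @param tandem_pairs optional tandem-pair registry in root coordinates
#'   (data.frame with `pair_id, root_chr, c1_start, c1_end, c2_start,
#'   c2_end`).
#' @param protected optional data.frame (`chr, start, end`, root
#'   coordinates) of regions no indel/SV/NUMT edit may touch (junction
#'   telomere arrays, for instance, must stay where they were planted);
#'   substitutions still occur there.
#' @param seed integer seed (one RNG stream for the whole panel).
#' @return list with `tips` (per genome: `hap1`/`hap2`, each
#'   `list(seqs, map)`, plus `mito`), `events` (per edge: `snvs`,
#'   `edits`), `edge_tips` (per edge: carrier tip set), and the `tree`.
#' @export
evolve_panel <- function(seqs, mito, params, tree,
                         micro_flags = NULL, tandem_pairs = NULL,
                         protected = NULL, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  set.seed(seed)
  if (is.null(micro_flags)) {
    micro_flags <- stats::setNames(rep(FALSE, length(seqs)), names(seqs))
  }
  env <- new.env(parent = emptyenv())
  env$vid <- 0L
  env$events <- list()
  if (!is.null(protected) && nrow(protected)) {
    env$zones <- data.frame(chr = protected$chr,
                            start = protected$start,
                            end = protected$end,
                            stringsAsFactors = FALSE)
  }
  if (!is.null(tandem_pairs)) {
    env$tandem <- tandem_pairs
    env$tandem_used <- rep(FALSE, nrow(tandem_pairs))
  } else {
    env$tandem <- NULL
  }

  ntip <- length(tree$tip.label)
  node_label <- function(nd) {
    if (nd <= ntip) tree$tip.label[nd] else paste0("node", nd)
  }
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  root <- ntip + 1L
  tips <- list()
  edge_tips <- list()

  descend <- function(node, state) {
    for (ei in children[[as.character(node)]]) {
      child <- tree$edge[ei, 2L]
      lab <- node_label(child)
      st <- .evolve_branch(state, params, tree$edge.length[ei], lab, env)
      if (child <= ntip) {
        g <- tree$tip.label[child]
        if (params$het_depth > 0) {
          h1 <- .evolve_branch(st, params, params$het_depth,
                               paste0(g, "::hap1"), env)
          h2 <- .evolve_branch(st, params, params$het_depth,
                               paste0(g, "::hap2"), env)
        } else {
          h1 <- st; h2 <- st
        }
        tips[[g]] <<- list(
          hap1 = list(seqs = lapply(h1$seqs, seq_decode), map = h1$map),
          hap2 = list(seqs = lapply(h2$seqs, seq_decode), map = h2$map),
          mito = seq_decode(st$mito))
      } else {
        descend(child, st)
      }
    }
  }

  state0 <- .new_state(seqs, mito, micro_flags)
  descend(root, state0)

  # carrier tip set per edge
  tipset <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]],
                  function(ei) tipset(tree$edge[ei, 2L])))
  }
  for (ei in seq_len(nrow(tree$edge))) {
    child <- tree$edge[ei, 2L]
    edge_tips[[node_label(child)]] <- sort(tipset(child))
  }
  for (g in tree$tip.label) {
    edge_tips[[paste0(g, "::hap1")]] <- g
    edge_tips[[paste0(g, "::hap2")]] <- g
  }

  list(tips = tips, events = env$events, edge_tips = edge_tips,
       tree = tree, tandem_used = if (is.null(env$tandem)) NULL
       else env$tandem_used)
}

#' Expected substitution-count odds ratio for a genome under given rates
#'
#' `N(GC->AT) / N(AT->GC)` expected from the per-class site tallies of
#' `seqs`, including the CpG-context multiplier (CpG-context sites are G
#' or C, so the multiplier inflates only the GC->AT numerator).
#'
#' @param seqs named character vector.
#' @param params an [evolution_params()].
#' @return the expected count odds ratio.
#' @export
expected_count_or <- function(seqs, params) {
  n_gc_cpg <- 0; n_gc_non <- 0; n_at <- 0
  for (s in seqs) {
    v <- seq_encode(s)
    cpg <- logical(length(v))
    cpg[cpg_context_sites(v)] <- TRUE
    gc <- v == .CODE_C | v == .CODE_G
    at <- v == .CODE_A | v == .CODE_T
    n_gc_cpg <- n_gc_cpg + sum(gc & cpg)
    n_gc_non <- n_gc_non + sum(gc & !cpg)
    n_at <- n_at + sum(at)
  }
  m <- params$cpg_multiplier
  (params$rate_gc_to_at * (n_gc_non + m * n_gc_cpg)) /
    (params$rate_at_to_gc * n_at)
}
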