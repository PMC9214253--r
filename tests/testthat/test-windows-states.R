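test_that("window tiling floors at the scaffold end and stays disjoint", {
  w <- make_windows(c(s1 = 250000L, s2 = 99000L), 100000L)
  expect_equal(nrow(w), 2L)
  expect_equal(w$chrom, c("s1", "s1"))
  expect_equal(w$start, c(0L, 100000L))
  expect_true(all(w$end[-nrow(w)] <= w$start[-1] |
                    w$chrom[-nrow(w)] != w$chrom[-1]))
  expect_equal(nrow(make_windows(c(s = 99000L), 100000L)), 0L)
})

test_that("composition counts GC over non-N bases and scans CpG overlaps", {
  seqs <- c(s = strrep("ACGT", 2500))
  w <- window_composition(make_windows(c(s = 10000L), 5000L), seqs)
  expect_equal(w$gc_pct, c(50, 50))
  # each ACGT repeat has one CG; boundary pair splits are not counted
  expect_equal(w$cpg_count[1], 1250L)

  seqs2 <- c(s = paste0("ACGCGT", strrep("A", 9994)))
  w2 <- window_composition(make_windows(c(s = 10000L), 10000L), seqs2)
  expect_equal(w2$cpg_count, 2L)

  seqs3 <- c(s = paste0("ANGC", strrep("N", 9996)))
  w3 <- window_composition(make_windows(c(s = 10000L), 10000L), seqs3)
  expect_equal(w3$gc_pct, 100 * 2 / 3, tolerance = 1e-9)
})

test_that("isochore families split at the classical GC boundaries", {
  expect_equal(isochore_family(36.9), "L1")
  expect_equal(isochore_family(37), "L2")
  expect_equal(isochore_family(41.0), "H1")
  expect_equal(isochore_family(46), "H2")
  expect_equal(isochore_family(60), "H3")
  # total and deterministic over the whole range
  g <- seq(0, 100, by = 0.25)
  f <- isochore_family(g)
  expect_false(anyNA(f))
  expect_identical(f, isochore_family(g))
})

test_that("state assignment takes the size-class consensus across assemblies", {
  w <- data.frame(chrom = "f", start = 0L, end = 100000L)
  cfg <- size_class_config(20e6, 40e6)
  mk_asm <- function(chroms, lens, sex = "autosome") {
    list(blocks = data.frame(
      ref_id = chroms, ref_start = 0L, ref_end = 50000L,
      qry_id = "f", qry_start = 0L, qry_end = 50000L, strand = "+",
      identity = 1, stringsAsFactors = FALSE),
      sizes = data.frame(chrom = chroms, length = lens, sex = sex,
                         stringsAsFactors = FALSE))
  }
  # micro-sized hits in all three assemblies
  res <- assign_state(w, list(mk_asm("c1", 15e6), mk_asm("c2", 12e6),
                              mk_asm("c3", 18e6)), cfg)
  expect_equal(res$state, "micro")
  # one conflicting hit makes the window ambiguous
  res2 <- assign_state(w, list(mk_asm("c1", 15e6), mk_asm("c2", 45e6)), cfg)
  expect_equal(res2$state, "ambiguous")
  # no alignment at all
  res3 <- assign_state(w, list(list(blocks = mk_asm("c1", 15e6)$blocks[0, ],
                                    sizes = mk_asm("c1", 15e6)$sizes)), cfg)
  expect_equal(res3$state, "unaligned")
  # sex chromosomes flag the window
  res4 <- assign_state(w, list(mk_asm("cZ", 80e6, sex = "Z")), cfg)
  expect_equal(res4$sex_flag, "Z")
  expect_error(assign_state(w, list(list(blocks = mk_asm("c1", 1e6)$blocks,
                                         sizes = NULL))),
               "size table")
})

test_that("feature aggregation clips repeats and signs net indel bp", {
  w <- make_windows(c(s = 200000L), 100000L)
  reps <- data.frame(chrom = "s", start = 50000L, end = 150000L)
  v <- data.frame(chrom = "s", pos = c(10L, 120000L),
                  ref = c("A", "ATT"), alt = c("ATTTT", "A"),
                  vclass = c("INS", "DEL"), stringsAsFactors = FALSE)
  svs <- data.frame(svtype = c("INS", "DEL"), qry_id = "s",
                    qry_start = c(10000L, 110000L),
                    qry_end = c(10000L, 110200L),
                    length_bp = c(200L, 50L), stringsAsFactors = FALSE)
  out <- aggregate_features(w, v, svs, reps, NULL)
  expect_equal(out$te_bases, c(50000, 50000))
  # window 1: +4 (small INS) + 200 (SV INS); window 2: -2 - 50
  expect_equal(out$net_indel_bp, c(204, -52))
  expect_equal(out$n_sv_ins, c(1L, 0L))
  expect_equal(out$n_sv_del, c(0L, 1L))

  zero <- aggregate_features(w)
  expect_true(all(zero$te_bases == 0) && all(zero$n_snv == 0L))
})

test_that("fused micro windows get ancestral micro, current macro states", {
  fx <- small_panel()
  panel <- fx$panel
  hp <- panel$genomes$g1$hap1
  w <- make_windows(vapply(hp$seqs, nchar, 0L), 20000L)
  truth_cls <- truth_window_anc_class(panel, "g1", 1, w)

  og_sizes <- data.frame(chrom = names(panel$outgroup$seqs),
                         length = nchar(panel$outgroup$seqs),
                         stringsAsFactors = FALSE)
  own_sizes <- data.frame(chrom = names(hp$seqs),
                          length = vapply(hp$seqs, nchar, 0L),
                          stringsAsFactors = FALSE)
  cfg <- panel$size_classes
  anc <- assign_state(w, list(list(blocks = fx$blocks$g1[[1]],
                                   sizes = og_sizes)), cfg)
  cur <- assign_state(w, list(list(
    blocks = map_to_blocks(identity_map(unlist(hp$seqs))),
    sizes = own_sizes)), cfg)

  clean <- !is.na(truth_cls) & truth_cls != "mixed" &
    anc$state %in% c("micro", "intermediate", "macro")
  expect_gt(sum(clean), 10L)
  expect_identical(anc$state[clean], truth_cls[clean])
  # the fused scaffold exceeds the micro threshold: ancestrally micro
  # windows now sit on a large chromosome
  fused_micro <- clean & truth_cls == "micro" &
    w$chrom == names(panel$fused$seqs)[1]
  expect_gt(sum(fused_micro), 0L)
  expect_true(all(cur$state[fused_micro] == "macro"))
})
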