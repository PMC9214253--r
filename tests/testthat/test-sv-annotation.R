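mk_blocks <- function(rs, re, qs, qe, strand = "+") {
  data.frame(ref_id = "r", ref_start = rs, ref_end = re,
             qry_id = "q", qry_start = qs, qry_end = qe,
             strand = strand, identity = 1, len1 = re - rs, len2 = qe - qs,
             stringsAsFactors = FALSE)
}

test_that("anchor-gap pairs classify as INS/DEL only when one side is clean", {
  run_ins <- mk_blocks(c(0L, 1000L), c(1000L, 2000L),
                       c(0L, 1100L), c(1000L, 2100L))
  sv <- classify_large_indels(list(run_ins))
  expect_equal(sv$svtype, "INS")
  expect_equal(sv$length_bp, 100L)

  run_del <- mk_blocks(c(0L, 1100L), c(1000L, 2100L),
                       c(0L, 1000L), c(1000L, 2000L))
  sv <- classify_large_indels(list(run_del))
  expect_equal(sv$svtype, "DEL")
  expect_equal(sv$length_bp, 100L)

  run_both <- mk_blocks(c(0L, 1060L), c(1000L, 2060L),
                        c(0L, 1060L), c(1000L, 2060L))
  expect_equal(nrow(classify_large_indels(list(run_both))), 0L)
})

test_that("inversions follow majority-rule directionality", {
  b <- mk_blocks(c(0L, 1000L, 1200L), c(1000L, 1200L, 2200L),
                 c(0L, 1000L, 1200L), c(1000L, 1200L, 2200L),
                 strand = c("+", "-", "+"))
  sv <- classify_inversions(b)
  expect_equal(sv$svtype, "INV")
  expect_equal(sv$length_bp, 200L)

  # all blocks minus: the majority is minus, so zero inversions
  b2 <- b; b2$strand <- "-"
  expect_equal(nrow(classify_inversions(b2)), 0L)

  # a run of two 40 bp minority blocks aggregates to one 80 bp INV
  b3 <- mk_blocks(c(0L, 1000L, 1050L, 1100L),
                  c(1000L, 1040L, 1090L, 2100L),
                  c(0L, 1000L, 1050L, 1100L),
                  c(1000L, 1040L, 1090L, 2100L),
                  strand = c("+", "-", "-", "+"))
  sv3 <- classify_inversions(b3)
  expect_equal(nrow(sv3), 1L)
  expect_equal(sv3$length_bp, 80L)
})

test_that("flipping every strand leaves the inversion set unchanged", {
  b <- mk_blocks(c(0L, 1000L, 1200L, 1500L),
                 c(1000L, 1200L, 1500L, 3000L),
                 c(0L, 1000L, 1200L, 1500L),
                 c(1000L, 1200L, 1500L, 3000L),
                 strand = c("+", "-", "+", "+"))
  flip <- b
  flip$strand <- ifelse(b$strand == "+", "-", "+")
  a1 <- classify_inversions(b)
  a2 <- classify_inversions(flip)
  expect_equal(a1[c("ref_start", "ref_end", "length_bp")],
               a2[c("ref_start", "ref_end", "length_bp")])
})

test_that("segmental events need >= 2 blocks onto one proximal locus", {
  # two disjoint 1 kb query blocks onto the same reference kb -> SEGDUP
  b <- mk_blocks(c(0L, 0L), c(1000L, 1000L),
                 c(0L, 1000L), c(1000L, 2000L))
  sv <- classify_segmental(b)
  expect_equal(sv$svtype, "SEGDUP")
  expect_equal(sv$length_bp, 1000L)

  # mirror: two reference blocks onto one query locus -> SEGDEL
  b2 <- mk_blocks(c(0L, 1000L), c(1000L, 2000L),
                  c(0L, 0L), c(1000L, 1000L))
  expect_equal(classify_segmental(b2)$svtype, "SEGDEL")

  # overlap of only 30 bp < 50 -> no call
  b3 <- mk_blocks(c(0L, 970L), c(1000L, 2000L),
                  c(0L, 2000L), c(1000L, 3030L))
  expect_equal(nrow(classify_segmental(b3)), 0L)
})

test_that("duplicated-region exclusion removes calls at multi-covered loci", {
  blocks <- rbind(
    mk_blocks(c(0L, 5000L), c(4000L, 9000L), c(0L, 5000L),
              c(4000L, 9000L)),
    mk_blocks(2000L, 3000L, 10000L, 11000L))   # second cover of ref 2-3k
  keep <- data.frame(svtype = "DEL", ref_id = "r", ref_start = 4200L,
                     ref_end = 4400L, qry_id = "q", qry_start = 4200L,
                     qry_end = 4200L, length_bp = 200L,
                     stringsAsFactors = FALSE)
  drop <- keep
  drop$ref_start <- 2500L; drop$ref_end <- 2700L
  out <- exclude_duplicated(rbind(keep, drop), blocks)
  expect_equal(nrow(out), 1L)
  expect_equal(out$ref_start, 4200L)

  # an inversion overlapping a SEGDUP locus is removed
  seg <- data.frame(svtype = "SEGDUP", ref_id = "r", ref_start = 6000L,
                    ref_end = 6500L, qry_id = "q", qry_start = 12000L,
                    qry_end = 12500L, length_bp = 500L,
                    stringsAsFactors = FALSE)
  inv <- keep
  inv$svtype <- "INV"; inv$ref_start <- 6400L; inv$ref_end <- 6800L
  out2 <- exclude_duplicated(inv, blocks, seg_svs = seg)
  expect_equal(nrow(out2), 0L)

  # empty block index leaves the catalog unchanged
  expect_equal(exclude_duplicated(keep, blocks[0, , drop = FALSE]), keep)
})

test_that("the private filter removes same-type overlaps across genomes", {
  sv <- function(g, tp, s, e) {
    data.frame(svtype = tp, ref_id = "r", ref_start = s, ref_end = e,
               qry_id = "q", qry_start = s, qry_end = e,
               length_bp = e - s, genome_id = g, stringsAsFactors = FALSE)
  }
  catalog <- rbind(
    sv("g1", "DEL", 100L, 300L), sv("g2", "DEL", 150L, 350L),
    sv("g3", "DEL", 200L, 250L),          # identical locus in 3 genomes
    sv("g1", "DEL", 5000L, 5200L),        # private deletion
    sv("g1", "DEL", 9000L, 9100L), sv("g2", "INV", 9000L, 9100L))
  out <- private_filter(catalog)
  expect_equal(nrow(out), 3L)
  # the shared DEL is removed from every genome
  expect_false(any(out$ref_start < 1000))
  # type mismatch does not mask: both the DEL and the INV survive
  expect_setequal(out$svtype[out$ref_start == 9000], c("DEL", "INV"))
})

test_that("SV classification is invariant to block input order", {
  fx <- small_panel()
  b <- fx$blocks$g1[[1]]
  set.seed(12)
  shuffled <- b[sample.int(nrow(b)), , drop = FALSE]
  a1 <- classify_svs(b)
  a2 <- classify_svs(shuffled)
  key <- function(x) {
    sort(paste(x$svtype, x$ref_id, x$ref_start, x$ref_end, x$length_bp))
  }
  expect_identical(key(a1), key(a2))
})

test_that("planted SVs are recovered with high recall and precision", {
  fx <- small_panel()
  panel <- fx$panel
  n_fn <- 0L; n_fp <- 0L; n_truth <- 0L; n_calls <- 0L
  for (g in names(panel$genomes)) {
    for (hap in 1:2) {
      calls <- classify_svs(fx$blocks[[g]][[hap]])
      truth <- truth_sv_table(panel, g, hap)
      m <- match_svs(calls, truth)
      n_fn <- n_fn + sum(!m$hit & m$detectable)
      n_fp <- n_fp + sum(m$used == FALSE)
      n_truth <- n_truth + sum(m$detectable)
      n_calls <- n_calls + nrow(calls)
    }
  }
  expect_gt(n_truth, 60L)
  expect_gte(1 - n_fn / n_truth, 0.95)
  expect_gte(1 - n_fp / n_calls, 0.95)
})
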