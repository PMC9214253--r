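rand_seq <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

test_that("template preparation rotates to the anchor and doubles", {
  t <- prepare_template("CCCAAATTT", "AAA")
  expect_equal(t$rotated, "AAATTTCCC")
  expect_equal(nchar(t$doubled), 18L)
  # rotation preserves the circular k-mer multiset
  circ_kmers <- function(s, k = 3) {
    d <- paste0(s, substr(s, 1, k - 1))
    sort(vapply(1:nchar(s), function(i) substr(d, i, i + k - 1), ""))
  }
  expect_identical(circ_kmers("CCCAAATTT"), circ_kmers(t$rotated))
  expect_error(prepare_template("CCCAAATTT", "GGG"), "absent")
  expect_error(prepare_template("AAATTTAAA", "AAA"), "more than once")
})

test_that("seed-and-extend finds planted fragments and nothing in noise", {
  mito <- rand_seq(8000, 0.45, seed = 51)
  tmpl <- prepare_template(mito)
  host <- rand_seq(300000, 0.42, seed = 52)
  frag <- strsplit(substr(mito, 2001, 2500), "")[[1]]
  set.seed(53)
  mut <- sample(500, 75)                       # 85% identity
  frag[mut] <- sample(c("A", "C", "G", "T"), 75, TRUE)
  planted <- paste0(substr(host, 1, 150000), paste(frag, collapse = ""),
                    substring(host, 150001))
  hits <- detect_numts(c(s = planted), tmpl)
  expect_equal(nrow(hits), 1L)
  ov <- min(hits$end, 150500) - max(hits$start, 150000)
  expect_gte(ov, 0.9 * 500)
  expect_gt(hits$identity, 0.80)

  # seeded random negative control
  neg <- detect_numts(c(s = rand_seq(500000, 0.42, seed = 54)), tmpl)
  expect_equal(nrow(neg), 0L)
})

test_that("a fragment spanning the circular origin is one hit", {
  mito <- rand_seq(6000, 0.45, seed = 55)
  tmpl <- prepare_template(mito)
  frag <- paste0(substring(mito, 5701), substr(mito, 1, 300))  # wraps
  host <- rand_seq(100000, 0.42, seed = 56)
  planted <- paste0(substr(host, 1, 50000), frag, substring(host, 50001))
  hits <- detect_numts(c(s = planted), tmpl)
  expect_equal(nrow(hits), 1L)
  expect_gte(hits$length_bp, 0.95 * 600)
  # modulo-mapped coordinates stay within one mitogenome length
  expect_lt(hits$mito_start, 6000L)
  expect_lte(hits$mito_end - hits$mito_start, 6000L)

  # the reverse strand is found too
  planted_rc <- paste0(substr(host, 1, 50000), revcomp(frag),
                       substring(host, 50001))
  hits_rc <- detect_numts(c(s = planted_rc), tmpl)
  expect_equal(nrow(hits_rc), 1L)
  expect_equal(hits_rc$strand, "-")
})

test_that("zygosity is fixed on cross-haplotype overlap, het otherwise", {
  h <- function(s, e) data.frame(scaffold = "s", start = s, end = e,
                                 mito_start = 0L, mito_end = e - s,
                                 strand = "+", identity = 0.9,
                                 length_bp = e - s,
                                 stringsAsFactors = FALSE)
  both <- numt_zygosity(h(100L, 400L), h(120L, 380L))
  expect_equal(both$zygosity, c("fixed", "fixed"))
  only1 <- numt_zygosity(h(100L, 400L), h(5000L, 5300L))
  expect_equal(only1$zygosity, c("het", "het"))
  partial <- numt_zygosity(h(100L, 400L), h(399L, 700L))  # 1 bp overlap
  expect_equal(partial$zygosity, c("fixed", "fixed"))
})

test_that("synteny groups are connected components under any overlap", {
  mk <- function(g, s, e) data.frame(genome_id = g, shared_chr = "r",
                                     shared_start = s, shared_end = e,
                                     stringsAsFactors = FALSE)
  hits <- rbind(mk("g1", 100L, 300L), mk("g2", 150L, 350L),
                mk("g3", 120L, 200L),           # one locus in 3 genomes
                mk("g1", 9000L, 9200L),         # singleton
                mk("g1", 500L, 600L), mk("g2", 590L, 700L),
                mk("g3", 690L, 800L))           # chain A-B, B-C
  out <- numt_synteny(hits)
  expect_equal(length(unique(out$synteny_group[1:3])), 1L)
  expect_false(out$syntenous[4])
  expect_equal(length(unique(out$synteny_group[5:7])), 1L)
  expect_true(all(out$syntenous[5:7]))
})

test_that("greedy clustering respects the identity threshold and ordering", {
  a <- rand_seq(400, 0.5, seed = 57)
  expect_equal(max(cluster_numts(c(x = a, y = a))$cluster), 1L)

  # ~75% identity pair: two clusters at the 0.80 threshold
  mutate <- function(s, k, seed) {
    set.seed(seed)
    v <- strsplit(s, "")[[1]]
    i <- sample(length(v), k)
    v[i] <- vapply(v[i], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "")
    paste(v, collapse = "")
  }
  b75 <- mutate(a, 100, 58)
  expect_equal(max(cluster_numts(c(x = a, y = b75))$cluster), 2L)
  b90 <- mutate(a, 40, 59)
  expect_equal(max(cluster_numts(c(x = a, y = b90))$cluster), 1L)

  # cluster count is monotone non-increasing in the threshold
  seqs <- c(a = a, b = b90, c = b75, d = mutate(a, 200, 60),
            e = rand_seq(300, 0.5, seed = 61))
  counts <- vapply(c(0.95, 0.85, 0.7, 0.5), function(th) {
    max(cluster_numts(seqs, threshold = th)$cluster)
  }, 0L)
  expect_true(all(diff(counts) <= 0))

  # permuting equal-length inputs cannot change the cluster count at 1.0
  s3 <- c(p = a, q = a, r = mutate(a, 1, 62))
  n1 <- max(cluster_numts(s3, 1.0)$cluster)
  n2 <- max(cluster_numts(s3[c(3, 1, 2)], 1.0)$cluster)
  expect_equal(n1, n2)
})

test_that("insertion-bias tests reproduce the exact binomial machinery", {
  r1 <- insertion_bias_test(0L, 158L, 0.02755)
  expect_equal(round(r1$ci[2], 4), 0.0231)
  r2 <- insertion_bias_test(0L, 413L, 0.1016)
  expect_equal(round(r2$ci[2], 4), 0.0089)
  r3 <- insertion_bias_test(79L, 158L, 0.5)
  expect_gt(r3$p, 0.93)
  expect_error(insertion_bias_test(0L, 0L, 0.5), "no NUMTs")
})

test_that("telomere scan reports tandem runs and the interstitial flag", {
  mid <- paste0(rand_seq(5000, 0.4, seed = 63), strrep("TTAGGG", 5),
                rand_seq(5000, 0.4, seed = 64))
  hits <- scan_interstitial_telomeres(c(s = mid))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$unit_count, 5L)
  expect_true(hits$interstitial)

  term <- paste0(strrep("TTAGGG", 5), rand_seq(5000, 0.4, seed = 65))
  h2 <- scan_interstitial_telomeres(c(s = term))
  expect_equal(nrow(h2), 1L)
  expect_false(h2$interstitial)

  short <- paste0(rand_seq(3000, 0.4, seed = 66), strrep("TTAGGG", 2),
                  rand_seq(3000, 0.4, seed = 67))
  expect_equal(nrow(scan_interstitial_telomeres(c(s = short))), 0L)

  rev <- paste0(rand_seq(3000, 0.4, seed = 68), strrep("CCCTAA", 4),
                rand_seq(3000, 0.4, seed = 69))
  h4 <- scan_interstitial_telomeres(c(s = rev))
  expect_equal(h4$motif, "CCCTAA")
})

test_that("junction telomere arrays are recovered as interstitial hits", {
  fx <- small_panel()
  panel <- fx$panel
  for (g in names(panel$genomes)) {
    hp <- panel$genomes[[g]]$hap1
    truth <- truth_junction_telomeres(panel, g, 1)
    hits <- scan_interstitial_telomeres(unlist(hp$seqs))
    inter <- hits[hits$interstitial, , drop = FALSE]
    for (i in seq_len(nrow(truth))) {
      ov <- inter$scaffold == truth$scaffold[i] &
        inter$start < truth$end[i] & inter$end > truth$start[i]
      expect_true(any(ov))
    }
    # no interstitial hit away from a planted junction region (the
    # junction array abuts the fused chromosomes' old terminal arrays,
    # so allow that flanking margin; terminal arrays at scaffold ends
    # are flagged non-interstitial)
    pad <- 100L
    away <- vapply(seq_len(nrow(inter)), function(j) {
      !any(truth$scaffold == inter$scaffold[j] &
             truth$start - pad < inter$end[j] &
             truth$end + pad > inter$start[j])
    }, TRUE)
    expect_equal(sum(away), 0L)
  }
})

test_that("repeat ORF activity respects the per-class length thresholds", {
  # bare ORFs (no flanking sequence, so no frame leaks past the ends)
  orf <- function(n_codons) {
    body <- paste(rep("GCT", n_codons), collapse = "")
    paste0("ATG", body, "TAA")
  }
  line_seq <- orf(700)      # 2106 nt ORF >= 2000
  dna_seq <- orf(400)       # 1206 nt >= 1200
  short_seq <- orf(300)     # 906 nt: inactive for LINE
  seqs <- c(s1 = line_seq, s2 = dna_seq, s3 = short_seq)
  reps <- data.frame(chrom = c("s1", "s2", "s3"),
                     start = 0L,
                     end = nchar(seqs),
                     class = c("LINE", "DNA", "LINE"),
                     stringsAsFactors = FALSE)
  out <- scan_repeat_orfs(seqs, reps)
  expect_equal(out$active, c(TRUE, TRUE, FALSE))

  # an internal stop truncates the ORF below threshold
  broken <- strsplit(line_seq, "")[[1]]
  stop_at <- 3 + 350 * 3   # in frame, mid-ORF
  broken[(stop_at + 1):(stop_at + 3)] <- c("T", "A", "A")
  out2 <- scan_repeat_orfs(c(s1 = paste(broken, collapse = "")),
                           reps[1, , drop = FALSE])
  expect_false(out2$active)

  expect_warning(
    scan_repeat_orfs(seqs, data.frame(chrom = "s1", start = 0L,
                                      end = 100L, class = "SINE")),
    "unknown class")
})
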