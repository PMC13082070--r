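# Charge metrics, hydropathy decoration, complexity, distribution distances,
# and motif scanning.

test_that("FCR counts exactly the four charged residue types", {
  expect_equal(fcr("EKEK"), 1)
  expect_equal(fcr("GGGG"), 0)
  expect_equal(fcr("EKGGG"), 0.4)
  expect_equal(fcr("HHHHCC"), 0)   # histidine/cysteine neutral at pH 7
  expect_error(fcr(""), "empty")
})

test_that("NCPR profiles are windowed charge means with truncated ends", {
  expect_equal(ncpr_profile("KKKKK", 5L), rep(1, 5))
  expect_equal(ncpr_profile("EEEEE", 5L), rep(-1, 5))
  ch <- c(-1, 1, -1, 1, -1, 1)   # EKEKEK
  w <- 2L
  oracle <- sapply(1:6, function(i) {
    lo <- max(1, i - 0L); hi <- min(6, i + 1L)   # window 2: self + next
    mean(ch[lo:hi])
  })
  expect_equal(ncpr_profile("EKEKEK", 2L), oracle)
  expect_true(all(abs(ncpr_profile(random_aa_seq(60, 2))) <= 1))
})

test_that("kappa separates blocky from alternating charge patterns", {
  blocky <- paste0(strrep("E", 25), strrep("K", 25))
  expect_equal(kappa(blocky), 1, tolerance = 1e-12)
  alternating <- strrep("EK", 25)
  expect_lt(kappa(alternating), 0.1)
  expect_true(is.na(kappa(strrep("G", 30))))
  expect_error(kappa("EK"), "shorter")
})

test_that("kappa is invariant to reversal and charge swap, and bounded", {
  set.seed(31)
  for (i in 1:25) {
    s <- synth_idr_corpus(corpus_spec(1, median_length = 60,
                                      charge_block = runif(1)), seed = i)[[1]]
    k <- kappa(s)
    if (is.na(k)) next
    expect_gte(k, 0); expect_lte(k, 1)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(kappa(rev_s), k, tolerance = 1e-9)
    swapped <- chartr("EKDR", "KERD", s)   # + <-> - everywhere
    expect_equal(kappa(swapped), k, tolerance = 1e-9)
  }
})

test_that("SHD equals its closed form for pairs and a brute-force pair sum", {
  scale <- idrlm:::KD_SCALED
  expect_equal(shd("AC"), (scale[["A"]] + scale[["C"]]) / 2, tolerance = 1e-12)
  zero <- stats::setNames(rep(0, 20), idrlm:::AA20)
  expect_equal(shd(random_aa_seq(30, 3), scale = zero), 0)
  set.seed(7)
  for (i in 1:10) {
    s <- random_aa_seq(30)
    h <- unname(scale[strsplit(s, "")[[1]]])
    oracle <- 0
    for (a in 1:29) for (b in (a + 1):30)
      oracle <- oracle + (h[a] + h[b]) / (b - a)
    expect_equal(shd(s), oracle / 30, tolerance = 1e-9)
  }
  expect_error(shd("A"), "at least 2")
})

test_that("SEG complexity matches windowed Shannon entropy", {
  expect_equal(seg_complexity(strrep("Q", 50)), 0)
  twelve <- paste(idrlm:::AA20[1:12], collapse = "")
  expect_equal(seg_complexity(twelve, 12L), log2(12), tolerance = 1e-12)
  expect_equal(seg_complexity("AAAAAAGGGGGG", 12L), 1)
  # short sequences fall back to a single whole-sequence window
  expect_equal(seg_complexity("AG", 12L), 1)
  set.seed(13)
  for (i in 1:10) {
    s <- random_aa_seq(40)
    chars <- strsplit(s, "")[[1]]
    w <- 12L
    oracle <- mean(sapply(1:(40 - w + 1), function(j) {
      p <- table(chars[j:(j + w - 1)]) / w
      -sum(p * log2(p))
    }))
    expect_equal(seg_complexity(s, w), oracle, tolerance = 1e-9)
  }
})

test_that("composition enrichment pools counts rather than averaging sequences", {
  seqs <- c(paste(idrlm:::AA20, collapse = ""), "GGPP")
  expect_equal(unname(composition_enrichment(seqs, seqs)), rep(1, 20))
  # residues absent from both sets are undefined, not 1
  expect_true(is.nan(composition_enrichment("PPPP", "PPPP")[["W"]]))
  uniform <- paste(idrlm:::AA20, collapse = "")
  enr <- composition_enrichment("PPPP", uniform)
  expect_equal(unname(enr[["P"]]), 20)
  expect_equal(unname(enr[["A"]]), 0)
  # pooled-count oracle: one long and one short sequence
  a <- c(strrep("A", 90), strrep("G", 10))
  ref <- strrep("AG", 50)
  enr2 <- composition_enrichment(a, ref)
  expect_equal(unname(enr2[["A"]]), (90 / 100) / (50 / 100), tolerance = 1e-12)
  expect_true(is.infinite(composition_enrichment("W", "A")[["W"]]))
})

test_that("Wasserstein-1 matches the sorted-coupling oracle and metric axioms", {
  x <- rnorm(100)
  expect_equal(wasserstein1(x, x, normalizer = 1), 0)
  expect_equal(wasserstein1(0, 3.5, normalizer = 1), 3.5)
  set.seed(17)
  a <- rnorm(100); b <- rnorm(100, 1, 2)
  expect_equal(wasserstein1(a, b, normalizer = 1), mean(abs(sort(a) - sort(b))),
               tolerance = 1e-9)
  # unequal sizes: compare with a dense-grid CDF integral
  a2 <- rnorm(80); b2 <- rnorm(50, 0.5)
  grid <- seq(min(c(a2, b2)) - 1, max(c(a2, b2)) + 1, length.out = 200001)
  oracle <- sum(abs(ecdf(a2)(grid) - ecdf(b2)(grid))) * diff(grid[1:2])
  expect_equal(wasserstein1(a2, b2, normalizer = 1), oracle, tolerance = 1e-3)
  # symmetry and triangle inequality (unnormalized)
  cc <- rnorm(100, -1)
  expect_equal(wasserstein1(a, b, 1), wasserstein1(b, a, 1), tolerance = 1e-12)
  expect_lte(wasserstein1(a, cc, 1),
             wasserstein1(a, b, 1) + wasserstein1(b, cc, 1) + 1e-12)
  # default normalizer is the reference sample's sd
  expect_equal(wasserstein1(a, b), wasserstein1(a, b, 1) / sd(b),
               tolerance = 1e-12)
  expect_error(wasserstein1(a, rep(1, 5)), "normalizer")
})

test_that("motif scanning reports overlapping matches with 1-based coordinates", {
  pats <- data.frame(name = "RGG", class = "RNA", regex = "RGG")
  hits <- motif_scan("RGGRGG", pats)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$start, c(1L, 4L))
  expect_equal(hits$end, c(3L, 6L))
  # overlapping occurrences are all reported
  hits2 <- motif_scan("GGGG", data.frame(name = "GG", regex = "GG"))
  expect_equal(hits2$start, 1:3)
  # a sequence without basic residues cannot match an NLS
  nls <- load_motif_patterns()
  nls <- nls[nls$class == "NLS", ]
  expect_equal(nrow(motif_scan(strrep("GSA", 30), nls)), 0L)
})

test_that("planted motifs are recovered exactly from the manifest", {
  pl <- plant_motifs(25, length = 60, motif = "RGG", sites_per_seq = 2,
                     seed = 5)
  pats <- data.frame(name = "RGG", regex = "RGG")
  for (id in names(pl$seqs)) {
    hits <- motif_scan(pl$seqs[[id]], pats)
    want <- pl$manifest[pl$manifest$seq == id, ]
    expect_equal(sort(hits$start), sort(want$start))
  }
})

test_that("PTM density counts unique planted sites", {
  pats <- data.frame(name = "MOD_TEST", class = "MOD", regex = "WHW")
  none <- plant_motifs(10, 60, motif = "WHW", sites_per_seq = 0, seed = 1)
  expect_equal(ptm_density(none$seqs, pats), 0)
  one <- plant_motifs(10, 60, motif = "WHW", sites_per_seq = 1, seed = 2)
  expect_equal(ptm_density(one$seqs, pats), 1)
  set.seed(3)
  counts <- rpois(400, 3)
  counts <- pmin(counts, 10)
  pois <- plant_motifs(400, 80, motif = "WHW", sites_per_seq = counts,
                       seed = 4)
  dens <- ptm_density(pois$seqs, pats)
  # the scanner recovers exactly what was planted ...
  expect_equal(dens, nrow(pois$manifest) / 400)
  # ... and the planted density is statistically consistent with lambda = 3
  se <- sqrt(3 / 400)
  expect_lt(abs(dens - 3), 3 * se + 1e-9)
})

test_that("motif co-occurrence uses start distance against the span", {
  pats <- data.frame(name = "RGG", regex = "RGG")
  one <- paste0(strrep("S", 20), "RGG", strrep("S", 40))
  expect_equal(unname(motif_cooccurrence(one, pats)), c(TRUE, FALSE))
  near <- paste0("RGG", strrep("S", 7), "RGG", strrep("S", 40))  # 10 apart
  expect_equal(unname(motif_cooccurrence(near, pats)), c(TRUE, TRUE))
  far <- paste0("RGG", strrep("S", 28), "RGG", strrep("S", 20))  # 31 apart
  expect_equal(unname(motif_cooccurrence(far, pats, span = 30L)),
               c(TRUE, FALSE))
  expect_equal(unname(motif_cooccurrence(strrep("S", 50), pats)),
               c(FALSE, FALSE))
})

test_that("metric tables carry normalized compositions and sane ranges", {
  seqs <- synth_idr_corpus(corpus_spec(20, median_length = 60), seed = 9)
  mt <- metric_table(seqs)
  expect_equal(nrow(mt), 20L)
  comp <- as.matrix(mt[, paste0("comp_", idrlm:::AA20)])
  expect_true(all(abs(rowSums(comp) - 1) < 1e-12))
  expect_true(all(mt$fcr >= 0 & mt$fcr <= 1))
  expect_true(all(is.na(mt$kappa) | (mt$kappa >= 0 & mt$kappa <= 1)))
  expect_true(all(mt$length == nchar(seqs)))
})
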