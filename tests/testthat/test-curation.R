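# pLDDT smoothing, three-state classification, region relabeling, and IDR
# record extraction.

test_that("smoothing is exact on constant traces and identity at window 1", {
  expect_equal(smooth_plddt(rep(90, 50), 15L), rep(90, 50))
  x <- runif(40, 0, 100)
  expect_equal(smooth_plddt(x, 1L), x)
  expect_error(smooth_plddt(numeric(0), 15L), "empty")
  expect_error(smooth_plddt(rep(50, 10), 4L), "odd")
})

test_that("smoothing matches a brute-force windowed mean on a step trace", {
  x <- c(rep(100, 20), rep(40, 20))
  w <- 15L
  h <- (w - 1L) %/% 2L
  oracle <- sapply(seq_along(x), function(i)
    mean(x[max(1, i - h):min(length(x), i + h)]))
  expect_equal(smooth_plddt(x, w), oracle, tolerance = 1e-12)
  # random trace, random odd windows
  set.seed(7)
  for (w in c(3L, 7L, 15L)) {
    y <- runif(60, 0, 100)
    h <- (w - 1L) %/% 2L
    oracle <- sapply(seq_along(y), function(i)
      mean(y[max(1, i - h):min(length(y), i + h)]))
    expect_equal(smooth_plddt(y, w), oracle, tolerance = 1e-12)
  }
})

test_that("residue classification applies strict thresholds with gaps between", {
  p <- segmentation_params()
  expect_equal(classify_residues(c(90, 60, 75), p),
               c("FOLDED", "DISORDERED", "GAP"))
  # exact threshold values are gaps on both sides
  expect_equal(classify_residues(c(80, 70), p), c("GAP", "GAP"))
  set.seed(1)
  x <- runif(200, 0, 100)
  oracle <- ifelse(x > 80, "FOLDED", ifelse(x < 70, "DISORDERED", "GAP"))
  expect_equal(classify_residues(x, p), oracle)
})

test_that("region relabeling follows the gap rules", {
  p <- segmentation_params()
  run <- function(labels) refine_segments(labels, p)
  # single disordered run is untouched
  s <- run(rep("DISORDERED", 40))
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 0L)
  expect_equal(s$end, 40L)
  expect_equal(s$label, "DISORDERED")
  # gap flanked by two disordered runs becomes disordered
  s <- run(c(rep("DISORDERED", 20), rep("GAP", 5), rep("DISORDERED", 20)))
  expect_equal(s$label, "DISORDERED")
  expect_equal(c(s$start, s$end), c(0L, 45L))
  # gap flanked by folded runs becomes folded
  s <- run(c(rep("FOLDED", 20), rep("GAP", 5), rep("FOLDED", 20)))
  expect_equal(s$label, "FOLDED")
  expect_equal(c(s$start, s$end), c(0L, 45L))
  # short disordered run -> gap -> terminal, not next to disordered -> folded
  s <- run(c(rep("DISORDERED", 5), rep("FOLDED", 50)))
  expect_equal(s$label, "FOLDED")
  expect_equal(c(s$start, s$end), c(0L, 55L))
  # terminal gap next to a disordered run extends the IDR
  s <- run(c(rep("GAP", 8), rep("DISORDERED", 30)))
  expect_equal(s$label, "DISORDERED")
  # internal gap between disordered and folded goes to folded
  s <- run(c(rep("DISORDERED", 20), rep("GAP", 5), rep("FOLDED", 20)))
  expect_equal(s$label, c("DISORDERED", "FOLDED"))
  expect_equal(s$end[1], 20L)
})

test_that("refinement has no gaps, tiles the protein, and is idempotent", {
  p <- segmentation_params()
  set.seed(42)
  for (i in 1:30) {
    labels <- sample(c("FOLDED", "DISORDERED", "GAP"), 120, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
    # make runs plausible by repeating each label a random number of times
    labels <- rep(labels, times = sample(1:12, 120, replace = TRUE))[1:150]
    s <- refine_segments(labels, p)
    expect_false(any(s$label == "GAP"))
    expect_equal(s$start[1], 0L)
    expect_equal(s$end[nrow(s)], length(labels))
    if (nrow(s) > 1L) {
      expect_equal(s$start[-1], s$end[-nrow(s)])
      expect_true(all(s$label[-1] != s$label[-nrow(s)]))
    }
    relabeled <- rep(s$label, times = s$end - s$start)
    expect_equal(refine_segments(relabeled, p), s)
  }
})

test_that("record extraction enforces the filtering rules and coordinates", {
  p <- segmentation_params()
  mkseq <- function(n) random_aa_seq(n, seed = n)
  # protein longer than 512 residues yields nothing
  long <- plddt_trace("long", mkseq(600), rep(50, 600))
  segs <- data.frame(start = 0L, end = 600L, label = "DISORDERED")
  expect_length(extract_idr_records(long, segs, p), 0L)
  # entirely disordered protein yields nothing
  idp <- plddt_trace("idp", mkseq(100), rep(50, 100))
  segs <- data.frame(start = 0L, end = 100L, label = "DISORDERED")
  expect_length(extract_idr_records(idp, segs, p), 0L)
  # F x 100 | D x 40 | F x 60 -> one record with 1-based coordinates
  tr <- plddt_trace("p1", mkseq(200), c(rep(90, 100), rep(50, 40), rep(90, 60)))
  segs <- data.frame(start = c(0L, 100L, 140L), end = c(100L, 140L, 200L),
                     label = c("FOLDED", "DISORDERED", "FOLDED"))
  recs <- extract_idr_records(tr, segs, p)
  expect_length(recs, 1L)
  r <- recs[[1]]
  expect_equal(r$idr_start, 101L)
  expect_equal(r$idr_end, 140L)
  expect_equal(nchar(r$n_context), 100L)
  expect_equal(nchar(r$c_context), 60L)
  expect_equal(paste0(r$n_context, r$idr, r$c_context), tr$sequence)
  # short IDRs are dropped
  segs2 <- data.frame(start = c(0L, 100L, 120L), end = c(100L, 120L, 200L),
                      label = c("FOLDED", "DISORDERED", "FOLDED"))
  expect_length(extract_idr_records(tr, segs2, p), 0L)
  # non-canonical residues skip the protein
  seqx <- paste0(substr(tr$sequence, 1, 199), "X")
  trx <- plddt_trace("px", seqx, tr$plddt)
  expect_length(extract_idr_records(trx, segs, p), 0L)
})

test_that("curation reconstructs sequences exactly (concatenation invariant)", {
  set.seed(11)
  for (i in 1:20) {
    lay <- segment_layout(c("FOLDED", "DISORDERED", "FOLDED"),
                          c(60, sample(30:80, 1), 60))
    sp <- synth_protein_with_plddt(lay, protein_id = paste0("p", i), seed = i)
    recs <- curate_trace(sp$trace)
    for (r in recs)
      expect_equal(paste0(r$n_context, r$idr, r$c_context), sp$trace$sequence)
  }
})

test_that("segmentation recovers planted low-pLDDT segments within the smoothing half-window", {
  params <- segmentation_params()
  half <- (params$window - 1L) %/% 2L
  set.seed(99)
  n_checked <- 0L
  for (i in 1:200) {
    n_seg <- sample(2:4, 1)
    labels <- rep(c("FOLDED", "DISORDERED"), length.out = n_seg)
    if (runif(1) < 0.5) labels <- rev(labels)
    lens <- sample(40:90, n_seg, replace = TRUE)
    lay <- segment_layout(labels, lens, folded_mean = 92, folded_sd = 2,
                          disordered_mean = 55, disordered_sd = 2, ramp = 0L)
    sp <- synth_protein_with_plddt(lay, seed = 1000L + i)
    sm <- smooth_plddt(sp$trace, params$window)
    segs <- refine_segments(classify_residues(sm, params), params)
    truth <- sp$truth[sp$truth$label == "DISORDERED", ]
    found <- segs[segs$label == "DISORDERED", ]
    expect_equal(nrow(found), nrow(truth))
    if (nrow(found) == nrow(truth) && nrow(truth) > 0) {
      expect_true(all(abs(found$start - truth$start) <= half))
      expect_true(all(abs(found$end - truth$end) <= half))
      n_checked <- n_checked + nrow(truth)
    }
  }
  expect_gt(n_checked, 100L)
})

test_that("file-level curation reads FASTA plus JSON/CSV traces", {
  dir <- withr::local_tempdir()
  lay <- segment_layout(c("FOLDED", "DISORDERED"), c(60, 50))
  sp1 <- synth_protein_with_plddt(lay, protein_id = "protA", seed = 1)
  sp2 <- synth_protein_with_plddt(lay, protein_id = "protB", seed = 2)
  write_fasta(c(protA = sp1$trace$sequence, protB = sp2$trace$sequence),
              file.path(dir, "prot.fasta"))
  jsonlite::write_json(list(plddt = sp1$trace$plddt),
                       file.path(dir, "protA.json"))
  utils::write.csv(data.frame(index = seq_along(sp2$trace$plddt),
                              plddt = sp2$trace$plddt),
                   file.path(dir, "protB.csv"), row.names = FALSE)
  recs <- curate_fasta(file.path(dir, "prot.fasta"), dir)
  expect_equal(sort(unique(vapply(recs, `[[`, "", "protein_id"))),
               c("protA", "protB"))
  out <- file.path(dir, "records.jsonl")
  write_idr_records(recs, out)
  back <- read_idr_records(out)
  expect_equal(length(back), length(recs))
  expect_equal(back[[1]]$idr, recs[[1]]$idr)
})
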