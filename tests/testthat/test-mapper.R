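# Perfect-match mapper: exactness, strand handling, quality masking, read
# classification, and SAM interchange.

test_that("full-length and reverse-complement queries hit where expected", {
  atlas <- toy_atlas()
  idx <- build_read_index(atlas)
  full <- atlas$alleles$extended_sequence[1L]
  reads <- reads_df(c(full, revcomp_chr(substr(full, 1, 150))))
  hits <- map_reads_perfect(idx, reads, mode = "full")
  h1 <- hits[hits$read_id == "rd001", ]
  expect_equal(h1$offset, 0L)
  expect_equal(h1$strand, "+")
  expect_equal(h1$allele_id, "a1")
  h2 <- hits[hits$read_id == "rd002", ]
  expect_true(all(h2$strand == "-"))
  expect_true(any(h2$offset == 0L & h2$region_id == "r1"))
})

test_that("flank-only reads hit every allele of the region", {
  atlas <- toy_atlas()
  idx <- build_read_index(atlas)
  # r2's 5' flank is shared verbatim by its three alleles
  flank_read <- substr(atlas$alleles$extended_sequence[2L], 1L, 150L)
  hits <- map_reads_perfect(idx, reads_df(flank_read), mode = "full")
  r2 <- hits[hits$region_id == "r2", ]
  expect_setequal(r2$allele_id, c("a1", "a2", "a3"))
  cls <- classify_reads(hits)
  expect_equal(cls$class, "multimapper")
})

test_that("quality masking turns low-quality mismatches into wildcards", {
  atlas <- toy_atlas()
  idx <- build_read_index(atlas)
  src <- substr(atlas$alleles$extended_sequence[1L], 11L, 160L)
  ch <- strsplit(src, "")[[1L]]
  ch[40L] <- setdiff(c("A", "C", "G", "T"), ch[40L])[1L]
  q <- rep(37L, 150L); q[40L] <- 10L
  read <- data.frame(read_id = "m1", sequence = paste(ch, collapse = ""),
                     quality = int_to_phred(q), stringsAsFactors = FALSE)
  expect_equal(nrow(map_reads_perfect(idx, read, mode = "full")), 0L)
  masked <- map_reads_perfect(idx, read, mode = "quality_masked",
                              min_base_quality = 20L)
  expect_true(nrow(masked) >= 1L)
  expect_true(any(masked$region_id == "r1" & masked$offset == 10L))
  # quality above the mask threshold: the mismatch counts again
  read$quality <- int_to_phred(rep(37L, 150L))
  expect_equal(nrow(map_reads_perfect(idx, read, mode = "quality_masked")),
               0L)
})

test_that("indexed mapper agrees with the brute-force scan on random reads", {
  cfg <- tiled_config(seed = 31)
  atlas <- simulate_atlas(cfg)
  idx <- build_read_index(atlas)
  withr::local_seed(99)
  mk_read <- function(i) {
    a <- sample(nrow(atlas$alleles), 1L)
    ext <- atlas$alleles$extended_sequence[a]
    o <- sample(nchar(ext) - 150L + 1L, 1L)
    s <- substr(ext, o, o + 149L)
    ch <- strsplit(s, "")[[1L]]
    q <- rep(37L, 150L)
    nmut <- sample(0:2, 1L)
    if (nmut > 0L) {
      at <- sample(150L, nmut)
      ch[at] <- vapply(ch[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      q[at] <- sample(c(10L, 37L), nmut, replace = TRUE)
    }
    s <- paste(ch, collapse = "")
    if (runif(1) < 0.5) {
      s <- revcomp_chr(s); q <- rev(q)
    }
    data.frame(read_id = sprintf("rr%03d", i), sequence = s,
               quality = int_to_phred(q), stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, lapply(1:150, mk_read))
  for (mode in c("full", "quality_masked")) {
    fast <- map_reads_perfect(idx, reads, mode = mode)
    slow <- scan_reads_naive(atlas, reads, mode = mode)
    attr(fast, "qc_log") <- NULL
    expect_equal(fast, slow, info = mode)
  }
})

test_that("mapping reverse-complemented reads flips strands only", {
  atlas <- toy_atlas()
  idx <- build_read_index(atlas)
  withr::local_seed(5)
  ext <- atlas$alleles$extended_sequence[2L]
  offs <- sample(nchar(ext) - 149L, 10L)
  reads <- reads_df(substring(ext, offs, offs + 149L))
  fwd <- map_reads_perfect(idx, reads, mode = "full")
  rev_reads <- reads
  rev_reads$sequence <- vapply(reads$sequence, revcomp_chr, "")
  rev <- map_reads_perfect(idx, rev_reads, mode = "full")
  key <- function(h) paste(h$read_id, h$region_id, h$allele_id, h$offset)
  expect_setequal(paste(key(fwd), h = fwd$strand),
                  paste(key(rev), h = chartr("+-", "-+", rev$strand)))
})

test_that("masking more positions never removes a hit", {
  cfg <- tiled_config(seed = 41)
  atlas <- simulate_atlas(cfg)
  idx <- build_read_index(atlas)
  withr::local_seed(7)
  ext <- atlas$alleles$extended_sequence
  reads <- do.call(rbind, lapply(1:40, function(i) {
    a <- sample(length(ext), 1L)
    o <- sample(nchar(ext[a]) - 149L, 1L)
    s <- substr(ext[a], o, o + 149L)
    q <- sample(c(10L, 25L, 37L), 150L, replace = TRUE,
                prob = c(0.1, 0.2, 0.7))
    data.frame(read_id = sprintf("q%03d", i), sequence = s,
               quality = int_to_phred(q), stringsAsFactors = FALSE)
  }))
  key <- function(h) paste(h$read_id, h$region_id, h$allele_id, h$offset,
                           h$strand)
  h_strict <- map_reads_perfect(idx, reads, "quality_masked",
                                min_base_quality = 9L)
  for (mq in c(20L, 30L)) {
    h_loose <- map_reads_perfect(idx, reads, "quality_masked",
                                 min_base_quality = mq)
    expect_true(all(key(h_strict) %in% key(h_loose)), info = mq)
    h_strict <- h_loose
  }
})

test_that("classification partitions reads by distinct allele count", {
  hits <- data.frame(
    read_id = c("r2", "r3", rep("r4", 3L)),
    region_id = c("ra", "ra", "ra", "ra", "rb"),
    allele_id = c("a1", "a2", "a1", "a2", "a1"),
    offset = 0L, strand = "+", stringsAsFactors = FALSE)
  cls <- classify_reads(hits, read_ids = c("r1", "r2", "r3", "r4"))
  expect_equal(cls$class, c("unmapped", "unique", "unique", "multimapper"))
  expect_equal(sum(cls$class == "unique") + sum(cls$class == "multimapper") +
                 sum(cls$class == "unmapped"), 4L)
  expect_equal(cls$allele_id[cls$read_id == "r2"], "a1")
  # a read hitting one allele at two offsets is still unique
  dup <- data.frame(read_id = "rx", region_id = "ra", allele_id = "a1",
                    offset = c(0L, 7L), strand = "+",
                    stringsAsFactors = FALSE)
  expect_equal(classify_reads(dup)$class, "unique")
})

test_that("unique counts match simulator provenance truth", {
  cfg <- iso_config(seed = 61, n_participants = 1L, n_twin_pairs = 0L,
                    depth = 400L)
  atlas <- simulate_atlas(cfg)
  truth <- simulate_cohort(atlas, cfg)
  reads <- simulate_reads(truth, atlas, cfg)[["P001"]]
  prov <- attr(reads, "provenance")
  idx <- build_read_index(atlas)
  hits <- map_reads_perfect(idx, reads, mode = "full")
  cls <- classify_reads(hits, read_ids = reads$read_id)
  uniq <- cls[cls$class == "unique", ]
  m <- match(uniq$read_id, prov$read_id)
  expect_equal(uniq$region_id, prov$region_id[m])
  expect_equal(uniq$allele_id, prov$allele_id[m])
})

test_that("empty reads are logged, not fatal", {
  atlas <- toy_atlas()
  idx <- build_read_index(atlas)
  reads <- reads_df(c(substr(atlas$alleles$extended_sequence[1L], 1, 150),
                      ""))
  hits <- map_reads_perfect(idx, reads, mode = "full")
  expect_match(attr(hits, "qc_log"), "rd002")
  expect_true(all(hits$read_id == "rd001"))
})

test_that("SAM round-trips internal hits and rejects gapped CIGARs", {
  atlas <- toy_atlas()
  idx <- build_read_index(atlas)
  withr::local_seed(13)
  ext <- atlas$alleles$extended_sequence[2L]
  offs <- sample(nchar(ext) - 149L, 20L)
  seqs <- substring(ext, offs, offs + 149L)
  flip <- runif(20) < 0.5
  seqs[flip] <- vapply(seqs[flip], revcomp_chr, "")
  reads <- reads_df(seqs)
  hits <- map_reads_perfect(idx, reads, mode = "full")
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(hits, reads, atlas, sam)
  back <- ingest_sam(sam, atlas, mode = "full")
  attr(hits, "qc_log") <- NULL
  attr(back, "read_ids") <- NULL
  expect_equal(back, hits)
  # a gapped alignment is excluded even if the record is otherwise valid
  lines <- readLines(sam)
  rec <- strsplit(lines[length(lines)], "\t")[[1L]]
  rec[6L] <- "75M1I74M"
  writeLines(c(lines, paste(rec, collapse = "\t")), sam)
  again <- ingest_sam(sam, atlas, mode = "full")
  attr(again, "read_ids") <- NULL
  expect_equal(again, hits)
  # unknown reference names are an error
  rec[3L] <- "nosuch|a9"
  writeLines(c(lines, paste(rec, collapse = "\t")), sam)
  expect_error(ingest_sam(sam, atlas, mode = "full"), "nosuch")
})

test_that("secondary alignments are retained on ingestion", {
  atlas <- toy_atlas()
  idx <- build_read_index(atlas)
  flank_read <- substr(atlas$alleles$extended_sequence[2L], 1L, 150L)
  reads <- reads_df(flank_read)
  hits <- map_reads_perfect(idx, reads, mode = "full")
  expect_true(nrow(hits) >= 3L)    # one primary + secondaries
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(hits, reads, atlas, sam)
  flags <- vapply(strsplit(grep("^@", readLines(sam), value = TRUE,
                                invert = TRUE), "\t"), `[[`, "", 2L)
  expect_true(sum(as.integer(flags) >= 256L) >= 2L)
  back <- ingest_sam(sam, atlas, mode = "full")
  expect_equal(nrow(back), nrow(hits))
})
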