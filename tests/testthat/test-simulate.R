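# Synthetic cohorts: determinism, twin sharing, sampling calibration, GC
# bias, phenotype generation, config validation.

test_that("config validates rates, twin counts and allele splits", {
  expect_error(sim_config(1, alleles_per_region = 0L), "alleles_per_region")
  expect_error(sim_config(1, n_participants = 4L, n_twin_pairs = 3L),
               "n_twin_pairs")
  expect_error(sim_config(1, somatic_rate = 1.5), "rates")
  expect_error(sim_config(1, germline_alleles_per_region = 9L),
               "germline_alleles_per_region")
  expect_error(sim_config(1, nonsense = 2), "unknown config field")
  cfg <- sim_config(1)
  expect_equal(cfg$germline_alleles_per_region, cfg$alleles_per_region)
})

test_that("a fixed seed gives byte-identical artifacts", {
  cfg <- tiled_config(seed = 201)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    atlas <- simulate_atlas(cfg)
    write_atlas_fasta(atlas, file.path(d, "atlas.fasta"))
    truth <- simulate_cohort(atlas, cfg)
    reads <- simulate_reads(truth, atlas, cfg, participants = "P001")
    write_fastq(reads$P001, file.path(d, "P001.fastq"))
  }
  expect_identical(readLines(file.path(d1, "atlas.fasta")),
                   readLines(file.path(d2, "atlas.fasta")))
  expect_identical(readLines(file.path(d1, "P001.fastq")),
                   readLines(file.path(d2, "P001.fastq")))
})

test_that("generated alleles re-diff to their declared variant sets", {
  cfg <- tiled_config(seed = 211)
  atlas <- simulate_atlas(cfg)
  for (i in seq_len(nrow(atlas$alleles))) {
    rid <- atlas$alleles$region_id[i]
    reg <- atlas$regions[atlas$regions$region_id == rid, ]
    refseq <- substr(atlas$reference[[reg$subunit_id]], reg$start, reg$end)
    rediff <- derive_variant_keys(atlas$alleles$core_sequence[i], refseq,
                                  reg$start)
    expect_equal(rediff, sort(atlas$alleles$variants[[i]],
                              method = "radix")[
      order(parse_variant_key(sort(atlas$alleles$variants[[i]],
                                   method = "radix"))$position)] |>
        as.character(), info = paste(rid, atlas$alleles$allele_id[i]))
  }
})

test_that("reference-only atlases yield all-zero variant frequencies", {
  cfg <- iso_config(seed = 221, alleles_per_region = 1L,
                    n_participants = 2L, n_twin_pairs = 0L)
  atlas <- simulate_atlas(cfg)
  truth <- simulate_cohort(atlas, cfg)
  expect_equal(ncol(truth$true_freq), 0L)
})

test_that("twins share true frequencies exactly when somatic rate is zero", {
  cfg <- iso_config(seed = 231, n_participants = 10L, n_twin_pairs = 5L,
                    somatic_rate = 0)
  atlas <- simulate_atlas(cfg)
  truth <- simulate_cohort(atlas, cfg)
  for (i in seq_len(nrow(truth$twin_pairs)))
    expect_equal(truth$true_freq[truth$twin_pairs$id_a[i], ],
                 truth$true_freq[truth$twin_pairs$id_b[i], ])
  # with heavy somatic injection and no germline variation they differ
  cfg2 <- iso_config(seed = 231, n_participants = 10L, n_twin_pairs = 5L,
                     germline_alleles_per_region = 1L, somatic_rate = 0.05)
  truth2 <- simulate_cohort(atlas, cfg2)
  expect_false(isTRUE(all.equal(truth2$true_freq[truth2$twin_pairs$id_a[1L], ],
                                truth2$true_freq[truth2$twin_pairs$id_b[1L], ])))
})

test_that("read draws follow the copy composition binomially", {
  cfg <- iso_config(seed = 241, n_participants = 1L, n_twin_pairs = 0L,
                    depth = 10000L, alleles_per_region = 3L)
  atlas <- simulate_atlas(cfg)
  truth <- simulate_cohort(atlas, cfg)
  reads <- simulate_reads(truth, atlas, cfg)
  prov <- attr(reads$P001, "provenance")
  cp <- truth$copies[truth$copies$participant_id == "P001", ]
  for (rid in unique(cp$region_id)) {
    sub <- cp[cp$region_id == rid, ]
    for (k in seq_len(nrow(sub))) {
      p_true <- sub$copies[k] / sum(sub$copies)
      got <- mean(prov$allele_id[prov$region_id == rid] == sub$allele_id[k])
      tol <- 3 * sqrt(p_true * (1 - p_true) / cfg$depth) + 1e-9
      expect_lt(abs(got - p_true), tol + 1e-6)
    }
  }
})

test_that("error-free reads all map perfectly; errors go low-quality", {
  cfg <- iso_config(seed = 251, n_participants = 1L, n_twin_pairs = 0L,
                    depth = 300L, error_rate = 0, low_quality_rate = 0,
                    gc_bias_strength = 0)
  atlas <- simulate_atlas(cfg)
  truth <- simulate_cohort(atlas, cfg)
  reads <- simulate_reads(truth, atlas, cfg)$P001
  idx <- build_read_index(atlas)
  cls <- classify_reads(map_reads_perfect(idx, reads, "full"),
                        read_ids = reads$read_id)
  expect_equal(sum(cls$class == "unmapped"), 0L)
  # with errors, full-mode mapping loses reads but masked mode keeps them
  cfg2 <- iso_config(seed = 251, n_participants = 1L, n_twin_pairs = 0L,
                     depth = 300L, error_rate = 0.02, low_quality_rate = 0)
  truth2 <- simulate_cohort(atlas, cfg2)
  reads2 <- simulate_reads(truth2, atlas, cfg2)$P001
  full2 <- classify_reads(map_reads_perfect(idx, reads2, "full"),
                          read_ids = reads2$read_id)
  masked2 <- classify_reads(
    map_reads_perfect(idx, reads2, "quality_masked"),
    read_ids = reads2$read_id)
  expect_gt(sum(full2$class == "unmapped"), 0L)
  expect_equal(sum(masked2$class == "unmapped"), 0L)
})

test_that("GC bias depresses coverage of high-GC windows", {
  # one GC-rich tract region; compare observed start-position coverage of
  # the tract under bias vs no bias, over replicates
  cfg0 <- sim_config(seed = 261, subunit_lengths = c("X" = 600L),
                     regions_per_subunit = c("X" = 1L),
                     n_participants = 1L, n_twin_pairs = 0L,
                     depth = 4000L, gc_rich_tracts = TRUE,
                     gc_bias_strength = 0)
  atlas <- simulate_atlas(cfg0)
  gc_frac <- function(s) mean(strsplit(s, "")[[1L]] %in% c("G", "C"))
  # per-window GC of the first allele
  ext <- atlas$alleles$extended_sequence[1L]
  wins <- substring(ext, 1:(nchar(ext) - 149L), 150:(nchar(ext)))
  hi <- which(rank(-vapply(wins, gc_frac, 1)) <= 50L)  # top-GC windows
  cover_hi <- function(strength, seed) {
    cfg <- sim_config(seed = seed, subunit_lengths = c("X" = 600L),
                      regions_per_subunit = c("X" = 1L),
                      n_participants = 1L, n_twin_pairs = 0L,
                      depth = 4000L, gc_rich_tracts = TRUE,
                      gc_bias_strength = strength)
    truth <- simulate_cohort(atlas, cfg)
    prov <- attr(simulate_reads(truth, atlas, cfg)$P001, "provenance")
    mean((prov$offset + 1L) %in% hi)
  }
  unbiased <- mean(vapply(1:5, function(s) cover_hi(0, 300 + s), 1))
  biased <- mean(vapply(1:5, function(s) cover_hi(1, 300 + s), 1))
  expect_lt(biased, unbiased)
})

test_that("null phenotypes give uniform p-values and planted effects rank first", {
  cfg <- iso_config(seed = 271, n_participants = 300L, n_twin_pairs = 0L,
                    alleles_per_region = 3L)
  atlas <- simulate_atlas(cfg)
  truth <- simulate_cohort(atlas, cfg)
  vft <- simulate_frequency_table(truth, depth = 5000L, seed = 3)
  cov <- truth$participants
  # null: no effect anywhere
  ph0 <- simulate_phenotypes(truth, effects = numeric(), noise_sd = 1,
                             seed = 5)
  res0 <- associate(vft$freq, ph0$traits["trait1"], cov, model = "linear")
  expect_gt(min(res0$p_value), 1e-4)   # no extreme hit among ~9 variants
  # planted effect on the most variable germline variant
  key <- names(sort(apply(truth$true_freq, 2, var), decreasing = TRUE))[1L]
  eff <- stats::setNames(8, key)
  ph1 <- simulate_phenotypes(truth, effects = eff, noise_sd = 0.5, seed = 6)
  res1 <- associate(vft$freq, ph1$traits["trait1"], cov, model = "linear")
  expect_equal(res1$predictor[which.min(res1$p_value)], key)
  expect_error(simulate_phenotypes(truth, effects = c(`9:A:T` = 1)),
               "unknown variant key")
})

test_that("disease simulation respects the burden logistic link", {
  cfg <- iso_config(seed = 281, n_participants = 400L, n_twin_pairs = 0L,
                    germline_alleles_per_region = 1L, somatic_rate = 0.02)
  atlas <- simulate_atlas(cfg)
  truth <- simulate_cohort(atlas, cfg)
  burden <- matrix(withr::with_seed(3, runif(400, 0, 0.2)), ncol = 1,
                   dimnames = list(truth$participants$participant_id,
                                   "su01_r01"))
  ph <- simulate_phenotypes(truth, disease_spec = c(su01_r01 = 0),
                            burden = burden, prevalence = 0.1, seed = 7)
  expect_lt(abs(mean(ph$cases$D1) - 0.1), 0.05)
  ph2 <- simulate_phenotypes(truth, disease_spec = c(su01_r01 = 15),
                             burden = burden, prevalence = 0.1, seed = 8)
  hi <- burden[, 1] > stats::median(burden[, 1])
  expect_gt(mean(ph2$cases$D1[hi]), mean(ph2$cases$D1[!hi]))
})
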