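# Fixtures built in code: a tiny hand-made atlas plus config shortcuts for
# the two simulator study designs (tiled subunits with shared flanks;
# isolated short regions where every read spans its whole region).

rand_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

# 600 bp subunit tiled into three 200 bp regions; the middle region carries
# three alleles (reference, one SNV, SNV+insertion), the outer two are
# reference-only.
toy_atlas <- function(seed = 11, flank_len = 150L) {
  ref <- c("18S" = rand_dna(600L, seed))
  regions <- data.frame(
    region_id = c("r1", "r2", "r3"), subunit_id = "18S",
    region_class = c("ES", "non-ES", "ES"),
    start = c(1L, 201L, 401L), end = c(200L, 400L, 600L),
    stringsAsFactors = FALSE)
  r2ref <- substr(ref[["18S"]], 201L, 400L)
  b250 <- substr(ref[["18S"]], 250L, 250L)
  b320 <- substr(ref[["18S"]], 320L, 320L)
  snv <- sprintf("250:%s:%s", b250, setdiff(c("A", "C", "G", "T"), b250)[1L])
  ins <- sprintf("320:%s:%sTG", b320, b320)
  alleles <- data.frame(
    region_id = c("r1", "r2", "r2", "r2", "r3"),
    allele_id = c("a1", "a1", "a2", "a3", "a1"),
    core_sequence = c(
      substr(ref[["18S"]], 1L, 200L),
      r2ref,
      apply_variant_keys(r2ref, 201L, snv),
      apply_variant_keys(r2ref, 201L, c(snv, ins)),
      substr(ref[["18S"]], 401L, 600L)),
    atlas_abundance = c(1, 0.7, 0.2, 0.1, 1),
    stringsAsFactors = FALSE)
  alleles$variants <- list(character(), character(), snv, c(snv, ins),
                           character())
  at <- rdna_atlas(ref, regions, alleles, flank_len = flank_len)
  attr(at, "toy_keys") <- c(snv = snv, ins = ins)
  at
}

# reads data frame from raw sequences with uniform quality
reads_df <- function(sequences, q = 37L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("rd%03d", seq_along(sequences))
  data.frame(read_id = ids, sequence = sequences,
             quality = vapply(nchar(sequences), function(n)
               int_to_phred(rep(q, n)), ""),
             stringsAsFactors = FALSE)
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# isolated-region design: each subunit is a single 150 bp region, so every
# simulated read spans its whole region and maps uniquely
iso_config <- function(seed, n_regions = 3L, ...) {
  nm <- sprintf("su%02d", seq_len(n_regions))
  sim_config(seed = seed,
             subunit_lengths = stats::setNames(rep(150L, n_regions), nm),
             regions_per_subunit = stats::setNames(rep(1L, n_regions), nm),
             ...)
}

# small tiled design for mapper-level tests
tiled_config <- function(seed, ...) {
  sim_config(seed = seed,
             subunit_lengths = c("18S" = 600L, "28S" = 900L),
             regions_per_subunit = c("18S" = 1L, "28S" = 2L),
             n_participants = 4L, n_twin_pairs = 1L, depth = 300L, ...)
}

# full covariate table in the association design layout
make_covariates <- function(n, n_batches = 3L, seed = 1L) {
  withr::with_seed(seed, {
    cov <- data.frame(
      age = round(runif(n, 40, 70)), sex = rbinom(n, 1L, 0.5),
      rdna_cn = rnorm(n, 400, 60),
      batch = sample(sprintf("B%d", seq_len(n_batches)), n, replace = TRUE),
      stringsAsFactors = FALSE)
    for (i in 1:20) cov[[paste0("PC", i)]] <- rnorm(n)
    cov
  })
}

# cohort hits for all participants at a given policy/mode
cohort_counts <- function(atlas, reads_list, mode = "full",
                          policy = "fractional", min_q = 20L) {
  idx <- build_read_index(atlas)
  lapply(reads_list, function(r)
    count_alleles(map_reads_perfect(idx, r, mode = mode,
                                    min_base_quality = min_q),
                  policy = policy))
}
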