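# Rare-variant burden: cohort support filtering, allele collapsing, depth
# QC, copy-scaled zeroing, renormalization and the MAF/burden statistic.

support_fixture <- function() {
  atlas <- toy_atlas()
  # cohort unique counts: a1 well supported, a2 at the boundary, a3 below
  u <- data.frame(
    participant_id = c("P1", "P2", "P1", "P2", "P1"),
    region_id = "r2",
    allele_id = c("a1", "a1", "a2", "a2", "a3"),
    count = c(50L, 60L, 1L, 1L, 1L), stringsAsFactors = FALSE)
  list(atlas = atlas, u = u)
}

test_that("cohort support uses at-least semantics with a strict option", {
  fx <- support_fixture()
  s <- cohort_allele_support(fx$u, fx$atlas, min_support = 2L)
  expect_setequal(s$r2$resolved, c("a1", "a2"))     # sum 2 passes ">= 2"
  expect_equal(s$r2$retained, "a3")
  expect_setequal(s$r2$resolvable, c("a1", "a2", "a3"))
  strict <- cohort_allele_support(fx$u, fx$atlas, min_support = 2L,
                                  strict = TRUE)
  expect_equal(strict$r2$resolved, "a1")            # sum 2 fails "> 2"
  # the retained representative is the most atlas-abundant excluded allele
  expect_equal(strict$r2$retained, "a2")            # abundance 0.2 > 0.1
  # all alleles supported: resolvable set is the full set, nothing retained
  big <- fx$u; big$count <- big$count + 10L
  s2 <- cohort_allele_support(big, fx$atlas, min_support = 2L)
  expect_null(s2$r2$retained)
  expect_setequal(s2$r2$resolvable, c("a1", "a2", "a3"))
  # zero-support regions are flagged, not errors
  expect_true(s$r1$zero_support)
})

test_that("collapsed recount credits excluded-only reads to the representative", {
  fx <- support_fixture()
  s <- cohort_allele_support(fx$u, fx$atlas, min_support = 2L,
                             strict = TRUE)   # resolved {a1}, retained a2
  hits <- data.frame(
    read_id = c("x1", "x1", "x2", "x3", "x3", "x4"),
    region_id = "r2",
    allele_id = c("a2", "a3", "a1", "a1", "a2", "a3"),
    offset = 0L, strand = "+", stringsAsFactors = FALSE)
  up <- recount_with_collapsed_alleles(hits, s)
  # x1 hit only excluded alleles -> credited to a2 (representative);
  # x2 unique to a1; x3 mixes resolved+excluded -> stays multi; x4 -> a2
  expect_equal(up$count[up$allele_id == "a1"], 1L)
  expect_equal(up$count[up$allele_id == "a2"], 2L)
  expect_false("a3" %in% up$allele_id)
  # collapsing only ever adds unique mappers
  plain <- unique_mapper_counts(hits)
  expect_gte(sum(up$count), sum(plain$count))
})

test_that("collapsing adds unique mappers across a simulated cohort", {
  cfg <- iso_config(seed = 81, n_participants = 4L, n_twin_pairs = 0L,
                    depth = 300L)
  atlas <- simulate_atlas(cfg)
  truth <- simulate_cohort(atlas, cfg)
  reads <- simulate_reads(truth, atlas, cfg)
  idx <- build_read_index(atlas)
  hits <- lapply(reads, function(r) map_reads_perfect(idx, r, "full"))
  u_list <- lapply(hits, unique_mapper_counts)
  u <- do.call(rbind, lapply(names(u_list), function(p)
    cbind(participant_id = p, u_list[[p]])))
  s <- cohort_allele_support(u, atlas, min_support = 50L)
  for (p in names(hits)) {
    up <- recount_with_collapsed_alleles(hits[[p]], s)
    expect_gte(sum(up$count), sum(u_list[[p]]$count))
  }
})

test_that("segment depth follows both formula modes and the median QC", {
  regions <- data.frame(region_id = "rA", subunit_id = "18S",
                        region_class = "ES", start = 1L, end = 500L,
                        length = 500L, stringsAsFactors = FALSE)
  u <- data.frame(participant_id = c("P1", "P2", "P3"),
                  region_id = "rA", allele_id = "a1",
                  count = c(100L, 100L, 90L), stringsAsFactors = FALSE)
  d <- segment_depth(u, regions, read_length = 150L, mode = "coverage",
                     min_median = 30)
  expect_equal(d$per_participant$depth[1L], 100 * 150 / 500)  # = 30
  expect_equal(d$per_region$median_depth, 30)
  expect_true(d$per_region$pass_qc)
  lit <- segment_depth(u, regions, mode = "literal", min_median = 30)
  expect_equal(lit$per_participant$depth[1L], 100 / 500)
  expect_false(lit$per_region$pass_qc)
  # cohort median just under the threshold excludes the region
  u2 <- u; u2$count <- c(99L, 99L, 99L)
  d2 <- segment_depth(u2, regions, min_median = 30)
  expect_false(d2$per_region$pass_qc)
  # zero counts give zero depth
  u3 <- u; u3$count <- 0L
  expect_equal(unique(segment_depth(u3, regions)$per_participant$depth), 0)
})

test_that("resolve_frequencies zeroes sub-copy alleles and renormalizes", {
  fx <- support_fixture()
  s <- cohort_allele_support(fx$u, fx$atlas, min_support = 2L)
  up_even <- data.frame(region_id = "r2", allele_id = c("a1", "a2"),
                        count = c(100L, 100L), stringsAsFactors = FALSE)
  r <- resolve_frequencies(up_even, c45S = 400, s)
  r2 <- r[r$region_id == "r2", ]
  expect_equal(r2$pi[r2$allele_id %in% c("a1", "a2")], c(0.5, 0.5))
  expect_equal(r2$copy[r2$allele_id == "a1"], 200)
  expect_equal(r2$maf[1L], 0.5)
  expect_equal(r2$burden[1L], 0.5)
  # a 0.2% allele at c45S = 400 is 0.8 copies -> zeroed -> MAF 1, burden 0
  up_rare <- data.frame(region_id = "r2", allele_id = c("a1", "a2"),
                        count = c(998L, 2L), stringsAsFactors = FALSE)
  rr <- resolve_frequencies(up_rare, c45S = 400, s)
  rr2 <- rr[rr$region_id == "r2", ]
  expect_equal(rr2$copy_star[rr2$allele_id == "a2"], 0)
  expect_equal(rr2$pi_star[rr2$allele_id == "a1"], 1)
  expect_equal(rr2$maf[1L], 1)
  expect_equal(rr2$burden[1L], 0)
  # normalization invariants
  expect_equal(sum(r2$pi), 1, tolerance = 1e-9)
  expect_equal(sum(r2$pi_star), 1, tolerance = 1e-9)
  expect_true(all(rr2$copy_star == 0 | rr2$copy_star >= 1))
  # raising the zero threshold never adds nonzero copies
  r_hi <- resolve_frequencies(up_rare, c45S = 400, s, zero_threshold = 5)
  expect_lte(sum(r_hi$copy_star > 0), sum(rr$copy_star > 0))
})

test_that("all-zero copy regions are flagged unresolved", {
  fx <- support_fixture()
  s <- cohort_allele_support(fx$u, fx$atlas, min_support = 2L)
  up <- data.frame(region_id = "r2", allele_id = c("a1", "a2"),
                   count = c(5L, 5L), stringsAsFactors = FALSE)
  r <- resolve_frequencies(up, c45S = 1, s)   # 0.5 copies each -> all zeroed
  expect_true(all(r$unresolved[r$region_id == "r2"]))
  expect_true(all(is.na(r$pi_star[r$region_id == "r2"])))
})

test_that("burden table masks QC failures and annotates region class", {
  fx <- support_fixture()
  s <- cohort_allele_support(fx$u, fx$atlas, min_support = 2L)
  up <- data.frame(region_id = "r2", allele_id = c("a1", "a2"),
                   count = c(100L, 100L), stringsAsFactors = FALSE)
  res <- list(P1 = resolve_frequencies(up, 400, s),
              P2 = resolve_frequencies(up, 400, s))
  qc <- data.frame(region_id = c("r1", "r2", "r3"),
                   median_depth = c(50, 10, 50),
                   pass_qc = c(TRUE, FALSE, TRUE), stringsAsFactors = FALSE)
  tab <- region_burden_table(res, depth_qc = qc, regions = fx$atlas$regions)
  expect_true(all(is.na(tab$burden[, "r2"])))
  expect_equal(tab$region_class[["r2"]], "non-ES")
  tab2 <- region_burden_table(res, regions = fx$atlas$regions)
  expect_equal(unname(tab2$burden[, "r2"]), c(0.5, 0.5))
})

test_that("full pipeline reduces to plain unique frequencies when all alleles resolve", {
  cfg <- iso_config(seed = 91, n_participants = 6L, n_twin_pairs = 0L,
                    depth = 500L, alleles_per_region = 3L)
  atlas <- simulate_atlas(cfg)
  truth <- simulate_cohort(atlas, cfg)
  reads <- simulate_reads(truth, atlas, cfg)
  idx <- build_read_index(atlas)
  hits <- lapply(reads, function(r)
    map_reads_perfect(idx, r, "quality_masked"))
  cn <- stats::setNames(truth$participants$c45S_true,
                        truth$participants$participant_id)
  pipe <- rdna_burden(hits, atlas, cn, min_support = 1L, min_median = 0)
  # every allele is resolvable at this depth: A-bar == A
  expect_true(all(vapply(pipe$support, function(s)
    is.null(s$retained), TRUE)))
  # so u+ equals plain unique-mapper counts
  for (p in names(hits)) {
    plain <- unique_mapper_counts(hits[[p]])
    up <- pipe$u_plus[pipe$u_plus$participant_id == p,
                      c("region_id", "allele_id", "count")]
    rownames(up) <- NULL
    expect_equal(up, plain)
  }
  # burden stays in [0, 1] and pi* sums to 1 per resolved region
  b <- pipe$tables$burden
  expect_true(all(b[!is.na(b)] >= 0 & b[!is.na(b)] <= 1))
  for (r in pipe$results) {
    for (rid in unique(r$region_id[!r$unresolved])) {
      expect_equal(sum(r$pi_star[r$region_id == rid]), 1, tolerance = 1e-9)
      expect_equal(sum(r$pi[r$region_id == rid]), 1, tolerance = 1e-9)
    }
  }
})

test_that("burden recovers germline proportions and tracks somatic load", {
  # germline-only twins/cohort: single dominant germline allele per region,
  # no somatic injection -> burden 0 after sub-copy zeroing
  cfg <- iso_config(seed = 101, n_participants = 4L, n_twin_pairs = 0L,
                    depth = 2000L, alleles_per_region = 4L,
                    germline_alleles_per_region = 1L, somatic_rate = 0)
  atlas <- simulate_atlas(cfg)
  truth <- simulate_cohort(atlas, cfg)
  reads <- simulate_reads(truth, atlas, cfg)
  idx <- build_read_index(atlas)
  hits <- lapply(reads, function(r)
    map_reads_perfect(idx, r, "quality_masked"))
  cn <- stats::setNames(truth$participants$c45S_true,
                        truth$participants$participant_id)
  pipe <- rdna_burden(hits, atlas, cn, min_median = 0)
  b <- pipe$tables$burden
  expect_true(all(b[!is.na(b)] == 0))
  # with somatic injection well above one copy-equivalent, burden > 0
  cfg2 <- iso_config(seed = 101, n_participants = 4L, n_twin_pairs = 0L,
                     depth = 2000L, alleles_per_region = 4L,
                     germline_alleles_per_region = 1L, somatic_rate = 0.05)
  truth2 <- simulate_cohort(atlas, cfg2)
  reads2 <- simulate_reads(truth2, atlas, cfg2)
  hits2 <- lapply(reads2, function(r)
    map_reads_perfect(idx, r, "quality_masked"))
  pipe2 <- rdna_burden(hits2, atlas, cn, min_median = 0)
  b2 <- pipe2$tables$burden
  expect_gt(mean(b2[!is.na(b2)]), 0.02)
})
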